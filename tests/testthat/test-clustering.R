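test_that("the family threshold is the base distance plus the average RMSD", {
  expect_equal(family_threshold(0), 2.0)
  expect_equal(family_threshold(2.5), 4.5)
  expect_equal(family_threshold(1.0, base = 3.0), 4.0)
  expect_error(family_threshold(-0.1))
})

test_that("threshold semantics merge close pockets and split distant ones", {
  one <- pocket_table(pocket_row("s1", "a", c(0, 0, 0), 10))
  r1 <- cluster_pockets(one, 2)
  expect_length(r1$clusters, 1)
  expect_equal(r1$clusters[[1]]$n_c, 1)

  two_near <- pocket_table(pocket_row("s1", "a", c(0, 0, 0), 10),
                           pocket_row("s2", "b", c(1, 0, 0), 10))
  expect_length(cluster_pockets(two_near, 2)$clusters, 1)
  two_far <- pocket_table(pocket_row("s1", "a", c(0, 0, 0), 10),
                          pocket_row("s2", "b", c(3, 0, 0), 10))
  expect_length(cluster_pockets(two_far, 2)$clusters, 2)
  # boundary: distance exactly at the threshold is a neighbor
  two_edge <- pocket_table(pocket_row("s1", "a", c(0, 0, 0), 10),
                           pocket_row("s2", "b", c(2, 0, 0), 10))
  expect_length(cluster_pockets(two_edge, 2)$clusters, 1)

  expect_length(cluster_pockets(one[0, ], 2)$clusters, 0)
})

test_that("greedy clustering matches the brute-force oracle on planted blobs", {
  for (seed in 1:5) {
    set.seed(seed)
    blob_centers <- rbind(c(0, 0, 0), c(20, 0, 0), c(0, 25, 0))
    centers <- do.call(rbind, lapply(1:3, function(k)
      sweep(matrix(rnorm(15, sd = 1), 5), 2, blob_centers[k, ], "+")))
    centers <- rbind(centers, matrix(runif(15, -40, 40), 5))
    n <- nrow(centers)
    sizes <- sample(20:120, n, replace = TRUE)
    ids <- sprintf("p%02d", seq_len(n))
    pk <- do.call(pocket_table, lapply(seq_len(n), function(i)
      pocket_row("s1", ids[i], centers[i, ], sizes[i])))
    got <- cluster_pockets(pk, 4)
    want <- oracle_greedy(centers, sizes, ids, 4)
    expect_length(got$clusters, length(want))
    for (k in seq_along(want)) {
      expect_equal(got$clusters[[k]]$founder, want[[k]]$founder)
      expect_equal(sort(got$clusters[[k]]$members), want[[k]]$members)
    }
  }
})

test_that("clustering partitions the input and respects the founder-distance bound", {
  set.seed(99)
  n <- 30
  centers <- matrix(runif(3 * n, 0, 30), n)
  pk <- do.call(pocket_table, lapply(seq_len(n), function(i)
    pocket_row(sprintf("s%d", (i %% 5) + 1), sprintf("p%02d", i),
               centers[i, ], sample(10:100, 1))))
  res <- cluster_pockets(pk, 5)
  all_members <- unlist(lapply(res$clusters, `[[`, "members"))
  expect_equal(sort(all_members), 1:n)          # exactly once each
  expect_equal(sum(vapply(res$clusters, `[[`, integer(1), "n_c")), n)
  for (cl in res$clusters) {
    f <- match(cl$founder, pk$pocket_id)
    d <- sqrt(colSums((t(centers[cl$members, , drop = FALSE]) -
                         centers[f, ])^2))
    expect_true(all(d <= 5 + 1e-12))
  }
})

test_that("raising the threshold does not increase the cluster count", {
  set.seed(123)
  n <- 25
  centers <- matrix(runif(3 * n, 0, 30), n)
  sizes <- sample(seq(10, 500, by = 7), n)   # distinct sizes: unique greedy
  pk <- do.call(pocket_table, lapply(seq_len(n), function(i)
    pocket_row("s1", sprintf("p%02d", i), centers[i, ], sizes[i])))
  counts <- vapply(c(1, 2, 4, 8, 16, 32),
                   function(th) length(cluster_pockets(pk, th)$clusters),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 1)
})

test_that("structural conservation is the percentage of covered representatives", {
  cl <- list(structure_ids = c("s1", "s2", "s3", "s3"))
  expect_equal(structural_conservation(cl, m = 5), 60)
  expect_equal(structural_conservation(cl, m = 3), 100)
  expect_error(structural_conservation(cl, m = 0))
})

test_that("cluster score combines mean member size with coverage", {
  pk <- pocket_table(pocket_row("s1", "a", c(0, 0, 0), 10),
                     pocket_row("s2", "b", c(0.5, 0, 0), 20),
                     pocket_row("s3", "c", c(1, 0, 0), 30))
  tab <- score_and_rank(cluster_pockets(pk, 2), m = 10)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_c, 3)
  expect_equal(tab$n_r, 3)
  expect_equal(tab$str_c, 30)
  expect_equal(tab$score_c, 20 * 30)   # mean size 20 x coverage 30%
})

test_that("equal mean sizes rank by coverage; ranks start at 1", {
  pk <- pocket_table(
    # cluster A: coverage 80% (4 of 5 reps), mean size 50
    pocket_row("s1", "a1", c(0, 0, 0), 50),
    pocket_row("s2", "a2", c(0.3, 0, 0), 50),
    pocket_row("s3", "a3", c(0.6, 0, 0), 50),
    pocket_row("s4", "a4", c(0.9, 0, 0), 50),
    # cluster B: coverage 40% (2 of 5), mean size 50
    pocket_row("s1", "b1", c(30, 0, 0), 50),
    pocket_row("s2", "b2", c(30.3, 0, 0), 50)
  )
  tab <- score_and_rank(cluster_pockets(pk, 2), m = 5)
  expect_equal(tab$cluster_rank, c(1, 2))
  expect_equal(tab$str_c, c(80, 40))
  expect_equal(tab$founder, c("a1", "b1"))

  single <- score_and_rank(cluster_pockets(pk[1, ], 2), m = 5)
  expect_equal(single$cluster_rank, 1)
})
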