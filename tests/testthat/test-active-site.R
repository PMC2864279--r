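test_that("active sites map to the pocket holding the residue majority", {
  pk <- pocket_table(
    pocket_row("s1", "A", c(0, 0, 0), 50, "A:1;A:2;A:3;A:4"),
    pocket_row("s1", "B", c(20, 0, 0), 40, "A:10;A:11"),
    pocket_row("s2", "C", c(0, 0, 0), 40, "A:1")
  )
  # all residues in one pocket: unambiguous
  m1 <- map_active_site(list(structure_id = "s1",
                             residues = c("A:1", "A:2", "A:3")), pk)
  expect_equal(m1$pocket_id, "A")
  expect_false(m1$ambiguous)

  # split 2 vs 1: majority wins but flagged ambiguous
  m2 <- map_active_site(list(structure_id = "s1",
                             residues = c("A:1", "A:2", "A:10")), pk)
  expect_equal(m2$pocket_id, "A")
  expect_true(m2$ambiguous)

  # no pocket contains any annotated residue
  m3 <- map_active_site(list(structure_id = "s1", residues = "A:99"), pk)
  expect_true(is.na(m3$pocket_id))
  expect_false(m3$ambiguous)

  # tie for the majority maps to none, ambiguous
  m4 <- map_active_site(list(structure_id = "s1",
                             residues = c("A:1", "A:10")), pk)
  expect_true(is.na(m4$pocket_id))
  expect_true(m4$ambiguous)

  # invariant to pocket order
  m5 <- map_active_site(list(structure_id = "s1",
                             residues = c("A:1", "A:2", "A:10")),
                        pk[c(3, 2, 1), ])
  expect_equal(m5$pocket_id, m2$pocket_id)
  expect_error(map_active_site(list(structure_id = "s1",
                                    residues = character(0)), pk), "empty")
})

test_that("the active-site cluster holds the most mapped pockets, ties by rank", {
  tab <- data.frame(
    cluster_rank = 1:3,
    member_pockets = c("a;b;c", "d;e", "f"),
    stringsAsFactors = FALSE
  )
  expect_equal(active_site_cluster(tab, c("d", "e")), 2)
  expect_equal(active_site_cluster(tab, c("a", "b", "c", "d", "e")), 1)
  expect_equal(active_site_cluster(tab, c("a", "d")), 1)  # tie -> better rank
  expect_true(is.na(active_site_cluster(tab, character(0))))
  expect_true(is.na(active_site_cluster(tab, "zzz")))
})

test_that("perfectly separable active sites give 100% recall, 0% contamination", {
  fams <- lapply(1:3, function(f) {
    rows <- list()
    act <- character(0)
    for (s in 1:5) {
      sid <- sprintf("f%d_s%d", f, s)
      pid <- paste0(sid, "|act")
      rows[[length(rows) + 1L]] <- pocket_row(sid, pid, c(0, 0, 0), 100)
      act <- c(act, pid)
      rows[[length(rows) + 1L]] <-
        pocket_row(sid, paste0(sid, "|far"), c(100, 100, 100), 50)
    }
    list(pockets = do.call(pocket_table, rows), active_pocket_ids = act,
         avg_rmsd = 0)
  })
  bench <- benchmark_thresholds(fams, fixed_values = c(0, 2, 5))
  expect_equal(bench$pct_active_sites, rep(100, 3))
  expect_equal(bench$pct_non_active, rep(0, 3))
})

test_that("an engulfing threshold drives both percentages to 100", {
  fams <- make_bench_cohort()
  bench <- benchmark_thresholds(fams, fixed_values = c(0, 50))
  expect_equal(bench$pct_active_sites[2], 100)
  expect_equal(bench$pct_non_active[2], 100)
  expect_lt(bench$pct_non_active[1], 100)
})

test_that("benchmark percentages are non-decreasing in the fixed value", {
  fams <- make_bench_cohort()
  bench <- benchmark_thresholds(fams, fixed_values = 0:10)
  expect_true(all(diff(bench$pct_active_sites) >= 0))
  expect_true(all(diff(bench$pct_non_active) >= 0))
  # add_rmsd shifts the sweep: threshold v alone vs v + avg_rmsd
  bench_abs <- benchmark_thresholds(fams, fixed_values = 0:10,
                                    add_rmsd = FALSE)
  expect_true(all(bench$pct_non_active >= bench_abs$pct_non_active))
})

test_that("planted contamination is recovered by the benchmark bookkeeping", {
  # one family: active pockets coincident; 2 of 6 decoys planted inside the
  # active-site cluster radius, 4 far away -> contamination 2/6 at small v
  rows <- list()
  act <- character(0)
  for (s in 1:4) {
    sid <- sprintf("s%d", s)
    pid <- paste0(sid, "|act")
    rows[[length(rows) + 1L]] <- pocket_row(sid, pid, c(0, 0, 0), 100)
    act <- c(act, pid)
  }
  rows[[length(rows) + 1L]] <- pocket_row("s1", "s1|near", c(1, 0, 0), 10)
  rows[[length(rows) + 1L]] <- pocket_row("s2", "s2|near", c(0, 1, 0), 10)
  for (s in 1:4) {
    rows[[length(rows) + 1L]] <- pocket_row(sprintf("s%d", s),
                                            sprintf("s%d|far", s),
                                            c(60, 0, 0), 10)
  }
  fam <- list(pockets = do.call(pocket_table, rows), active_pocket_ids = act,
              avg_rmsd = 0)
  bench <- benchmark_thresholds(list(fam), fixed_values = 2)
  expect_equal(bench$pct_active_sites, 100)
  expect_equal(bench$pct_non_active, 100 * 2 / 6)
  expect_error(benchmark_thresholds(list(), fixed_values = 2))
})
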