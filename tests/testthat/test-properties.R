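test_that("B-factor normalization is an exact per-structure z-score", {
  s <- toy_structure(gen_scaffold(3), bfactors = c(10, 20, 30))
  prof <- normalize_bfactors(s)
  expect_equal(prof$bprime, c(-1, 0, 1))

  set.seed(4)
  s2 <- toy_structure(gen_scaffold(50), bfactors = rnorm(50, 40, 15))
  p2 <- normalize_bfactors(s2)
  expect_equal(mean(p2$bprime), 0, tolerance = 1e-9)
  expect_equal(sd(p2$bprime), 1, tolerance = 1e-9)

  s3 <- toy_structure(gen_scaffold(5), bfactors = rep(7, 5))
  expect_warning(p3 <- normalize_bfactors(s3), "constant")
  expect_equal(p3$bprime, rep(0, 5))
})

test_that("normalized B factors are invariant to affine rescaling", {
  set.seed(5)
  b <- rnorm(40, 50, 10)
  s1 <- toy_structure(gen_scaffold(40), bfactors = b)
  s2 <- toy_structure(gen_scaffold(40), bfactors = 3.7 * b + 12)
  expect_equal(normalize_bfactors(s1)$bprime, normalize_bfactors(s2)$bprime,
               tolerance = 1e-9)
})

test_that("NMR pseudo B factors follow the RMSF closed form", {
  coords <- gen_scaffold(30)
  # identical models: zero fluctuation
  s0 <- toy_structure(coords, models = list(coords, coords, coords),
                      method = "nmr", resolution = NA)
  expect_equal(nmr_pseudo_bfactors(s0)$rmsf, rep(0, 30))

  # one residue displaced 2 A between two models: each model sits 1 A from
  # the mean, so RMSF = 1 and pseudo-B = 8 pi^2 / 3
  m1 <- coords
  m2 <- coords
  m2[10, 1] <- m2[10, 1] + 2
  # displace a far-away residue symmetrically so the rigid fit stays identity
  # (the bulk of residues anchors the superposition)
  s <- toy_structure(coords, models = list(m1, m2), method = "nmr",
                     resolution = NA)
  prof <- nmr_pseudo_bfactors(s)
  expect_equal(prof$rmsf[10], 1.0, tolerance = 0.05)
  expect_equal(prof$pseudo_b[10], 8 * pi^2 / 3 * prof$rmsf[10]^2,
               tolerance = 1e-9)
  expect_equal(8 * pi^2 / 3, 26.3189, tolerance = 1e-4)
  expect_error(nmr_pseudo_bfactors(toy_structure(coords)), "ensemble")
})

test_that("pocket flexibility classification separates extremes and never both", {
  prof <- list(structure_id = "x",
               bprime = c(rep(2, 10), rep(0, 90)), source = "bfactor")
  class(prof) <- "flex_profile"
  hi <- pocket_flexibility_test(prof, 1:10)
  expect_equal(hi$flex_class, "flexible")

  prof$bprime <- c(rep(-2, 10), rep(0, 90))
  lo <- pocket_flexibility_test(prof, 1:10)
  expect_equal(lo$flex_class, "rigid")
  expect_error(pocket_flexibility_test(prof, integer(0)), "empty")

  # one-sided p-values are complementary up to tie corrections
  set.seed(6)
  for (i in 1:20) {
    prof$bprime <- rnorm(80)
    r <- pocket_flexibility_test(prof, sample(80, 10))
    expect_true(r$flex_class %in% c("flexible", "rigid", "neither"))
    expect_gte(r$p_greater + r$p_less, 1 - 1e-9)
    expect_false(r$p_greater <= 0.05 && r$p_less <= 0.05)
  }
})

test_that("screened Coulomb potential matches its closed form", {
  # no charged residues
  s0 <- toy_structure(gen_scaffold(10),
                      sequence = paste(rep("A", 10), collapse = ""))
  expect_equal(pocket_potential(s0, c(0, 0, 0)), 0)

  # +1 and -1 equidistant from the probe point cancel
  coords <- rbind(c(5, 0, 0), c(-5, 0, 0))
  s1 <- toy_structure(coords, sequence = "KD", id = "pair")
  expect_equal(pocket_potential(s1, c(0, 0, 0)), 0, tolerance = 1e-12)

  # single +1 charge at 5 A: phi = (560.74 / eps) * exp(-r/lambda) / r
  s2 <- toy_structure(matrix(c(5, 0, 0), 1, 3,
                             dimnames = list(NULL, c("x", "y", "z"))),
                      sequence = "R", id = "lone")
  got <- pocket_potential(s2, c(0, 0, 0), dielectric = 80, debye_length = 8)
  expect_equal(got, 560.74 / 80 * exp(-5 / 8) / 5, tolerance = 1e-10)

  # additive over charges, monotone decay with distance
  s3 <- toy_structure(rbind(c(5, 0, 0), c(0, 7, 0)), sequence = "RK",
                      id = "two")
  expect_equal(pocket_potential(s3, c(0, 0, 0)),
               pocket_potential(s2, c(0, 0, 0)) +
                 560.74 / 80 * exp(-7 / 8) / 7, tolerance = 1e-10)
  pots <- vapply(c(2, 4, 8, 16), function(d)
    pocket_potential(s2, c(5 - d, 0, 0)), numeric(1))
  expect_true(all(diff(pots) < 0))
})

test_that("cluster summaries aggregate member flags independent of order", {
  cl <- list(cluster_rank = 1L, n_c = 4L, str_c = 80,
             member_ids = c("p1", "p2", "p3", "p4"))
  reports <- data.frame(
    pocket_id = c("p3", "p1", "p4", "p2"),
    seq_significant = c(TRUE, TRUE, FALSE, NA),
    flex_class = c("flexible", "rigid", "neither", "neither"),
    potential_kT_e = c(1, 2, 3, 4), stringsAsFactors = FALSE
  )
  s <- summarize_cluster(cl, reports)
  expect_equal(s$pct_seq_conserved, 50)
  expect_equal(s$pct_flexible, 25)
  expect_equal(s$pct_rigid, 25)
  expect_equal(s$mean_potential, 2.5)
  s2 <- summarize_cluster(cl, reports[c(2, 4, 1, 3), ])
  expect_equal(s, s2)

  cl_bad <- cl
  cl_bad$member_ids <- c("p1", "zzz")
  expect_error(summarize_cluster(cl_bad, reports), "missing")
})
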