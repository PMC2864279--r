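# Shared synthetic cohorts for the benchmark and pipeline tests.

# Tightly co-located active-site pockets plus smaller decoy pockets at graded
# distances, each decoy in its own direction so decoys never chain together
# and the active-site cluster grows radially with the threshold.
make_bench_cohort <- function(n_fam = 4, seed = 17) {
  set.seed(seed)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  lapply(seq_len(n_fam), function(f) {
    rows <- list()
    act <- character(0)
    for (s in 1:6) {
      sid <- sprintf("f%d_s%d", f, s)
      pid <- paste0(sid, "|act")
      rows[[length(rows) + 1L]] <-
        pocket_row(sid, pid, c(0, 0, 0) + rnorm(3, sd = 0.2), 100)
      act <- c(act, pid)
      dists <- c(3, 5, 7, 9)
      for (k in seq_along(dists)) {
        rows[[length(rows) + 1L]] <-
          pocket_row(sid, sprintf("%s|d%d", sid, dists[k]),
                     dists[k] * dirs[k, ] + rnorm(3, sd = 0.2), 20)
      }
    }
    list(pockets = do.call(pocket_table, rows), active_pocket_ids = act,
         avg_rmsd = 0.5)
  })
}

# Family fixture with a planted active site and a distant, fully conserved
# second pocket; conserved alignment columns surround the active site.
make_pipeline_fixture <- function(dir, seed = 7, m = 6) {
  cons <- which(colSums((t(gen_scaffold(60)) - c(0, 0, 20))^2) <= 64)
  b <- gen_family(seed = seed, m = m, n_res = 60, noise_sigma = 0.5,
                  clusters = list(planted_cluster(c(0, 0, 20)),
                                  planted_cluster(c(0, 0, 75))),
                  conserved_residues = cons, active_site_cluster = 1)
  list(bundle = b, paths = write_family_fixture(b, dir))
}
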