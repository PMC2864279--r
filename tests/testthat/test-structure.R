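test_that("PDB reading extracts the Calpha trace, B factors and header metadata", {
  path <- write_tiny_pdb()
  s <- read_structure(path)
  expect_s3_class(s, "protein_structure")
  expect_equal(n_residues(s), 3)          # HETATM zinc ignored
  expect_equal(s$bfactors, c(10, 20, 30))
  expect_equal(s$sequence, "AGS")
  expect_equal(s$method, "xray")
  expect_equal(s$resolution, 1.8)
  expect_equal(residue_keys(s), c("A:1", "A:2", "A:3"))
  expect_equal(unname(s$calpha_coords[, 1]), c(1.0, 4.8, 8.6))
})

test_that("multi-model files populate the ensemble with zero self-displacement", {
  coords <- gen_scaffold(35)
  s <- toy_structure(coords, method = "nmr", resolution = NA,
                     models = list(coords, coords))
  path <- tempfile(fileext = ".pdb")
  write_structure_pdb(s, path)
  r <- read_structure(path)
  expect_equal(r$method, "nmr")
  expect_length(r$models, 2)
  expect_equal(r$models[[1]], r$models[[2]])
  disp <- sqrt(rowSums((r$models[[1]] - r$models[[2]])^2))
  expect_equal(disp, rep(0, 35))
})

test_that("unreadable and Calpha-free inputs raise errors", {
  expect_error(read_structure(tempfile()), "cannot read")
  p <- tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1 ZN    ZN A   1       0.0     0.0     0.0  1.00  1.00",
               "END"), p)
  expect_error(read_structure(p))
})

test_that("quality filters drop poor resolution, missing resolution and short spans", {
  mk <- function(id, method, res, n = 40, gf = NA) {
    s <- toy_structure(gen_scaffold(n), id = id, method = method,
                       resolution = res)
    s$gfactor <- gf
    s
  }
  xray_ok <- mk("a", "xray", 2.5)
  xray_bad <- mk("b", "xray", 3.2)
  no_res <- mk("c", "other", NA)
  nmr_ok <- mk("d", "nmr", NA)
  nmr_short <- mk("e", "nmr", NA, n = 25)
  bad_gf <- mk("f", "xray", 1.5, gf = -1.5)
  ok_gf <- mk("g", "xray", 1.5, gf = -0.2)
  kept <- apply_quality_filters(list(xray_ok, xray_bad, no_res, nmr_ok,
                                     nmr_short, bad_gf, ok_gf))
  expect_equal(vapply(kept, `[[`, character(1), "id"), c("a", "d", "g"))
  # boundary: resolution exactly at the cutoff passes
  expect_length(apply_quality_filters(list(mk("h", "xray", 3.0))), 1)
  # idempotence
  expect_identical(apply_quality_filters(kept), kept)
})

test_that("representative selection groups at 95% identity and keeps best resolution", {
  seq0 <- paste(rep(c("A", "C", "D", "E", "F"), 20), collapse = "")
  mk <- function(id, seq, method = "xray", res = 2.0) {
    toy_structure(gen_scaffold(nchar(seq)), sequence = seq, id = id,
                  method = method, resolution = res)
  }
  # four identical sequences: single group, best resolution wins over NMR
  fam <- family_set("f", list(mk("w", seq0, res = 2.8), mk("x", seq0, res = 1.9),
                              mk("y", seq0, res = 2.5),
                              mk("z", seq0, "nmr", NA)))
  out <- select_representatives(fam)
  expect_equal(out$representative_ids, "x")
  expect_equal(out$m, 1)

  # three mutually dissimilar sequences stay separate
  mut <- function(seq, at) {
    v <- strsplit(seq, "")[[1]]
    v[at] <- ifelse(v[at] == "G", "W", "G")
    paste(v, collapse = "")
  }
  s1 <- seq0
  s2 <- mut(seq0, seq(1, 100, by = 10))   # 10% mutated
  s3 <- mut(s2, seq(2, 100, by = 10))
  fam3 <- family_set("f", list(mk("a", s1), mk("b", s2), mk("c", s3)))
  out3 <- select_representatives(fam3)
  expect_equal(out3$m, 3)
})

test_that("complete linkage forbids groups with any sub-threshold pair", {
  seq0 <- paste(rep(c("A", "C", "D", "E", "F"), 20), collapse = "")
  mut <- function(seq, at) {
    v <- strsplit(seq, "")[[1]]; v[at] <- "G"; paste(v, collapse = "")
  }
  # a~b = 97%, b~c = 97%, a~c = 94%: a and c can never share a group
  a <- seq0
  b <- mut(seq0, c(3, 8, 13))
  c_ <- mut(b, c(22, 27, 33))
  expect_equal(sequence_identity(a, b), 0.97)
  expect_equal(sequence_identity(b, c_), 0.97)
  expect_equal(sequence_identity(a, c_), 0.94)
  mk <- function(id, seq) toy_structure(gen_scaffold(100), sequence = seq,
                                        id = id, resolution = 2.0)
  fam <- family_set("f", list(mk("a", a), mk("b", b), mk("c", c_)))
  out <- select_representatives(fam)
  expect_equal(out$m, 2)
  # every member must be >= 95% identical to all of its group: brute-force
  # check over the valid complete-linkage cuts {ab|c} and {a|bc}
  expect_true(identical(sort(out$representative_ids), c("a", "c")) ||
                identical(sort(out$representative_ids), c("b", "c")) ||
                identical(sort(out$representative_ids), c("a", "b")))
})

test_that("reference choice: longest sequence, then resolution, then id", {
  mk <- function(id, n, res) toy_structure(gen_scaffold(n), id = id,
                                           resolution = res)
  fam <- family_set("f", list(mk("p", 120, 1.0), mk("q", 150, 2.1),
                              mk("r", 150, 1.8)))
  expect_equal(choose_reference(fam), "r")
  expect_equal(choose_reference(family_set("f", list(mk("solo", 50, 2)))),
               "solo")
  fam_tie <- family_set("f", list(mk("m2", 80, 2.0), mk("m1", 80, 2.0)))
  expect_equal(choose_reference(fam_tie), "m1")
  # determinism
  expect_equal(choose_reference(fam), choose_reference(fam))
})

test_that("family manifest round-trips through TSV", {
  fam <- family_set("famX", list(toy_structure(gen_scaffold(40), id = "s1"),
                                 toy_structure(gen_scaffold(45), id = "s2")),
                    representative_ids = c("s1", "s2"), reference_id = "s2")
  p <- tempfile(fileext = ".tsv")
  df <- write_family_manifest(fam, p)
  back <- read.table(p, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 2)
  expect_equal(back$n_residues, c(40, 45))
  expect_equal(back$is_reference, c(FALSE, TRUE))
})
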