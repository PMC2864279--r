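# Independent oracles and tiny fixture builders used across the suite.
# Each oracle is coded from first principles, independent of the package
# internals it cross-checks.

# Optimal superposition RMSD via Horn's quaternion eigenvalue method.
rmsd_quaternion <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- t(bc) %*% ac
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  nmat <- matrix(c(
    sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(nmat, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(ac^2) + sum(bc^2) - 2 * lambda) / n
  sqrt(max(msd, 0))
}

# Brute-force greedy clustering: recomputes every pairwise distance and
# every score from scratch at each round, plain loops throughout.
oracle_greedy <- function(centers, sizes, ids, threshold) {
  pool <- seq_len(nrow(centers))
  clusters <- list()
  edist <- function(i, j) sqrt(sum((centers[i, ] - centers[j, ])^2))
  while (length(pool)) {
    best <- NA; best_score <- -Inf; best_id <- NA
    for (e in pool) {
      sc <- 0
      for (f in pool) if (edist(e, f) <= threshold) sc <- sc + sizes[f]
      if (sc > best_score || (sc == best_score && ids[e] < best_id)) {
        best <- e; best_score <- sc; best_id <- ids[e]
      }
    }
    members <- pool[vapply(pool, function(f) edist(best, f) <= threshold,
                           logical(1))]
    clusters[[length(clusters) + 1L]] <- list(founder = ids[best],
                                              members = sort(members))
    pool <- setdiff(pool, members)
  }
  clusters
}

# Direct weighted-entropy + z-score recomputation, loops only.
oracle_conservation <- function(msa, weights) {
  rows <- strsplit(unname(msa), "")
  L <- length(rows[[1]])
  H <- numeric(L)
  for (j in seq_len(L)) {
    syms <- vapply(rows, `[[`, character(1), j)
    tot <- sum(weights)
    h <- 0
    for (s in unique(syms)) {
      f <- sum(weights[syms == s]) / tot
      h <- h - f * log(f)
    }
    H[j] <- h
  }
  (mean(H) - H) / sd(H)
}

# Exact one-sided Mann-Whitney p by enumeration over all group assignments
# (no ties assumed; small n only).
oracle_mw_exact <- function(x, y) {
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  all_v <- c(x, y)
  combos <- utils::combn(length(all_v), length(x))
  ps <- apply(combos, 2, function(ix) {
    xx <- all_v[ix]; yy <- all_v[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  mean(ps >= u_obs)
}

# Hand-rolled PDB text for reader tests.
tiny_pdb_lines <- function() {
  c(
    "EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.    1.80 ANGSTROMS.",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  5.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00 10.00           C",
    "ATOM      3  CA  GLY A   2       4.800   0.000   0.000  1.00 20.00           C",
    "ATOM      4  CA  SER A   3       8.600   0.000   0.000  1.00 30.00           C",
    "HETATM    5 ZN    ZN A 101       2.000   2.000   2.000  1.00 15.00          ZN",
    "END"
  )
}

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(tiny_pdb_lines(), path)
  path
}

# Minimal structure straight from coordinates (no file round trip).
toy_structure <- function(coords, sequence = NULL, bfactors = NULL,
                          id = "toy", method = "xray", resolution = 2.0,
                          models = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(sequence)) sequence <- paste(rep("A", n), collapse = "")
  if (is.null(bfactors)) bfactors <- rep(10, n)
  residues <- data.frame(chain = rep("A", n), resno = seq_len(n),
                         insert = rep("", n),
                         resid = rep("ALA", n), stringsAsFactors = FALSE)
  protein_structure(id = id, residues = residues, calpha_coords = coords,
                    bfactors = bfactors, sequence = sequence, method = method,
                    resolution = resolution, models = models)
}

# Pocket table row builder.
pocket_row <- function(structure_id, pocket_id, center, size,
                       residues = "") {
  data.frame(structure_id = structure_id, pocket_id = pocket_id,
             x = center[1], y = center[2], z = center[3], size = size,
             n_residues = if (residues == "") 0L else
               length(strsplit(residues, ";")[[1]]),
             residues = residues, stringsAsFactors = FALSE)
}

pocket_table <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}

# Random proper rotation for invariance tests.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
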