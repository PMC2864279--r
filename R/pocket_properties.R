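#' Normalize B factors to a per-structure z-score
#'
#' The relative backbone flexibility of a residue is the z-score of its
#' Calpha B factor within its own structure: `B' = (B - <B>) / sd(B)`, with
#' the sample (n-1) standard deviation. A degenerate structure with constant
#' B factors yields an all-zero profile with a warning.
#'
#' @param structure A [protein_structure()] with at least 2 residues carrying
#'   B factors.
#' @return A `flex_profile`: list with `structure_id`, `bprime` (per-residue)
#'   and `source = "bfactor"`.
#' @export
normalize_bfactors <- function(structure) {
  b <- structure$bfactors
  if (length(b) < 2 || anyNA(b)) {
    stop("need >= 2 residues with B factors; for NMR ensembles use ",
         "nmr_pseudo_bfactors()")
  }
  s <- stats::sd(b)
  if (s == 0) {
    warning("constant B factors in ", structure$id, "; flat flexibility profile")
    bp <- rep(0, length(b))
  } else {
    bp <- (b - mean(b)) / s
  }
  out <- list(structure_id = structure$id, bprime = bp, source = "bfactor")
  class(out) <- "flex_profile"
  out
}

#' Pseudo B factors from an NMR ensemble
#'
#' All models are rigidly superimposed onto the first model (Kabsch over all
#' Calpha), the per-residue root-mean-square fluctuation about the ensemble
#' mean position is computed, converted to a pseudo B factor via
#' `B = (8 pi^2 / 3) * RMSF^2`, and normalized as in [normalize_bfactors()].
#'
#' @param structure A multi-model [protein_structure()] (>= 2 models with
#'   identical residue lists).
#' @return A `flex_profile` with `source = "nmr_pseudo_b"`; the raw `rmsf`
#'   and `pseudo_b` vectors are attached.
#' @export
nmr_pseudo_bfactors <- function(structure) {
  models <- structure$models
  if (is.null(models) || length(models) < 2) {
    stop("need an ensemble of >= 2 models")
  }
  ref <- models[[1]]
  fitted <- lapply(models, function(m) {
    if (identical(m, ref)) return(m)
    tr <- kabsch_fit(ref, m)
    apply_transform(m, tr)
  })
  nres <- nrow(ref)
  mean_pos <- Reduce(`+`, fitted) / length(fitted)
  sq <- vapply(fitted, function(m) rowSums((m - mean_pos)^2), numeric(nres))
  rmsf <- sqrt(rowMeans(matrix(sq, nrow = nres)))
  pseudo_b <- (8 * pi^2 / 3) * rmsf^2
  s <- stats::sd(pseudo_b)
  bp <- if (is.na(s) || s == 0) rep(0, nres) else (pseudo_b - mean(pseudo_b)) / s
  out <- list(structure_id = structure$id, bprime = bp,
              source = "nmr_pseudo_b", rmsf = rmsf, pseudo_b = pseudo_b)
  class(out) <- "flex_profile"
  out
}

#' Flexibility profile for any structure
#'
#' Dispatches to [nmr_pseudo_bfactors()] for multi-model entries and
#' [normalize_bfactors()] otherwise.
#'
#' @param structure A [protein_structure()].
#' @return A `flex_profile`.
#' @export
flexibility_profile <- function(structure) {
  if (!is.null(structure$models) && length(structure$models) >= 2) {
    nmr_pseudo_bfactors(structure)
  } else {
    normalize_bfactors(structure)
  }
}

#' Classify a pocket as flexible, rigid or neither
#'
#' Two one-sided Wilcoxon-Mann-Whitney tests compare the pocket residues'
#' normalized B factors against those of the whole structure (background
#' includes the pocket). Significantly higher marks the pocket `flexible`,
#' significantly lower `rigid`, otherwise `neither`; the two outcomes cannot
#' co-occur at `alpha < 0.5`.
#'
#' @param profile A `flex_profile`.
#' @param pocket_index Integer indices (into the profile) of the pocket's
#'   residues.
#' @param alpha Significance level.
#' @return List with `flex_class`, `p_greater`, `p_less`.
#' @export
pocket_flexibility_test <- function(profile, pocket_index, alpha = 0.05) {
  if (length(pocket_index) == 0) stop("empty pocket")
  x <- profile$bprime[pocket_index]
  y <- profile$bprime
  pg <- .mw_p(x, y, "greater")
  pl <- .mw_p(x, y, "less")
  cls <- if (pg <= alpha) "flexible" else if (pl <= alpha) "rigid" else "neither"
  list(flex_class = cls, p_greater = pg, p_less = pl)
}

# Bjerrum length of vacuum at 298 K: e^2 / (4 pi eps0 kT), in Angstrom.
# Dividing by the relative dielectric gives the Coulomb prefactor in kT/e
# for charges in units of e and distances in Angstrom.
.COULOMB_KT_ANG <- 560.74

#' Screened Coulomb electrostatic potential at a point
#'
#' A Debye-screened Coulomb sum over residue point charges:
#' `phi = (l_B / eps) * sum_i q_i * exp(-r_i / lambda_D) / r_i` in kT/e at
#' 298 K, with unit charges -1 e on Asp/Glu and +1 e on Lys/Arg placed on the
#' Calpha (the only atom retained in this representation). Distances are
#' floored at 1 Angstrom. This is a deliberately simple point-charge model:
#' its sign and relative magnitude distinguish charged from neutral pockets,
#' but its absolute values are not comparable to potentials from a
#' Poisson-Boltzmann solver.
#'
#' @param structure A [protein_structure()].
#' @param point Numeric 3-vector, Angstrom.
#' @param dielectric Relative dielectric constant.
#' @param debye_length Screening length, Angstrom.
#' @return Potential in kT/e (0 when the structure has no charged residues).
#' @export
pocket_potential <- function(structure, point, dielectric = 80,
                             debye_length = 8) {
  if (!all(is.finite(point))) stop("point must be finite")
  aa <- strsplit(structure$sequence, "")[[1]]
  q <- ifelse(aa %in% c("D", "E"), -1, ifelse(aa %in% c("K", "R"), 1, 0))
  sel <- q != 0
  if (!any(sel)) return(0)
  r <- sqrt(colSums((t(structure$calpha_coords[sel, , drop = FALSE]) - point)^2))
  r <- pmax(r, 1)
  .COULOMB_KT_ANG / dielectric * sum(q[sel] * exp(-r / debye_length) / r)
}

#' Characterize one pocket
#'
#' Combines the sequence-conservation test, the flexibility classification
#' and the electrostatic potential at the pocket center into a per-pocket
#' property report.
#'
#' @param pocket One row of a pocket table.
#' @param structure The owning [protein_structure()] (coordinates in the same
#'   frame as the pocket center).
#' @param conservation Optional `conservation_profile` for the structure.
#' @param flex Optional `flex_profile` (default [flexibility_profile()]).
#' @param alpha Significance level for both tests.
#' @param dielectric,debye_length Passed to [pocket_potential()].
#' @return A one-row data frame: `pocket_id`, `seq_p`, `seq_significant`,
#'   `flex_p_greater`, `flex_p_less`, `flex_class`, `potential_kT_e`.
#' @export
characterize_pocket <- function(pocket, structure, conservation = NULL,
                                flex = flexibility_profile(structure),
                                alpha = 0.05, dielectric = 80,
                                debye_length = 8) {
  keys <- residue_keys(structure)
  res <- split_residues(pocket$residues)
  idx <- match(res, keys)
  idx <- idx[!is.na(idx)]
  seq_p <- NA_real_
  seq_sig <- NA
  if (!is.null(conservation) && length(idx)) {
    tst <- pocket_conservation_test(conservation$scores[idx],
                                    conservation$scores, alpha = alpha)
    seq_p <- tst$p_value
    seq_sig <- tst$significant
  }
  if (length(idx)) {
    fx <- pocket_flexibility_test(flex, idx, alpha = alpha)
  } else {
    fx <- list(flex_class = "neither", p_greater = 1, p_less = 1)
  }
  pot <- pocket_potential(structure, c(pocket$x, pocket$y, pocket$z),
                          dielectric = dielectric,
                          debye_length = debye_length)
  data.frame(
    pocket_id = pocket$pocket_id, seq_p = seq_p, seq_significant = seq_sig,
    flex_p_greater = fx$p_greater, flex_p_less = fx$p_less,
    flex_class = fx$flex_class, potential_kT_e = pot,
    stringsAsFactors = FALSE
  )
}

#' Summarize pocket properties at the cluster level
#'
#' Aggregates per-pocket reports over a cluster's members: the percentage of
#' member pockets significantly conserved in sequence, flexible, and rigid,
#' and the mean and SD of the member potentials. Percentages are computed
#' over member pockets only, independent of the cluster's family coverage.
#'
#' @param cluster A ranked cluster (element of the `clusters` attribute of
#'   [score_and_rank()]).
#' @param reports Data frame of per-pocket reports ([characterize_pocket()]
#'   rows) covering every member pocket.
#' @return A one-row data frame: `cluster_rank`, `n_c`, `str_c`,
#'   `pct_seq_conserved`, `pct_flexible`, `pct_rigid`, `mean_potential`,
#'   `sd_potential`.
#' @export
summarize_cluster <- function(cluster, reports) {
  i <- match(cluster$member_ids, reports$pocket_id)
  if (anyNA(i)) stop("missing property reports for cluster members")
  r <- reports[i, , drop = FALSE]
  data.frame(
    cluster_rank = cluster$cluster_rank,
    n_c = cluster$n_c,
    str_c = cluster$str_c,
    pct_seq_conserved = 100 * mean(r$seq_significant %in% TRUE),
    pct_flexible = 100 * mean(r$flex_class == "flexible"),
    pct_rigid = 100 * mean(r$flex_class == "rigid"),
    mean_potential = mean(r$potential_kT_e),
    sd_potential = if (nrow(r) > 1) stats::sd(r$potential_kT_e) else 0,
    stringsAsFactors = FALSE
  )
}
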