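#' Least-squares rigid superposition (Kabsch)
#'
#' Computes the proper rotation and translation that minimize the RMSD of
#' `coords_b` mapped onto `coords_a`, via singular value decomposition of the
#' cross-covariance matrix with the usual sign correction so the rotation has
#' determinant +1 (no reflection).
#'
#' @param coords_a,coords_b Numeric n x 3 matrices in 1:1 row correspondence,
#'   n >= 3, not collinear.
#' @return List with `rotation` (3 x 3), `translation` (length 3) and `rmsd`
#'   (Angstrom): `x_fitted = x_b %*% t(rotation) + translation`.
#' @export
kabsch_fit <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (nrow(a) != nrow(b) || ncol(a) != 3 || ncol(b) != 3) {
    stop("coordinate sets must be n x 3 matrices in correspondence")
  }
  n <- nrow(a)
  if (n < 3) stop("degenerate fit: need at least 3 corresponded points")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  # collinearity check: centered points must span at least a plane
  if (qr(ac)$rank < 2 || qr(bc)$rank < 2) {
    stop("degenerate fit: collinear point set")
  }
  h <- crossprod(bc, ac)                 # 3x3 cross-covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- ca - as.numeric(rot %*% cb)
  fitted <- bc %*% t(rot)
  rmsd <- sqrt(sum((ac - fitted)^2) / n)
  list(rotation = rot, translation = as.numeric(trans), rmsd = rmsd)
}

# Apply a rigid transform to an n x 3 coordinate matrix.
apply_transform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2,
        transform$translation, "+")
}

.identity_transform <- function() {
  list(rotation = diag(3), translation = c(0, 0, 0), rmsd = 0)
}

# Residue correspondences between two structures from a global sequence
# alignment; only identically aligned columns are paired. Returns a 2-column
# matrix of residue indices (ref, mem).
.sequence_correspondence <- function(ref, mem) {
  aln <- .global_align(ref$sequence, mem$sequence)
  a <- strsplit(aln$a, "")[[1]]
  b <- strsplit(aln$b, "")[[1]]
  ia <- cumsum(a != "-")
  ib <- cumsum(b != "-")
  keep <- a != "-" & b != "-" & a == b
  cbind(ref = ia[keep], mem = ib[keep])
}

#' Superimpose the representatives of a family onto its reference
#'
#' Each representative is rigidly fitted onto the reference with
#' [kabsch_fit()] over corresponded Calpha atoms. Correspondences may be
#' supplied per structure (2-column matrix of residue indices, reference
#' first); otherwise they are derived from a global sequence alignment to the
#' reference, pairing identically aligned columns only. The family threshold
#' for pocket clustering is built on `avg_rmsd`, the mean post-fit RMSD over
#' non-reference representatives; a single-representative family has
#' `avg_rmsd = 0`. With `pre_superimposed = TRUE` no transform is applied and
#' only RMSDs are computed.
#'
#' @param family A [family_set()] with a reference chosen.
#' @param correspondences Optional named list (by structure id) of 2-column
#'   residue-index matrices mapping reference residues to member residues.
#' @param pre_superimposed If `TRUE`, coordinates are taken to be in a common
#'   frame already; transforms stay identity.
#' @param min_corresponded Minimum corresponded Calpha pairs per structure.
#'
#' @return An object of class `superposed_family`: the input family with
#'   member coordinates in the reference frame, per-representative
#'   `transforms`, `per_structure_rmsd`, `avg_rmsd` and ids of structures
#'   `excluded` for insufficient correspondence.
#' @export
superimpose_family <- function(family, correspondences = NULL,
                               pre_superimposed = FALSE,
                               min_corresponded = 3) {
  if (is.null(family$reference_id)) stop("choose a reference first")
  ref <- family_member(family, family$reference_id)
  transforms <- list()
  rmsds <- numeric(0)
  excluded <- character(0)
  members <- family$members
  for (sid in family$representative_ids) {
    if (sid == family$reference_id) {
      transforms[[sid]] <- .identity_transform()
      next
    }
    mem <- family_member(family, sid)
    cor <- if (!is.null(correspondences) && !is.null(correspondences[[sid]])) {
      as.matrix(correspondences[[sid]])
    } else {
      .sequence_correspondence(ref, mem)
    }
    if (nrow(cor) < min_corresponded) {
      excluded <- c(excluded, sid)
      next
    }
    ca <- ref$calpha_coords[cor[, 1], , drop = FALSE]
    cb <- mem$calpha_coords[cor[, 2], , drop = FALSE]
    if (pre_superimposed) {
      tr <- .identity_transform()
      tr$rmsd <- sqrt(sum((ca - cb)^2) / nrow(ca))
    } else {
      tr <- tryCatch(kabsch_fit(ca, cb), error = function(e) NULL)
      if (is.null(tr)) {
        excluded <- c(excluded, sid)
        next
      }
      i <- match(sid, family$member_ids)
      members[[i]]$calpha_coords <- apply_transform(mem$calpha_coords, tr)
      if (!is.null(mem$models)) {
        members[[i]]$models <- lapply(mem$models, apply_transform, transform = tr)
      }
    }
    transforms[[sid]] <- tr
    rmsds[sid] <- tr$rmsd
  }
  fam <- family_set(family$family_id, members,
                    representative_ids = family$representative_ids,
                    reference_id = family$reference_id)
  out <- list(
    family = fam,
    transforms = transforms,
    per_structure_rmsd = rmsds,
    avg_rmsd = if (length(rmsds)) mean(rmsds) else 0,
    excluded = excluded
  )
  class(out) <- "superposed_family"
  out
}

#' @export
print.superposed_family <- function(x, ...) {
  cat(sprintf(
    "superposed_family %s: %d representatives on reference %s, avg RMSD %.3f A\n",
    x$family$family_id, x$family$m, x$family$reference_id, x$avg_rmsd
  ))
  if (length(x$excluded)) {
    cat("  excluded (insufficient correspondence):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write superposition transforms as JSON
#'
#' @param superposed A `superposed_family`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_transforms <- function(superposed, path) {
  obj <- lapply(superposed$transforms, function(tr) {
    list(rotation = unname(lapply(seq_len(3), function(i) tr$rotation[i, ])),
         translation = tr$translation, rmsd = tr$rmsd)
  })
  jsonlite::write_json(
    list(family_id = superposed$family$family_id,
         reference_id = superposed$family$reference_id,
         avg_rmsd = superposed$avg_rmsd, transforms = obj),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read residue correspondences from a two-column TSV
#'
#' @param path TSV with columns `ref_residue`, `member_residue` (1-based
#'   residue indices).
#' @return A 2-column integer matrix.
#' @export
read_correspondence_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  as.matrix(df[, 1:2])
}
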