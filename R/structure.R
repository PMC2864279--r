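#' Protein structure container
#'
#' A single protein chain/domain reduced to its Calpha trace: ordered
#' residues, Calpha coordinates, B factors, optional NMR ensemble models and
#' experimental metadata. This is the unit every downstream stage (filtering,
#' superposition, pocket detection, conservation mapping) operates on.
#'
#' @param id Character identifier, conventionally `"<entry>_<chain>"`.
#' @param residues Data frame with columns `chain`, `resno`, `insert`,
#'   `resid` (three-letter residue name), one row per Calpha-bearing residue,
#'   in file order.
#' @param calpha_coords Numeric matrix, one row per residue, columns x/y/z
#'   in Angstrom.
#' @param bfactors Numeric vector of per-residue Calpha B factors (A^2).
#' @param sequence One-letter amino-acid string, one character per residue.
#' @param method Experimental method: `"xray"`, `"nmr"` or `"other"`.
#' @param resolution Resolution in Angstrom, or `NA` when not applicable.
#' @param gfactor Optional stereochemistry G-factor supplied as external
#'   metadata; `NA` when unknown.
#' @param models Optional list of coordinate matrices (NMR ensemble), each
#'   with the same rows as `calpha_coords`.
#'
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(id, residues, calpha_coords, bfactors,
                              sequence, method = "other", resolution = NA_real_,
                              gfactor = NA_real_, models = NULL) {
  calpha_coords <- as.matrix(calpha_coords)
  storage.mode(calpha_coords) <- "double"
  n <- nrow(residues)
  stopifnot(
    nrow(calpha_coords) == n, ncol(calpha_coords) == 3,
    length(bfactors) == n, nchar(sequence) == n,
    method %in% c("xray", "nmr", "other")
  )
  if (!is.na(resolution) && resolution <= 0) {
    stop("resolution must be positive when present")
  }
  if (!is.null(models)) {
    ok <- vapply(models, function(m) nrow(m) == n && ncol(m) == 3, logical(1))
    if (!all(ok)) stop("all ensemble models must share the residue list")
    models <- lapply(models, function(m) {
      m <- as.matrix(m); storage.mode(m) <- "double"; m
    })
  }
  out <- list(
    id = as.character(id), residues = residues,
    calpha_coords = calpha_coords, bfactors = as.numeric(bfactors),
    sequence = sequence, method = method,
    resolution = as.numeric(resolution), gfactor = as.numeric(gfactor),
    models = models
  )
  class(out) <- "protein_structure"
  out
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf(
    "protein_structure %s: %d residues, method=%s, resolution=%s%s\n",
    x$id, nrow(x$residues), x$method,
    ifelse(is.na(x$resolution), "NA", sprintf("%.2f A", x$resolution)),
    if (!is.null(x$models)) sprintf(", %d models", length(x$models)) else ""
  ))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure A [protein_structure()].
#' @return Integer residue count.
#' @export
n_residues <- function(structure) nrow(structure$residues)

#' Residue identity keys
#'
#' Residues are identified by (chain, author residue number, insertion code),
#' rendered as `"chain:resno"` or `"chain:resno:insert"`.
#'
#' @param structure A [protein_structure()].
#' @return Character vector of residue keys, in structure order.
#' @export
residue_keys <- function(structure) {
  r <- structure$residues
  ins <- ifelse(is.na(r$insert) | r$insert == "", "", paste0(":", r$insert))
  paste0(r$chain, ":", r$resno, ins)
}

# Map PDB EXPDTA text onto the method enum.
.parse_method <- function(expdta) {
  if (length(expdta) == 0 || all(is.na(expdta))) return("other")
  txt <- toupper(paste(expdta, collapse = " "))
  if (grepl("NMR", txt)) return("nmr")
  if (grepl("X-RAY|XRAY", txt)) return("xray")
  "other"
}

# Extract method and resolution from raw PDB header lines.
.parse_pdb_header <- function(lines) {
  expdta <- grep("^EXPDTA", lines, value = TRUE)
  method <- .parse_method(sub("^EXPDTA\\s*", "", expdta))
  res <- NA_real_
  rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem2)) {
    tail2 <- sub(".*RESOLUTION\\.?", "", rem2[1])
    m <- regmatches(tail2, regexpr("[0-9]+\\.?[0-9]*", tail2))
    if (length(m)) res <- suppressWarnings(as.numeric(m))
  }
  list(method = method, resolution = res)
}

# Extract method/resolution from an mmCIF file's text.
.parse_cif_header <- function(lines) {
  method <- "other"
  em <- grep("_exptl\\.method", lines, value = TRUE)
  if (length(em)) method <- .parse_method(sub(".*_exptl\\.method", "", em[1]))
  res <- NA_real_
  rl <- grep("_refine\\.ls_d_res_high|_reflns\\.d_resolution_high", lines, value = TRUE)
  for (ln in rl) {
    tl <- sub(".*res(olution)?_high", "", ln)
    m <- regmatches(tl, regexpr("[0-9]+\\.?[0-9]*", tl))
    if (length(m) && !is.na(suppressWarnings(as.numeric(m)))) {
      res <- as.numeric(m); break
    }
  }
  list(method = method, resolution = res)
}

#' Read a protein structure from a PDB or mmCIF file
#'
#' Extracts the Calpha trace of one chain (or all chains) from a coordinate
#' file: residue identities, Calpha coordinates and B factors, in file order.
#' Multi-model (NMR ensemble) entries populate the `models` field; the first
#' model provides the primary coordinates and B factors. Experimental method
#' and resolution are read from the header when present. Only `ATOM` records
#' contribute; HETATM ligands and waters are ignored.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param chain Optional chain identifier; default keeps all chains.
#' @param id Structure identifier; defaults to the file base name (plus
#'   `_<chain>` when a chain is selected).
#' @param gfactor Optional externally computed stereochemistry G-factor to
#'   attach as metadata (no stereochemistry evaluation is performed here).
#'
#' @return A [protein_structure()].
#' @export
read_structure <- function(path, chain = NULL, id = NULL, gfactor = NA_real_) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, multi = TRUE, verbose = FALSE)
    else bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse structure file ", path, ": ",
                             conditionMessage(e))
  )
  lines <- readLines(path, warn = FALSE)
  hdr <- if (is_cif) .parse_cif_header(lines) else .parse_pdb_header(lines)

  atoms <- pdb$atom
  sel <- atoms$type == "ATOM" & atoms$elety == "CA"
  if (!is.null(chain)) sel <- sel & atoms$chain %in% chain
  if (!any(sel)) stop("no Calpha atoms found in ", path)
  atoms <- atoms[sel, , drop = FALSE]
  # guard against altLoc duplicates: keep first occurrence per residue
  key <- paste(atoms$chain, atoms$resno, atoms$insert)
  keep <- !duplicated(key)
  atoms <- atoms[keep, , drop = FALSE]

  residues <- data.frame(
    chain = atoms$chain, resno = atoms$resno,
    insert = ifelse(is.na(atoms$insert), "", atoms$insert),
    resid = atoms$resid, stringsAsFactors = FALSE
  )
  coords <- cbind(atoms$x, atoms$y, atoms$z)
  colnames(coords) <- c("x", "y", "z")
  seq1 <- paste(bio3d::aa321(atoms$resid), collapse = "")

  models <- NULL
  xyz <- pdb$xyz
  if (is.matrix(xyz) && nrow(xyz) > 1) {
    idx <- which(sel)[keep]
    cols <- bio3d::atom2xyz(idx)
    models <- lapply(seq_len(nrow(xyz)), function(i) {
      m <- matrix(xyz[i, cols], ncol = 3, byrow = TRUE)
      colnames(m) <- c("x", "y", "z")
      m
    })
    coords <- models[[1]]
  }

  if (is.null(id)) {
    id <- sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
    if (!is.null(chain)) id <- paste0(id, "_", chain)
  }
  protein_structure(
    id = id, residues = residues, calpha_coords = coords,
    bfactors = atoms$b, sequence = seq1,
    method = hdr$method, resolution = hdr$resolution,
    gfactor = gfactor, models = models
  )
}

#' Apply structural quality filters
#'
#' Keeps a structure when it is NMR-solved, or when a resolution value is
#' present and no worse than `min_resolution`; non-NMR entries without a
#' resolution are discarded. Entries carrying a G-factor below `min_gfactor`
#' are dropped (absent G-factor passes). Structures spanning fewer than
#' `min_span` residues are dropped. Order is preserved and the filter is
#' idempotent.
#'
#' @param structures List of [protein_structure()] objects.
#' @param min_resolution Worst acceptable resolution in Angstrom.
#' @param min_gfactor Lowest acceptable G-factor when one is attached.
#' @param min_span Minimum residue count.
#'
#' @return Filtered list of structures (possibly empty).
#' @export
apply_quality_filters <- function(structures, min_resolution = 3.0,
                                  min_gfactor = -1.00, min_span = 30) {
  keep <- vapply(structures, function(s) {
    res_ok <- s$method == "nmr" ||
      (!is.na(s$resolution) && s$resolution <= min_resolution)
    gf_ok <- is.na(s$gfactor) || s$gfactor >= min_gfactor
    span_ok <- n_residues(s) >= min_span
    res_ok && gf_ok && span_ok
  }, logical(1))
  structures[keep]
}

#' Protein family container
#'
#' Groups structures belonging to one protein family, together with the
#' selected non-redundant representatives and the reference structure used
#' for superposition. `m` is the representative count that enters the
#' structural-conservation denominator.
#'
#' @param family_id Family identifier.
#' @param members List of [protein_structure()] objects.
#' @param representative_ids Character ids of the representative subset
#'   (defaults to all members).
#' @param reference_id Id of the reference structure (defaults to unset).
#'
#' @return An object of class `family_set`.
#' @export
family_set <- function(family_id, members, representative_ids = NULL,
                       reference_id = NULL) {
  ids <- vapply(members, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate structure ids in family")
  if (is.null(representative_ids)) representative_ids <- ids
  if (!all(representative_ids %in% ids)) {
    stop("representatives must be a subset of members")
  }
  if (!is.null(reference_id) && !reference_id %in% representative_ids) {
    stop("reference must be one of the representatives")
  }
  out <- list(
    family_id = as.character(family_id), members = members,
    member_ids = ids, representative_ids = representative_ids,
    reference_id = reference_id, m = length(representative_ids)
  )
  class(out) <- "family_set"
  out
}

#' @export
print.family_set <- function(x, ...) {
  cat(sprintf(
    "family_set %s: %d members, %d representatives, reference=%s\n",
    x$family_id, length(x$members), x$m,
    ifelse(is.null(x$reference_id), "<unset>", x$reference_id)
  ))
  invisible(x)
}

#' Retrieve a member structure by id
#' @param family A [family_set()].
#' @param id Structure id.
#' @return The matching [protein_structure()].
#' @export
family_member <- function(family, id) {
  i <- match(id, family$member_ids)
  if (is.na(i)) stop("no member with id ", id)
  family$members[[i]]
}

#' Pairwise sequence identity from a global alignment
#'
#' Identity is the number of identical aligned positions divided by the full
#' alignment length (gaps included in the denominator), a simple and
#' symmetric definition.
#'
#' @param seq_a,seq_b One-letter amino-acid strings.
#' @return Fraction in `[0, 1]`.
#' @export
sequence_identity <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) return(0)
  if (seq_a == seq_b) return(1)
  aln <- .global_align(seq_a, seq_b)
  a <- strsplit(aln$a, "")[[1]]
  b <- strsplit(aln$b, "")[[1]]
  sum(a == b & a != "-") / length(a)
}

# Global (Needleman-Wunsch) alignment via Biostrings; returns the two
# gapped strings.
.global_align <- function(seq_a, seq_b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global"
  )
  list(
    a = as.character(Biostrings::alignedPattern(aln)),
    b = as.character(Biostrings::alignedSubject(aln))
  )
}

# Resolution used for ranking: NMR and missing values sort after any
# numeric resolution.
.resolution_rank <- function(s) {
  if (s$method == "nmr" || is.na(s$resolution)) Inf else s$resolution
}

#' Select non-redundant family representatives
#'
#' Members are grouped by complete-linkage hierarchical clustering on
#' pairwise sequence identity, cut so that every within-group pair has
#' identity at or above `identity_threshold`. From each group the member
#' with the best (smallest) resolution becomes the representative; NMR and
#' resolution-less entries rank below every numeric resolution, and residual
#' ties break on lexicographic id.
#'
#' @param family A [family_set()]; every member needs a sequence.
#' @param identity_threshold Within-group identity floor (fraction).
#' @return The family with `representative_ids` and `m` updated (reference
#'   cleared; choose it afterwards with [choose_reference()]).
#' @export
select_representatives <- function(family, identity_threshold = 0.95) {
  n <- length(family$members)
  if (n == 0) stop("empty family")
  if (n == 1) {
    groups <- 1L
  } else {
    seqs <- vapply(family$members, `[[`, character(1), "sequence")
    idm <- diag(1, n)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        idm[i, j] <- idm[j, i] <- sequence_identity(seqs[i], seqs[j])
      }
    }
    d <- stats::as.dist(1 - idm)
    tree <- stats::hclust(d, method = "complete")
    groups <- stats::cutree(tree, h = 1 - identity_threshold)
  }
  reps <- character(0)
  for (g in sort(unique(groups))) {
    idx <- which(groups == g)
    ranks <- vapply(family$members[idx], .resolution_rank, numeric(1))
    ids <- family$member_ids[idx]
    best <- idx[order(ranks, ids, method = "radix")][1]
    reps <- c(reps, family$member_ids[best])
  }
  family_set(family$family_id, family$members,
             representative_ids = sort(reps), reference_id = NULL)
}

#' Choose the family reference structure
#'
#' The representative with the longest sequence is the reference; resolution
#' is the second selection parameter (best wins; NMR ranks last) and
#' lexicographic id breaks residual ties.
#'
#' @param family A [family_set()] with at least one representative.
#' @return The reference structure id.
#' @export
choose_reference <- function(family) {
  if (family$m < 1) stop("family has no representatives")
  reps <- family$members[match(family$representative_ids, family$member_ids)]
  len <- vapply(reps, n_residues, integer(1))
  res <- vapply(reps, .resolution_rank, numeric(1))
  ids <- vapply(reps, `[[`, character(1), "id")
  ids[order(-len, res, ids, method = "radix")][1]
}

#' Assemble a family: filter, select representatives, choose reference
#'
#' Convenience wrapper running [apply_quality_filters()],
#' [select_representatives()] and [choose_reference()] in sequence.
#'
#' @param family_id Family identifier.
#' @param structures List of [protein_structure()] objects.
#' @param identity_threshold Identity floor for representative grouping.
#' @param ... Passed to [apply_quality_filters()].
#' @return A [family_set()] with representatives and reference set, or
#'   `NULL` when no structure survives filtering.
#' @export
build_family <- function(family_id, structures, identity_threshold = 0.95, ...) {
  kept <- apply_quality_filters(structures, ...)
  if (length(kept) == 0) return(NULL)
  fam <- select_representatives(family_set(family_id, kept),
                                identity_threshold = identity_threshold)
  ref <- choose_reference(fam)
  family_set(fam$family_id, fam$members,
             representative_ids = fam$representative_ids, reference_id = ref)
}

#' Write a family manifest table
#'
#' @param family A [family_set()].
#' @param path Output TSV path.
#' @return The manifest data frame, invisibly.
#' @export
write_family_manifest <- function(family, path) {
  df <- data.frame(
    family_id = family$family_id,
    structure_id = family$member_ids,
    method = vapply(family$members, `[[`, character(1), "method"),
    resolution = vapply(family$members, `[[`, numeric(1), "resolution"),
    n_residues = vapply(family$members, n_residues, integer(1)),
    is_representative = family$member_ids %in% family$representative_ids,
    is_reference = family$member_ids %in% family$reference_id,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
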