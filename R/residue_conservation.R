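#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or Stockholm file into a named character vector of
#' equal-length gapped sequences. Gaps `.` are normalized to `-` and
#' sequences are upper-cased.
#'
#' @param path Alignment file path.
#' @param format `"fasta"`, `"stockholm"`, or `"auto"` (sniff the first line).
#' @return Named character vector of aligned sequences.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    aln <- Biostrings::readBStringSet(path)
    seqs <- toupper(as.character(aln))
    names(seqs) <- names(aln)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                     nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    ids <- vapply(parts, `[[`, character(1), 1)
    chunks <- vapply(parts, `[[`, character(1), 2)
    seqs <- vapply(split(chunks, factor(ids, levels = unique(ids))),
                   paste, character(1), collapse = "")
    seqs <- toupper(seqs)
  }
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (length(unique(nchar(seqs))) > 1) stop("ragged alignment in ", path)
  seqs
}

#' Write an alignment as aligned FASTA
#' @param msa Named character vector of aligned sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  ids <- names(msa)
  if (is.null(ids)) ids <- paste0("seq", seq_along(msa))
  writeLines(as.vector(rbind(paste0(">", ids), unname(msa))), path)
  invisible(path)
}

# Alignment as a character matrix (rows = sequences).
.msa_matrix <- function(msa) {
  if (length(unique(nchar(msa))) > 1) stop("ragged alignment")
  do.call(rbind, strsplit(toupper(msa), ""))
}

#' Position-based (Henikoff) sequence weights
#'
#' Down-weights redundant sequences: at each column a sequence receives
#' `1 / (r * s)` where `r` is the number of distinct symbols in the column
#' and `s` the count of the sequence's own symbol; per-sequence sums are
#' normalized so the weights total the number of sequences. Gaps count as a
#' symbol.
#'
#' @param msa Named character vector of aligned sequences.
#' @return Numeric weights, one per sequence, summing to `length(msa)`.
#' @export
sequence_weights <- function(msa) {
  m <- .msa_matrix(msa)
  n <- nrow(m)
  if (n == 1) return(stats::setNames(1, names(msa)))
  w <- numeric(n)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    counts <- table(col)
    r <- length(counts)
    w <- w + 1 / (r * as.numeric(counts[col]))
  }
  w <- w * n / sum(w)
  stats::setNames(w, names(msa))
}

#' Per-column conservation scores from weighted entropy
#'
#' Computes the weighted Shannon entropy of each alignment column over the 20
#' amino acids plus gap as a 21st symbol, then inverts and standardizes it:
#' `score = (mean(H) - H) / sd(H)` across columns, so strongly conserved
#' (low-entropy) columns score high. An alignment whose columns all share the
#' same entropy gets all-zero scores.
#'
#' @param msa Named character vector of aligned sequences.
#' @param weights Per-sequence weights (default [sequence_weights()]).
#' @return Numeric score per alignment column.
#' @export
conservation_scores <- function(msa, weights = sequence_weights(msa)) {
  m <- .msa_matrix(msa)
  if (length(weights) != nrow(m)) stop("weights must match sequences")
  h <- apply(m, 2, function(col) {
    f <- tapply(weights, col, sum) / sum(weights)
    -sum(f * log(f))
  })
  s <- stats::sd(h)
  if (!is.finite(s) || s == 0) return(rep(0, length(h)))
  (mean(h) - h) / s
}

#' Map alignment-column scores onto a structure's residues
#'
#' Finds the MSA row matching the structure (exact ungapped sequence match,
#' or the highest-identity row via a global pairwise alignment as fallback)
#' and assigns each residue the score of its alignment column. Residues
#' falling in gap regions of the matched row, or unaligned in the pairwise
#' fallback, are flagged uncovered (`NA` score).
#'
#' @param structure A [protein_structure()].
#' @param msa Named character vector of aligned sequences.
#' @param scores Per-column scores (default computed from `msa`).
#' @param row Optional MSA row name or index to force the mapping row.
#' @return A `conservation_profile`: list with `structure_id`, `scores`
#'   (per-residue, `NA` where uncovered), `covered` (logical), `row` (the MSA
#'   row used).
#' @export
map_scores_to_structure <- function(structure, msa,
                                    scores = conservation_scores(msa),
                                    row = NULL) {
  if (length(scores) != nchar(msa[[1]])) {
    stop("scores must have one value per alignment column")
  }
  ungapped <- gsub("-", "", msa, fixed = TRUE)
  sq <- structure$sequence
  n <- nchar(sq)
  if (is.null(row)) {
    hit <- which(ungapped == sq)
    row <- if (length(hit)) hit[1] else NA_integer_
  } else if (is.character(row)) {
    row <- match(row, names(msa))
  }
  res_scores <- rep(NA_real_, n)
  if (!is.na(row) && ungapped[[row]] == sq) {
    cols <- which(strsplit(msa[[row]], "")[[1]] != "-")
    res_scores <- scores[cols]
  } else {
    # pairwise fallback: align the structure sequence to the closest row
    if (is.na(row)) {
      idents <- vapply(ungapped, sequence_identity, numeric(1), seq_b = sq)
      row <- which.max(idents)
    }
    aln <- .global_align(ungapped[[row]], sq)
    a <- strsplit(aln$a, "")[[1]]   # msa row, ungapped coords
    b <- strsplit(aln$b, "")[[1]]   # structure
    ia <- cumsum(a != "-")
    ib <- cumsum(b != "-")
    row_cols <- which(strsplit(msa[[row]], "")[[1]] != "-")
    pair <- a != "-" & b != "-"
    res_scores[ib[pair]] <- scores[row_cols[ia[pair]]]
  }
  covered <- !is.na(res_scores)
  if (mean(covered) < 0.5) {
    warning(sprintf("low alignment coverage for %s: %.0f%% of residues mapped",
                    structure$id, 100 * mean(covered)))
  }
  out <- list(structure_id = structure$id, scores = res_scores,
              covered = covered, row = row)
  class(out) <- "conservation_profile"
  out
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("conservation_profile %s: %d residues, %.0f%% covered\n",
              x$structure_id, length(x$scores), 100 * mean(x$covered)))
  invisible(x)
}

# Guarded one-sided Mann-Whitney p-value; constant data gives p = 1.
.mw_p <- function(x, y, alternative) {
  if (length(x) == 0 || length(y) == 0) return(1)
  if (stats::sd(c(x, y)) %in% c(0, NA) || all(c(x, y) == c(x, y)[1])) return(1)
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = NULL)$p.value
  )
}

#' Test a pocket for significant sequence conservation
#'
#' One-sided Wilcoxon-Mann-Whitney test of the pocket residues' conservation
#' scores being stochastically greater than the scores of all residues in the
#' structure (the background deliberately includes the pocket's own
#' residues). Significant when `p <= alpha`.
#'
#' @param pocket_scores Conservation scores of the pocket's residues.
#' @param all_scores Conservation scores of all residues in the structure.
#' @param alpha Significance level.
#' @return List with `p_value` and logical `significant`.
#' @export
pocket_conservation_test <- function(pocket_scores, all_scores, alpha = 0.05) {
  if (length(pocket_scores) == 0) stop("pocket has no scored residues")
  pocket_scores <- pocket_scores[!is.na(pocket_scores)]
  all_scores <- all_scores[!is.na(all_scores)]
  if (length(pocket_scores) == 0 || length(all_scores) == 0) {
    return(list(p_value = 1, significant = FALSE))
  }
  p <- .mw_p(pocket_scores, all_scores, "greater")
  list(p_value = p, significant = p <= alpha)
}

#' Write a conservation profile as TSV
#' @param profile A `conservation_profile`.
#' @param structure The matching [protein_structure()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_profile_tsv <- function(profile, structure, path) {
  df <- data.frame(
    structure_id = profile$structure_id,
    chain = structure$residues$chain,
    resnum = structure$residues$resno,
    score = profile$scores,
    covered = profile$covered,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
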