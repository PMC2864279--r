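#' Map an active-site annotation to a pocket
#'
#' Annotated active-site residues (typically 1-3 per structure) are matched
#' against the residue lists of the structure's pockets. The pocket
#' containing the most annotated residues wins; the mapping is flagged
#' ambiguous when more than one pocket contains at least one annotated
#' residue. A tie for the majority maps to none (and is ambiguous); so does
#' an annotation no pocket contains.
#'
#' @param annotation List with `structure_id` and `residues` (character
#'   residue keys, see [residue_keys()]).
#' @param pockets Pocket table for the annotation's structure (with a
#'   `residues` column).
#' @return List with `pocket_id` (or `NA`) and logical `ambiguous`.
#' @export
map_active_site <- function(annotation, pockets) {
  if (length(annotation$residues) == 0) stop("empty active-site annotation")
  pockets <- pockets[pockets$structure_id == annotation$structure_id, ,
                     drop = FALSE]
  if (nrow(pockets) == 0) return(list(pocket_id = NA_character_, ambiguous = FALSE))
  hits <- vapply(pockets$residues, function(r)
    sum(annotation$residues %in% split_residues(r)), integer(1))
  touched <- sum(hits > 0)
  if (touched == 0) return(list(pocket_id = NA_character_, ambiguous = FALSE))
  best <- max(hits)
  winners <- pockets$pocket_id[hits == best]
  if (length(winners) > 1) {
    return(list(pocket_id = NA_character_, ambiguous = TRUE))
  }
  list(pocket_id = winners, ambiguous = touched > 1)
}

#' Identify the active-site cluster
#'
#' The cluster containing the largest number of pockets mapped to active-site
#' annotations; ties break on better (lower) cluster rank.
#'
#' @param cluster_table Ranked cluster table from [score_and_rank()].
#' @param mapped_pocket_ids Character vector of active-site pocket ids
#'   (unambiguous mappings).
#' @return The winning `cluster_rank`, or `NA` if no mapped pocket falls in
#'   any cluster.
#' @export
active_site_cluster <- function(cluster_table, mapped_pocket_ids) {
  mapped_pocket_ids <- mapped_pocket_ids[!is.na(mapped_pocket_ids)]
  if (length(mapped_pocket_ids) == 0) return(NA_integer_)
  counts <- vapply(cluster_table$member_pockets, function(mp)
    sum(mapped_pocket_ids %in% split_residues(mp)), integer(1))
  if (all(counts == 0)) return(NA_integer_)
  cluster_table$cluster_rank[order(-counts, cluster_table$cluster_rank)][1]
}

#' Benchmark clustering thresholds against known active sites
#'
#' For each candidate fixed distance `v`, every family's pockets are
#' clustered at threshold `v + avg_rmsd` (or `v` alone when
#' `add_rmsd = FALSE`), the family's active-site cluster is identified, and
#' two rates are accumulated: the percentage of all active-site pockets that
#' land inside their family's active-site cluster (true positives) and the
#' percentage of non-active-site pockets swept into that cluster (false
#' positives). Rates are pocket-weighted across families by default;
#' `aggregate = "family_mean"` averages the per-family percentages instead.
#'
#' @param families List of family inputs, each a list with `pockets` (pocket
#'   table in the reference frame), `active_pocket_ids` (unambiguously mapped
#'   active-site pocket ids) and `avg_rmsd`.
#' @param fixed_values Numeric vector of base distances to sweep, Angstrom.
#' @param add_rmsd Add each family's `avg_rmsd` to the fixed value?
#' @param aggregate `"pocket"` (pooled counts) or `"family_mean"`.
#' @return Data frame with columns `fixed_value`, `pct_active_sites`,
#'   `pct_non_active`, ordered by `fixed_value`.
#' @export
benchmark_thresholds <- function(families, fixed_values = 0:10,
                                 add_rmsd = TRUE,
                                 aggregate = c("pocket", "family_mean")) {
  aggregate <- match.arg(aggregate)
  if (length(families) == 0) stop("no families to benchmark")
  ok <- vapply(families, function(f) length(f$active_pocket_ids) > 0, logical(1))
  if (!all(ok)) stop("every family needs >= 1 unambiguous active-site mapping")
  fixed_values <- sort(fixed_values)
  rows <- lapply(fixed_values, function(v) {
    tp <- fp <- tp_den <- fp_den <- 0
    fam_tp <- fam_fp <- numeric(0)
    for (f in families) {
      thr <- if (add_rmsd) v + f$avg_rmsd else v
      tab <- score_and_rank(cluster_pockets(f$pockets, thr),
                            m = length(unique(f$pockets$structure_id)))
      asc <- active_site_cluster(tab, f$active_pocket_ids)
      members <- if (is.na(asc)) character(0) else
        split_residues(tab$member_pockets[tab$cluster_rank == asc])
      act <- f$active_pocket_ids
      nonact <- setdiff(f$pockets$pocket_id, act)
      tp_f <- sum(act %in% members)
      fp_f <- sum(nonact %in% members)
      tp <- tp + tp_f; tp_den <- tp_den + length(act)
      fp <- fp + fp_f; fp_den <- fp_den + length(nonact)
      fam_tp <- c(fam_tp, 100 * tp_f / length(act))
      fam_fp <- c(fam_fp, if (length(nonact)) 100 * fp_f / length(nonact) else 0)
    }
    if (aggregate == "pocket") {
      data.frame(fixed_value = v,
                 pct_active_sites = 100 * tp / tp_den,
                 pct_non_active = if (fp_den) 100 * fp / fp_den else 0)
    } else {
      data.frame(fixed_value = v,
                 pct_active_sites = mean(fam_tp),
                 pct_non_active = mean(fam_fp))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read active-site annotations from TSV
#'
#' Expects columns `structure_id` and `residues` (semicolon-joined
#' `chain:resnum` keys).
#'
#' @param path TSV path.
#' @return List of annotations (each with `structure_id`, `residues`).
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  lapply(seq_len(nrow(df)), function(i)
    list(structure_id = df$structure_id[i],
         residues = split_residues(df$residues[i])))
}

#' Write active-site annotations as TSV
#' @param annotations List of annotations.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_annotation_tsv <- function(annotations, path) {
  df <- data.frame(
    structure_id = vapply(annotations, `[[`, character(1), "structure_id"),
    residues = vapply(annotations, function(a)
      paste(a$residues, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
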