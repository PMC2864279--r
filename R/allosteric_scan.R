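#' Scan for conserved, spatially separated pocket-cluster pairs
#'
#' Candidate functional/allosteric site pairs are unordered pairs of pocket
#' clusters that are both structurally conserved (coverage at or above
#' `str_threshold`) and whose centroids lie at least `min_distance` apart.
#' Optionally both clusters must also pass a sequence-conservation floor, and
#' exactly one of the two must be the family's active-site cluster. Pairs are
#' sorted by descending `min(str_a, str_b)`.
#'
#' @param cluster_table Ranked cluster table from [score_and_rank()].
#' @param summaries Optional data frame of cluster summaries (from
#'   [summarize_cluster()], one row per cluster) supplying
#'   `pct_seq_conserved`; required when `seq_threshold` is set.
#' @param min_distance Minimum centroid distance, Angstrom.
#' @param str_threshold Structural-conservation floor, percent.
#' @param seq_threshold Optional sequence-conservation floor, percent.
#' @param active_site_rank Optional rank of the family's active-site cluster.
#' @param require_active_site If `TRUE`, keep only pairs where exactly one
#'   cluster is the active-site cluster.
#' @param max_rank Optional rank cutoff: only clusters ranked at or better
#'   than this enter the scan.
#' @param family_id Family identifier for the output rows.
#' @return Data frame of pairs: `family_id`, `cluster_a`, `cluster_b`,
#'   `centroid_distance`, `str_a`, `str_b`, `seq_a`, `seq_b`,
#'   `active_site_a`, `active_site_b`.
#' @export
scan_pairs <- function(cluster_table, summaries = NULL, min_distance = 8.0,
                       str_threshold = 50, seq_threshold = NULL,
                       active_site_rank = NA_integer_,
                       require_active_site = FALSE, max_rank = NULL,
                       family_id = "family") {
  empty <- data.frame(
    family_id = character(0), cluster_a = integer(0), cluster_b = integer(0),
    centroid_distance = numeric(0), str_a = numeric(0), str_b = numeric(0),
    seq_a = numeric(0), seq_b = numeric(0), active_site_a = logical(0),
    active_site_b = logical(0), stringsAsFactors = FALSE
  )
  tab <- cluster_table
  if (!is.null(max_rank)) tab <- tab[tab$cluster_rank <= max_rank, , drop = FALSE]
  if (nrow(tab) < 2) return(empty)
  seqc <- rep(NA_real_, nrow(tab))
  if (!is.null(summaries)) {
    seqc <- summaries$pct_seq_conserved[match(tab$cluster_rank,
                                              summaries$cluster_rank)]
  }
  if (!is.null(seq_threshold) && anyNA(seqc)) {
    stop("seq_threshold requires cluster summaries with pct_seq_conserved")
  }
  cent <- as.matrix(tab[, c("centroid_x", "centroid_y", "centroid_z")])
  d <- as.matrix(stats::dist(cent))
  rows <- list()
  for (i in seq_len(nrow(tab) - 1)) {
    for (j in seq(i + 1, nrow(tab))) {
      if (tab$str_c[i] < str_threshold || tab$str_c[j] < str_threshold) next
      if (d[i, j] < min_distance) next
      if (!is.null(seq_threshold) &&
          (seqc[i] < seq_threshold || seqc[j] < seq_threshold)) next
      as_a <- !is.na(active_site_rank) && tab$cluster_rank[i] == active_site_rank
      as_b <- !is.na(active_site_rank) && tab$cluster_rank[j] == active_site_rank
      if (require_active_site && sum(as_a, as_b) != 1) next
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = family_id,
        cluster_a = tab$cluster_rank[i], cluster_b = tab$cluster_rank[j],
        centroid_distance = d[i, j],
        str_a = tab$str_c[i], str_b = tab$str_c[j],
        seq_a = seqc[i], seq_b = seqc[j],
        active_site_a = as_a, active_site_b = as_b,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-pmin(out$str_a, out$str_b)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count families with qualifying cluster pairs over a threshold grid
#'
#' For each (structural, sequence) conservation threshold pair, counts the
#' families with at least one qualifying cluster pair: structurally conserved
#' only; additionally sequence conserved; structurally conserved with an
#' active-site member; and with both the sequence filter and an active-site
#' member.
#'
#' @param family_results List of per-family inputs, each a list with
#'   `family_id`, `cluster_table`, `summaries` and optional
#'   `active_site_rank`.
#' @param thresholds Data frame with columns `str` and `seq` (percent), one
#'   row per grid cell.
#' @param min_distance Minimum centroid distance, Angstrom.
#' @return Data frame: `str_threshold`, `seq_threshold`, `n_struct`,
#'   `n_struct_seq`, `n_struct_active`, `n_struct_seq_active`.
#' @export
family_counts <- function(family_results,
                          thresholds = data.frame(str = c(50, 75, 100),
                                                  seq = c(50, 75, 100)),
                          min_distance = 8.0) {
  rows <- lapply(seq_len(nrow(thresholds)), function(k) {
    st <- thresholds$str[k]
    se <- thresholds$seq[k]
    n1 <- n2 <- n3 <- n4 <- 0L
    for (f in family_results) {
      asr <- if (is.null(f$active_site_rank)) NA_integer_ else f$active_site_rank
      base <- scan_pairs(f$cluster_table, f$summaries,
                         min_distance = min_distance, str_threshold = st,
                         family_id = f$family_id, active_site_rank = asr)
      if (nrow(base) > 0) n1 <- n1 + 1L
      wseq <- scan_pairs(f$cluster_table, f$summaries,
                         min_distance = min_distance, str_threshold = st,
                         seq_threshold = se, family_id = f$family_id,
                         active_site_rank = asr)
      if (nrow(wseq) > 0) n2 <- n2 + 1L
      if (!is.na(asr)) {
        wact <- base[xor(base$active_site_a, base$active_site_b), , drop = FALSE]
        if (nrow(wact) > 0) n3 <- n3 + 1L
        wboth <- wseq[xor(wseq$active_site_a, wseq$active_site_b), , drop = FALSE]
        if (nrow(wboth) > 0) n4 <- n4 + 1L
      }
    }
    data.frame(str_threshold = st, seq_threshold = se, n_struct = n1,
               n_struct_seq = n2, n_struct_active = n3,
               n_struct_seq_active = n4)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
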