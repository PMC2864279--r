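#' Family-specific clustering threshold
#'
#' The neighbor distance used to cluster pocket centers across superimposed
#' structures: a fixed base distance plus the family's average superposition
#' RMSD, so families with larger structural fluctuation get a wider net.
#'
#' @param avg_rmsd Average superposition RMSD of the family, Angstrom (>= 0).
#' @param base Fixed base distance, Angstrom.
#' @return Threshold in Angstrom.
#' @export
family_threshold <- function(avg_rmsd, base = 2.0) {
  if (!is.finite(avg_rmsd) || avg_rmsd < 0) stop("avg_rmsd must be >= 0")
  base + avg_rmsd
}

#' Greedy size-weighted clustering of pocket centers
#'
#' Elements are pocket centers of mass in a common reference frame; neighbors
#' are elements within `threshold` Euclidean distance (every element is its
#' own neighbor). Each element is scored by the sum of its own size and the
#' sizes of all its neighbors still in the pool. Iteratively, the
#' highest-scoring element founds a cluster made of itself and all its
#' current neighbors; members leave the pool and scores are recomputed, until
#' the pool is empty. Pockets from the same or different structures are not
#' distinguished. Score ties break on ascending pocket id.
#'
#' @param pockets Pocket table (data frame with `structure_id`, `pocket_id`,
#'   `x`, `y`, `z`, `size`).
#' @param threshold Neighbor distance, Angstrom.
#' @return An object of class `pocket_clustering`: list with `threshold` and
#'   `clusters`, each cluster holding `members` (row indices into `pockets`),
#'   `founder` (pocket id), `centroid`, `n_c`, and the member pocket table.
#' @export
cluster_pockets <- function(pockets, threshold) {
  n <- nrow(pockets)
  out <- list(threshold = threshold, pockets = pockets, clusters = list())
  class(out) <- "pocket_clustering"
  if (n == 0) return(out)
  centers <- as.matrix(pockets[, c("x", "y", "z")])
  sizes <- as.numeric(pockets$size)
  ids <- as.character(pockets$pocket_id)
  nb <- as.matrix(stats::dist(centers)) <= threshold
  diag(nb) <- TRUE

  pool <- rep(TRUE, n)
  clusters <- list()
  while (any(pool)) {
    live <- which(pool)
    score <- as.numeric(nb[live, live, drop = FALSE] %*% sizes[live])
    founder <- live[order(-score, ids[live], method = "radix")][1]
    members <- live[nb[founder, live]]
    clusters[[length(clusters) + 1L]] <- list(
      founder = ids[founder],
      members = members,
      member_ids = ids[members],
      centroid = colMeans(centers[members, , drop = FALSE]),
      n_c = length(members),
      sizes = sizes[members],
      structure_ids = as.character(pockets$structure_id[members])
    )
    pool[members] <- FALSE
  }
  out$clusters <- clusters
  out
}

#' @export
print.pocket_clustering <- function(x, ...) {
  cat(sprintf("pocket_clustering: %d pockets in %d clusters (threshold %.2f A)\n",
              nrow(x$pockets), length(x$clusters), x$threshold))
  invisible(x)
}

#' Structural conservation of a pocket cluster
#'
#' The percentage of a family's representative structures contributing at
#' least one pocket to the cluster: `100 * n_r / m`, where `n_r` counts the
#' representatives with a member pocket and `m` is the representative count.
#'
#' @param cluster A cluster element of a [cluster_pockets()] result, or any
#'   list with a `structure_ids` field.
#' @param m Number of representative structures (>= 1).
#' @return Percentage in `(0, 100]`.
#' @export
structural_conservation <- function(cluster, m) {
  if (m < 1) stop("m must be >= 1")
  100 * length(unique(cluster$structure_ids)) / m
}

#' Score and rank pocket clusters
#'
#' Each cluster receives `score_c = mean member size x Str_c`, combining the
#' average size of its member pockets with its structural conservation
#' (coverage of the family's representatives, as a percentage). Clusters are
#' ranked by descending score; ties break on descending coverage, then
#' ascending founder id. Ranks start at 1.
#'
#' @param clustering A [cluster_pockets()] result.
#' @param m Number of representative structures.
#' @return A data frame (the cluster table) with columns `cluster_rank`,
#'   `founder`, `n_c`, `n_r`, `m`, `str_c`, `score_c`, `centroid_x`,
#'   `centroid_y`, `centroid_z`, `member_pockets` (semicolon-joined ids).
#'   The ranked cluster list is attached as attribute `clusters`.
#' @export
score_and_rank <- function(clustering, m) {
  cl <- clustering$clusters
  if (length(cl) == 0) {
    out <- data.frame(
      cluster_rank = integer(0), founder = character(0), n_c = integer(0),
      n_r = integer(0), m = integer(0), str_c = numeric(0),
      score_c = numeric(0), centroid_x = numeric(0), centroid_y = numeric(0),
      centroid_z = numeric(0), member_pockets = character(0),
      stringsAsFactors = FALSE
    )
    attr(out, "clusters") <- list()
    return(out)
  }
  n_r <- vapply(cl, function(c) length(unique(c$structure_ids)), integer(1))
  str_c <- 100 * n_r / m
  mean_size <- vapply(cl, function(c) mean(c$sizes), numeric(1))
  score_c <- mean_size * str_c
  founders <- vapply(cl, `[[`, character(1), "founder")
  ord <- order(-score_c, -str_c, founders, method = "radix")
  ranked <- cl[ord]
  for (i in seq_along(ranked)) {
    ranked[[i]]$cluster_rank <- i
    ranked[[i]]$n_r <- n_r[ord][i]
    ranked[[i]]$str_c <- str_c[ord][i]
    ranked[[i]]$score_c <- score_c[ord][i]
  }
  out <- data.frame(
    cluster_rank = seq_along(ranked),
    founder = founders[ord],
    n_c = vapply(ranked, `[[`, integer(1), "n_c"),
    n_r = n_r[ord],
    m = m,
    str_c = str_c[ord],
    score_c = score_c[ord],
    centroid_x = vapply(ranked, function(c) c$centroid[1], numeric(1)),
    centroid_y = vapply(ranked, function(c) c$centroid[2], numeric(1)),
    centroid_z = vapply(ranked, function(c) c$centroid[3], numeric(1)),
    member_pockets = vapply(ranked, function(c)
      paste(c$member_ids, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "clusters") <- ranked
  out
}

#' Cluster a family's pockets and rank the clusters
#'
#' Convenience wrapper: computes the family threshold from the superposition
#' RMSD, runs [cluster_pockets()] and [score_and_rank()].
#'
#' @param pockets Pocket table in the reference frame.
#' @param avg_rmsd Family average superposition RMSD, Angstrom.
#' @param m Number of representative structures.
#' @param base Base clustering distance, Angstrom.
#' @return The ranked cluster table (see [score_and_rank()]), with the
#'   threshold attached as attribute `threshold`.
#' @export
cluster_family_pockets <- function(pockets, avg_rmsd, m, base = 2.0) {
  thr <- family_threshold(avg_rmsd, base = base)
  tab <- score_and_rank(cluster_pockets(pockets, thr), m)
  attr(tab, "threshold") <- thr
  tab
}

#' Write a ranked cluster table as TSV
#' @param cluster_table Output of [score_and_rank()].
#' @param family_id Family identifier column value.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_cluster_tsv <- function(cluster_table, family_id, path) {
  df <- cbind(family_id = family_id, cluster_table)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
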