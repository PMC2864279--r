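#' Pipeline run configuration
#'
#' Bundles the input locations and stage parameters for
#' [run_family_analysis()]. Defaults reproduce the method's standard
#' settings: 2.0 A base clustering distance plus the family RMSD, 8 A residue
#' assignment radius, 8 A minimum pair distance, p <= 0.05 significance, 95%
#' identity for representative selection, and at least 5 representatives for
#' the conservation analyses.
#'
#' @param input_dir Directory holding the family's structure files
#'   (`*.pdb` / `*.cif`).
#' @param out_dir Output directory for all reports.
#' @param family_id Family identifier.
#' @param msa_path Optional aligned FASTA/Stockholm for the family.
#' @param annotations_path Optional active-site annotation TSV.
#' @param pockets_path Optional pre-computed pocket table TSV (bypasses the
#'   grid detector; centers are taken in each structure's own frame and moved
#'   into the reference frame by the superposition stage).
#' @param seed Integer seed (the pipeline itself is deterministic; the seed
#'   is fixed for any downstream consumer of R's RNG).
#' @param grid A [grid_params()] object for the detector.
#' @param base_threshold Base clustering distance, Angstrom.
#' @param residue_radius Pocket residue assignment radius, Angstrom.
#' @param alpha Significance level for the conservation/flexibility tests.
#' @param identity_threshold Sequence-identity floor for representative
#'   grouping.
#' @param min_representatives Minimum representatives for conservation
#'   summaries and the pair scan.
#' @param pair_min_distance Minimum centroid distance for the pair scan,
#'   Angstrom.
#' @param str_threshold Structural-conservation floor for the pair scan, %.
#' @param seq_threshold Optional sequence-conservation floor for the pair
#'   scan, %.
#' @param quality List of [apply_quality_filters()] arguments
#'   (`min_resolution`, `min_gfactor`, `min_span`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir, out_dir, family_id = "family",
                       msa_path = NULL, annotations_path = NULL,
                       pockets_path = NULL, seed = 1,
                       grid = grid_params(), base_threshold = 2.0,
                       residue_radius = 8.0, alpha = 0.05,
                       identity_threshold = 0.95, min_representatives = 5,
                       pair_min_distance = 8.0, str_threshold = 50,
                       seq_threshold = NULL,
                       quality = list(min_resolution = 3.0,
                                      min_gfactor = -1.00, min_span = 30)) {
  out <- as.list(environment())
  class(out) <- "run_config"
  out
}

# Deterministic TSV writer used for all reports.
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full family analysis pipeline
#'
#' Executes filter -> representative selection -> reference choice ->
#' superposition -> pocket detection (or intake of a pre-computed pocket
#' table) -> family clustering and ranking -> per-pocket characterization
#' (sequence conservation, flexibility, electrostatic potential) ->
#' active-site mapping -> conserved-pair scan, writing every stage's table
#' under `config$out_dir` plus a human-readable `summary.txt`. Families with
#' fewer than `min_representatives` representatives are clustered but
#' excluded from the conservation summaries and the pair scan, with the
#' reason logged in the summary.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the computed objects: `family`,
#'   `superposed`, `pockets`, `cluster_table`, `profiles`, `pocket_reports`,
#'   `cluster_summaries`, `active_site`, `pairs`, and the vector of written
#'   `paths`.
#' @export
run_family_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  log_lines <- c(sprintf("family: %s", config$family_id),
                 sprintf("seed: %d", config$seed),
                 sprintf("parameters: base_threshold=%.2f residue_radius=%.2f alpha=%.2f identity=%.2f min_representatives=%d pair_min_distance=%.2f str_threshold=%.1f",
                         config$base_threshold, config$residue_radius,
                         config$alpha, config$identity_threshold,
                         config$min_representatives,
                         config$pair_min_distance, config$str_threshold))

  files <- sort(list.files(config$input_dir,
                           pattern = "\\.(pdb|cif)$", full.names = TRUE))
  finish_empty <- function(reason) {
    warning(reason, call. = FALSE)
    log_lines <- c(log_lines, paste("note:", reason))
    p <- file.path(config$out_dir, "summary.txt")
    writeLines(log_lines, p)
    invisible(list(family = NULL, pockets = NULL, cluster_table = NULL,
                   pairs = NULL, paths = p))
  }
  if (length(files) == 0) {
    return(finish_empty("no structure files found; empty report"))
  }

  structures <- lapply(files, function(f)
    tryCatch(read_structure(f), error = function(e) {
      warning("skipping ", f, ": ", conditionMessage(e), call. = FALSE)
      NULL
    }))
  structures <- Filter(Negate(is.null), structures)
  if (length(structures) == 0) {
    return(finish_empty("no parseable structures; empty report"))
  }

  fam <- build_family(config$family_id, structures,
                      identity_threshold = config$identity_threshold,
                      min_resolution = config$quality$min_resolution,
                      min_gfactor = config$quality$min_gfactor,
                      min_span = config$quality$min_span)
  if (is.null(fam)) {
    return(finish_empty("no structure passed the quality filters"))
  }
  p <- file.path(config$out_dir, "family_manifest.tsv")
  write_family_manifest(fam, p)
  paths <- c(paths, p)

  sup <- superimpose_family(fam)
  p <- file.path(config$out_dir, "transforms.json")
  write_transforms(sup, p)
  paths <- c(paths, p)
  for (sid in sup$excluded) {
    log_lines <- c(log_lines,
                   sprintf("note: %s excluded from superposition (insufficient correspondence)", sid))
  }

  reps <- setdiff(sup$family$representative_ids, sup$excluded)
  if (!is.null(config$pockets_path)) {
    raw <- read_pocket_tsv(config$pockets_path)
    raw <- raw[raw$structure_id %in% reps, , drop = FALSE]
    pockets <- raw
    for (i in seq_len(nrow(raw))) {
      tr <- sup$transforms[[raw$structure_id[i]]]
      ctr <- as.numeric(tr$rotation %*% c(raw$x[i], raw$y[i], raw$z[i]) +
                          tr$translation)
      pockets$x[i] <- ctr[1]; pockets$y[i] <- ctr[2]; pockets$z[i] <- ctr[3]
    }
  } else {
    pockets <- do.call(rbind, lapply(reps, function(sid)
      detect_pockets(family_member(sup$family, sid), params = config$grid,
                     residue_radius = config$residue_radius)))
    if (is.null(pockets)) pockets <- read_pocket_tsv_empty()
  }
  p <- file.path(config$out_dir, "pockets.tsv")
  write_pocket_tsv(pockets, p)
  paths <- c(paths, p)

  m <- length(reps)
  threshold <- family_threshold(sup$avg_rmsd, base = config$base_threshold)
  cluster_table <- score_and_rank(cluster_pockets(pockets, threshold), m)
  clusters <- attr(cluster_table, "clusters")
  p <- file.path(config$out_dir, "clusters.tsv")
  write_cluster_tsv(cluster_table, config$family_id, p)
  paths <- c(paths, p)
  log_lines <- c(log_lines,
                 sprintf("representatives: %d of %d members (reference %s)",
                         m, length(fam$members), fam$reference_id),
                 sprintf("avg_rmsd: %.3f A; clustering threshold: %.3f A",
                         sup$avg_rmsd, threshold),
                 sprintf("pockets: %d in %d clusters",
                         nrow(pockets), nrow(cluster_table)))

  # str_c histogram export (5%-wide bins)
  if (nrow(cluster_table) > 0) {
    breaks <- seq(0, 100, by = 5)
    bin <- cut(cluster_table$str_c, breaks = breaks, include.lowest = TRUE)
    p <- file.path(config$out_dir, "strc_histogram.tsv")
    .write_tsv(data.frame(bin_low = breaks[-length(breaks)],
                          bin_high = breaks[-1],
                          count = as.integer(table(bin))), p)
    paths <- c(paths, p)
  }

  # per-structure conservation profiles
  profiles <- NULL
  if (!is.null(config$msa_path)) {
    msa <- read_msa(config$msa_path)
    scores <- conservation_scores(msa)
    profiles <- lapply(reps, function(sid)
      map_scores_to_structure(family_member(sup$family, sid), msa, scores))
    names(profiles) <- reps
  }

  # per-pocket property reports
  pocket_reports <- NULL
  cluster_summaries <- NULL
  low_m <- m < config$min_representatives
  if (low_m) {
    log_lines <- c(log_lines,
                   sprintf("note: %d representatives < %d; conservation summaries and pair scan skipped",
                           m, config$min_representatives))
  }
  if (!low_m && nrow(pockets) > 0) {
    flex_cache <- lapply(reps, function(sid)
      tryCatch(flexibility_profile(family_member(sup$family, sid)),
               error = function(e) NULL))
    names(flex_cache) <- reps
    rows <- lapply(seq_len(nrow(pockets)), function(i) {
      sid <- pockets$structure_id[i]
      st <- family_member(sup$family, sid)
      fx <- flex_cache[[sid]]
      if (is.null(fx)) {
        fx <- list(structure_id = sid,
                   bprime = rep(0, n_residues(st)), source = "bfactor")
        class(fx) <- "flex_profile"
      }
      characterize_pocket(pockets[i, ], st,
                          conservation = profiles[[sid]], flex = fx,
                          alpha = config$alpha)
    })
    pocket_reports <- do.call(rbind, rows)
    rank_of <- rep(NA_integer_, nrow(pockets))
    for (cl in clusters) rank_of[cl$members] <- cl$cluster_rank
    pocket_reports$cluster_rank <- rank_of[match(pocket_reports$pocket_id,
                                                 pockets$pocket_id)]
    p <- file.path(config$out_dir, "pocket_reports.tsv")
    .write_tsv(pocket_reports, p)
    paths <- c(paths, p)

    cluster_summaries <- do.call(rbind, lapply(clusters, summarize_cluster,
                                               reports = pocket_reports))
    p <- file.path(config$out_dir, "cluster_summaries.tsv")
    .write_tsv(cluster_summaries, p)
    paths <- c(paths, p)
  }

  # active-site mapping
  active <- NULL
  as_rank <- NA_integer_
  if (!is.null(config$annotations_path) && nrow(pockets) > 0) {
    anns <- read_annotation_tsv(config$annotations_path)
    anns <- Filter(function(a) a$structure_id %in% reps, anns)
    maps <- lapply(anns, map_active_site, pockets = pockets)
    active <- data.frame(
      structure_id = vapply(anns, `[[`, character(1), "structure_id"),
      pocket_id = vapply(maps, `[[`, character(1), "pocket_id"),
      ambiguous = vapply(maps, `[[`, logical(1), "ambiguous"),
      stringsAsFactors = FALSE
    )
    p <- file.path(config$out_dir, "active_site_map.tsv")
    .write_tsv(active, p)
    paths <- c(paths, p)
    unambig <- active$pocket_id[!is.na(active$pocket_id) & !active$ambiguous]
    as_rank <- active_site_cluster(cluster_table, unambig)
    log_lines <- c(log_lines,
                   sprintf("active-site cluster: %s",
                           ifelse(is.na(as_rank), "none", as_rank)))
  }

  # conserved-pair scan
  pairs <- NULL
  if (!low_m && nrow(cluster_table) >= 2) {
    pairs <- scan_pairs(cluster_table, cluster_summaries,
                        min_distance = config$pair_min_distance,
                        str_threshold = config$str_threshold,
                        seq_threshold = config$seq_threshold,
                        active_site_rank = as_rank,
                        family_id = config$family_id)
    p <- file.path(config$out_dir, "pairs.tsv")
    .write_tsv(pairs, p)
    paths <- c(paths, p)
    log_lines <- c(log_lines, sprintf("qualifying cluster pairs: %d",
                                      nrow(pairs)))
  }

  # human-readable summary: top 3 clusters + active-site cluster
  show <- unique(c(seq_len(min(3, nrow(cluster_table))),
                   if (!is.na(as_rank)) as_rank))
  for (r in show) {
    row <- cluster_table[cluster_table$cluster_rank == r, ]
    extra <- ""
    if (!is.null(cluster_summaries)) {
      s <- cluster_summaries[cluster_summaries$cluster_rank == r, ]
      extra <- sprintf(" seq_conserved=%.1f%% flexible=%.1f%% rigid=%.1f%%",
                       s$pct_seq_conserved, s$pct_flexible, s$pct_rigid)
    }
    log_lines <- c(log_lines,
                   sprintf("cluster %d%s: n_c=%d str_c=%.1f%% score=%.1f%s",
                           r, ifelse(!is.na(as_rank) && r == as_rank,
                                     " (active site)", ""),
                           row$n_c, row$str_c, row$score_c, extra))
  }
  p <- file.path(config$out_dir, "summary.txt")
  writeLines(log_lines, p)
  paths <- c(paths, p)

  invisible(list(
    family = fam, superposed = sup, pockets = pockets,
    cluster_table = cluster_table, profiles = profiles,
    pocket_reports = pocket_reports, cluster_summaries = cluster_summaries,
    active_site = active, active_site_rank = as_rank, pairs = pairs,
    threshold = threshold, paths = paths
  ))
}
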