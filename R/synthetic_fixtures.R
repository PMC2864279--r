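#' Helical Calpha scaffold
#'
#' An alpha-helix-like curve sampled so that consecutive Calpha atoms are
#' ~3.8 Angstrom apart (2.3 A radius, 1.5 A rise, 100 degrees per residue),
#' giving realistic inter-residue distances for the 8 A residue-assignment
#' rule.
#'
#' @param n_res Number of residues.
#' @return An `n_res` x 3 coordinate matrix.
#' @export
gen_scaffold <- function(n_res) {
  i <- seq_len(n_res) - 1
  ang <- i * 100 * pi / 180
  cbind(x = 2.3 * cos(ang), y = 2.3 * sin(ang), z = 1.5 * i)
}

# Uniform random proper rotation (QR of a Gaussian matrix, det +1).
.random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Build a protein_structure on given coordinates with defaults suitable for
# fixtures.
.fixture_structure <- function(id, coords, sequence = NULL, bfactors = NULL,
                               method = "xray", resolution = 2.0,
                               models = NULL) {
  n <- nrow(coords)
  if (is.null(sequence)) sequence <- paste(rep("A", n), collapse = "")
  if (is.null(bfactors)) bfactors <- rep(10, n)
  residues <- data.frame(
    chain = rep("A", n), resno = seq_len(n), insert = rep("", n),
    resid = bio3d::aa123(strsplit(sequence, "")[[1]]),
    stringsAsFactors = FALSE
  )
  protein_structure(id = id, residues = residues, calpha_coords = coords,
                    bfactors = bfactors, sequence = sequence,
                    method = method, resolution = resolution, models = models)
}

#' Specification of one planted pocket cluster
#'
#' @param center Numeric 3-vector, cluster center in the scaffold frame.
#' @param presence Per-structure probability of contributing a pocket.
#' @param size_mean,size_sd Normal parameters for pocket sizes (grid points).
#' @param jitter SD (Angstrom, per coordinate) of member centers about the
#'   cluster center.
#' @return A list usable in [gen_family()]'s `clusters` argument.
#' @export
planted_cluster <- function(center, presence = 1.0, size_mean = 100,
                            size_sd = 10, jitter = 0.5) {
  stopifnot(presence >= 0, presence <= 1, length(center) == 3)
  list(center = as.numeric(center), presence = presence,
       size_mean = size_mean, size_sd = size_sd, jitter = jitter)
}

#' Generate a synthetic protein family with planted pocket clusters
#'
#' Emits `m` perturbed copies of a helical Calpha scaffold (i.i.d. Gaussian
#' coordinate noise of SD `noise_sigma`), each optionally moved by a random
#' rigid transform so the superposition stage has real work to do. Pockets
#' are planted around the given cluster centers with the stated per-structure
#' presence probabilities, plus optional uniform scatter pockets. Member
#' sequences are copies of a random base sequence mutated at rate
#' `mutation_rate` outside the `conserved_residues` positions, and double as
#' a gap-free alignment. Per-pocket truth labels and realized per-cluster
#' coverage are returned alongside.
#'
#' @param seed Integer seed; fully determines the output.
#' @param m Number of structures.
#' @param n_res Residues per structure.
#' @param noise_sigma Coordinate noise SD, Angstrom.
#' @param clusters List of [planted_cluster()] specs.
#' @param scatter_rate Expected number of random decoy pockets per structure.
#' @param mutation_rate Per-position mutation probability for member
#'   sequences.
#' @param conserved_residues Residue indices never mutated (planted conserved
#'   alignment columns).
#' @param apply_rigid Apply a random rotation + translation to each member
#'   (and its pockets)?
#' @param active_site_cluster Index into `clusters` marking the planted
#'   active site, or `NA` for none; annotations list the 2 scaffold residues
#'   nearest that cluster's center.
#'
#' @return List with `family` (a [family_set()], representatives = all
#'   members, reference chosen), `pockets` (pocket table in each member's own
#'   frame), `pockets_common` (the same pockets in the common scaffold
#'   frame), `truth` (per-pocket `cluster` label, 0 = scatter, and per-cluster
#'   realized `coverage` in percent), `msa`, `annotations`, and the `seed`.
#' @export
gen_family <- function(seed, m = 20, n_res = 60, noise_sigma = 0.5,
                       clusters = list(planted_cluster(c(0, 0, 30))),
                       scatter_rate = 0, mutation_rate = 0.1,
                       conserved_residues = integer(0),
                       apply_rigid = TRUE, active_site_cluster = NA) {
  set.seed(seed)
  scaffold <- gen_scaffold(n_res)
  base_seq <- sample(.AA20, n_res, replace = TRUE)

  members <- vector("list", m)
  msa <- character(m)
  pk_rows <- list()
  pk_rows_common <- list()
  labels <- integer(0)
  present <- matrix(FALSE, nrow = m, ncol = length(clusters))
  ann_res <- NULL
  if (!is.na(active_site_cluster)) {
    ctr <- clusters[[active_site_cluster]]$center
    d2 <- colSums((t(scaffold) - ctr)^2)
    ann_res <- order(d2)[1:2]
  }
  annotations <- list()

  for (s in seq_len(m)) {
    sid <- sprintf("S%02d", s)
    coords <- scaffold + matrix(stats::rnorm(3 * n_res, sd = noise_sigma),
                                ncol = 3)
    colnames(coords) <- c("x", "y", "z")
    aa <- base_seq
    mut <- stats::runif(n_res) < mutation_rate
    mut[conserved_residues] <- FALSE
    if (any(mut)) aa[mut] <- sample(.AA20, sum(mut), replace = TRUE)
    seq1 <- paste(aa, collapse = "")
    msa[s] <- seq1

    # pockets in the common frame
    centers <- list()
    sizes <- integer(0)
    labs <- integer(0)
    for (k in seq_along(clusters)) {
      cl <- clusters[[k]]
      if (stats::runif(1) <= cl$presence) {
        centers[[length(centers) + 1L]] <-
          cl$center + stats::rnorm(3, sd = cl$jitter)
        sizes <- c(sizes, max(1L, round(stats::rnorm(1, cl$size_mean,
                                                     cl$size_sd))))
        labs <- c(labs, k)
        present[s, k] <- TRUE
      }
    }
    n_scatter <- if (scatter_rate > 0) stats::rpois(1, scatter_rate) else 0L
    if (n_scatter > 0) {
      lo <- apply(scaffold, 2, min) - 15
      hi <- apply(scaffold, 2, max) + 15
      for (q in seq_len(n_scatter)) {
        centers[[length(centers) + 1L]] <- stats::runif(3, lo, hi)
        sizes <- c(sizes, max(1L, round(stats::rnorm(1, 40, 10))))
        labs <- c(labs, 0L)
      }
    }

    rigid <- if (apply_rigid) {
      list(rotation = .random_rotation(),
           translation = stats::runif(3, -20, 20))
    } else {
      list(rotation = diag(3), translation = c(0, 0, 0))
    }
    member_coords <- apply_transform(coords, rigid)
    colnames(member_coords) <- c("x", "y", "z")
    members[[s]] <- .fixture_structure(
      sid, member_coords, sequence = seq1,
      bfactors = round(stats::rnorm(n_res, 50, 10), 2),
      resolution = round(stats::runif(1, 1.5, 2.8), 2)
    )

    if (length(centers)) {
      for (q in seq_along(centers)) {
        ctr_common <- centers[[q]]
        ctr_member <- as.numeric(rigid$rotation %*% ctr_common +
                                   rigid$translation)
        # residue assignment uses the member's own geometry (common frame
        # noisy coords are congruent to the member frame)
        d2 <- colSums((t(coords) - ctr_common)^2)
        res <- paste0("A:", which(d2 <= 8^2))
        pid <- sprintf("%s|P%d", sid, q)
        pk_rows[[length(pk_rows) + 1L]] <- data.frame(
          structure_id = sid, pocket_id = pid,
          x = ctr_member[1], y = ctr_member[2], z = ctr_member[3],
          size = sizes[q], n_residues = length(res),
          residues = paste(res, collapse = ";"), stringsAsFactors = FALSE
        )
        pk_rows_common[[length(pk_rows_common) + 1L]] <- data.frame(
          structure_id = sid, pocket_id = pid,
          x = ctr_common[1], y = ctr_common[2], z = ctr_common[3],
          size = sizes[q], n_residues = length(res),
          residues = paste(res, collapse = ";"), stringsAsFactors = FALSE
        )
      }
      labels <- c(labels, labs)
    }
    if (!is.null(ann_res)) {
      annotations[[length(annotations) + 1L]] <-
        list(structure_id = sid, residues = paste0("A:", ann_res))
    }
  }

  names(msa) <- vapply(members, `[[`, character(1), "id")
  fam <- family_set("FAM_SYNTH", members,
                    representative_ids = names(msa))
  fam <- family_set(fam$family_id, fam$members,
                    representative_ids = fam$representative_ids,
                    reference_id = choose_reference(fam))
  bind <- function(rows) {
    if (length(rows) == 0) {
      return(read_pocket_tsv_empty())
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  list(
    seed = seed,
    family = fam,
    pockets = bind(pk_rows),
    pockets_common = bind(pk_rows_common),
    truth = list(
      labels = labels,
      coverage = 100 * colSums(present) / m,
      present = present
    ),
    msa = msa,
    annotations = annotations,
    active_site_cluster = active_site_cluster
  )
}

# Empty pocket table with the canonical columns.
read_pocket_tsv_empty <- function() {
  data.frame(structure_id = character(0), pocket_id = character(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             size = integer(0), n_residues = integer(0),
             residues = character(0), stringsAsFactors = FALSE)
}

#' Hollow cubic shell fixture for the pocket detector
#'
#' Pseudo-atoms tile the six faces of a closed cube so that the detector's
#' protein mask leaves a cavity of the requested inner width around a known
#' center — ground truth for detector geometry tests.
#'
#' @param inner_width Cavity width, Angstrom (must exceed twice the detector
#'   grid spacing).
#' @param thickness Wall thickness, Angstrom (> 0; converted to atom layers).
#' @param spacing Atom spacing on each face, Angstrom.
#' @param center Cavity center, Angstrom.
#' @param pad Protein-mask reach of one atom (probe + atom radius of the
#'   intended [grid_params()]), Angstrom.
#' @param grid_spacing Detector grid spacing the cavity must accommodate.
#' @param id Structure id.
#' @return A [protein_structure()] with attribute `cavity_center`.
#' @export
gen_hollow_shell <- function(inner_width, thickness = 1.5, spacing = 1.5,
                             center = c(0, 0, 0), pad = 3.3,
                             grid_spacing = 1.0, id = "shell") {
  if (thickness <= 0) stop("thickness must be > 0")
  if (inner_width <= 2 * grid_spacing) {
    stop("inner_width must exceed twice the grid spacing")
  }
  n_layers <- max(1L, as.integer(round(thickness / spacing)))
  pts <- list()
  for (l in seq_len(n_layers) - 1L) {
    w <- inner_width / 2 + pad + l * spacing
    g <- seq(-w, w, by = spacing)
    if (g[length(g)] < w) g <- c(g, w)
    face <- as.matrix(expand.grid(a = g, b = g))
    for (axis in 1:3) {
      for (sgn in c(-w, w)) {
        f <- matrix(0, nrow(face), 3)
        f[, axis] <- sgn
        f[, setdiff(1:3, axis)] <- face
        pts[[length(pts) + 1L]] <- f
      }
    }
  }
  coords <- unique(do.call(rbind, pts))
  coords <- sweep(coords, 2, center, "+")
  colnames(coords) <- c("x", "y", "z")
  s <- .fixture_structure(id, coords)
  attr(s, "cavity_center") <- as.numeric(center)
  s
}

#' Concatenate structures into one (e.g. two shells in one frame)
#'
#' @param structures List of [protein_structure()] objects.
#' @param id Id for the combined structure.
#' @return A single [protein_structure()] with renumbered residues.
#' @export
merge_structures <- function(structures, id = "merged") {
  coords <- do.call(rbind, lapply(structures, `[[`, "calpha_coords"))
  n <- nrow(coords)
  seq1 <- paste(vapply(structures, `[[`, character(1), "sequence"),
                collapse = "")
  b <- unlist(lapply(structures, `[[`, "bfactors"))
  s <- .fixture_structure(id, coords, sequence = seq1, bfactors = b)
  s
}

#' Generate a random alignment with planted conserved columns
#'
#' Non-conserved columns draw uniformly over the 20 amino acids per sequence;
#' conserved columns are fixed to a single residue type across all sequences.
#'
#' @param seed Integer seed.
#' @param n_sequences,n_columns Alignment dimensions.
#' @param conserved_cols Integer column indices planted as invariant.
#' @param gap_rate Per-cell probability of a gap in non-conserved columns.
#' @return Named character vector of aligned sequences, with attribute
#'   `conserved_cols`.
#' @export
gen_msa <- function(seed, n_sequences = 10, n_columns = 30,
                    conserved_cols = integer(0), gap_rate = 0) {
  set.seed(seed)
  m <- matrix(sample(.AA20, n_sequences * n_columns, replace = TRUE),
              n_sequences, n_columns)
  if (gap_rate > 0) {
    g <- matrix(stats::runif(length(m)) < gap_rate, n_sequences, n_columns)
    m[g] <- "-"
  }
  for (j in conserved_cols) m[, j] <- sample(.AA20, 1)
  msa <- apply(m, 1, paste, collapse = "")
  names(msa) <- sprintf("seq%02d", seq_len(n_sequences))
  attr(msa, "conserved_cols") <- conserved_cols
  msa
}

#' Generate a structure with planted flexibility patches
#'
#' B factors are drawn from a Normal(50, 10^2) baseline; each planted patch
#' shifts its residues' mean by `shift` baseline SDs (negative = rigid,
#' positive = flexible).
#'
#' @param seed Integer seed.
#' @param n_res Number of residues.
#' @param patches List of lists with `start`, `len`, `shift` (in SD units).
#' @return A [protein_structure()] with attribute `patches`.
#' @export
gen_flex <- function(seed, n_res = 100, patches = list()) {
  set.seed(seed)
  b <- stats::rnorm(n_res, 50, 10)
  for (p in patches) {
    idx <- seq(p$start, length.out = p$len)
    b[idx] <- stats::rnorm(p$len, 50 + p$shift * 10, 10)
  }
  s <- .fixture_structure(sprintf("flex%d", seed), gen_scaffold(n_res),
                          bfactors = round(b, 2))
  attr(s, "patches") <- patches
  s
}

#' Write a structure as a PDB file
#'
#' Emits standard fixed-width ATOM records for the Calpha trace, an EXPDTA
#' record for the method, a REMARK 2 resolution record, and MODEL/ENDMDL
#' blocks for ensembles, so generated fixtures round-trip through
#' [read_structure()].
#'
#' @param structure A [protein_structure()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  lines <- character(0)
  expdta <- switch(structure$method,
                   xray = "X-RAY DIFFRACTION",
                   nmr = "SOLUTION NMR",
                   "UNKNOWN")
  lines <- c(lines, sprintf("EXPDTA    %s", expdta))
  if (!is.na(structure$resolution)) {
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.",
                              structure$resolution))
  } else {
    lines <- c(lines, "REMARK   2 RESOLUTION. NOT APPLICABLE.")
  }
  atom_block <- function(coords) {
    r <- structure$residues
    sprintf(
      "ATOM  %5d  CA  %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(nrow(r)), r$resid, r$chain, r$resno,
      ifelse(r$insert == "", " ", r$insert),
      coords[, 1], coords[, 2], coords[, 3],
      1.00, structure$bfactors
    )
  }
  if (!is.null(structure$models) && length(structure$models) >= 2) {
    for (i in seq_along(structure$models)) {
      lines <- c(lines, sprintf("MODEL     %4d", i),
                 atom_block(structure$models[[i]]), "ENDMDL")
    }
  } else {
    lines <- c(lines, atom_block(structure$calpha_coords))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a generated family to disk as standard files
#'
#' Emits one PDB per member, the alignment as aligned FASTA, active-site
#' annotations as TSV, the planted pocket table as TSV, and a manifest JSON
#' recording the ground truth — the on-disk input set for the end-to-end
#' pipeline and the command-line interface.
#'
#' @param bundle Output of [gen_family()].
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_family_fixture <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pdbs <- character(0)
  for (s in bundle$family$members) {
    p <- file.path(dir, paste0(s$id, ".pdb"))
    write_structure_pdb(s, p)
    pdbs <- c(pdbs, p)
  }
  msa_path <- file.path(dir, "family.afa")
  write_msa_fasta(bundle$msa, msa_path)
  pockets_path <- file.path(dir, "pockets.tsv")
  write_pocket_tsv(bundle$pockets, pockets_path)
  ann_path <- NA_character_
  if (length(bundle$annotations)) {
    ann_path <- file.path(dir, "active_sites.tsv")
    write_annotation_tsv(bundle$annotations, ann_path)
  }
  manifest <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(seed = bundle$seed,
         m = bundle$family$m,
         coverage = bundle$truth$coverage,
         labels = bundle$truth$labels,
         active_site_cluster = bundle$active_site_cluster),
    manifest, auto_unbox = TRUE, digits = NA
  )
  invisible(list(pdbs = pdbs, msa = msa_path, pockets = pockets_path,
                 annotations = ann_path, manifest = manifest))
}
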