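#' Grid parameters for pocket detection
#'
#' Defaults are tuned so that globular structures yield on the order of 5-10
#' pockets: 1.0 A spacing, a 1.6 A probe over a uniform 1.7 A atom radius,
#' enclosure on at least 5 of the 7 scan directions, a 30-point minimum
#' component size and at most 10 reported pockets.
#'
#' @param spacing Grid spacing in Angstrom (> 0).
#' @param probe_radius Solvent probe radius in Angstrom.
#' @param atom_radius Uniform atom radius in Angstrom.
#' @param psp_min Minimum protein-solvent-protein direction count (1-7) for a
#'   grid point to be a pocket point.
#' @param min_pocket_points Minimum connected-component size (grid points).
#' @param max_pockets Maximum number of pockets reported per structure.
#' @param margin Grid margin beyond the structure bounding box, Angstrom.
#'
#' @return A list of class `grid_params`.
#' @export
grid_params <- function(spacing = 1.0, probe_radius = 1.6, atom_radius = 1.7,
                        psp_min = 5, min_pocket_points = 30, max_pockets = 10,
                        margin = 8.0) {
  stopifnot(spacing > 0, psp_min >= 1, psp_min <= 7, min_pocket_points >= 1,
            max_pockets >= 1, margin >= 0)
  out <- list(spacing = spacing, probe_radius = probe_radius,
              atom_radius = atom_radius, psp_min = psp_min,
              min_pocket_points = min_pocket_points,
              max_pockets = max_pockets, margin = margin)
  class(out) <- "grid_params"
  out
}

# Shadow mask: TRUE where some protein grid point lies strictly beyond the
# point along integer grid direction d. One ordered sweep per direction.
.shadow <- function(P, d) {
  ax <- which(d != 0)[1]
  perm <- c(ax, setdiff(1:3, ax))
  Pp <- aperm(P, perm)
  dp <- d[perm]
  dims <- dim(Pp)
  rng <- function(nd, dd) {
    if (dd == 0) list(t = seq_len(nd), s = seq_len(nd))
    else if (dd == 1) list(t = seq_len(nd - 1), s = 2:nd)
    else list(t = 2:nd, s = seq_len(nd - 1))
  }
  i2 <- rng(dims[2], dp[2])
  i3 <- rng(dims[3], dp[3])
  A <- array(FALSE, dims)
  n1 <- dims[1]
  is <- if (dp[1] == 1) seq(n1 - 1, 1) else seq(2, n1)
  for (i in is) {
    src <- i + dp[1]
    A[i, i2$t, i3$t] <- Pp[src, i2$s, i3$s] | A[src, i2$s, i3$s]
  }
  aperm(A, order(perm))
}

# The 7 scan directions: 3 axes + 4 cube diagonals.
.psp_directions <- function() {
  list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
       c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

# 26-connectivity component labelling of flagged grid points.
.components26 <- function(pts, dims) {
  n <- length(pts)
  idx3 <- arrayInd(pts, dims)
  id_of <- integer(prod(dims))
  id_of[pts] <- seq_len(n)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  nxy <- dims[1] * dims[2]
  comp <- integer(n)
  cur <- 0L
  for (seed in seq_len(n)) {
    if (comp[seed] > 0L) next
    cur <- cur + 1L
    comp[seed] <- cur
    queue <- seed
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      nb <- sweep(off, 2, idx3[p, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] + (nb[, 3] - 1L) * nxy
      qi <- id_of[lin]
      qi <- qi[qi > 0L]
      qi <- qi[comp[qi] == 0L]
      if (length(qi)) {
        comp[qi] <- cur
        queue <- c(queue, qi)
      }
    }
  }
  comp
}

#' Detect ligand-binding pockets with a protein-solvent-protein grid scan
#'
#' A rectangular grid is laid over the structure with the given spacing and
#' margin. Grid points within `probe_radius + atom_radius` of any Calpha
#' pseudo-atom are "protein"; the rest are solvent. Each solvent point is
#' scanned along 7 directions (3 axes, 4 cube diagonals); its
#' protein-solvent-protein (PSP) count is the number of directions on which
#' protein encloses it on both sides. Solvent points with PSP count at or
#' above `psp_min` are pocket points, grouped by 26-connectivity; components
#' of at least `min_pocket_points` points become pockets, ordered by
#' descending size and truncated at `max_pockets`. Each pocket's center is
#' the mean of its grid-point coordinates and its size is the grid-point
#' count. Residues within `residue_radius` of the center are assigned to the
#' pocket.
#'
#' @param structure A [protein_structure()] (or any object with a
#'   `calpha_coords` matrix); coordinates must be finite.
#' @param params A [grid_params()] object.
#' @param residue_radius Residue assignment radius in Angstrom.
#' @return A pocket table: data frame with columns `structure_id`,
#'   `pocket_id`, `x`, `y`, `z`, `size`, `n_residues`, `residues`
#'   (semicolon-joined residue keys). Attribute `grid_spacing` records the
#'   spacing used.
#' @export
detect_pockets <- function(structure, params = grid_params(),
                           residue_radius = 8.0) {
  coords <- structure$calpha_coords
  if (is.null(coords) || nrow(coords) == 0) stop("empty structure")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  sp <- params$spacing
  origin <- apply(coords, 2, min) - params$margin
  upper <- apply(coords, 2, max) + params$margin
  dims <- pmax(as.integer(floor((upper - origin) / sp)) + 1L, 2L)

  # protein mask: union of balls of radius probe + atom radius
  P <- array(FALSE, dims)
  r <- params$probe_radius + params$atom_radius
  r2 <- r^2
  for (k in seq_len(nrow(coords))) {
    at <- coords[k, ]
    lo <- pmax(as.integer(ceiling((at - r - origin) / sp)) + 1L, 1L)
    hi <- pmin(as.integer(floor((at - r - origin) / sp + 2 * r / sp)) + 1L, dims)
    if (any(lo > hi)) next
    gx <- origin[1] + (seq(lo[1], hi[1]) - 1) * sp
    gy <- origin[2] + (seq(lo[2], hi[2]) - 1) * sp
    gz <- origin[3] + (seq(lo[3], hi[3]) - 1) * sp
    d2 <- outer(outer((gx - at[1])^2, (gy - at[2])^2, "+"), (gz - at[3])^2, "+")
    P[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      P[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] | (d2 <= r2)
  }

  psp <- array(0L, dims)
  for (d in .psp_directions()) {
    enc <- .shadow(P, d) & .shadow(P, -d)
    psp <- psp + enc
  }
  pocket_mask <- !P & psp >= params$psp_min
  pts <- which(pocket_mask)

  empty <- data.frame(
    structure_id = character(0), pocket_id = character(0),
    x = numeric(0), y = numeric(0), z = numeric(0), size = integer(0),
    n_residues = integer(0), residues = character(0), stringsAsFactors = FALSE
  )
  attr(empty, "grid_spacing") <- sp
  if (length(pts) == 0) return(empty)

  comp <- .components26(pts, dims)
  idx3 <- arrayInd(pts, dims)
  sizes <- tabulate(comp)
  keep <- which(sizes >= params$min_pocket_points)
  if (length(keep) == 0) return(empty)
  first_pt <- vapply(keep, function(cc) min(pts[comp == cc]), numeric(1))
  ord <- keep[order(-sizes[keep], first_pt, method = "radix")]
  ord <- ord[seq_len(min(length(ord), params$max_pockets))]

  rows <- lapply(seq_along(ord), function(i) {
    cc <- ord[i]
    member <- idx3[comp == cc, , drop = FALSE]
    center <- origin + (colMeans(member) - 1) * sp
    res <- assign_pocket_residues(center, structure, radius = residue_radius)
    data.frame(
      structure_id = structure$id,
      pocket_id = sprintf("%s|P%d", structure$id, i),
      x = center[1], y = center[2], z = center[3],
      size = sizes[cc], n_residues = length(res),
      residues = paste(res, collapse = ";"), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "grid_spacing") <- sp
  out
}

#' Assign residues to a pocket center
#'
#' Returns the residues whose Calpha lies within `radius` (closed boundary)
#' of the pocket's center of mass, in structure order.
#'
#' @param center Numeric 3-vector, pocket center in the structure's frame.
#' @param structure A [protein_structure()].
#' @param radius Assignment radius in Angstrom.
#' @return Character vector of residue keys (see [residue_keys()]).
#' @export
assign_pocket_residues <- function(center, structure, radius = 8.0) {
  d2 <- colSums((t(structure$calpha_coords) - center)^2)
  residue_keys(structure)[d2 <= radius^2]
}

#' Write a pocket table as TSV
#' @param pockets Pocket table from [detect_pockets()] or [read_pocket_tsv()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_pocket_tsv <- function(pockets, path) {
  utils::write.table(pockets, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pocket table from TSV
#'
#' Accepts externally computed pocket lists (at minimum `structure_id`,
#' `pocket_id`, `x`, `y`, `z`, `size`), so the clustering layers are
#' detector-agnostic.
#'
#' @param path TSV path.
#' @return Pocket table data frame.
#' @export
read_pocket_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(structure_id = "character",
                                         pocket_id = "character"))
  need <- c("structure_id", "pocket_id", "x", "y", "z", "size")
  if (!all(need %in% names(df))) {
    stop("pocket table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$residues)) df$residues <- ""
  if (is.null(df$n_residues)) {
    df$n_residues <- ifelse(df$residues == "", 0L,
                            lengths(strsplit(df$residues, ";", fixed = TRUE)))
  }
  df
}

# Split a semicolon-joined residue field into a character vector.
split_residues <- function(residues) {
  if (is.na(residues) || residues == "") return(character(0))
  strsplit(residues, ";", fixed = TRUE)[[1]]
}
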