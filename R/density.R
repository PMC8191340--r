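# Voxelized ion density maps, GFE conversion, overlap coefficient, and
# density-peak binding-site detection.

#' Gas constant in kcal/(mol K)
#' @export
GAS_CONSTANT_KCAL <- 1.9872e-3

#' Construct a density grid
#'
#' Voxel \code{(i, j, k)} (1-based) is centered at
#' \code{origin + (c(i, j, k) - 1) * spacing}.
#'
#' @param values numeric 3D array (nx x ny x nz), all >= 0.
#' @param origin center of the first voxel (A), length 3.
#' @param spacing per-axis voxel spacing (A), length 1 or 3.
#' @param normalization one of \code{"raw_counts"}, \code{"counts_per_frame"},
#'   \code{"probability"}.
#' @param n_frames number of frames accumulated into the grid.
#' @return An object of class \code{density_grid}.
#' @export
density_grid <- function(values, origin, spacing = 1,
                         normalization = "raw_counts", n_frames = 0L) {
  values <- unname(values)
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  if (any(values < 0)) stop("density values must be >= 0")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  origin <- as.numeric(origin)
  if (length(origin) != 3) stop("origin must have length 3")
  normalization <- match.arg(normalization,
                             c("raw_counts", "counts_per_frame", "probability"))
  structure(list(values = values, origin = origin, spacing = spacing,
                 normalization = normalization,
                 n_frames = as.integer(n_frames)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "density_grid: %d x %d x %d voxels, spacing %.3g/%.3g/%.3g A, %s (%d frames)\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    x$normalization, x$n_frames))
  invisible(x)
}

.same_lattice <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

# Nearest-voxel (top-hat) bin index per axis; NA when outside the lattice.
.voxel_index <- function(x, origin, spacing, n) {
  i <- as.integer(round((x - origin) / spacing)) + 1L
  i[i < 1L | i > n] <- NA_integer_
  i
}

#' Accumulate an ion density grid from a trajectory
#'
#' Each selected ion position increments exactly one voxel per frame
#' (nearest-voxel binning), so the total count equals the number of
#' in-extent (ion, frame) pairs exactly.
#'
#' @param traj an \code{ion_trajectory}.
#' @param topology matching \code{ion_topology}.
#' @param species species label(s) selecting the ions to bin (see
#'   \code{\link{ion_indices}}); alternatively \code{atoms} gives explicit
#'   atom indices.
#' @param atoms optional integer atom indices overriding \code{species}.
#' @param spacing voxel spacing (A), default 1.
#' @param extent optional list \code{(origin, shape)} fixing the lattice;
#'   when \code{NULL} the lattice is the selection's bounding box plus
#'   \code{padding}.
#' @param padding padding (A) added around the auto-computed bounding box.
#' @param frames optional integer vector of frame indices to accumulate.
#' @return A \code{density_grid} with \code{normalization = "raw_counts"}.
#' @export
accumulate_density <- function(traj, topology, species = NULL, atoms = NULL,
                               spacing = 1, extent = NULL, padding = 2,
                               frames = NULL) {
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  if (!length(frames)) stop("no frames to accumulate")
  if (is.null(atoms)) atoms <- ion_indices(topology, species)
  if (!length(atoms)) stop("empty ion selection")
  spacing <- rep_len(as.numeric(spacing), 3)
  pts <- matrix(aperm(traj$coords[atoms, , frames, drop = FALSE],
                      c(1, 3, 2)), ncol = 3)
  if (is.null(extent)) {
    lo <- apply(pts, 2, min) - padding
    hi <- apply(pts, 2, max) + padding
    origin <- lo
    shape <- pmax(as.integer(floor((hi - lo) / spacing)) + 1L, 1L)
  } else {
    origin <- as.numeric(extent$origin)
    shape <- as.integer(extent$shape)
  }
  ii <- .voxel_index(pts[, 1], origin[1], spacing[1], shape[1])
  jj <- .voxel_index(pts[, 2], origin[2], spacing[2], shape[2])
  kk <- .voxel_index(pts[, 3], origin[3], spacing[3], shape[3])
  ok <- !is.na(ii) & !is.na(jj) & !is.na(kk)
  lin <- (ii[ok] - 1L) + shape[1] * ((jj[ok] - 1L) + shape[2] * (kk[ok] - 1L))
  counts <- tabulate(lin + 1L, nbins = prod(shape))
  density_grid(array(as.numeric(counts), dim = shape), origin, spacing,
               "raw_counts", n_frames = length(frames))
}

#' Renormalize a density grid
#'
#' @param grid a \code{density_grid} with raw counts.
#' @param mode \code{"counts_per_frame"} (counts / n_frames) or
#'   \code{"probability"} (counts / total counts).
#' @return A \code{density_grid} in the requested normalization. The raw
#'   totals are retained so \code{\link{denormalize_density}} can recover
#'   the integer counts exactly.
#' @export
normalize_density <- function(grid, mode = c("counts_per_frame",
                                             "probability")) {
  mode <- match.arg(mode)
  if (grid$normalization != "raw_counts")
    stop("normalize_density expects a raw_counts grid")
  total <- sum(grid$values)
  if (mode == "probability" && total == 0)
    stop("cannot normalize an all-zero grid to a probability")
  denom <- if (mode == "counts_per_frame") grid$n_frames else total
  if (denom <= 0) stop("grid has no accumulated frames")
  out <- grid
  out$values <- grid$values / denom
  out$normalization <- mode
  attr(out, "denominator") <- denom
  out
}

#' Recover raw counts from a normalized grid
#' @param grid a grid produced by \code{\link{normalize_density}}.
#' @return The raw-counts \code{density_grid} (exact integers).
#' @export
denormalize_density <- function(grid) {
  denom <- attr(grid, "denominator")
  if (is.null(denom)) stop("grid does not carry its normalization denominator")
  out <- grid
  out$values <- round(grid$values * denom)
  out$normalization <- "raw_counts"
  attr(out, "denominator") <- NULL
  out
}

#' Convert occupancy to a grid free energy (GFE) map
#'
#' Per voxel, \code{GFE = min(-R T ln(occ / bulk), cap)} with
#' \code{R = 1.9872e-3} kcal/(mol K). Zero occupancy maps to the cap, and
#' the cap is reached exactly when \code{occ / bulk <= exp(-cap / (R T))}.
#'
#' @param grid a \code{density_grid} in counts-per-frame normalization.
#' @param bulk bulk occupancy reference (counts per frame per voxel), > 0;
#'   \code{NULL} uses the mean over voxels of \code{bulk_mask}.
#' @param bulk_mask optional logical array (same shape) designating a bulk
#'   shell for estimating \code{bulk}.
#' @param temperature temperature (K), default 300.
#' @param cap GFE cap (kcal/mol), default 3.
#' @return An object of class \code{gfe_map}: grid lattice plus per-voxel
#'   GFE values (kcal/mol), \code{temperature}, \code{cap}, \code{bulk}.
#' @export
gfe_from_density <- function(grid, bulk = NULL, bulk_mask = NULL,
                             temperature = 300, cap = 3) {
  if (grid$normalization != "counts_per_frame")
    stop("gfe_from_density expects a counts_per_frame grid")
  if (is.null(bulk)) {
    if (is.null(bulk_mask))
      stop("give either `bulk` or `bulk_mask`")
    bulk <- mean(grid$values[bulk_mask])
  }
  if (!is.finite(bulk) || bulk <= 0) stop("bulk occupancy must be > 0")
  rt <- GAS_CONSTANT_KCAL * temperature
  gfe <- pmin(-rt * log(grid$values / bulk), cap)
  structure(list(values = array(gfe, dim = dim(grid$values)),
                 origin = grid$origin, spacing = grid$spacing,
                 temperature = temperature, cap = cap, bulk = bulk),
            class = "gfe_map")
}

#' @export
print.gfe_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "gfe_map: %d x %d x %d voxels, T %.1f K, cap %.2f kcal/mol, min %.3f\n",
    d[1], d[2], d[3], x$temperature, x$cap, min(x$values)))
  invisible(x)
}

#' Overlap coefficient between two density maps
#'
#' \code{OC = sum_i min(a_i, b_i)} where \code{a}, \code{b} are the two
#' maps' values, thresholded then normalized to sum to 1. Symmetric,
#' bounded in [0, 1], equal to 1 iff the maps are proportional, and
#' invariant to rescaling either map.
#'
#' @param map_a,map_b two \code{density_grid}s on identical lattices.
#' @param exclusion_threshold voxels with value <= this (in each map's own
#'   units) are zeroed before normalization; default 0.
#' @return Overlap coefficient in [0, 1].
#' @export
overlap_coefficient <- function(map_a, map_b, exclusion_threshold = 0) {
  if (!.same_lattice(map_a, map_b))
    stop("overlap_coefficient requires identical lattices")
  norm1 <- function(v) {
    v[v <= exclusion_threshold] <- 0
    s <- sum(v)
    if (s == 0) stop("map is empty after applying the exclusion threshold")
    v / s
  }
  sum(pmin(norm1(as.numeric(map_a$values)), norm1(as.numeric(map_b$values))))
}

# 6-connected (face) component labels of a logical 3D mask.
.label_components <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      k <- (v - 1L) %/% (d[1] * d[2])
      rem <- (v - 1L) %% (d[1] * d[2])
      j <- rem %/% d[1]
      i <- rem %% d[1]
      nb <- integer(0)
      if (i > 0L) nb <- c(nb, v - 1L)
      if (i < d[1] - 1L) nb <- c(nb, v + 1L)
      if (j > 0L) nb <- c(nb, v - d[1])
      if (j < d[2] - 1L) nb <- c(nb, v + d[1])
      if (k > 0L) nb <- c(nb, v - d[1] * d[2])
      if (k < d[3] - 1L) nb <- c(nb, v + d[1] * d[2])
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  labels
}

#' Detect binding sites as connected density peaks
#'
#' Thresholds the map at \code{isovalue} and reports each face-connected
#' (6-neighborhood) component of at least \code{min_voxels} voxels as a
#' site, sorted by integrated density, descending.
#'
#' @param grid a \code{density_grid} in counts-per-frame normalization.
#' @param isovalue density threshold (counts per frame), default 0.1.
#' @param min_voxels minimum component size, default 1.
#' @return data.frame of class \code{site_calls}: one row per site with
#'   \code{site} (rank id), \code{n_voxels}, \code{peak},
#'   \code{integrated}, density-weighted centroid \code{cx, cy, cz} (A).
#'   The member-voxel label array is attached as attribute \code{"labels"}.
#' @export
detect_sites <- function(grid, isovalue = 0.1, min_voxels = 1L) {
  if (grid$normalization != "counts_per_frame")
    stop("detect_sites expects a counts_per_frame grid")
  mask <- grid$values >= isovalue
  labels <- .label_components(mask)
  ids <- setdiff(unique(as.integer(labels)), 0L)
  rows <- list()
  d <- dim(grid$values)
  for (id in ids) {
    vox <- which(labels == id)
    if (length(vox) < min_voxels) { labels[vox] <- 0L; next }
    w <- grid$values[vox]
    k <- (vox - 1L) %/% (d[1] * d[2])
    rem <- (vox - 1L) %% (d[1] * d[2])
    j <- rem %/% d[1]
    i <- rem %% d[1]
    cen <- c(sum(w * i), sum(w * j), sum(w * k)) / sum(w) *
      grid$spacing + grid$origin
    rows[[length(rows) + 1L]] <- data.frame(
      label = id, n_voxels = length(vox), peak = max(w), integrated = sum(w),
      cx = cen[1], cy = cen[2], cz = cen[3])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), n_voxels = integer(0), peak = numeric(0),
               integrated = numeric(0), cx = numeric(0), cy = numeric(0),
               cz = numeric(0))
  out <- out[order(-out$integrated, out$label), , drop = FALSE]
  out$site <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[c("site", "n_voxels", "peak", "integrated", "cx", "cy", "cz",
               "label")]
  attr(out, "labels") <- labels
  attr(out, "isovalue") <- isovalue
  class(out) <- c("site_calls", "data.frame")
  out
}
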