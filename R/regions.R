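# Region definitions (union of spheres around anchor atoms, optional slab)
# and per-frame ion occupancy bookkeeping.

#' Define a named region from residue selectors
#'
#' A region is the union of spheres of radius \code{radius} around the
#' anchor atoms, optionally intersected with a slab along one axis.
#' Membership is evaluated per frame against the anchors' current
#' coordinates with minimum-image distances.
#'
#' @param topology an \code{ion_topology}.
#' @param name region name.
#' @param residues residue selectors: an integer vector of residue ids, or
#'   a data.frame with columns \code{resid} and optionally \code{chain}.
#'   All atoms of the matched residues become anchors.
#' @param radius sphere radius R (A), > 0; default 6.
#' @param slab optional \code{list(axis = "z", min =, max =)} (A) bounding
#'   the region along one coordinate axis.
#' @return An object of class \code{ion_region} with the resolved anchor
#'   atom indices.
#' @export
make_region <- function(topology, name, residues, radius = 6, slab = NULL) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  a <- topology$atoms
  if (is.data.frame(residues)) {
    want_chain <- if ("chain" %in% names(residues)) residues$chain else
      rep(NA_character_, nrow(residues))
    keys <- paste(ifelse(is.na(want_chain), a$chain[1], want_chain),
                  residues$resid)
    sel_ids <- residues$resid
    anchors <- which(paste(a$chain, a$resid) %in% keys)
  } else {
    sel_ids <- as.integer(residues)
    anchors <- which(a$resid %in% sel_ids & a$species == "scaffold")
    if (!length(anchors)) anchors <- which(a$resid %in% sel_ids)
  }
  matched <- unique(a$resid[anchors])
  missing <- setdiff(sel_ids, matched)
  if (length(missing))
    stop(sprintf("region '%s': no atoms matched residue selector(s) %s",
                 name, paste(missing, collapse = ", ")))
  if (!is.null(slab)) {
    slab$axis <- match.arg(slab$axis, c("x", "y", "z"))
    if (is.null(slab$min) || is.null(slab$max) || slab$min >= slab$max)
      stop("slab needs min < max")
  }
  structure(list(name = name, anchors = anchors, radius = radius,
                 slab = slab),
            class = "ion_region")
}

#' @export
print.ion_region <- function(x, ...) {
  cat(sprintf("ion_region '%s': %d anchor atoms, R = %.2f A%s\n",
              x$name, length(x$anchors), x$radius,
              if (is.null(x$slab)) "" else
                sprintf(", slab %s in [%.2f, %.2f]", x$slab$axis,
                        x$slab$min, x$slab$max)))
  invisible(x)
}

#' Region membership of points in one frame
#'
#' @param region an \code{ion_region}.
#' @param points (n x 3) matrix of positions (A) or length-3 vector.
#' @param anchor_coords coordinates of all topology atoms in the current
#'   frame ((n_atoms x 3) matrix); anchors are re-resolved from it.
#' @param box orthorhombic box lengths (A) for minimum-image distances.
#' @return Logical vector: point within R of any anchor atom AND within
#'   the slab.
#' @export
region_membership <- function(region, points, anchor_coords, box) {
  pts <- matrix(points, ncol = 3)
  anch <- anchor_coords[region$anchors, , drop = FALSE]
  inside <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(anch))) {
    inside <- inside |
      (min_image_dist(anch[i, ], pts, box) <= region$radius)
  }
  if (!is.null(region$slab)) {
    d <- match(region$slab$axis, c("x", "y", "z"))
    inside <- inside & pts[, d] >= region$slab$min &
      pts[, d] <= region$slab$max
  }
  inside
}

# Per-frame logical membership matrix (n_frames x n_ions) for one region.
.membership_matrix <- function(traj, region, ion_idx) {
  nf <- traj$n_frames
  m <- matrix(FALSE, nf, length(ion_idx))
  for (f in seq_len(nf)) {
    fr <- matrix(traj$coords[, , f], ncol = 3)
    m[f, ] <- region_membership(region, fr[ion_idx, , drop = FALSE],
                                fr, traj$box[f, ])
  }
  m
}

#' Per-frame ion counts per region and species
#'
#' @param traj an \code{ion_trajectory}.
#' @param topology matching \code{ion_topology}.
#' @param regions list of \code{ion_region}s.
#' @param species character vector of species labels to count.
#' @return data.frame of class \code{occupancy_table}: columns
#'   \code{frame}, \code{region}, \code{species}, \code{count}; one row
#'   per (frame, region, species). Frame dt is attached as attribute
#'   \code{"dt"}.
#' @export
occupancy_counts <- function(traj, topology, regions, species) {
  if (inherits(regions, "ion_region")) regions <- list(regions)
  rows <- list()
  for (reg in regions) {
    for (sp in species) {
      idx <- ion_indices(topology, sp)
      m <- .membership_matrix(traj, reg, idx)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = seq_len(traj$n_frames), region = reg$name, species = sp,
        count = as.integer(rowSums(m)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "dt") <- traj$dt
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Occupancy-fraction table
#'
#' Per (region, species), the percentage of frames in which 0, 1, 2, or
#' >= \code{max_bin} ions occupy the region. Rows sum to 100 within 1e-9.
#'
#' @param table an \code{occupancy_table} from
#'   \code{\link{occupancy_counts}}.
#' @param max_bin counts >= this are pooled into the top bin; default 3.
#' @return data.frame with one row per (region, species) and columns
#'   \code{n0 .. n<max_bin-1>}, \code{n<max_bin>plus} (percent).
#' @export
occupancy_fractions <- function(table, max_bin = 3L) {
  if (!nrow(table)) stop("empty occupancy table")
  bins <- c(paste0("n", 0:(max_bin - 1)), paste0("n", max_bin, "plus"))
  split_key <- interaction(table$region, table$species, drop = TRUE)
  rows <- lapply(split(table, split_key), function(d) {
    cnt <- pmin(d$count, max_bin)
    pct <- 100 * tabulate(cnt + 1L, nbins = max_bin + 1L) / nrow(d)
    out <- data.frame(region = d$region[1], species = d$species[1],
                      stringsAsFactors = FALSE)
    out[bins] <- as.list(pct)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
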