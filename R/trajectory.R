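# Trajectory container and multi-frame XYZ (text) I/O.
# Coordinates in Angstrom, frame spacing dt in ns, frame times (i-1)*dt.

#' Construct a trajectory object
#'
#' @param coords numeric array (n_atoms x 3 x n_frames), Angstrom.
#' @param dt time per frame (ns), > 0.
#' @param box per-frame box lengths: either a length-3 vector (constant box)
#'   or an (n_frames x 3) matrix.
#' @return An object of class \code{ion_trajectory}: list with
#'   \code{coords}, \code{dt}, \code{box} (n_frames x 3 matrix),
#'   \code{n_frames}.
#' @export
ion_trajectory <- function(coords, dt, box) {
  coords <- unname(coords)
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an (n_atoms x 3 x n_frames) array")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a single positive number (ns)")
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
  box <- unname(as.matrix(box))
  if (nrow(box) != nf || ncol(box) != 3 || any(box <= 0))
    stop("box must give three positive lengths per frame")
  structure(list(coords = coords, dt = dt, box = box, n_frames = nf),
            class = "ion_trajectory")
}

#' @export
print.ion_trajectory <- function(x, ...) {
  cat(sprintf("ion_trajectory: %d atoms, %d frames, dt %.4g ns (%.4g ns total)\n",
              dim(x$coords)[1], x$n_frames, x$dt, x$n_frames * x$dt))
  invisible(x)
}

#' Frame times of a trajectory
#' @param traj an \code{ion_trajectory}.
#' @return Numeric vector of frame times (ns), starting at 0.
#' @export
frame_times <- function(traj) (seq_len(traj$n_frames) - 1) * traj$dt

#' Write a trajectory as multi-frame XYZ
#'
#' Standard XYZ blocks: atom count, a comment line carrying the frame index,
#' time and box, then \code{name x y z} lines. Coordinates are written with
#' 6 decimals, so text roundtrips are stable to well under 1e-3 A.
#'
#' @param traj an \code{ion_trajectory}.
#' @param topology matching \code{ion_topology} (atom names).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, topology, path) {
  na <- dim(traj$coords)[1]
  if (na != n_atoms(topology))
    stop(sprintf("trajectory has %d atoms but topology has %d",
                 na, n_atoms(topology)))
  con <- file(path, "w")
  on.exit(close(con))
  nm <- topology$atoms$name
  for (f in seq_len(traj$n_frames)) {
    writeLines(as.character(na), con)
    writeLines(sprintf("frame %d t= %.6f box %.6f %.6f %.6f",
                       f, (f - 1) * traj$dt,
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]), con)
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", nm,
                       traj$coords[, 1, f], traj$coords[, 2, f],
                       traj$coords[, 3, f]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path XYZ file path.
#' @param topology matching \code{ion_topology}; the per-frame atom count
#'   must equal the topology's.
#' @param dt time per frame (ns), > 0.
#' @return An \code{ion_trajectory}. Box lengths are taken from the comment
#'   lines when written by \code{\link{write_trajectory}}, otherwise from
#'   the topology box.
#' @export
read_trajectory <- function(path, topology, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a single positive number (ns)")
  lines <- readLines(path)
  na_top <- n_atoms(topology)
  i <- 1L
  frames <- list()
  boxes <- list()
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na)) stop("malformed XYZ atom-count line ", i)
    if (na != na_top)
      stop(sprintf("atom-count mismatch at line %d: expected %d, found %d",
                   i, na_top, na))
    comment <- lines[i + 1L]
    bx <- topology$box
    m <- regmatches(comment, regexec(
      "box +([-0-9.eE+]+) +([-0-9.eE+]+) +([-0-9.eE+]+)", comment))[[1]]
    if (length(m) == 4) bx <- as.numeric(m[2:4])
    block <- lines[(i + 2L):(i + 1L + na)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    xyz <- matrix(as.numeric(parts[, 2:4]), ncol = 3)
    if (any(!is.finite(xyz)))
      stop("unparseable coordinates in XYZ frame starting at line ", i)
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- bx
    i <- i + 2L + na
  }
  if (!length(frames)) stop("no frames in ", path)
  coords <- array(unlist(frames), dim = c(na_top, 3, length(frames)))
  ion_trajectory(coords, dt, do.call(rbind, boxes))
}

# Minimum-image displacement for an orthorhombic box: dx is an (n x 3)
# matrix of raw differences, box a length-3 vector.
.min_image <- function(dx, box) {
  dx - sweep(round(sweep(dx, 2, box, "/")), 2, box, "*")
}

#' Minimum-image distances between one point and a set of points
#'
#' @param p length-3 point (A).
#' @param pts (n x 3) matrix of points (A).
#' @param box orthorhombic box lengths (A).
#' @return Numeric vector of n distances.
#' @export
min_image_dist <- function(p, pts, box) {
  pts <- matrix(pts, ncol = 3)
  dx <- .min_image(sweep(pts, 2, as.numeric(p)), box)
  sqrt(rowSums(dx * dx))
}
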