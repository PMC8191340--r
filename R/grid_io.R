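# OpenDX scalar-grid I/O for density grids and GFE maps.

#' Write a grid to an OpenDX file
#'
#' Standard regular-grid scalar DX layout: gridpositions with origin and
#' per-axis delta records, gridconnections, and the data array with the
#' z index varying fastest. Values are written with enough digits that a
#' roundtrip read agrees to better than 1e-6.
#'
#' @param grid a \code{density_grid} or \code{gfe_map}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_grid <- function(grid, path) {
  v <- grid$values
  if (is.null(v) || !length(v) || all(v == 0 & inherits(grid, "density_grid")))
    stop("refusing to write an empty grid")
  d <- dim(v)
  n <- prod(d)
  flat <- as.vector(aperm(v, c(3, 2, 1)))  # z fastest
  pad <- c(flat, rep(NA_real_, (3 - n %% 3) %% 3))
  m <- matrix(pad, ncol = 3, byrow = TRUE)
  data_lines <- apply(m, 1, function(r)
    paste(sprintf("%.10g", r[!is.na(r)]), collapse = " "))
  lines <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.10g %.10g %.10g",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.10g 0 0", grid$spacing[1]),
    sprintf("delta 0 %.10g 0", grid$spacing[2]),
    sprintf("delta 0 0 %.10g", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            n),
    data_lines,
    "attribute \"dep\" string \"positions\"",
    "object \"regular positions regular connections\" class field",
    "component \"positions\" value 1",
    "component \"connections\" value 2",
    "component \"data\" value 3")
  writeLines(lines, path)
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' @param path DX file path.
#' @param normalization normalization tag to assign to the resulting grid,
#'   or \code{"gfe"} to return a \code{gfe_map} (temperature/cap unknown,
#'   recorded as \code{NA}).
#' @param n_frames frame count to record on the grid (metadata only).
#' @return A \code{density_grid} (or \code{gfe_map}).
#' @export
read_grid <- function(path, normalization = "raw_counts", n_frames = 0L) {
  lines <- readLines(path)
  grab <- function(pattern) grep(pattern, lines, value = TRUE)[1]
  cl <- grab("^object .*gridpositions counts")
  if (is.na(cl)) stop("not an OpenDX gridpositions file: ", path)
  d <- as.integer(strsplit(sub(".*counts +", "", cl), "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(sub("^origin", "",
                                           grab("^origin"))), "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dmat <- do.call(rbind, lapply(deltas, function(s)
    as.numeric(strsplit(trimws(sub("^delta", "", s)), "\\s+")[[1]])))
  spacing <- diag(dmat[1:3, 1:3, drop = FALSE])
  start <- grep("data follows", lines)[1]
  n <- prod(d)
  vals <- numeric(0)
  i <- start + 1L
  while (length(vals) < n && i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(tok))
    if (any(is.na(num))) break
    vals <- c(vals, num)
    i <- i + 1L
  }
  if (length(vals) < n)
    stop(sprintf("DX data truncated: expected %d values, found %d",
                 n, length(vals)))
  arr <- aperm(array(vals[seq_len(n)], dim = rev(d)), c(3, 2, 1))
  if (identical(normalization, "gfe")) {
    structure(list(values = arr, origin = origin, spacing = spacing,
                   temperature = NA_real_, cap = NA_real_, bulk = NA_real_),
              class = "gfe_map")
  } else {
    density_grid(arr, origin, spacing, normalization, n_frames)
  }
}
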