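# Visit (residence interval) extraction, residence statistics, and
# entry/exchange bookkeeping. Frames are 1-based; durations in ns.

# Merge in-region runs of a logical membership vector: gaps of up to
# `gap_tolerance` FALSE frames strictly between two runs are bridged,
# then runs shorter than `min_duration` frames are discarded.
.runs_from_membership <- function(mem, gap_tolerance, min_duration) {
  r <- rle(mem)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (!length(on)) return(data.frame(start = integer(0), end = integer(0)))
  iv <- data.frame(start = starts[on], end = ends[on])
  if (gap_tolerance > 0 && nrow(iv) > 1) {
    merged <- iv[1, , drop = FALSE]
    for (i in 2:nrow(iv)) {
      gap <- iv$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= gap_tolerance) {
        merged$end[nrow(merged)] <- iv$end[i]
      } else {
        merged <- rbind(merged, iv[i, ])
      }
    }
    iv <- merged
  }
  iv[iv$end - iv$start + 1L >= min_duration, , drop = FALSE]
}

#' Extract per-ion visits to a region
#'
#' A visit is a maximal run of frames in which an ion is inside the
#' region; out-of-region gaps of at most \code{gap_tolerance} frames are
#' bridged, and merged runs shorter than \code{min_duration} frames are
#' discarded. Visits truncated by either trajectory end are flagged
#' censored.
#'
#' @param traj an \code{ion_trajectory}.
#' @param topology matching \code{ion_topology}.
#' @param region an \code{ion_region}.
#' @param species species label(s) of the ions to track; \code{NULL} for
#'   all ion species.
#' @param gap_tolerance frames, >= 0; default 2.
#' @param min_duration frames, >= 1; default 1.
#' @return data.frame of class \code{visit_table}: one row per visit with
#'   \code{ion} (atom index), \code{species}, \code{region}, \code{start},
#'   \code{end} (1-based frames, inclusive), \code{duration_ns}
#'   \code{= (end - start + 1) * dt}, \code{censored_start},
#'   \code{censored_end}. Attributes record \code{dt}, \code{n_frames},
#'   \code{gap_tolerance}, \code{min_duration}.
#' @export
extract_visits <- function(traj, topology, region, species = NULL,
                           gap_tolerance = 2L, min_duration = 1L) {
  if (gap_tolerance < 0) stop("gap_tolerance must be >= 0")
  if (min_duration < 1) stop("min_duration must be >= 1")
  idx <- ion_indices(topology, species)
  mem <- .membership_matrix(traj, region, idx)
  nf <- traj$n_frames
  rows <- list()
  for (j in seq_along(idx)) {
    iv <- .runs_from_membership(mem[, j], gap_tolerance, min_duration)
    if (!nrow(iv)) next
    rows[[length(rows) + 1L]] <- data.frame(
      ion = idx[j], species = topology$atoms$species[idx[j]],
      region = region$name, start = iv$start, end = iv$end,
      duration_ns = (iv$end - iv$start + 1L) * traj$dt,
      censored_start = iv$start == 1L, censored_end = iv$end == nf,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    ion = integer(0), species = character(0), region = character(0),
    start = integer(0), end = integer(0), duration_ns = numeric(0),
    censored_start = logical(0), censored_end = logical(0))
  rownames(out) <- NULL
  attr(out, "dt") <- traj$dt
  attr(out, "n_frames") <- nf
  attr(out, "gap_tolerance") <- gap_tolerance
  attr(out, "min_duration") <- min_duration
  class(out) <- c("visit_table", "data.frame")
  out
}

#' Residence-time statistics per (region, species)
#'
#' Statistics are computed over uncensored visits by default; censored
#' visits (truncated by a trajectory end) are counted separately, and
#' their durations are lower bounds.
#'
#' @param visits a \code{visit_table}.
#' @param censoring \code{"exclude"} (default) or \code{"include"}
#'   censored visits in the statistics.
#' @param groups optional data.frame with columns \code{region},
#'   \code{species} naming the groups to report; groups without any visit
#'   get \code{n_visits = 0} and \code{NA} (undefined) statistics, not 0.
#' @return data.frame with columns \code{region}, \code{species},
#'   \code{n_visits} (used for the statistics), \code{n_censored},
#'   \code{mean_ns}, \code{median_ns}, \code{max_ns}.
#' @export
residence_stats <- function(visits, censoring = c("exclude", "include"),
                            groups = NULL) {
  censoring <- match.arg(censoring)
  empty_row <- function(region, species) {
    k <- length(region)
    data.frame(region = region, species = species,
               n_visits = integer(k), n_censored = integer(k),
               mean_ns = rep(NA_real_, k), median_ns = rep(NA_real_, k),
               max_ns = rep(NA_real_, k), stringsAsFactors = FALSE)
  }
  if (!nrow(visits)) {
    if (is.null(groups))
      return(empty_row(character(0), character(0)))
    out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i)
      empty_row(groups$region[i], groups$species[i])))
    return(out)
  }
  key <- interaction(visits$region, visits$species, drop = TRUE)
  rows <- lapply(split(visits, key), function(d) {
    cens <- d$censored_start | d$censored_end
    use <- if (censoring == "exclude") d$duration_ns[!cens] else
      d$duration_ns
    data.frame(region = d$region[1], species = d$species[1],
               n_visits = length(use), n_censored = sum(cens),
               mean_ns = if (length(use)) mean(use) else NA_real_,
               median_ns = if (length(use)) stats::median(use) else NA_real_,
               max_ns = if (length(use)) max(use) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(groups)) {
    have <- paste(out$region, out$species)
    for (i in seq_len(nrow(groups))) {
      k <- paste(groups$region[i], groups$species[i])
      if (!k %in% have)
        out <- rbind(out, empty_row(groups$region[i], groups$species[i]))
    }
  }
  rownames(out) <- NULL
  out
}

#' Entry and exchange counts per (region, species)
#'
#' An entry is the start of a visit that is not censored at the trajectory
#' start. An exchange is a frame boundary at which the identity of the
#' region-occupying ions changes (some ion leaves) while the occupant
#' count never drops to zero.
#'
#' @param visits a \code{visit_table} (needs its \code{n_frames}
#'   attribute, present when produced by \code{\link{extract_visits}}).
#' @return data.frame with columns \code{region}, \code{species},
#'   \code{n_entries}, \code{n_exchanges}.
#' @export
count_entries <- function(visits) {
  nf <- attr(visits, "n_frames")
  if (is.null(nf)) stop("visit table lacks its n_frames attribute")
  grid <- unique(visits[c("region", "species")])
  if (!nrow(grid))
    return(data.frame(region = character(0), species = character(0),
                      n_entries = integer(0), n_exchanges = integer(0)))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    d <- visits[visits$region == grid$region[g] &
                  visits$species == grid$species[g], , drop = FALSE]
    n_entries <- sum(!d$censored_start)
    # occupant sets per frame from the visit intervals
    occ <- vector("list", nf)
    for (i in seq_len(nrow(d))) {
      fr <- d$start[i]:d$end[i]
      for (f in fr) occ[[f]] <- c(occ[[f]], d$ion[i])
    }
    n_ex <- 0L
    if (nf > 1) {
      for (f in seq_len(nf - 1L)) {
        a <- occ[[f]]; b <- occ[[f + 1L]]
        if (length(a) && length(b) && length(setdiff(a, b)))
          n_ex <- n_ex + 1L
      }
    }
    data.frame(region = grid$region[g], species = grid$species[g],
               n_entries = n_entries, n_exchanges = n_ex,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
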