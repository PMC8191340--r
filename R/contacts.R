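# Per-residue ion contact frequencies and binding-site residue ranking.

#' Ion-protein contact frequencies per residue
#'
#' A residue is in contact in a frame when any of its non-hydrogen atoms
#' lies within \code{cutoff} of at least one selected ion's position
#' (per-frame binary contact; minimum-image distances). The frequency is
#' the fraction of analyzed frames in contact, in [0, 1], and is invariant
#' to frame reordering.
#'
#' @param traj an \code{ion_trajectory}.
#' @param topology matching \code{ion_topology}.
#' @param species species label(s) selecting the ions; alternatively
#'   \code{ions} gives explicit atom indices.
#' @param ions optional integer atom indices overriding \code{species}.
#' @param cutoff contact cutoff (A), default 5.
#' @param frames optional frame filter: integer frame indices or a logical
#'   vector over frames (e.g. frames in which the ion occupies a stated
#'   region), default all frames.
#' @return data.frame of class \code{contact_table}: one row per
#'   (residue, species) with columns \code{chain}, \code{resid},
#'   \code{resname}, \code{species}, \code{frequency}, \code{n_frames}.
#'   Attribute \code{"cutoff"} records the cutoff used.
#' @export
contact_frequencies <- function(traj, topology, species = NULL,
                                ions = NULL, cutoff = 5, frames = NULL) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (is.null(ions)) ions <- ion_indices(topology, species)
  if (!length(ions)) stop("empty ion selection")
  nf <- traj$n_frames
  if (is.null(frames)) frames <- seq_len(nf)
  if (is.logical(frames)) frames <- which(frames)
  if (!length(frames)) stop("empty frame filter")
  a <- topology$atoms
  elem <- substr(gsub("^[0-9]+", "", a$name), 1, 1)
  cand <- which(a$species == "scaffold" & elem != "H")
  resk <- paste(a$chain[cand], a$resid[cand])
  res_of <- match(resk, unique(resk))
  n_res <- max(res_of)
  ion_sp <- a$species[ions]
  out_rows <- list()
  for (sp in unique(ion_sp)) {
    sel <- ions[ion_sp == sp]
    hits <- integer(n_res)
    for (f in frames) {
      fr <- matrix(traj$coords[, , f], ncol = 3)
      box <- traj$box[f, ]
      near <- rep(FALSE, length(cand))
      for (i in sel) {
        near <- near |
          (min_image_dist(fr[i, ], fr[cand, , drop = FALSE], box) <=
             cutoff)
      }
      touched <- unique(res_of[near])
      hits[touched] <- hits[touched] + 1L
    }
    first <- cand[!duplicated(res_of)]
    out_rows[[sp]] <- data.frame(
      chain = a$chain[first], resid = a$resid[first],
      resname = a$resname[first], species = sp,
      frequency = hits / length(frames), n_frames = length(frames),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out_rows)
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Rank the residues constituting a binding site
#'
#' Residues whose contact frequency meets the threshold, sorted by
#' frequency descending with ties broken by residue id ascending.
#'
#' @param table a \code{contact_table}.
#' @param threshold minimum frequency, in (0, 1].
#' @param species optional species label restricting the ranking.
#' @return data.frame subset of \code{table}, ordered as described.
#' @export
rank_site_residues <- function(table, threshold = 0.5, species = NULL) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  d <- table
  if (!is.null(species)) d <- d[d$species %in% species, , drop = FALSE]
  d <- d[d$frequency >= threshold, , drop = FALSE]
  d <- d[order(d$species, -d$frequency, d$resid), , drop = FALSE]
  rownames(d) <- NULL
  d
}
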