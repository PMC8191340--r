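# Synthetic scaffolds and ion trajectories with analytically known binding
# kinetics. These generators are the ground-truth oracle for the occupancy,
# residence, contact, and density estimators. Units: A, ns, kcal/mol, K.

#' Specification of a synthetic cavity scaffold
#'
#' A cylindrical cavity of wall pseudo-atoms inside an orthorhombic box,
#' with named anchor residues at fixed positions (the stand-ins for the
#' basic residues flanking a transporter's permeation cavity).
#'
#' @param cavity_radius cavity radius (A), > 0.
#' @param cavity_depth cavity depth along the axis (A), > 0.
#' @param anchor_residues data.frame with columns \code{resname},
#'   \code{resid}, \code{x}, \code{y}, \code{z} (A); residue ids unique,
#'   positions inside the box.
#' @param box orthorhombic box lengths (A); coordinates live in
#'   \code{[0, box]}.
#' @param cavity_axis unit vector of the cavity axis (default +z). The
#'   cavity is centered at the box center.
#' @param wall_atom_spacing spacing between wall pseudo-atoms (A).
#' @return An object of class \code{scaffold_spec}.
#' @export
scaffold_spec <- function(cavity_radius, cavity_depth, anchor_residues,
                          box, cavity_axis = c(0, 0, 1),
                          wall_atom_spacing = 2) {
  if (!is.numeric(cavity_radius) || cavity_radius <= 0)
    stop("cavity_radius must be > 0")
  if (cavity_depth <= 0) stop("cavity_depth must be > 0")
  if (wall_atom_spacing <= 0) stop("wall_atom_spacing must be > 0")
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths")
  axis <- as.numeric(cavity_axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("cavity_axis must be nonzero")
  axis <- axis / nrm
  ar <- as.data.frame(anchor_residues)
  stopifnot(all(c("resname", "resid", "x", "y", "z") %in% names(ar)))
  if (anyDuplicated(ar$resid)) stop("anchor residue_ids must be unique")
  pos <- as.matrix(ar[c("x", "y", "z")])
  out <- sweep(pos, 2, box, function(p, b) p < 0 | p > b)
  bad <- which(rowSums(out) > 0)
  if (length(bad))
    stop(sprintf("anchor residue %s %d lies outside the box",
                 ar$resname[bad[1]], ar$resid[bad[1]]))
  structure(list(cavity_radius = cavity_radius, cavity_depth = cavity_depth,
                 anchor_residues = ar, box = box, cavity_axis = axis,
                 wall_atom_spacing = wall_atom_spacing),
            class = "scaffold_spec")
}

# Representative anchor-atom name per residue type: side-chain terminal
# nitrogen / guanidinium carbon for basic residues, carboxylate carbon for
# acidic ones, CA otherwise.
.anchor_atom_name <- function(resname) {
  switch(resname,
         LYS = "NZ", ARG = "CZ", ASP = "CG", GLU = "CD", "CA")
}

#' Build a scaffold topology from a specification
#'
#' Wall pseudo-atoms are laid out on a cylinder of the requested radius and
#' depth around the cavity axis (through the box center); anchor residues
#' are single pseudo-atoms at their requested positions. Deterministic for
#' a given spec.
#'
#' @param spec a \code{\link{scaffold_spec}}.
#' @return An \code{ion_topology} whose reference coordinates hold the
#'   scaffold geometry. Wall atoms are residues named \code{WAL} on chain
#'   \code{W}; anchors keep their requested residue names/ids on chain
#'   \code{A}.
#' @export
build_scaffold <- function(spec) {
  stopifnot(inherits(spec, "scaffold_spec"))
  center <- spec$box / 2
  a <- spec$cavity_axis
  # orthonormal basis completing the axis
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  hs <- seq(-spec$cavity_depth / 2, spec$cavity_depth / 2,
            by = spec$wall_atom_spacing)
  n_ring <- max(3L, ceiling(2 * pi * spec$cavity_radius /
                              spec$wall_atom_spacing))
  th <- seq(0, 2 * pi, length.out = n_ring + 1L)[-(n_ring + 1L)]
  ring <- spec$cavity_radius * (cos(th) %o% e1 + sin(th) %o% e2)
  wall <- do.call(rbind, lapply(hs, function(h)
    sweep(ring, 2, center + h * a, "+")))
  ar <- spec$anchor_residues
  wall_atoms <- data.frame(
    name = "W", resname = "WAL",
    resid = seq_len(nrow(wall)), chain = "W", stringsAsFactors = FALSE)
  anchor_atoms <- data.frame(
    name = vapply(as.character(ar$resname), .anchor_atom_name, ""),
    resname = as.character(ar$resname), resid = as.integer(ar$resid),
    chain = "A", stringsAsFactors = FALSE)
  ion_topology(rbind(wall_atoms, anchor_atoms),
               rbind(wall, as.matrix(ar[c("x", "y", "z")])),
               spec$box)
}

#' Markov-state kinetic model for synthetic ions
#'
#' Each ion hops between named states under a row-stochastic per-step
#' transition matrix. A state's placement rule is either a point with
#' Gaussian jitter (a localized binding region) or \code{"bulk"} (uniform
#' resampling in the solvent shell: the box minus an exclusion radius
#' around every bound-state point). The geometric sojourn law gives the
#' exact expected residence of state s as \code{dt / (1 - P[s, s])}.
#'
#' @param states named list; each element is either the string
#'   \code{"bulk"} or \code{list(point = c(x, y, z), jitter = sd_A)}.
#' @param P transition matrix (rows = from), row-stochastic within 1e-12,
#'   with dimnames matching \code{states}.
#' @param dt time per step (ns), > 0.
#' @param species character vector of ion species labels.
#' @param n_ions integer vector, ions per species (same length as
#'   \code{species}).
#' @param box orthorhombic box lengths (A).
#' @param seed integer RNG seed.
#' @param initial_state starting state for every ion (default: the first
#'   bulk state if any, else the first state).
#' @param single_occupancy if TRUE, at most one ion may occupy each bound
#'   state at a time; an ion whose transition lands on an occupied bound
#'   state is redirected to the bulk state instead.
#' @param exclusion_radius bulk resampling keeps at least this distance
#'   (A) from every bound-state point.
#' @return An object of class \code{markov_model}; element
#'   \code{expected_residence_ns} holds the closed-form per-state mean
#'   residence times.
#' @export
markov_model <- function(states, P, dt, species, n_ions, box, seed,
                         initial_state = NULL, single_occupancy = FALSE,
                         exclusion_radius = 6) {
  P <- as.matrix(P)
  sn <- names(states)
  if (is.null(sn) || anyDuplicated(sn)) stop("states must be uniquely named")
  if (nrow(P) != length(states) || ncol(P) != length(states))
    stop("P must be square with one row per state")
  if (is.null(dimnames(P))) dimnames(P) <- list(sn, sn)
  if (!identical(rownames(P), sn) || !identical(colnames(P), sn))
    stop("dimnames(P) must match names(states)")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12))
    stop("P must be row-stochastic (rows sum to 1 within 1e-12)")
  if (dt <= 0) stop("dt must be > 0")
  if (length(species) != length(n_ions))
    stop("species and n_ions must have equal length")
  is_bulk <- vapply(states, function(s) identical(s, "bulk"), TRUE)
  if (is.null(initial_state))
    initial_state <- if (any(is_bulk)) sn[which(is_bulk)[1]] else sn[1]
  if (!initial_state %in% sn) stop("unknown initial_state")
  if (single_occupancy && !any(is_bulk))
    stop("single_occupancy requires a bulk state to redirect to")
  for (s in sn[!is_bulk]) {
    st <- states[[s]]
    if (!is.list(st) || is.null(st$point) || length(st$point) != 3)
      stop("bound state '", s, "' needs a 3D placement point")
    if (is.null(st$jitter)) states[[s]]$jitter <- 0.5
  }
  structure(list(states = states, P = P, dt = dt, species = species,
                 n_ions = as.integer(n_ions), box = as.numeric(box),
                 seed = as.integer(seed), initial_state = initial_state,
                 single_occupancy = single_occupancy,
                 exclusion_radius = exclusion_radius,
                 is_bulk = is_bulk,
                 expected_residence_ns =
                   stats::setNames(dt / (1 - diag(P)), sn)),
            class = "markov_model")
}

# CHARMM-style residue name for a species label (inverse of the default
# species map; unknown labels fall back to "ION").
.resname_for_species <- function(species) {
  map <- default_species_map()
  inv <- stats::setNames(names(map), map)
  out <- inv[species]
  out[is.na(out)] <- "ION"
  unname(out)
}

.bulk_sample <- function(n, box, bound_points, exclusion_radius) {
  out <- matrix(NA_real_, n, 3)
  need <- seq_len(n)
  while (length(need)) {
    cand <- cbind(stats::runif(length(need), 0, box[1]),
                  stats::runif(length(need), 0, box[2]),
                  stats::runif(length(need), 0, box[3]))
    ok <- rep(TRUE, length(need))
    if (!is.null(bound_points) && nrow(bound_points)) {
      for (b in seq_len(nrow(bound_points))) {
        d <- min_image_dist(bound_points[b, ], cand, box)
        ok <- ok & d > exclusion_radius
      }
    }
    out[need[ok], ] <- cand[ok, , drop = FALSE]
    need <- need[!ok]
  }
  out
}

#' Simulate ions under a Markov-state model
#'
#' One coordinate per ion per frame, placed by the ion's current state.
#' Bit-identical output for identical (model, n_steps).
#'
#' @param model a \code{\link{markov_model}} (carries its own seed).
#' @param n_steps number of frames to generate, >= 1.
#' @param scaffold optional \code{ion_topology} from
#'   \code{\link{build_scaffold}}; when given, the returned topology and
#'   trajectory contain the static scaffold atoms followed by the ions.
#' @return List with \code{topology} (\code{ion_topology}),
#'   \code{trajectory} (\code{ion_trajectory}), and \code{ground_truth}:
#'   the exact state sequence (n_steps x n_ions character matrix), per-ion
#'   species, the closed-form \code{expected_residence_ns}, and the ion
#'   atom indices within the topology.
#' @export
simulate_markov_ions <- function(model, n_steps, scaffold = NULL) {
  stopifnot(inherits(model, "markov_model"), n_steps >= 1)
  set.seed(model$seed)
  sn <- names(model$states)
  n_states <- length(sn)
  ion_species <- rep(model$species, model$n_ions)
  n_ions <- length(ion_species)
  if (!n_ions) stop("model defines no ions")
  bound_idx <- which(!model$is_bulk)
  bound_points <- if (length(bound_idx))
    do.call(rbind, lapply(model$states[bound_idx], `[[`, "point"))
  else NULL
  bulk_code <- which(model$is_bulk)[1]
  cum <- t(apply(model$P, 1, cumsum))
  state_seq <- matrix(NA_integer_, n_steps, n_ions)
  cur <- rep(match(model$initial_state, sn), n_ions)
  state_seq[1, ] <- cur
  if (n_steps > 1) {
    for (t in 2:n_steps) {
      u <- stats::runif(n_ions)
      nxt <- integer(n_ions)
      for (s in unique(cur)) {
        idx <- which(cur == s)
        nxt[idx] <- findInterval(u[idx], cum[s, ], left.open = TRUE) + 1L
      }
      if (model$single_occupancy && length(bound_idx)) {
        for (s in bound_idx) {
          occupants <- which(nxt == s)
          if (length(occupants) > 1L) {
            # ions already in s keep it; otherwise lowest index wins
            keep <- occupants[cur[occupants] == s][1]
            if (is.na(keep)) keep <- occupants[1]
            nxt[setdiff(occupants, keep)] <- bulk_code
          }
        }
      }
      state_seq[t, ] <- nxt
      cur <- nxt
    }
  }
  coords <- array(NA_real_, dim = c(n_ions, 3, n_steps))
  for (t in seq_len(n_steps)) {
    st <- state_seq[t, ]
    for (s in unique(st)) {
      idx <- which(st == s)
      if (model$is_bulk[s]) {
        coords[idx, , t] <- .bulk_sample(length(idx), model$box,
                                         bound_points,
                                         model$exclusion_radius)
      } else {
        spec <- model$states[[s]]
        coords[idx, , t] <- matrix(spec$point, length(idx), 3,
                                   byrow = TRUE) +
          matrix(stats::rnorm(3 * length(idx), sd = spec$jitter),
                 length(idx), 3)
      }
    }
  }
  ion_atoms <- data.frame(
    name = substr(.resname_for_species(ion_species), 1, 4),
    resname = .resname_for_species(ion_species),
    resid = seq_len(n_ions), chain = "I", stringsAsFactors = FALSE)
  if (is.null(scaffold)) {
    topology <- ion_topology(ion_atoms, matrix(coords[, , 1], ncol = 3),
                             model$box)
    all_coords <- coords
    ion_index <- seq_len(n_ions)
  } else {
    if (any(abs(scaffold$box - model$box) > 1e-9))
      stop("scaffold box and model box differ")
    n_sc <- n_atoms(scaffold)
    topology <- ion_topology(rbind(scaffold$atoms[
      c("name", "resname", "resid", "chain")], ion_atoms),
      rbind(scaffold$coords, coords[, , 1]),
      model$box, warn_unknown = FALSE)
    all_coords <- array(NA_real_, dim = c(n_sc + n_ions, 3, n_steps))
    all_coords[seq_len(n_sc), , ] <- scaffold$coords  # static scaffold
    all_coords[n_sc + seq_len(n_ions), , ] <- coords
    ion_index <- n_sc + seq_len(n_ions)
  }
  traj <- ion_trajectory(all_coords, model$dt, model$box)
  gt <- list(states = matrix(sn[state_seq], n_steps, n_ions),
             species = ion_species, ion_index = ion_index,
             expected_residence_ns = model$expected_residence_ns,
             seed = model$seed)
  list(topology = topology, trajectory = traj, ground_truth = gt)
}

#' Brownian-dynamics specification for synthetic ions
#'
#' Overdamped Langevin (Euler-Maruyama) motion in a potential made of
#' Gaussian wells: \code{U(x) = -sum_j depth_j exp(-|x - c_j|^2 /
#' (2 w_j^2))}. The construction-time stability contract requires the
#' deterministic drift per step to be small relative to every well width:
#' \code{dt * D * max|grad U| / kT <= 0.1 * width}.
#'
#' @param wells list of \code{list(center = c(x, y, z), depth, width)}
#'   (kcal/mol, A); \code{depth >= 0}. May be empty (free diffusion).
#' @param diffusion_coefficient D (A^2/ns), > 0 allowed to be 0 for the
#'   frozen-ion degenerate case.
#' @param kT thermal energy (kcal/mol), default 0.596 (300 K).
#' @param dt time step (ns).
#' @param n_steps number of frames.
#' @param box orthorhombic box lengths (A).
#' @param n_ions number of ions.
#' @param start optional (n_ions x 3) start positions; default uniform in
#'   the box (seeded).
#' @param seed integer RNG seed.
#' @return An object of class \code{brownian_spec}.
#' @export
brownian_spec <- function(wells, diffusion_coefficient, kT = 0.596,
                          dt, n_steps, box, n_ions = 1, start = NULL,
                          seed = 1) {
  if (diffusion_coefficient < 0) stop("diffusion_coefficient must be >= 0")
  if (dt <= 0 || n_steps < 1) stop("dt > 0 and n_steps >= 1 required")
  if (kT <= 0) stop("kT must be > 0")
  box <- as.numeric(box)
  for (w in wells) {
    if (is.null(w$center) || length(w$center) != 3 || w$width <= 0)
      stop("each well needs a 3D center and positive width")
    if (w$depth < 0) stop("well depth must be >= 0")
    # max |grad U| of an isolated Gaussian well: depth * exp(-1/2) / width
    drift <- dt * diffusion_coefficient * w$depth * exp(-0.5) /
      (w$width * kT)
    if (drift > 0.1 * w$width)
      stop(sprintf(
        "stability contract violated: per-step drift %.3g A exceeds 0.1 x width (%.3g A); reduce dt",
        drift, w$width))
  }
  structure(list(wells = wells,
                 diffusion_coefficient = diffusion_coefficient, kT = kT,
                 dt = dt, n_steps = as.integer(n_steps), box = box,
                 n_ions = as.integer(n_ions), start = start,
                 seed = as.integer(seed)),
            class = "brownian_spec")
}

# -grad U at positions x (n x 3) for Gaussian wells (minimum image).
.well_force <- function(x, wells, box) {
  f <- matrix(0, nrow(x), 3)
  for (w in wells) {
    dx <- .min_image(sweep(x, 2, w$center), box)
    r2 <- rowSums(dx * dx)
    g <- w$depth / w$width^2 * exp(-r2 / (2 * w$width^2))
    f <- f - dx * g  # force pulls toward the center
  }
  f
}

#' Simulate ions by overdamped Langevin dynamics
#'
#' Euler-Maruyama: \code{x <- x + (D / kT) F dt + sqrt(2 D dt) N(0, 1)},
#' with periodic wrapping into the box. Deterministic per seed.
#'
#' @param spec a \code{\link{brownian_spec}}.
#' @param species species label for the ions, default \code{"Cl-"}.
#' @return List with \code{topology}, \code{trajectory} (wrapped
#'   coordinates), and \code{ground_truth} containing the unwrapped
#'   coordinate array (for displacement statistics) and the spec.
#' @export
simulate_brownian_ions <- function(spec, species = "Cl-") {
  stopifnot(inherits(spec, "brownian_spec"))
  set.seed(spec$seed)
  n <- spec$n_ions
  x <- if (is.null(spec$start)) {
    cbind(stats::runif(n, 0, spec$box[1]), stats::runif(n, 0, spec$box[2]),
          stats::runif(n, 0, spec$box[3]))
  } else {
    matrix(spec$start, ncol = 3)
  }
  unwrapped <- array(NA_real_, dim = c(n, 3, spec$n_steps))
  unwrapped[, , 1] <- x
  sig <- sqrt(2 * spec$diffusion_coefficient * spec$dt)
  mob <- spec$diffusion_coefficient * spec$dt / spec$kT
  if (spec$n_steps > 1) {
    for (t in 2:spec$n_steps) {
      drift <- if (length(spec$wells))
        mob * .well_force(x, spec$wells, spec$box) else 0
      x <- x + drift + matrix(stats::rnorm(3 * n, sd = sig), n, 3)
      unwrapped[, , t] <- x
    }
  }
  wrapped <- unwrapped
  for (d in 1:3) wrapped[, d, ] <- wrapped[, d, ] %% spec$box[d]
  rn <- .resname_for_species(rep(species, n))
  topology <- ion_topology(
    data.frame(name = substr(rn, 1, 4), resname = rn, resid = seq_len(n),
               chain = "I", stringsAsFactors = FALSE),
    matrix(wrapped[, , 1], ncol = 3), spec$box)
  list(topology = topology,
       trajectory = ion_trajectory(wrapped, spec$dt, spec$box),
       ground_truth = list(unwrapped = unwrapped, spec = spec))
}
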