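# Independent brute-force oracles and fixture builders. These deliberately
# use different algorithms from the package code paths they check.

# Minimum-image distance, scalar loop (oracle route).
oracle_dist <- function(p, q, box) {
  d <- 0
  for (k in 1:3) {
    dd <- p[k] - q[k]
    dd <- dd - box[k] * round(dd / box[k])
    d <- d + dd * dd
  }
  sqrt(d)
}

# Union-of-spheres membership by exhaustive anchor scan.
oracle_membership <- function(pt, anchors, radius, box, slab = NULL) {
  inside <- FALSE
  for (i in seq_len(nrow(anchors))) {
    if (oracle_dist(pt, anchors[i, ], box) <= radius) inside <- TRUE
  }
  if (inside && !is.null(slab)) {
    d <- match(slab$axis, c("x", "y", "z"))
    inside <- pt[d] >= slab$min && pt[d] <= slab$max
  }
  inside
}

# Visit extraction oracle: fill every interior FALSE gap of length <=
# gap_tolerance, then enumerate TRUE runs by linear scan and drop short
# ones. (The package route merges rle() intervals instead.)
oracle_visits <- function(mem, gap_tolerance, min_duration) {
  n <- length(mem)
  m <- mem
  i <- 1L
  while (i <= n) {
    if (!m[i]) {
      j <- i
      while (j <= n && !m[j]) j <- j + 1L
      if (i > 1L && j <= n && (j - i) <= gap_tolerance)
        m[i:(j - 1L)] <- TRUE
      i <- j
    } else {
      i <- i + 1L
    }
  }
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (m[i]) {
      j <- i
      while (j <= n && m[j]) j <- j + 1L
      if ((j - i) >= min_duration)
        runs[[length(runs) + 1L]] <- c(start = i, end = j - 1L)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (!length(runs)) return(data.frame(start = integer(0), end = integer(0)))
  as.data.frame(do.call(rbind, runs))
}

# Nearest-voxel assignment by exhaustive argmin over voxel centers.
oracle_bin <- function(pts, origin, spacing, shape) {
  counts <- array(0, dim = shape)
  centers <- list(
    origin[1] + (seq_len(shape[1]) - 1) * spacing[1],
    origin[2] + (seq_len(shape[2]) - 1) * spacing[2],
    origin[3] + (seq_len(shape[3]) - 1) * spacing[3])
  for (r in seq_len(nrow(pts))) {
    idx <- integer(3)
    ok <- TRUE
    for (k in 1:3) {
      d <- abs(centers[[k]] - pts[r, k])
      idx[k] <- which.min(d)
      if (min(d) > spacing[k] / 2) ok <- FALSE
    }
    if (ok) counts[idx[1], idx[2], idx[3]] <- counts[idx[1], idx[2], idx[3]] + 1
  }
  counts
}

# Contact frequency oracle: triple loop frames x residues x (atoms, ions).
oracle_contacts <- function(traj, top, ion_idx, cutoff) {
  a <- top$atoms
  cand <- which(a$species == "scaffold")
  resk <- unique(paste(a$chain[cand], a$resid[cand]))
  freq <- setNames(numeric(length(resk)), resk)
  for (f in seq_len(traj$n_frames)) {
    fr <- matrix(traj$coords[, , f], ncol = 3)
    box <- traj$box[f, ]
    for (rk in resk) {
      atoms_r <- cand[paste(a$chain[cand], a$resid[cand]) == rk]
      hit <- FALSE
      for (at in atoms_r) for (io in ion_idx) {
        if (oracle_dist(fr[at, ], fr[io, ], box) <= cutoff) hit <- TRUE
      }
      if (hit) freq[rk] <- freq[rk] + 1
    }
  }
  freq / traj$n_frames
}

# --- fixture builders -------------------------------------------------

# Trajectory whose region membership follows `patterns` (frames x ions
# 0/1 matrix or vector) for a sphere of radius 4 around a fixed anchor.
traj_from_pattern <- function(patterns, dt = 0.1) {
  patterns <- as.matrix(patterns)
  nf <- nrow(patterns)
  n_ion <- ncol(patterns)
  box <- c(30, 30, 30)
  anchor <- c(15, 15, 15)
  atoms <- rbind(
    data.frame(name = "NZ", resname = "LYS", resid = 539, chain = "A"),
    data.frame(name = "CLA", resname = "CLA", resid = seq_len(n_ion),
               chain = "I"))
  coords <- array(0, dim = c(1 + n_ion, 3, nf))
  coords[1, , ] <- anchor
  for (j in seq_len(n_ion)) for (f in seq_len(nf)) {
    coords[1 + j, , f] <- if (patterns[f, j]) anchor + c(1 + j / 10, 0, 0)
      else anchor + c(10 + j, 0, 0)
  }
  top <- ion_topology(atoms, coords[, , 1], box, warn_unknown = FALSE)
  traj <- ion_trajectory(coords, dt, box)
  reg <- make_region(top, "site", 539, radius = 4)
  list(top = top, traj = traj, reg = reg)
}

# Topology with single-atom scaffold residues plus one chloride ion whose
# per-frame positions are given.
contact_fixture <- function(res_pos, ion_pos, dt = 0.1,
                            box = c(50, 50, 50)) {
  n_res <- nrow(res_pos)
  atoms <- rbind(
    data.frame(name = "CA", resname = "GLY", resid = seq_len(n_res),
               chain = "A"),
    data.frame(name = "CLA", resname = "CLA", resid = 1, chain = "I"))
  nf <- nrow(ion_pos)
  coords <- array(0, dim = c(n_res + 1, 3, nf))
  for (f in seq_len(nf)) {
    coords[seq_len(n_res), , f] <- as.matrix(res_pos)
    coords[n_res + 1, , f] <- as.numeric(ion_pos[f, ])
  }
  top <- ion_topology(atoms, coords[, , 1], box, warn_unknown = FALSE)
  list(top = top, traj = ion_trajectory(coords, dt, box))
}

# Tiny scaffold: three basic anchor residues flanking a 16 A deep cavity.
fixture_scaffold <- function(box = c(40, 40, 40)) {
  anch <- data.frame(resname = c("LYS", "ARG", "LYS"),
                     resid = c(539, 730, 851),
                     x = c(20, 23, 17), y = c(23, 20, 20),
                     z = c(18, 24, 24))
  build_scaffold(scaffold_spec(9, 16, anch, box = box))
}

# Two-site Markov scenario: bulk plus bound states S1/S2 at the anchor
# positions, chloride and bicarbonate competing for them.
fixture_two_site_model <- function(seed = 7, n_cl = 4, n_hco3 = 4,
                                   jitter = 0.5) {
  states <- list(bulk = "bulk",
                 S1 = list(point = c(20, 23, 18), jitter = jitter),
                 S2 = list(point = c(23, 20, 24), jitter = jitter))
  P <- rbind(c(0.88, 0.05, 0.07),
             c(0.03, 0.97, 0.00),
             c(0.02, 0.00, 0.98))
  dimnames(P) <- list(names(states), names(states))
  markov_model(states, P, dt = 0.1, species = c("Cl-", "HCO3-"),
               n_ions = c(n_cl, n_hco3), box = c(40, 40, 40), seed = seed)
}

# Hand-built topology: ions at fixed positions, no scaffold.
fixture_ion_topology <- function(n, box = c(30, 30, 30),
                                 species = "Cl-") {
  rn <- unname(c("Cl-" = "CLA", "HCO3-" = "BIC", "Na+" = "SOD",
                 "CO32-" = "CO3")[species])
  ion_topology(data.frame(name = rn, resname = rn, resid = seq_len(n),
                          chain = "I", stringsAsFactors = FALSE),
               matrix(box[1] / 2, n, 3), box)
}

# Trajectory from an explicit (n_atoms x 3 x n_frames) coordinate array.
fixture_traj <- function(coords, dt = 0.1, box = c(30, 30, 30)) {
  ion_trajectory(coords, dt, box)
}

# Two-site YAML-free pipeline config built on fixture_two_site_model.
fixture_pipeline_config <- function(seed = 11, n_steps = 800) {
  list(
    seed = seed,
    synthetic = list(
      box = c(40, 40, 40), dt = 0.1, n_steps = n_steps,
      species = list("Cl-", "HCO3-"), n_ions = list(4, 4),
      scaffold = list(
        cavity_radius = 9, cavity_depth = 16,
        anchor_residues = list(
          list(resname = "LYS", resid = 539, x = 20, y = 23, z = 18),
          list(resname = "ARG", resid = 730, x = 23, y = 20, z = 24),
          list(resname = "LYS", resid = 851, x = 17, y = 20, z = 24))),
      states = list(bulk = "bulk",
                    S1 = list(point = c(20, 23, 18), jitter = 0.5),
                    S2 = list(point = c(23, 20, 24), jitter = 0.5)),
      P = list(c(0.88, 0.05, 0.07),
               c(0.03, 0.97, 0.00),
               c(0.02, 0.00, 0.98))),
    regions = list(center = list(residues = c(539, 730, 851), radius = 6)))
}
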