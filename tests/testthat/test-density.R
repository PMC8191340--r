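# density_maps: binning, normalization, GFE conversion, overlap, sites.

test_that("accumulate_density bins with exact mass conservation", {
  top <- fixture_ion_topology(1)
  coords <- array(rep(c(15.2, 15.2, 15.2), 100), dim = c(1, 3, 100))
  traj <- fixture_traj(coords)
  g <- accumulate_density(traj, top, species = "Cl-", spacing = 1)
  expect_equal(sum(g$values), 100)
  expect_equal(max(g$values), 100)   # a single voxel holds everything
  expect_equal(sum(g$values > 0), 1)

  # moving ions always inside the extent: total = frames x ions
  top3 <- fixture_ion_topology(3)
  set.seed(40)
  coords3 <- array(runif(3 * 3 * 50, 10, 20), dim = c(3, 3, 50))
  traj3 <- fixture_traj(coords3)
  g3 <- accumulate_density(traj3, top3, species = "Cl-", spacing = 1,
                           extent = list(origin = c(5, 5, 5),
                                         shape = c(25, 25, 25)))
  expect_equal(sum(g3$values), 3 * 50)
})

test_that("binning matches the brute-force nearest-voxel oracle", {
  set.seed(41)
  n <- 1000
  pts <- matrix(runif(3 * n, 2, 12), n, 3)
  top <- fixture_ion_topology(n)
  traj <- fixture_traj(array(pts, dim = c(n, 3, 1)))
  origin <- c(2, 2, 2)
  shape <- c(11, 11, 11)
  g <- accumulate_density(traj, top, species = "Cl-", spacing = 1,
                          extent = list(origin = origin, shape = shape))
  want <- oracle_bin(pts, origin, c(1, 1, 1), shape)
  expect_equal(g$values, want)
})

test_that("normalization modes and exact denormalization", {
  top <- fixture_ion_topology(1)
  coords <- array(rep(c(15.2, 15.2, 15.2), 100), dim = c(1, 3, 100))
  g <- accumulate_density(fixture_traj(coords), top, species = "Cl-")
  cpf <- normalize_density(g, "counts_per_frame")
  expect_equal(max(cpf$values), 1.0)
  prob <- normalize_density(g, "probability")
  expect_equal(sum(prob$values), 1.0)
  back <- denormalize_density(cpf)
  expect_identical(back$values, g$values)
  expect_error(normalize_density(cpf, "probability"), "raw_counts")
})

test_that("GFE conversion reproduces the capped Boltzmann inversion", {
  vals <- array(0, dim = c(3, 1, 1))
  vals[1, 1, 1] <- 1.0        # occ == bulk -> 0 exactly
  vals[2, 1, 1] <- exp(1)     # occ/bulk = e -> -RT at 300 K
  vals[3, 1, 1] <- 0          # empty voxel -> cap
  g <- density_grid(vals, c(0, 0, 0), 1, "counts_per_frame", 10)
  gfe <- gfe_from_density(g, bulk = 1.0, temperature = 300, cap = 3)
  expect_identical(gfe$values[1, 1, 1], 0)
  expect_equal(gfe$values[2, 1, 1], -1.9872e-3 * 300, tolerance = 1e-9)
  expect_equal(gfe$values[2, 1, 1], -0.59616, tolerance = 1e-6)
  expect_identical(gfe$values[3, 1, 1], 3)

  # monotone non-increasing in occupancy; capped iff occ/bulk <= exp(-cap/RT)
  occ <- sort(c(10^seq(-4, 1, length.out = 40), exp(-3 / (1.9872e-3 * 300))))
  gm <- gfe_from_density(
    density_grid(array(occ, dim = c(length(occ), 1, 1)), c(0, 0, 0), 1,
                 "counts_per_frame", 1), bulk = 1.0)
  v <- as.numeric(gm$values)
  expect_true(all(diff(v) <= 1e-12))
  thresh <- exp(-3 / (1.9872e-3 * 300))
  expect_true(all((v >= 3 - 1e-9) == (occ <= thresh + 1e-15)))
  expect_true(all(v <= 3))

  expect_error(gfe_from_density(g, bulk = 0), "bulk")
})

test_that("overlap coefficient has its defining properties", {
  mk <- function(v) density_grid(array(v, dim = c(length(v), 1, 1)),
                                 c(0, 0, 0), 1, "counts_per_frame", 1)
  a <- mk(c(0.7, 0.3))
  b <- mk(c(0.3, 0.7))
  expect_equal(overlap_coefficient(a, a), 1.0)
  expect_equal(overlap_coefficient(a, b), 0.6)
  expect_lt(abs(overlap_coefficient(a, b) - overlap_coefficient(b, a)),
            1e-12)
  expect_equal(overlap_coefficient(mk(c(1, 0)), mk(c(0, 1))), 0.0)
  # invariant to common rescaling; proportional maps give exactly 1
  expect_equal(overlap_coefficient(mk(c(0.2, 0.8)), mk(10 * c(0.2, 0.8))),
               1.0)
  expect_error(overlap_coefficient(a, mk(c(1, 2, 3))), "lattice")
})

test_that("detect_sites separates face-connected components", {
  # two Gaussian blobs well above the isovalue
  d <- c(21, 21, 21)
  vals <- array(0, dim = d)
  centers <- list(c(6, 6, 6), c(15, 15, 15))
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    for (cc in centers) {
      r2 <- sum((c(i, j, k) - cc)^2)
      vals[i, j, k] <- vals[i, j, k] + exp(-r2 / 4)
    }
  }
  g <- density_grid(vals, c(0, 0, 0), 1, "counts_per_frame", 1)
  s <- detect_sites(g, isovalue = 0.1, min_voxels = 2)
  expect_equal(nrow(s), 2)
  got <- as.matrix(s[c("cx", "cy", "cz")])
  want <- rbind(c(5, 5, 5), c(14, 14, 14))  # voxel centers (0-origin lattice)
  for (r in 1:2)
    expect_lt(min(sqrt(rowSums((got - matrix(want[r, ], 2, 3,
                                             byrow = TRUE))^2))), 1)

  expect_equal(nrow(detect_sites(
    density_grid(array(0, dim = c(4, 4, 4)), c(0, 0, 0), 1,
                 "counts_per_frame", 1), 0.1)), 0)

  # a one-voxel sub-isovalue gap splits a blob under face connectivity
  line <- array(0, dim = c(7, 1, 1))
  line[, 1, 1] <- c(0.5, 0.5, 0.5, 0.05, 0.5, 0.5, 0.5)
  gl <- density_grid(line, c(0, 0, 0), 1, "counts_per_frame", 1)
  expect_equal(nrow(detect_sites(gl, isovalue = 0.1)), 2)

  # diagonal-only adjacency does not connect
  diagv <- array(0, dim = c(3, 3, 1))
  diagv[1, 1, 1] <- 1
  diagv[2, 2, 1] <- 1
  gd <- density_grid(diagv, c(0, 0, 0), 1, "counts_per_frame", 1)
  expect_equal(nrow(detect_sites(gd, isovalue = 0.5)), 2)

  # sites are ordered by integrated density, descending
  two <- array(0, dim = c(9, 1, 1))
  two[1:3, 1, 1] <- 0.2
  two[6:8, 1, 1] <- 0.9
  gt <- density_grid(two, c(0, 0, 0), 1, "counts_per_frame", 1)
  st <- detect_sites(gt, isovalue = 0.1)
  expect_true(st$integrated[1] > st$integrated[2])
  expect_equal(st$cx[1], 6)
})
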