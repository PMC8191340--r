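# synthetic_data: scaffold construction and the two trajectory generators.

test_that("build_scaffold places anchors and walls as specified", {
  anch <- data.frame(resname = c("LYS", "ARG", "GLU"),
                     resid = c(539, 730, 535),
                     x = c(20, 24, 16), y = c(20, 20, 20),
                     z = c(20, 22, 22))
  spec <- scaffold_spec(8, 16, anch, box = c(40, 40, 40))
  top <- build_scaffold(spec)
  res <- residue_table(top)
  non_wall <- res[res$resname != "WAL", ]
  expect_equal(nrow(non_wall), 3)
  expect_setequal(non_wall$resid, c(539, 730, 535))
  expect_setequal(non_wall$resname, c("LYS", "ARG", "GLU"))

  # anchor requested at the box corner sits exactly there
  anch0 <- data.frame(resname = "LYS", resid = 1, x = 0, y = 0, z = 0)
  top0 <- build_scaffold(scaffold_spec(5, 10, anch0, box = c(20, 20, 20)))
  a0 <- which(top0$atoms$resname == "LYS")
  expect_equal(unname(top0$coords[a0, ]), c(0, 0, 0))

  # exhaustive distance scan: no wall atom within the cavity radius of
  # the axis (z axis through the box center)
  wall <- top$coords[top$atoms$resname == "WAL", ]
  d_axis <- sqrt((wall[, 1] - 20)^2 + (wall[, 2] - 20)^2)
  expect_true(all(d_axis >= 8 - 1e-9))

  # deterministic construction
  expect_identical(build_scaffold(spec)$coords, top$coords)
})

test_that("scaffold_spec rejects bad anchors and geometry", {
  anch <- data.frame(resname = "LYS", resid = 539, x = 99, y = 5, z = 5)
  expect_error(scaffold_spec(8, 16, anch, box = c(40, 40, 40)),
               "LYS 539")
  ok <- data.frame(resname = "LYS", resid = 1, x = 5, y = 5, z = 5)
  expect_error(scaffold_spec(-1, 16, ok, box = c(40, 40, 40)),
               "cavity_radius")
  dup <- data.frame(resname = c("LYS", "ARG"), resid = c(7, 7),
                    x = c(5, 6), y = c(5, 6), z = c(5, 6))
  expect_error(scaffold_spec(8, 16, dup, box = c(40, 40, 40)), "unique")
})

test_that("markov_model validates its transition matrix", {
  states <- list(bulk = "bulk", S = list(point = c(5, 5, 5), jitter = 0.3))
  bad <- rbind(c(0.9, 0.2), c(0.1, 0.9))
  dimnames(bad) <- list(names(states), names(states))
  expect_error(markov_model(states, bad, dt = 0.1, species = "Cl-",
                            n_ions = 1, box = c(20, 20, 20), seed = 1),
               "row-stochastic")
  P <- rbind(c(0.9, 0.1), c(0.01, 0.99))
  dimnames(P) <- list(names(states), names(states))
  m <- markov_model(states, P, dt = 0.1, species = "Cl-", n_ions = 1,
                    box = c(20, 20, 20), seed = 1)
  expect_equal(unname(m$expected_residence_ns["S"]), 0.1 / (1 - 0.99))
})

test_that("markov state sojourns follow the geometric law", {
  states <- list(bulk = "bulk", S = list(point = c(10, 10, 10),
                                         jitter = 0.3))
  # forced exit: P[S, S] = 0 means every visit to S lasts exactly 1 step
  P0 <- rbind(c(0.5, 0.5), c(1, 0))
  dimnames(P0) <- list(names(states), names(states))
  m0 <- markov_model(states, P0, dt = 0.1, species = "Cl-", n_ions = 5,
                     box = c(20, 20, 20), seed = 2)
  sim0 <- simulate_markov_ions(m0, 400)
  runs <- apply(sim0$ground_truth$states == "S", 2, function(v) {
    r <- rle(v)
    r$lengths[r$values]
  })
  expect_true(all(unlist(runs) == 1))

  # geometric closed form: P[S, S] = 0.99, dt = 0.1 -> mean 10 ns,
  # empirical mean over >= 2000 completed visits within 10%
  P <- rbind(c(0.7, 0.3), c(0.01, 0.99))
  dimnames(P) <- list(names(states), names(states))
  m <- markov_model(states, P, dt = 0.1, species = "Cl-", n_ions = 20,
                    box = c(20, 20, 20), seed = 3)
  sim <- simulate_markov_ions(m, 12000)
  durs <- unlist(lapply(seq_len(20), function(j) {
    v <- sim$ground_truth$states[, j] == "S"
    r <- rle(v)
    len <- r$lengths[r$values]
    # drop runs touching either end (censored)
    if (v[1]) len <- len[-1]
    if (v[length(v)] && length(len)) len <- len[-length(len)]
    len
  }))
  expect_gt(length(durs), 2000)
  expect_lt(abs(mean(durs) * 0.1 - 10) / 10, 0.10)
})

test_that("absorbing bound state yields a single terminal visit", {
  states <- list(bulk = "bulk", S = list(point = c(10, 10, 10),
                                         jitter = 0.2))
  P <- rbind(c(0.8, 0.2), c(0, 1))
  dimnames(P) <- list(names(states), names(states))
  m <- markov_model(states, P, dt = 0.1, species = "Cl-", n_ions = 3,
                    box = c(20, 20, 20), seed = 4)
  sim <- simulate_markov_ions(m, 300)
  for (j in 1:3) {
    v <- sim$ground_truth$states[, j] == "S"
    k <- which(v)[1]
    expect_false(is.na(k))
    expect_true(all(v[k:300]))
    expect_true(all(!v[seq_len(k - 1)]))
  }
})

test_that("markov trajectories are bit-identical per seed", {
  m <- fixture_two_site_model(seed = 42)
  a <- simulate_markov_ions(m, 200)
  b <- simulate_markov_ions(m, 200)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$ground_truth$states, b$ground_truth$states)
  c <- simulate_markov_ions(fixture_two_site_model(seed = 43), 200)
  expect_false(identical(a$trajectory$coords, c$trajectory$coords))
})

test_that("bulk placement stays out of the bound-site exclusion zone", {
  m <- fixture_two_site_model(seed = 5)
  sim <- simulate_markov_ions(m, 300)
  pts <- rbind(c(20, 23, 18), c(23, 20, 24))
  for (j in seq_along(sim$ground_truth$species)) {
    bulk_frames <- which(sim$ground_truth$states[, j] == "bulk")
    xyz <- t(sim$trajectory$coords[sim$ground_truth$ion_index[j], ,
                                   bulk_frames])
    for (b in 1:2) {
      expect_true(all(min_image_dist(pts[b, ], xyz,
                                     c(40, 40, 40)) > 6))
    }
  }
})

test_that("free Brownian diffusion matches the Einstein relation", {
  spec <- brownian_spec(list(), diffusion_coefficient = 10, dt = 0.01,
                        n_steps = 400, box = c(200, 200, 200),
                        n_ions = 120, seed = 6)
  sim <- simulate_brownian_ions(spec)
  u <- sim$ground_truth$unwrapped
  lag <- 200
  disp <- u[, , 1 + lag] - u[, , 1]
  msd <- mean(rowSums(disp^2))
  expected <- 6 * 10 * lag * 0.01
  expect_lt(abs(msd - expected) / expected, 0.10)
})

test_that("degenerate and confined Brownian cases behave", {
  frozen <- brownian_spec(list(), diffusion_coefficient = 0, dt = 0.01,
                          n_steps = 50, box = c(20, 20, 20), n_ions = 5,
                          seed = 7)
  sim <- simulate_brownian_ions(frozen)
  expect_true(all(sim$trajectory$coords ==
                    array(sim$trajectory$coords[, , 1],
                          dim = dim(sim$trajectory$coords))))

  # deep well: depth 10 kT, width 2 A, ion started at the center stays
  # within 3 widths for 1e4 steps (Boltzmann escape bound)
  kT <- 0.596
  well <- list(list(center = c(10, 10, 10), depth = 10 * kT, width = 2))
  spec <- brownian_spec(well, diffusion_coefficient = 10, kT = kT,
                        dt = 0.001, n_steps = 1e4, box = c(20, 20, 20),
                        n_ions = 1, start = c(10, 10, 10), seed = 8)
  sim <- simulate_brownian_ions(spec)
  d <- min_image_dist(c(10, 10, 10),
                      t(sim$trajectory$coords[1, , ]), c(20, 20, 20))
  expect_true(all(d < 6))

  # stability contract: huge step rejected at construction
  expect_error(brownian_spec(well, diffusion_coefficient = 1000,
                             kT = kT, dt = 1, n_steps = 10,
                             box = c(20, 20, 20), seed = 9),
               "stability")

  # determinism
  a <- simulate_brownian_ions(spec)
  expect_identical(a$trajectory$coords, sim$trajectory$coords)
})
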