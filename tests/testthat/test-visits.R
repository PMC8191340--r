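# regions_occupancy: visit extraction, residence statistics, entries.

test_that("extract_visits applies gap bridging and minimum duration", {
  f <- traj_from_pattern(c(0, 0, 0, 1, 1, 1, 0, 0))
  v <- extract_visits(f$traj, f$top, f$reg, gap_tolerance = 0)
  expect_equal(nrow(v), 1)
  expect_equal(c(v$start, v$end), c(4, 6))
  expect_equal(v$duration_ns, 3 * 0.1)
  expect_false(v$censored_start || v$censored_end)

  f2 <- traj_from_pattern(c(0, 0, 1, 1, 0, 1, 1))
  v2 <- extract_visits(f2$traj, f2$top, f2$reg, gap_tolerance = 1)
  expect_equal(nrow(v2), 1)
  expect_equal(c(v2$start, v2$end), c(3, 7))
  expect_true(v2$censored_end)

  v3 <- extract_visits(f2$traj, f2$top, f2$reg, gap_tolerance = 0)
  expect_equal(nrow(v3), 2)
  expect_equal(v3$start, c(3, 6))
  expect_equal(v3$end, c(4, 7))

  v4 <- extract_visits(f2$traj, f2$top, f2$reg, gap_tolerance = 0,
                       min_duration = 3)
  expect_equal(nrow(v4), 0)
})

test_that("visit merging matches the brute-force oracle on random patterns", {
  set.seed(20)
  for (rep in 1:25) {
    nf <- sample(5:30, 1)
    pat <- runif(nf) < 0.5
    gap <- sample(0:3, 1)
    md <- sample(1:3, 1)
    f <- traj_from_pattern(pat)
    v <- extract_visits(f$traj, f$top, f$reg, gap_tolerance = gap,
                        min_duration = md)
    o <- oracle_visits(pat, gap, md)
    expect_equal(nrow(v), nrow(o))
    if (nrow(o)) {
      expect_equal(v$start, o$start)
      expect_equal(v$end, o$end)
    }
  }
})

test_that("merging is monotone in gap tolerance and minimum duration", {
  set.seed(21)
  for (rep in 1:10) {
    pat <- runif(24) < 0.5
    f <- traj_from_pattern(pat)
    counts_gap <- vapply(0:4, function(g)
      nrow(extract_visits(f$traj, f$top, f$reg, gap_tolerance = g)), 0L)
    expect_true(all(diff(counts_gap) <= 0))
    counts_md <- vapply(1:5, function(md)
      nrow(extract_visits(f$traj, f$top, f$reg, gap_tolerance = 0,
                          min_duration = md)), 0L)
    expect_true(all(diff(counts_md) <= 0))
  }
})

test_that("occupancy and visit bookkeeping conserve frame counts", {
  m <- fixture_two_site_model(seed = 22, n_cl = 3, n_hco3 = 3)
  sim <- simulate_markov_ions(m, 120, scaffold = fixture_scaffold())
  reg <- make_region(sim$topology, "center", c(539, 730, 851), radius = 6)
  occ <- occupancy_counts(sim$trajectory, sim$topology, reg,
                          c("Cl-", "HCO3-"))
  vis <- extract_visits(sim$trajectory, sim$topology, reg,
                        gap_tolerance = 0, min_duration = 1)
  # sum over ions of frames-in-region == sum over frames of counts, exactly
  expect_identical(sum(vis$end - vis$start + 1L), sum(occ$count))

  # per ion, entries and exits differ by at most 1
  for (i in unique(vis$ion)) {
    d <- vis[vis$ion == i, ]
    entries <- sum(!d$censored_start)
    exits <- sum(!d$censored_end)
    expect_lte(abs(entries - exits), 1)
  }
})

test_that("residence_stats summarizes uncensored visits", {
  f <- traj_from_pattern(c(0, 1, 0, 1, 1, 0, 1, 1, 1, 0), dt = 1)
  v <- extract_visits(f$traj, f$top, f$reg, gap_tolerance = 0)
  s <- residence_stats(v)
  expect_equal(s$mean_ns, 2)         # durations 1, 2, 3 ns
  expect_equal(s$median_ns, 2)
  expect_equal(s$max_ns, 3)
  expect_equal(s$n_visits, 3)

  # censored visits excluded by default, included on request
  fc <- traj_from_pattern(c(1, 1, 0, 1, 0, 0))
  vc <- extract_visits(fc$traj, fc$top, fc$reg, gap_tolerance = 0)
  sc <- residence_stats(vc)
  expect_equal(sc$n_censored, 1)
  expect_equal(sc$n_visits, 1)
  si <- residence_stats(vc, censoring = "include")
  expect_equal(si$n_visits, 2)

  # no visits at all: count 0 and undefined (NA) statistics, not zero
  f0 <- traj_from_pattern(rep(0, 6))
  v0 <- extract_visits(f0$traj, f0$top, f0$reg)
  s0 <- residence_stats(v0)
  expect_equal(nrow(s0), 0)
  s0g <- residence_stats(v0, groups = data.frame(region = "site",
                                                 species = "Cl-"))
  expect_equal(s0g$n_visits, 0)
  expect_true(is.na(s0g$mean_ns))
})

test_that("count_entries books entries and exchanges", {
  # one uninterrupted interior visit -> 1 entry, 0 exchanges
  f1 <- traj_from_pattern(c(0, 1, 1, 0))
  v1 <- extract_visits(f1$traj, f1$top, f1$reg, gap_tolerance = 0)
  e1 <- count_entries(v1)
  expect_equal(e1$n_entries, 1)
  expect_equal(e1$n_exchanges, 0)

  # ion A occupies frames 1-3, ion B frames 3-6: the region never
  # empties and the occupant identity changes -> 2 entries, 1 exchange
  pat <- cbind(c(0, 1, 1, 0, 0, 0), c(0, 0, 1, 1, 1, 0))
  f2 <- traj_from_pattern(pat)
  v2 <- extract_visits(f2$traj, f2$top, f2$reg, gap_tolerance = 0)
  e2 <- count_entries(v2)
  expect_equal(e2$n_entries, 2)
  expect_equal(e2$n_exchanges, 1)

  # empty region -> zero entries
  f0 <- traj_from_pattern(rep(0, 5))
  v0 <- extract_visits(f0$traj, f0$top, f0$reg)
  e0 <- count_entries(v0)
  expect_equal(nrow(e0), 0)
})
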