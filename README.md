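# ionsite

Ion binding-site discovery from molecular-dynamics-style trajectories, and
H⁺/base flux quantification from intracellular pH recordings.

## What problem this solves

Membrane transporters of the SLC4 family (e.g. the Cl⁻/HCO₃⁻ exchanger AE1
and the Na⁺-HCO₃⁻ cotransporter NBCe1) bind their substrate anions at
localized sites inside a wide, solvent-exposed permeation cavity. Two
complementary kinds of evidence identify such sites:

1. **Trajectory statistics.** Given a topology and a trajectory of ions
   around a protein scaffold, the sites show up as (a) regions whose ion
   *occupancy* is high, with long *residence times* and many unique *entry
   events*; (b) residues with high ion *contact frequency* (fraction of
   frames with the ion within a cutoff, conventionally 5 Å); and (c)
   connected peaks in the voxelized 3D *ion density map*, conventionally
   drawn at an isovalue of 0.1 on a 1 Å grid.
2. **Functional flux.** In cells expressing the transporter, a bath-solution
   switch drives base transport; the initial rate of intracellular pH
   change, scaled by the cell's buffering power, gives the transport flux,
   and mutants are compared to wild type by ANOVA with Dunnett's
   many-to-one test.

`ionsite` implements both pipelines as tested, reusable R code, together
with synthetic-data generators whose kinetics are known in closed form, so
every estimator can be validated against analytic ground truth.

## The core quantities

With frames at spacing Δt, region membership *m(i, t)* of ion *i* at frame
*t* (inside a union of spheres of radius *R* around anchor atoms, with
minimum-image distances):

- **Occupancy fraction**: percentage of frames with 0, 1, 2, ≥3 ions in a
  region; rows sum to 100%.
- **Visit / residence time**: a maximal run of in-region frames (gaps ≤ a
  tolerance bridged); duration = (end − start + 1)·Δt; visits touching a
  trajectory end are censored. An *entry* is a visit not censored at the
  start; an *exchange* is a change of occupant identity with the region
  never emptying.
- **Contact frequency**: fraction of frames in which any non-hydrogen atom
  of a residue lies within the cutoff (default 5 Å) of an ion.
- **Density and grid free energy (GFE)**: ion positions are binned
  (nearest voxel, default 1 Å spacing) into counts per frame n(x), and

      GFE(x) = min{ −RT ln[ n(x) / ⟨n_bulk⟩ ], cap },   cap = 3 kcal/mol

  with R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹, T = 300 K. Map similarity uses the
  overlap coefficient OC = Σₓ min(a(x), b(x)) of unit-normalized maps
  (OC > 0.70 indicates convergence). Sites are face-connected components
  of voxels ≥ isovalue.
- **H⁺/base flux**: β_HCO3 = 2.3·[HCO₃⁻]_in, [HCO₃⁻]_in =
  [HCO₃⁻]_bath·10^(pH_i − pH_bath); flux = (β_i + β_HCO3) · dpH_i/dt, with
  dpH_i/dt the OLS slope over the initial 10–15 s after the switch.

The Markov generator gives the analytic benchmark: a bound state with
self-transition probability *p* has mean residence Δt/(1 − *p*) (geometric
law), e.g. *p* = 0.99, Δt = 0.1 ns → 10 ns.

## Worked example

Two binding sites S1/S2 inside a synthetic cavity, visited by competing
Cl⁻ and HCO₃⁻ ions with known kinetics:

```r
library(ionsite)

anchors <- data.frame(resname = c("LYS", "ARG", "LYS"),
                      resid   = c(539, 730, 851),
                      x = c(20, 23, 17), y = c(23, 20, 20), z = c(18, 24, 24))
scaffold <- build_scaffold(scaffold_spec(
  cavity_radius = 9, cavity_depth = 16,
  anchor_residues = anchors, box = c(40, 40, 40)))

states <- list(bulk = "bulk",
               S1 = list(point = c(20, 23, 18), jitter = 0.5),
               S2 = list(point = c(23, 20, 24), jitter = 0.5))
P <- rbind(c(0.88, 0.05, 0.07),
           c(0.03, 0.97, 0.00),
           c(0.02, 0.00, 0.98))
dimnames(P) <- list(names(states), names(states))
model <- markov_model(states, P, dt = 0.1, species = c("Cl-", "HCO3-"),
                      n_ions = c(4, 4), box = c(40, 40, 40), seed = 7)
model$expected_residence_ns
#>      bulk        S1        S2
#> 0.8333333 3.3333333 5.0000000
sim <- simulate_markov_ions(model, n_steps = 2000, scaffold = scaffold)

center <- make_region(sim$topology, "center", c(539, 730, 851), radius = 6)
vis <- extract_visits(sim$trajectory, sim$topology, center, gap_tolerance = 0)
residence_stats(vis)
#>   region species n_visits n_censored mean_ns median_ns max_ns
#> 1 center     Cl-      159          4    4.19       2.7   23.5
#> 2 center   HCO3-      163          4    3.95       2.5   19.5
count_entries(vis)
#>   region species n_entries n_exchanges
#> 1 center     Cl-       163         153
#> 2 center   HCO3-       167         162
```

The per-region means (4.19 / 3.95 ns) sit between the S1 and S2 analytic
residence times (3.33 and 5 ns) because the region covers both sites; the
entry counts show the ions exchanging freely, as expected for an open
cavity. Contact analysis ranks the anchor residues nearest the sites on
top, and the density map recovers both placement points within one voxel:

```r
ct <- contact_frequencies(sim$trajectory, sim$topology,
                          species = "HCO3-", cutoff = 5)
head(rank_site_residues(ct, threshold = 0.3), 2)
#>   chain resid resname species frequency n_frames
#> 1     A   730     ARG   HCO3-     0.989     2000
#> 2     A   539     LYS   HCO3-     0.549     2000

dens <- normalize_density(
  accumulate_density(sim$trajectory, sim$topology,
                     species = c("Cl-", "HCO3-"), spacing = 1),
  "counts_per_frame")
detect_sites(dens, isovalue = 0.1, min_voxels = 2)[, 1:7]
#>   site n_voxels   peak integrated    cx cy    cz
#> 1    1        7 1.6545      3.862 23.02 20 23.99
#> 2    2        7 0.5395      1.277 20.01 23 17.98
```

Site 1 (centroid ≈ (23, 20, 24)) is the stronger S2-like site; site 2
recovers S1 at (20, 23, 18). For the flux side, a noiseless synthetic
recording with a programmed flux of 0.05 mM/s inverts cleanly:

```r
baths <- data.frame(t_start = c(0, 30), hco3_bath_mM = c(24, 24),
                    ph_bath = c(7.4, 7.4))
trace <- simulate_ph_trace(0.05, beta_i = 20, baths = baths,
                           duration_s = 120, sampling_rate_hz = 2, seed = 3)
estimate_flux(trace, beta_i = 20)
#> flux_result: dpH/dt 0.001181 pH/s (se 5.79e-07), beta_total 42.35 mM/pH,
#>              flux 0.050018 mM/s
```

## Command line

```sh
inst/cli/ionsite run --config run.yaml --seed 11 --out outdir
```

runs simulate → occupancy → visits → contacts → density → GFE → sites and
writes CSV tables, OpenDX grids, `ground_truth.json` and `summary.json`
(exit codes: 0 ok, 2 config error, 1 stage failure). Single stages
(`occupancy`, `contacts`, `density`, `sites`, `flux`, ...) are available as
subcommands. Note that YAML 1.1 parses a bare `y` key as a boolean; the
config reader maps it back to the `y` coordinate for anchor positions.

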