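---
title: "ionsite: methods, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ionsite: methods, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionsite)
```

## Scope and model

`ionsite` quantifies where and how ions bind inside a protein's permeation
cavity, from two independent directions: geometric/statistical analysis of
ion trajectories (occupancy, residence, entries, contacts, density maps),
and functional flux analysis of intracellular pH recordings. The package
does not run molecular dynamics and does not model forces, water, or
electrostatics: trajectories are inputs (or are generated synthetically),
assumed already aligned and centered on the protein, with orthorhombic
periodic boxes and minimum-image distances throughout. Units are fixed:
Å, ns, kcal/mol, K for the trajectory side; s, mM, pH units for the flux
side.

## Trajectory-side definitions

**Regions.** A region is a union of spheres of radius `radius` (default
6 Å) around anchor atoms resolved from residue selectors, optionally
intersected with an axis-aligned slab. Anchors are re-resolved from the
coordinates of every frame, so a region tracks a moving scaffold. The
6 Å default, and the union-of-spheres geometry itself, are this package's
choices: cavity zones in the source literature are drawn qualitatively
around the flanking basic residues rather than defined by printed
coordinates, so any concrete geometry is a stand-in. The slab option
exists to split a "cavity" zone from a deeper "center" zone along the
pore axis.

**Visits.** Per ion, membership over frames is reduced to maximal runs;
out-of-region gaps of at most `gap_tolerance` frames (default 2) are
bridged, then merged runs shorter than `min_duration` frames (default 1)
are dropped. Bridging exists because a jittering ion at the region
boundary would otherwise register many spurious "unique entry events".
The defaults are deliberately mild; both knobs are exposed in the config,
and the estimator-recovery tests use `gap_tolerance = 0` so that the
measured sojourns correspond exactly to the generator's geometric law.
Visits touching either trajectory end are flagged censored; censored
visits are excluded from residence statistics by default (their durations
are lower bounds — an ion that never leaves reports the full trajectory
length), and a group with zero usable visits reports `NA` statistics, not
zero. Entries count visits not censored at the start; exchanges count
frame boundaries where the occupant set changes (someone leaves) while
the region never empties.

**Contacts.** A residue contacts an ion in a frame when any of its
non-hydrogen atoms is within `cutoff` (default 5 Å, the conventional
ion–protein interaction cutoff) of the ion's representative point. The
contact is per-frame binary, not atom-pair weighted: the convention in
the source analyses is stated only as "residues within 5 Å of the ion",
so the simplest frame-level indicator was chosen; it is reorder-invariant
and monotone in the cutoff, which the property tests exercise. The ion
representative point is its single atom (for real multi-atom anions, use
the central carbon when building the topology).

**Density and GFE maps.** Ion positions are binned into voxels by
nearest-center (top-hat) assignment on a lattice with default 1 Å
spacing. Top-hat binning (rather than a Gaussian kernel) makes mass
conservation exact — total counts equal in-extent (ion, frame) pairs as
an integer identity — which in turn makes the brute-force re-binning
oracle meaningful. Normalization modes are counts per frame (the default
working currency), and probability. The grid free energy is

$$\mathrm{GFE}(x) = \min\{-RT\,\ln[n(x)/\langle n_{\mathrm{bulk}}\rangle],\ \mathrm{cap}\}$$

with $R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$, default
$T = 300$ K and cap 3 kcal/mol. Empty voxels map to the cap, and the cap
is attained exactly when $n/\bar n_{\mathrm{bulk}} \le e^{-\mathrm{cap}/RT}$.
The bulk reference is either a user-supplied number or the mean
counts-per-frame over a designated bulk mask; the source procedure
normalizes "to bulk occupancy" without printing the estimator, so the
estimator is exposed rather than hard-coded (the pipeline defaults to the
mean over non-empty voxels, which is conservative for sparse boxes).

**Site detection.** Sites are face-connected (6-neighborhood) components
of voxels at or above `isovalue`, default 0.1 *in counts-per-frame
units* — the units of the conventional "isovalue 0.1" are not printed
anywhere authoritative, so the package fixes them to its own density
normalization and documents that choice. Components smaller than
`min_voxels` are discarded; sites are ranked by integrated density, with
density-weighted centroids reported. Face connectivity (not 26-neighbor)
was chosen so that a one-voxel sub-threshold gap genuinely separates two
sites; a test pins this behavior.

**Overlap coefficient.** $\mathrm{OC} = \sum_x \min(a_x, b_x)$ over maps
independently thresholded (default threshold 0) and normalized to unit
sum. The exact formula lives in a methods reference that is not part of
the source text; this Σmin form is symmetric, bounded in [0, 1], equal to
1 iff the maps are proportional, and invariant to rescaling either map —
the properties the convergence diagnostic needs and that the tests assert.

## Synthetic generators (the stated world)

The generators are first-class, tested code, and the oracle for every
estimator. They emulate: several ion species diffusing in a solvent
region and visiting one or two localized binding regions inside a static
scaffold, with controllable exit kinetics and species competition; and
pH traces with a programmed post-switch flux.

**Scaffold.** Wall pseudo-atoms on a cylinder (radius, depth,
atom spacing 2 Å by default) inside the box, plus named single-atom
anchor residues at fixed positions. Deterministic; anchors outside the
box are rejected by name.

**Markov ions.** Each ion hops independently between named states under
a row-stochastic per-step matrix `P` (rows must sum to 1 within 1e-12).
Bound states place the ion at a point with Gaussian jitter (default sd
0.5 Å); the bulk state resamples uniformly in the box excluding an
exclusion radius (default 6 Å) around every bound point — ions in bulk
are interchangeable, and downstream statistics only depend on region
membership, so no diffusion model is needed there. The geometric sojourn
law gives exact expected residences $\Delta t/(1 - P_{ss})$; the
acceptance test uses $P_{ss} = 0.99$, $\Delta t = 0.1$ ns (10 ns) with
≥ 2000 completed visits and a 10% band. Ion–ion interactions are omitted
so the oracle stays closed-form; an optional single-occupancy constraint
per bound state (redirecting a second arrival to bulk) emulates sites
that hold one anion at a time.

**Brownian ions.** Overdamped Langevin (Euler–Maruyama) motion in a sum
of Gaussian wells, $U(x) = -\sum_j d_j e^{-|x-c_j|^2/2w_j^2}$, with
periodic wrapping; the unwrapped coordinates are kept for displacement
statistics. A construction-time stability contract bounds the
deterministic per-step drift by 0.1 of every well width (the "≪ width"
requirement made concrete; 0.1 is this package's threshold). Free
diffusion is checked against the Einstein relation
$\langle r^2(t)\rangle = 6Dt$ (10% band over ≥ 100 ions), and a deep
well (depth 10 kT, width 2 Å) must confine a centered ion for 10⁴ steps.

**pH traces.** pH$_i$ is integrated forward from
$d\mathrm{pH}_i/dt = J/(\beta_i + \beta_{\mathrm{HCO3}}(\mathrm{pH}_i))$
after the first switch, with
$\beta_{\mathrm{HCO3}} = 2.3\,[\mathrm{HCO_3^-}]_{in}$ and
$[\mathrm{HCO_3^-}]_{in} = [\mathrm{HCO_3^-}]_{bath}\,
10^{\mathrm{pH}_i-\mathrm{pH}_{bath}}$ (CO₂ equilibration assumption —
the source uses $[\mathrm{HCO_3^-}]_{in}$ without printing its
estimator). Gaussian measurement noise is added after integration.
Default bath: 24 mM bicarbonate at pH 7.4 (the standard assay solution);
default sampling 2 Hz, a realistic fluorometer rate.

What a green test does **not** establish: the generators have no water,
no electrostatics, no correlated ion motion, no protein flexibility, and
no dye photophysics; recovering 10 ns from the geometric law validates
the estimator arithmetic, not any claim about real transporter kinetics.
Real headline numbers (residence times of order 100 ns, occupancy
percentages, entry-event counts from μs trajectories; mutant flux
percentages from recordings) require the original data and are
explicitly out of reach at desk scale.

## Flux-side conventions and two formula decisions

The literal flux expression in the source procedure,
$(\beta_i + \beta_{\mathrm{HCO3}}) \times d[\mathrm{H}^+_{in}]/dt$, is
dimensionally inconsistent with β in mM per pH unit (it would yield
mM²/s). The package therefore defaults to the standard physiological
form $J = (\beta_i + \beta_{\mathrm{HCO3}})\, d\mathrm{pH}_i/dt$, which
produces the stated mM/s, and offers the literal variant via
`deriv = "H"` (with $[\mathrm{H}^+]$ in mM $= 10^{3-\mathrm{pH}}$). The
same decision applies to $\beta_i$ (default denominator
$|\Delta \mathrm{pH}_i|$). Sign convention: base influx raises pH$_i$,
so a positive initial slope is a positive base flux.

The initial rate is the OLS slope over a window after the switch;
default window 12.5 s, the midpoint of the conventional 10–15 s, and at
least 3 samples are required. `estimate_flux` evaluates
$\beta_{\mathrm{HCO3}}$ at the window-mean pH, which makes the noiseless
round trip accurate to well under 1% even though β drifts slightly as
pH$_i$ rises.

Calibration: with ≥ 2 calibration points an OLS ratio→pH line is fitted
(duplicate ratios are rejected as degenerate); with the usual single
high-K⁺/nigericin point, an offset mapping with a configurable reference
slope (default 0.5 pH per ratio unit, a typical in-situ BCECF slope) is
used — whether the original recordings assumed a slope is unstated, so
the slope is a visible parameter rather than a constant.

**Group statistics.** Percent-of-WT uses the delta method for a ratio of
independent means (checked against a 10⁴-replicate bootstrap within
10%). `compare_to_control` runs the classic one-way ANOVA F-test and
then Dunnett's many-to-one procedure: adjusted p-values are
$P(\max_i |T_i| \ge |t|)$ under the exact multivariate t distribution of
the contrasts, computed with `mvtnorm` (correlation
$\rho_{ij} = \lambda_i\lambda_j$,
$\lambda_i = [(1/n_0)/(1/n_i + 1/n_0)]^{1/2}$ induced by the shared
control mean and pooled variance). With a single comparison this reduces
exactly to the pooled two-sample t-test, which is asserted to 1e-6; with
k ≥ 2 the quasi-Monte Carlo integrator draws from R's RNG stream, so
results are reproducible under `set.seed`. Zero pooled variance is
rejected rather than producing infinite statistics. Flags are reported
at α and at the conventional 0.001 / 0.005 reporting thresholds.

## Numerical choices and degenerate inputs

- Frames and atoms are **1-based** everywhere, as in every R API; a
  0-based surface would be a standing trap for R users. Durations use
  the inclusive convention (end − start + 1)·Δt.
- Nearest-voxel binning uses `round()`; points farther than half a
  voxel beyond the lattice edge are out of extent and simply not
  counted (conservation is over in-extent points).
- `normalize_density` keeps its denominator so `denormalize_density`
  recovers integer counts exactly; probability normalization of an
  all-zero grid is rejected.
- Empty selections, unknown species tags, atom-count mismatches,
  truncated PDB records, non-stochastic transition matrices, and
  stability-contract violations are all rejected with messages naming
  the offender; the pipeline aborts with the failing stage's name.
- Text formats are the canonical fixture formats (PDB, multi-frame XYZ,
  OpenDX, CSV, JSON): XYZ coordinates carry 6 decimals (roundtrip well
  under 1e-3 Å), DX values 10 significant digits (roundtrip under 1e-6).
  Binary DCD is intentionally not supported.

## Known limitations

- Region geometry, the isovalue's units, and the bulk-occupancy
  estimator are package conventions standing in for unprinted details of
  the source analyses; all three are parameters, not constants.
- The Markov bulk state teleports (uniform resampling), so bulk-phase
  transport quantities (e.g. diffusion constants from the Markov
  generator) are meaningless by construction; use the Brownian generator
  for those.
- Contact analysis treats ions as points and residues as atom sets; no
  hydrogen-bond geometry, no per-atom maps.
- The flux generator models a single well-mixed compartment with
  instantaneous bath switches; no dye leakage, no NH₄⁺-pulse transient
  shape, no cell-to-cell heterogeneity.
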