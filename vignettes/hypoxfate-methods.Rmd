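---
title: "Modeling post-hypoxic invasion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling post-hypoxic invasion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoxfate)
```

`hypoxfate` simulates the fate mapping of hypoxia in a growing 2D tumor:
cells permanently switch from DsRed to GFP expression when their local
pO~2~ drops below a hypoxia threshold, may acquire an enhanced,
oxygen-gradient-directed migratory phenotype, and retain that phenotype
for a tunable time after reoxygenation. The package asks, in silico,
under which combinations of phenotypic persistence time ($T_p$),
migration bias ($b^*$) and responder fraction ($F_r$) post-hypoxic cells
form invasive "plumes" into oxygenated tumor regions and escape the
tumor bulk. This vignette documents the model, its numerical treatment,
the calibration machinery, and the design decisions a maintainer should
know about.

## The oxygen microenvironment

Oxygen is a single diffusing substrate on a regular mesh (default
20&nbsp;µm voxels) obeying

$$\partial_t \sigma = D \nabla^2 \sigma - \lambda(x)\,\sigma,$$

with $\sigma$ the pO~2~ in mmHg, $D = 10^5$ µm²/min, and
$\lambda(x)$ the sum of a background decay (0.1/min) and per-cell uptake
apportioned to the voxel containing each cell (cell cross-section over
voxel area). The far field is a Dirichlet condition $\bar\sigma = 45$
mmHg — the midpoint of the 43–46 mmHg range measured at the tumor
periphery — applied on the domain boundary, or on randomly placed source
voxels in the heterogeneous-vasculature scenario.

Two solvers are provided:

* `step_diffusion()` — an implicit operator-split transient step
  (implicit reaction, then Thomas-solved 1D sweeps). Each sub-operator
  is an M-matrix, so the step is unconditionally stable and satisfies
  the discrete maximum principle at any step size. Its *fixed point*,
  however, carries a splitting bias that grows with the step size, so it
  is used for transient studies only.
* `solve_steady()` — red-black successive over-relaxation on the true
  discrete steady state. Because oxygen equilibrates within seconds at
  these scales (diffusion time across a 100 µm rim is
  $\sim 0.1$ min) while the cell population changes over hours, the
  coupled engine treats the field as quasi-static: it re-solves the
  steady state once per 6-min phenotype step, warm-started from the
  previous field. This replaces fine transient substepping, which would
  dominate the run time without changing the field the cells see.

The per-cell uptake rate (5.5/min, necrotic cells at 10%) is the one
tuned constant of this module: it was fixed once so that the steady
radial profile across a 0.25-mm packed tumor disc spans the measured
range — the far-field 45 mmHg at the periphery down to ≈6 mmHg at the
viable/necrotic interface (`steady_tumor_profile()` reproduces this
calibration).

## Cell agents

Each cell carries a position, phenotype state (normoxic, hypoxic,
post-hypoxic, necrotic), a binary gene pair $G = (G_0, G_1)$, normalized
DsRed/GFP concentrations, a two-state Ki67 cycle, a persistence clock, a
responder flag, and motility parameters.

**Fate switch.** Crossing below $\sigma_H = 10$ mmHg (the
pathophysiological hypoxia level reported for breast tumors) sets
$G = (0, 1)$ permanently and draws the responder flag once per lineage
(Bernoulli $F_r$). Crossing below $\sigma_T = 5$ mmHg makes the cell
necrotic — an absorbing state; necrotic cells stop consuming at the full
rate, persist as mechanical obstacles for 24 hr, then lyse and are
removed.

**Fluorescence.** The reporter proteins follow
$$\frac{d[\mathrm{DsRed}]}{dt} = \alpha_0 G_0 (1 - [\mathrm{DsRed}]) - \beta_0 [\mathrm{DsRed}] (1 - G_0),$$
and symmetrically for GFP with $(\alpha_1, \beta_1, G_1)$. With binary
gene states each equation is linear, so `update_fluorescence()` applies
the exact exponential update — there is no integration error to tune.
All four rates default to 0.002/min (a ≈6 hr protein timescale), chosen
so the DsRed→GFP color transition completes well within a 5-day
observation window while perinecrotic cells remain visibly
double-positive — the underlying rates are known only to have been
calibrated against imaging data.

**Cycle.** The Ki67 two-state model: Ki67⁻ cells enter Ki67⁺ at rate
$r \cdot \min(\sigma/\bar\sigma, 1)$ (the oxygen scaling is stated only
qualitatively in the source material; linear scaling capped at the far
field is the simplest consistent choice), remain Ki67⁺ for a fixed
15.5 hr, then divide; the daughter inherits the gene pair, responder
flag, protein levels and motility preset. The base rate $r = 1/838$ min⁻¹
puts the steady Ki67⁺ fraction at 52.5% under full oxygen — the midpoint
of the observed 50–55% range — after correcting for the 6-min discrete step.

**Motility.** All viable cells perform a biased persistent random walk:
with probability $dt/\tau$ per mechanics step the direction is redrawn
as $\mathrm{normalize}((1-b)\,\xi + b\,\mathbf{d})$, with $\xi$ a
uniform random unit vector and $\mathbf{d}$ the normalized local oxygen
gradient. $b = 0$ is Brownian motion, $b = 1$ deterministic motion along
$\mathbf{d}$. Presets: DsRed-like cells $(s, b) = (0.28, 0.1791)$,
GFP non-responders $(0.38, 0.1718)$, GFP responders $(0.38, b^*)$, all
with $\tau = 15$ min. The two calibrated biases (0.1718 and
0.1791) are treated as the GFP-nonresponder and DsRed baselines
respectively and are both exposed in `phenotype_params()`. $\tau$ is
reused inside the tumor simulation since no separate value is stated.
After reoxygenation a GFP⁺ cell keeps its migratory preset until its
persistence clock reaches $T_p$ ($T_p = \infty$ never reverts; re-entry
into hypoxia resets the clock); on reversion both speed and bias drop to
the DsRed preset — whether non-responders keep the elevated speed after
$T_p$ is not specified, and reverting both is the conservative choice.

**Mechanics.** Quadratic overlap repulsion (coefficient 10 µm/min inside
the summed radius) and quadratic adhesion (0.4 µm/min inside 1.25× the
summed radius), velocities summed with the motility term and integrated
by forward Euler at 0.1-min steps; neighbor search uses a uniform grid.
A dimensionless per-cell pressure accumulates from repulsive overlaps,
normalized so one neighbor at the equilibrium spacing contributes 1 (a
hexagonally packed interior cell reads ≈6). With `pressure_feedback`
enabled (the heterogeneous-oxygen scenario), cells above pressure 10
do not divide and negate their bias direction — a migration stimulus
away from crowded regions.

**Time steps.** Phenotype/cycle/fluorescence at 6 min, mechanics at
0.1 min, oxygen quasi-static per phenotype step. Division placement is
one cell radius away in a uniform random direction.

## Calibration by likelihood-free MCMC

`lf_mcmc()` infers $(b, s)$ from an observed displacement series — the
per-timepoint mean distance from origin of a tracked cohort. The
sampler is the Metropolis variant of approximate Bayesian computation:
uniform priors $b, s \sim U(0, 1)$, a Gaussian random-walk proposal
(sd 0.05, 0.02) reflected at the prior bounds (reflection keeps the
proposal symmetric), and an indicator kernel that accepts a proposal
when a forward-simulated 100-cell cohort's mean series lies within
$\varepsilon$ of the observation in the $\ell_2$ norm. Chains default to
10,000 iterations with 1,000 burn-in and one forward draw per proposal.

The tolerance default is $\varepsilon = 0.06\,\lVert y_o \rVert_2$.
This value is deliberate: the $\ell_2$ distance between two independent
100-cell cohorts simulated at identical parameters is ≈6% of the series
norm, so this $\varepsilon$ sits at the forward-model sampling noise
floor. A substantially larger tolerance (e.g. 15%) saturates the kernel
over a broad ridge in $(b, s)$ — speed and bias trade off against each
other in the mean displacement — and the posterior mode is then not a
useful point estimate. At 6%, recovery runs on synthetic cohorts return
the generating bias within ±0.05 and speed within ±0.03 in the large
majority of seeded runs, which is the contract the test suite asserts.

`map_estimate()` reports the posterior mode. Because the ABC posterior
is a narrow, nearly-flat-topped anti-correlated ridge in $(b, s)$, any
joint-density mode (histogram or 2D kernel) wanders along the ridge
from chain to chain. The default estimator therefore mirrors the way
such posteriors are reported — one histogram per parameter: the bias is
the mode of its 1D kernel-density marginal, and the speed is the mode
of the conditional density over samples whose bias lies within a
proposal-scale window (0.05) of that value. In repeated recovery runs
this decomposition returns the generating bias within ±0.05 and speed
within ±0.03 in 9 of 10 seeded runs per parameter set, and its output
is stable under the chain seed alone. Joint 2D-kernel and plain
histogram modes (bin centers, ties toward the lower center, bias
varying fastest) remain available via `method`.
`posterior_predictive()` re-simulates at a point estimate and reports
the $\ell_2$ residual.

## The synthetic track cohorts

`generate_track_cohort()` replaces the spheroid tracking tables: cohorts
of cells (GFP-like: 69, DsRed-like: 74) sampled every 15 min for 16 hr
from a common origin (displacement statistics are translation-invariant,
so a common origin loses nothing). Per-cell heterogeneity is in speed
only — a Gaussian truncated at zero (re-draw) — because the tracking
figures report Gaussian fits of speed and displacement but nothing about
per-cell bias. The walk direction is held for exactly one sampling
interval (the persistence time of the emulated experiment equals the
sampling interval), so with zero speed spread the sampled step length is
exactly $s\,\Delta t$ and `cohort_statistics()` recovers the input speed
identically — a generator-honesty property the tests assert.

The generator's two bias defaults are its calibrated constants:
0.35163 (GFP-like) and 0.30436 (DsRed-like), fixed once by Monte-Carlo
root-finding so the seed-averaged mean per-cell maximum displacement
matches the measured values (111.11 and 68.34 µm). Bias is the right
knob: the mean maximum displacement is first-order insensitive to the
speed spread (the walk scales linearly with speed), so `speed_sd`
(0.10 / 0.08 µm/min) only shapes the distribution widths, which are not
reported. Note these generator biases are larger than the
ABC-calibrated agent biases: the maximum-displacement statistic demands
more drift than the mean-displacement series the calibration used, and
the two parameterizations serve different purposes — the generator
emulates measured summary statistics; the agent presets are the
calibrated motility model.

What the generator does *not* emulate: spheroid geometry and collagen
resistance, unlabeled carrier cells, tracking dropouts, and any per-cell
bias heterogeneity. Tests passing on these cohorts therefore validate
the pipeline's statistics and the calibrator's self-consistency, not the
biology of the original tracking data.

## The morphometric classifier

`classify()` renders a snapshot (viable cells as filled discs, GFP⁺ in
green, DsRed in red, necrotic in blue) at 3 µm/px — 1000×1000 px for the
3-mm domain — and applies three Boolean tests with thresholds
$\varepsilon_P = 30$ px, $\varepsilon_S = 20$ px², $\varepsilon_N =
0.06$, defined at that reference resolution and rescaled proportionally
for other resolutions:

* **Plume** — the largest connected green cluster (after a 5-px closing
  that fuses single-cell speckle and a 3-px opening that removes
  isolated specks) is contour-extracted; the contour is fit by a direct
  least-squares ellipse $E_G$ and smoothed by a periodic local mean in
  arc-length order ($F_G$); vertices subsampled every ~10 px along
  $F_G$ are tested, and a plume is declared when the largest
  vertex-to-ellipse distance exceeds $\varepsilon_P$. The smoothing is
  essential: without it, the ragged single-cell boundary of a perfectly
  annular GFP ring reads up to ~58 px and false-positives the test.
* **Escape** — an ellipse $E_T$ is fit to the densified convex hull of
  all tumor pixels; green connected components whose centroid lies
  outside $E_T$ contribute their full pixel area, and escape is declared
  when the sum exceeds $\varepsilon_S$. Areas are counted per component
  (centroid rule), not per pixel.
* **Necrotic core** — the necrotic pixel fraction of all labeled pixels,
  strictly greater than $\varepsilon_N$.

"Largest" uses area (not perimeter). Degenerate inputs: an empty green
channel yields `(FALSE, 0)` for plume and escape; an empty tumor is an
error; an ellipse fit that degenerates (collinear points) falls back to
a centroid/RMS-radius circle. Distances to the ellipse are computed
against a dense (1440-point) polygonal sampling of the outline, accurate
to well under a pixel at these sizes. The classification is
deterministic and, on the constructed fixtures, invariant under image
rotation within rasterization tolerance.

## Scenario orchestration and study scales

`run_scenario()` couples everything and is fully deterministic given the
config seed (all randomness flows through R's RNG, including inside the
compiled engine). `sweep()` crosses $(T_p, b^*, F_r)$ grids with
consecutive replicate seeds and classifies each end-time snapshot;
`replicate_stability()` counts positive classifications over seeded
replicates; `label_hypoxyprobe()` marks viable cells currently below
$\sigma_H$, separating hypoxic from post-hypoxic (GFP⁺/probe⁻) cells.

Problem sizes: the reference scenario is a 3-mm domain seeded with a
0.25-mm packed disc (≈880 cells) run to 130 hr (≈4,100 cells). The test
suite exercises the qualitative regime map — no plumes at $T_p = 0$;
plumes and escape at $T_p = 50$ hr, $b^* = 0.5$; escape without plumes
at $F_r = 1\%$ — on a 1.5-mm domain to 80 hr with three seeds, and runs
the 20-replicate stability protocol at that same reduced scale; the
full-scale 20-replicate study ships as
`scripts/stability_regression.R`. At both scales the reference
parameter point ($T_p = 50$ hr, $b^* = 0.5$, $F_r = 50\%$) classifies
plume-positive and escape-positive with no necrotic core.

## Known limitations

* 2D only; the cited 3D geometries (small spheroid, radial core) are out
  of scope.
* No HIF signaling network, ECM remodeling, angiogenesis dynamics, or
  leader–follower coupling; plumes here arise without cell–cell
  coordination.
* Cell volume is fixed (no growth/shrinkage phases); necrotic cells keep
  their radius until lysis.
* The pressure feedback is a binary rule at a single estimated threshold
  (10), not a calibrated mechanical model.
* The quasi-static oxygen treatment filters out sub-minute transients;
  scenarios with rapidly fluctuating sources would need the transient
  stepper at small steps.
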