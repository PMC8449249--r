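# hypoxfate

Agent-based simulation of post-hypoxic tumor-cell invasion with
fate-mapped fluorescence, in R.

Solid tumors develop oxygen gradients: cells near the necrotic core
experience hypoxia, and fate-mapping reporters (a permanent DsRed→GFP
switch triggered by low pO₂) show that formerly hypoxic cells later
appear in well-oxygenated regions as invasive "plumes" and even escape
the tumor bulk. `hypoxfate` is for computational biologists who want to
reproduce and probe that phenomenon in silico: it couples a 2D oxygen
reaction–diffusion field to cell agents with oxygen-dependent phenotype
switching, an oxygen-scaled Ki67 cycle, necrosis, adhesion–repulsion
mechanics, and biased persistent random-walk motility along ∇σ.

The model in brief:

* **Oxygen**: ∂σ/∂t = D∇²σ − λ(x)σ, far field σ̄ = 45 mmHg (Dirichlet),
  per-cell uptake; hypoxia below σ_H = 10 mmHg, necrosis below σ_T = 5 mmHg.
* **Fate switch**: gene pair G = (G₀, G₁) flips (1,0)→(0,1) permanently at
  first hypoxic exposure; reporter proteins follow
  d[DsRed]/dt = α₀G₀(1−[DsRed]) − β₀[DsRed](1−G₀) (and symmetrically GFP).
* **Motility**: direction re-drawn with probability dt/τ as
  normalize((1−b)ξ + b d), d = ∇σ/|∇σ|; presets (s, b) = (0.28, 0.1791)
  for DsRed-like cells, (0.38, 0.1718) for GFP non-responders, and
  (0.38, b*) for the responder fraction F_r, kept for a persistence time
  T_p after reoxygenation.
* **Calibration**: likelihood-free MCMC (ABC) recovers (b, s) from a
  cohort's mean displacement series with an ℓ₂ indicator kernel.
* **Classification**: Boolean morphometrics on rendered snapshots —
  plume (contour-to-ellipse distance > 30 px), cell escape
  (outside-ellipse green area > 20 px²), necrotic core
  (necrotic fraction > 0.06), at 3 µm/px.

## Worked example

Calibrate motility from a synthetic GFP-like cohort, then simulate a
tumor and classify the outcome:

```r
library(hypoxfate)

# synthetic tracking cohort (69 cells, 15-min sampling, 16 hr)
co <- generate_track_cohort(gfp_like_spec(seed = 1))
cohort_statistics(co)
#> cohort_stats: 69 cells
#>   mean speed 0.3927 um/min (sd 0.0899)
#>   mean max displacement 124.67 um (sd 47.08)

# infer (bias, speed) from a cohort generated at known parameters
set.seed(1)
tracks <- simulate_tracks(motility_params(tau = 15, s = 0.38, b = 0.1718),
                          n_cells = 100, duration = 900, sample_interval = 15)
post <- lf_mcmc(displacement_series(tracks), calibration_config(seed = 2))
post
#> abc_posterior: 9000 samples, acceptance 0.229, eps 21.18 um
#>   MAP: b = 0.1937, s = 0.3816 um/min

# coupled scenario: 50-hr persistence, bias 0.5, all responders
cfg <- scenario_config(domain_um = 1500, init_radius_um = 250,
                       Tp = 3000, b_star = 0.5, Fr = 1,
                       end_time_hr = 80, seed = 1)
res <- run_scenario(cfg)
classify_snapshot(final_snapshot(res), cfg$domain_um)
#> morphometric_report: plume=TRUE (d_max 126.7 px), escape=TRUE (A 525 px^2),
#>   necrotic_core=FALSE (F_N 0.000)
```

The recovered speed is within 0.002 µm/min of the generating value and
the bias within 0.022 — the mean-displacement series constrains speed
tightly while bias carries most of the posterior width (this single cohort's mean maximum displacement, 124.7 µm, also
sits a seed fluctuation above the 111.11 µm seed average the generator
is calibrated to). The scenario output says the final snapshot contains an invasive
GFP⁺ plume protruding ≈127 px (≈380 µm) beyond the fitted green
ellipse, escaped green cells totalling 525 px² outside the tumor
ellipse, and no necrotic core above the 6% area threshold. Setting
`Tp = 0` in the same config yields `plume=FALSE, escape=FALSE`: without
phenotypic persistence, post-hypoxic cells revert before traversing the
viable rim.

A thin CLI over the same functions lives at `inst/cli/hypoxfate-cli.R`
(subcommands `synth`, `calibrate`, `simulate`, `classify`, `stability`).

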