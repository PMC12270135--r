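# chemodrift

Tools for studying how *Escherichia coli* populations that lack short-term
chemotactic adaptation (ΔcheR strains and their experimentally evolved
descendants) move in attractant gradients. Such cells cannot perform the
canonical temporal comparison that receptor methylation provides; instead,
their tumbling bias — the fraction of time spent tumbling,
`TB = t_tumble / (t_run + t_tumble)` — is a direct function of the ambient
attractant concentration. The package is written for quantitative
microbiologists and biophysicists who want to simulate this behaviour,
analyse 2-D cell-tracking data the way the motility literature does, and fit
the accompanying pathway-activity (FRET) dose-response curves.

## What it implements

* **Run-and-tumble simulator** — agents in a 2 mm channel with solid side
  walls, open ends connected to reservoirs (absorb–respawn), and a linear
  MeAsp gradient along `+y`. Motility is a two-state Markov process with
  run→tumble rate `λ_RT = TB/(τ_T (1 − TB))` and tumble→run rate `1/τ_T`,
  so the stationary tumble-time fraction is exactly the model `TB`.
* **Response models** — homogeneous:
  `TB(L) = TB∞ + (TB0 − TB∞) K^H / (L^H + K^H)`; heterogeneous: each cell
  responds sharply (`H_c = 10`) at its own log-normal sensitivity `K_i`,
  with a distributed basal bias and a shared residual fraction. Fitting by
  nonlinear least squares (homogeneous) or decile-distance minimisation over
  the phenotype hyperparameters (heterogeneous), plus an hour-scale
  adaptation memory `m' = m + Δt (L − m)/τ_adapt`.
* **Trajectory analysis** — swimmer filtering (diffusivity > 0.61 µm²/s,
  duration ≥ 1 s), 10-frame sliding-window velocity fits, run/tumble
  segmentation by normalized ballisticity (threshold 0.785, with optional
  localisation-noise debiasing), tumbling bias, duration-weighted
  chemotactic drift `V_chem = Σ V_i T_i / Σ T_i`, chemotaxis bias
  (`V_chem` / run speed), directional run statistics (up/down classification
  at `π/4` and `3π/4`), and gradient-plate spreading-bias ratios.
* **FRET processing** — baseline correction and normalisation of YFP/CFP
  ratio traces, kinase-activity calibration between full-activation and
  full-inactivation levels, and Hill dose-response fits
  `A(L) = A0 (1 − (1 − ρ) L^H/(L^H + K_D^H))` with a residual-activity
  parameter `ρ` for strains whose pathway is not fully inhibited at
  saturating attractant.
* **Synthetic data generators** — tracking data at 50 frames/s with
  realistic localisation noise (0.35 µm ≈ half a pixel at 0.7 µm/px) and
  finite track durations, FRET step recordings, and dose/response tables,
  all with ground-truth sidecars and byte-level determinism under a seed.

A noteworthy property, derived and demonstrated in the methods vignette
(`vignettes/chemodrift-methods.Rmd`): because both response models map the
*current local* concentration onto the tumbling bias with no memory, the
uniform isotropic state of the channel is exactly stationary and the
simulated population drift is zero in any gradient — runs lengthen strongly
inside the gradient, but symmetrically. Reproducing a positive drift
requires a derivative-like response, which adaptation-deficient cells lack
by construction.

## Worked example

Simulate tracking data for a homogeneous ΔcheR-like responder in a
0 → 1 mM MeAsp gradient, then run the full tracking analysis:

```r
library(chemodrift)

model <- homogeneous_response(tb0 = 0.25, tb_inf = 0.05, K = 30, H = 1.5)
spec <- track_gen_spec(n = 200, model = model,
                       channel = gradient_channel(c_low = 0, c_high = 1000),
                       noise_sigma = 0.35, seed = 42)
g <- generate_tracks(spec)

res <- track_summary(g$tracks, frame_rate = 50)
print(res$summary)
#> Motility summary over 200 trajectories
#>   pooled tumbling bias = 0.0916
#>   mean run speed = 24.52 um/s

sprintf("V_chem = %.3f +/- %.3f um/s, chemotaxis bias = %.4f",
        res$drift$v_chem, res$drift$sem, res$drift$bias)
#> "V_chem = 0.391 +/- 1.081 um/s, chemotaxis bias = 0.0159"

g$truth$pooled_tumbling_bias
#> [1] 0.066
```

The pooled tumbling bias is low because most of the channel sits well above
the half-response concentration (30 µM), so cells tumble near their residual
bias; the recovered value (0.092) tracks the ground truth (0.066) within the
pipeline's stated ±0.05 accuracy at this noise level, and the drift is
statistically indistinguishable from zero, as expected for a memoryless
response. The analysis accepts any tracking CSV with columns
`traj_id, frame, x, y` via `read_trajectories()` (pixel or µm units).

The `analysis/` directory holds the full study workflow as numbered scripts:
`01_fit_response_models.R` (fit both response models to tumbling-bias data),
`02_simulate_drift.R` (population drift by gradient, model, and adaptation),
`03_track_analysis.R` (ground-truth recovery and directional run
statistics), `04_fret_dose_response.R` (FRET pipeline and Hill recovery).
Each writes its tables under `results/`.

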