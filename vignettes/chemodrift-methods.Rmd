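---
title: "Models and methods behind chemodrift"
author: "chemodrift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemodrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chemodrift)
```

## Scope

`chemodrift` implements the computational workflow used to study chemotaxis
of *Escherichia coli* strains that lack short-term adaptation (deletion of
the methyltransferase CheR): an agent-based run-and-tumble simulator in a
linear attractant gradient, concentration-to-tumbling-bias response models
(homogeneous and phenotypically heterogeneous) with an optional hour-scale
adaptation term, the trajectory-analysis statistics used on 2-D particle
tracking data (swimmer filtering, sliding-window velocity fits,
ballisticity-based run/tumble segmentation, tumbling bias, chemotactic drift,
directional run statistics, gradient-plate spreading bias), FRET ratio
processing with Hill dose-response fits, and synthetic-data generators that
stand in for the experimental videos so that every stage is testable against
ground truth.

## Motility model

A cell is either *running* (straight swimming at its phenotype speed
$v_i$, default 25 µm/s, while the heading diffuses rotationally with
$D_r = 0.15$ rad²/s) or *tumbling* (stationary reorientation). Switching is
a two-state Markov process with rates

$$\lambda_{RT} = \frac{TB}{\tau_T\,(1 - TB)}, \qquad
  \lambda_{TR} = \frac{1}{\tau_T},$$

where $TB$ is the tumbling bias prescribed by the response model at the
cell's effective concentration and $\tau_T = 0.2$ s is the mean tumble
duration. This parameterisation makes the stationary fraction of time spent
tumbling exactly $TB$ — the quantity the response models specify and the
tracking statistics measure — which the test suite verifies against the
two-state closed form (tolerance ±0.01). A fresh heading is drawn uniformly
at each tumble-to-run switch. Phenotypes with $TB \ge 1 - 10^{-6}$ are
rejected at construction: the run-to-tumble rate diverges there.

Time stepping is first-order Euler with $\Delta t = 0.02$ s (configurable,
constrained to $\Delta t \le \tau_T/5$), which matches the 50 frames/s
acquisition of the tracking experiments so that simulated frames map
one-to-one onto video frames. The concentration used for a step's switching
decision is sampled at the position reached during that step
(`sensing = "step_end"`); the start-of-step alternative is available, and
both give statistically identical ensembles at this step size (the
difference is a half-step sensing offset).

## Channel geometry and boundaries

The arena is a rectangle of 2000 µm (gradient axis, $+y$) by 1000 µm with a
linear concentration profile between `c_low` at $y=0$ and `c_high` at the
top. Side walls reflect specularly. The open ends represent infinite
reservoirs: an agent crossing $y<0$ or $y>L$ is absorbed and immediately
respawned at an end chosen uniformly at random, at uniform lateral position,
with a heading uniform over the inward half-circle. This conserves the
active-cell count (tested) and corresponds to reservoirs of equal density at
both ends. Each residency between entry and exit (or the 60-s cap `t_max`)
is recorded as one trajectory; the step that exits the channel is discarded,
so every recorded position lies inside the arena.

## Response models

**Homogeneous:** every cell follows the population curve
$$TB(L) = TB_\infty + (TB_0 - TB_\infty)\frac{K_r^{H_r}}{L^{H_r}+K_r^{H_r}},$$
a Hill decrease from the basal bias $TB_0$ to a residual bias $TB_\infty$
(adaptation-deficient cells keep tumbling even at saturating attractant).

**Heterogeneous:** individual cells respond sharply (cell-level Hill
exponent $H_c = 10$, a smooth stand-in for a step that keeps the model
differentiable) but at a cell-specific sensitivity $K_i$ drawn from a
log-normal distribution $(\mu_K, \sigma_K)$; basal biases $TB_{0,i}$ come
from a Beta distribution or an empirical sample, and a shared residual
fraction $\rho$ keeps $\rho\,TB_{0,i}$ of the bias at saturation. With
degenerate distributions the heterogeneous model collapses exactly to the
homogeneous formula (tested). The reference parameter set
(`r1_response_models()`) represents an evolved ΔcheR strain: basal bias
around 0.25 falling to about 0.05, half-response near 30 µM, a broad basal
distribution (Beta(1.2, 3.6)) and $\sigma_K = 1$ so that sensitivities span
roughly 4–220 µM.

**Fitting.** The homogeneous model is fitted to population-mean biases by
Levenberg–Marquardt nonlinear least squares with bound constraints. The
heterogeneous model is fitted by minimising the summed squared distance
between the nine deciles of the predicted and observed per-concentration
tumbling-bias distributions over $(\mu_K, \log\sigma_K,
\mathrm{logit}\,\rho, \log a, \log b)$ (Nelder–Mead); predicted deciles come
from a deterministic 64×64 quantile grid over the basal and sensitivity
distributions, which keeps the objective smooth. $H_c$ is held fixed: decile
data barely constrain it once cells respond much more sharply than the
population, and the drift predictions are insensitive to its exact value.
Flat data (no concentration dependence) is flagged unidentifiable rather
than fitted. Recovery tests: homogeneous parameters within 15% (median over
replicate data sets) at noise 0.01 on 8 concentrations; $(\mu_K, \sigma_K)$
within 20% from 500 cells per concentration at 9 concentrations.

## Hour-scale adaptation

The adaptation state is a concentration memory $m$ relaxing towards the
local concentration, $\dot m = (L - m)/\tau_{adapt}$, and the response model
sees the effective concentration $\max(L - m, 0)$. With
$\tau_{adapt} = 3600$ s — the timescale of the slow tumbling-bias recovery
observed for the evolved strain — $m$ barely moves within a 60-s residency,
so enabling it leaves the drift unchanged (tested at 3 combined SEM).

Cells are initialised *naive* ($m = 0$), representing cells freshly
introduced into the gradient, with `preadapted = TRUE` available to start
cells equilibrated to their local concentration. The choice matters: a
pre-adapted population responds only to concentration *changes* relative to
its entry point, and the rectification $\max(L-m,0)$ then acts as a
per-cell differential sensor that produces a strong artificial drift
(≈ 0.75 µm/s under the reference gradient). Because the hour-scale recovery
is explicitly too slow to contribute to gradient sensing, the naive
initialisation is the default.

## Why the memoryless model produces no drift

The central numerical finding of the drift analyses
(`analysis/02_simulate_drift.R`, recomputed by `scripts/acceptance.R`) is
that every gradient condition yields a population drift statistically
indistinguishable from zero. This is not a sampling accident but a property
of the model class. Both response models make the switching rates functions
of the *current position only*. For such kinetics the uniform, isotropic
state is exactly stationary: writing the 1-D analogue with right/left-moving
densities $p, q$ and a tumbling pool $T$,

$$\partial_t p = -v\,\partial_x p - \lambda(x)\,p + \tfrac{1}{2}\mu T,\quad
  \partial_t q = +v\,\partial_x q - \lambda(x)\,q + \tfrac{1}{2}\mu T,\quad
  \partial_t T = \lambda(x)(p+q) - \mu T,$$

the choice $p = q = \text{const}$, $T(x) = 2\lambda(x)p/\mu$ satisfies all
three equations with zero flux, and it matches the equal-density reservoir
boundary condition at the open ends. The same argument goes through in 2-D
with rotational diffusion and for concentration-dependent tumble durations
or swim speeds. A lagging response to the absolute concentration (any
single-exponential memory of the past) only biases the drift *against* the
gradient; genuinely positive drift requires a derivative-like response — the
temporal comparison that receptor-methylation adaptation provides in
wildtype cells and that the adaptation-deficient strain lacks by
construction.

What the gradient does produce in the model — and what the package's
directional run analysis shows — is a strong *symmetric* elongation of runs
inside the gradient (mean run duration several-fold above the plain-buffer
value, because the tumbling bias is low over most of the channel), with no
up/down asymmetry. The experimentally observed asymmetric elongation and the
accompanying drift of the evolved cells therefore require response
ingredients beyond a memoryless tumbling-bias map, such as the dynamics of
flagellar motor remodeling; within this package that conclusion is visible
as the red gradient-drift checks in the acceptance suite, which assert the
qualitative drift ordering at $N = 10^4$ trajectories and fail because all
drifts are compatible with zero.

## Trajectory analysis

All computation is in µm and s; pixel coordinates are converted at ingest
(0.7 µm/px default). Frame indices are 0-based and the gradient axis is
$+y$ throughout.

* **Swimmer filter:** trajectories shorter than 1 s are discarded; the rest
  are swimmers iff the time-averaged positional variance per unit time
  exceeds 0.61 µm²/s (just above the diffusivity of non-motile cells).
* **Local velocity:** least-squares linear fit on a centered 10-frame
  sliding window; the first/last half-window frames reuse the nearest full
  window, avoiding shrinking-window bias at track ends. An independent
  per-window `lm()` oracle confirms the windowed implementation to
  $10^{-10}$ relative.
* **Ballisticity segmentation:** frames are labeled run when
  $v_n = |v| / (f\,\Delta r) \ge 0.785$, where $\Delta r$ is the mean
  frame-to-frame displacement over the same window; $v_n = 1$ for straight
  constant-speed motion and drops at pauses and direction reversals. The
  published description of $v_r(t)$ is typeset ambiguously; the ratio
  reading is adopted here because it is the only one under which a
  "normalized threshold" of 0.785 is dimensionless and scale-free.
* **Localisation-noise correction (default on):** at the acquisition noise
  this package emulates (σ = 0.35 µm at 50 frames/s and 25 µm/s, i.e. noise
  comparable to the 0.5-µm true frame step), the raw ratio is biased far
  below 1 during genuine runs and the 0.785 threshold labels everything
  tumble. The per-trajectory noise variance $\hat\sigma^2$ is therefore
  estimated as the median across windows of the window-fit residual
  variance, $4\hat\sigma^2$ (the noise contribution to a squared frame step)
  is subtracted from each squared step, and the debiased steps are averaged
  over the window. Debiasing per step before averaging preserves the
  property that numerator and denominator degrade together at run/tumble
  boundaries, which is what makes the raw formula's boundary placement
  accurate; with noise-free input the correction vanishes identically.
* **Minimum tumble length:** detected tumble stretches shorter than 3 frames
  are relabeled run. The 10-frame window smears any resolvable pause or
  reorientation over at least ~5 labeled frames, so 1–2-frame tumble labels
  are threshold noise; removing them corrects the run-duration distribution
  without touching real events. Validated against generator ground truth:
  pooled tumbling bias recovered to ±0.002 and mean run durations to ~3% at
  the full acquisition noise (the acceptance checks allow ±0.05 and 10%).
* **Drift:** $V_{chem} = \sum_i V_i T_i / \sum_i T_i$ with $V_i$ the net
  $y$-displacement over duration; identical (to $10^{-10}$) to the
  simulator's internal estimator, and the chemotaxis bias is $V_{chem}$
  divided by the mean run speed over run frames.
* **Directional runs:** runs shorter than 5 frames are removed;
  $\alpha = \arccos(\Delta y / \|\Delta\|)$ classifies runs as up
  ($\alpha < \pi/4$), down ($\alpha > 3\pi/4$) or transverse, with strict
  inequalities so the measure-zero boundaries fall into transverse; runs
  with zero net displacement are transverse and flagged.
* **Spreading bias:** the ratio of colony-edge distances up versus down the
  plate gradient, aggregated over replicates with a one-sided t test
  against 1.

## FRET processing

The YFP/CFP ratio is baseline-corrected by fitting a polynomial (default
linear, order 0–2 configurable) to the unstimulated segments identified from
the stimulus annotations, dividing it out, and normalising the first point
to 1. Kinase activity is the linear rescaling anchored at two calibration
levels (full activation under nickel, full inactivation under saturating
attractant mix); the mapping is affine-invariant. Response amplitudes use
the mean of 5 pre-stimulus points and the extremal excursion within 30 s
after addition — the window is exposed because the published analysis leaves
it open. Dose-response curves are fitted with
$A(L) = A_0\,(1 - (1-\rho)\,L^H/(L^H + K_D^H))$, where the residual fraction
$\rho$ multiplies the Hill term so that $A(0) = A_0$ exactly and the
saturating asymptote is $A_0\rho$ ($\rho \equiv 0$ for the wildtype form);
initialisation is $A_0 = \max A$, $K_D$ at the geometric mid-dose, $H = 1$,
$\rho = \min A / \max A$, with box constraints. At noise σ = 0.03 on 8
log-spaced doses, median relative errors over 100 replicates are a few
percent for $A_0$ and $K_D$ and below 10% for $H$ and $\rho$.

## Synthetic data

`generate_tracks()` wraps the simulator at the acquisition frame rate,
truncates each cell's first residency to a duration drawn from an
exponential (mean 4 s) clipped to [1, 60] s — mimicking finite residence in
a field of view — and adds isotropic Gaussian localisation noise (default
0.35 µm, half a pixel). Ground truth (true positions, per-frame states, per
trajectory biases, true segments) is emitted alongside, and generation is
byte-deterministic given the seed. What the generator does *not* emulate:
detection and linking failures (broken or swapped tracks), intensity-
dependent localisation error, the 2-D projection of 3-D swimming, cell-size
effects, or cell–cell proximity artifacts. Passing the recovery tests
therefore shows the analysis is correct for clean tracking output at
realistic noise, not that it is robust to tracking pathologies.

`generate_fret_trace()` builds step-stimulus recordings on a ratio scale
with known calibration levels, multiplicative linear drift (so that a
linear baseline fit removes it exactly) and additive noise;
`generate_dose_response()` and `generate_tb_response()` produce replicate
tables for the recovery studies.

## Problem sizes

The test and acceptance runs use: $N = 10^4$ trajectories per gradient
condition (scaled from the study's $1.5\times10^4$) and $N = 5000$ for the
zero-gradient control, 60 s residencies at $\Delta t = 0.02$ s; 400
synthetic tracks for segmentation recovery; 100 replicate dose tables for
Hill recovery; 500 cells per concentration at 9 concentrations for the
heterogeneous response fit; and 11 replicate mean-bias data sets for the
homogeneous response fit.

## Known limitations

* The simulator is 2-D; measured tracks are 2-D projections of 3-D swimming,
  so absolute speeds and run-length statistics are not directly comparable
  to 3-D reality.
* Tumbles are zero-displacement with uniform reorientation; real tumble
  angles are forward-biased, which rescales effective diffusivity but (being
  position-independent) does not change the zero-drift property.
* The noise-corrected ballisticity assumes localisation noise that is
  homogeneous within a trajectory; strongly intensity-dependent noise would
  bias $\hat\sigma^2$.
* The heterogeneous fit holds the cell-level sharpness fixed and assumes a
  log-normal sensitivity distribution and Beta basal distribution; these are
  parsimonious choices, not inferences.
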