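---
title: "Predicting ground reaction forces from shoe-sole sensors: models and methods"
author: "soleGRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ground reaction forces from shoe-sole sensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soleGRF)
```

## The problem

A force plate measures the three-directional ground reaction force (GRF) —
mediolateral $F_x$, anteroposterior $F_y$, vertical $F_z$ — with laboratory
accuracy, but only inside a laboratory. An instrumented shoe with four small
triaxial force sensors (heel, first metatarsal, fifth metatarsal, toe)
produces twelve force channels $f_{x1..4}, f_{y1..4}, f_{z1..4}$ anywhere.
soleGRF implements the full analysis chain that learns the mapping from the
twelve sensor channels to the three GRF components and quantifies how well
it generalizes across steps, for three gait movements: straight walking,
side-step turning and cross-step turning (turns change heading by roughly
20 degrees and mirror each other's mediolateral force signature).

Because the raw recordings of such a study are not publicly deposited, the
package ships a synthetic gait generator that emulates the recordings'
statistical structure; every stage downstream of the generator treats its
output exactly as it would treat measured data.

## The synthetic gait generator

`generateDataset()` draws, per participant, a body mass from
$\mathcal N(58.0, 5.4^2)$ kg truncated to $[40, 90]$, per-direction
amplitude scales (SD 0.07 between participants, 0.04 between steps), and
per-movement mediolateral shape effects (below). Each trial samples smooth
waveform templates on the three native clocks — sensors at 870 Hz, force
plate at 1000 Hz, heel/toe markers at 200 Hz — with a stance duration of
0.65 s jittered ±10 %, padded by ≥0.15 s of strictly sub-threshold baseline
noise on each side.

The waveform model (`grfTemplate()`) expresses each component in body
weights as sums of Gaussian bumps over the stance fraction $s \in [0,1]$,
tapered to zero over the first and last 3 % of stance:

* vertical: bumps of height 1.1 at $s = 0.25$ and $0.75$ (SD 0.16) minus a
  valley bump of 0.4 at mid-stance (SD 0.12), clipped at zero — a
  double-peaked curve with peaks near 1.07 BW and a valley near 0.25 BW.
  The main-bump width matters: much narrower bumps would drive the
  mid-stance force to zero, splitting the stance into two supra-threshold
  runs and making threshold-based stance detection ill-posed, so the width
  is chosen to keep a single positive-valley stance;
* anteroposterior: a braking/propulsion couple, $-$bump at $s=0.22$ and
  $+$bump at $s=0.80$ (SD 0.10), amplitude 0.20 BW;
* mediolateral: a base bump of 0.06 BW at $s=0.35$ plus a turn bump of
  0.08 BW at $s=0.55$ whose sign distinguishes side-step from cross-step
  turns.

`sensorProjection()` distributes $F_z$ over the four sites through
raised-cosine activation windows that sum to one at every $s$ (heel peaked
early, metatarsals mid-stance, toe late), and derives shear channels from
smooth site-specific shear-to-vertical ratio curves plus half of the shear
GRF shared across the windows. With noise off, the twelve channels
determine the GRF exactly (the vertical channels sum to $F_z$ identically);
this invertibility is what makes the regression stages meaningful.
Measurement noise is Gaussian per channel with SD equal to 2 % of that
channel's full-step range, applied to sensor and plate channels alike.

### Calibrating mediolateral variability

Reported gait studies show the mediolateral GRF to be the most variable
component, most of all in cross-step turning. Purely multiplicative
amplitude scaling cannot reproduce the reported pattern — straight walking
has the smallest mediolateral amplitude yet a between-participant SD
comparable to side-step turning — so the generator adds additive
mediolateral shape perturbations: a smooth unit bump scaled by a
per-participant coefficient (SD 0.148 / 0.151 / 0.221 N kg⁻¹ for
straight / side-step / cross-step) and a per-step coefficient (SD 0.089 /
0.121 / 0.183 N kg⁻¹). The bump is normalized so a coefficient of
$c$ N kg⁻¹ contributes exactly $c$ to the stance-averaged $|F_x|/m$
deviation, which makes the configured SDs directly comparable to the
between/within-participant SDs computed by `variabilitySummary()`. These
defaults were fixed when the generator was designed and are ordinary
configuration fields.

What the generator does *not* emulate: sensor saturation and hysteresis,
shoe deformation, double-support force sharing, marker noise or dropped
frames, inter-device clock offsets (available as a padding option but off
by default, since device synchronization is conventionally handled
upstream). Passing tests therefore demonstrate correctness of the analysis
chain and achievability of the accuracy bounds under clean, well-specified
conditions — not performance on any particular hardware.

## Preprocessing

`normalizeStep()` applies, in order:

1. a fourth-order Butterworth low-pass at 50 Hz, forward–backward for zero
   phase (offline gait analysis conventionally avoids filter lag between
   streams; the padding uses odd-symmetric reflection long enough —
   10 cycles of the cutoff — to absorb the startup transient);
2. stance detection as the *longest contiguous run* of samples at or above
   the stream's threshold: 15 N on the summed vertical sensor channels,
   50 N on the plate's vertical component. Equal-length competing runs
   reject the trial as ambiguous;
3. heading estimation: the signed planar angle $\varphi$ between the mean
   toe-minus-heel marker vector over the plate stance window and the
   walkway axis, then the rotation
   $[F_x, F_y, F_z]^T = R(\varphi)\,[F_X, F_Y, F_Z]^T$ into the shoe frame
   ($F_z$ unchanged). $\varphi$ is one scalar per trial; markers are used
   unfiltered;
4. resampling of every channel onto 101 equally spaced points (0–100 % of
   stance) by linear interpolation (cubic splines behind a switch), each
   stream normalized to *its own* stance window — alignment is by stance
   fraction, not wall clock, because the two devices cross their
   thresholds at slightly different instants.

Two consequences of the two-threshold design are worth stating. First, the
detected stance is the supra-threshold portion, so the first/last resampled
rows sit at the 15 N / 50 N crossings rather than at exactly zero force;
fidelity checks against the generator templates therefore evaluate the
template at the detected window's wall-clock times. Under noise-free
conditions the recovered shoe-frame GRFs then agree with the templates to
about 0.2 % relative RMS (the tests assert < 2 %). Second, the summed
vertical sensor channels and the plate's vertical GRF sit on slightly
different stance clocks: they agree within about 2 % of peak on the stance
interior, but differ by construction at the edge rows (15 N vs 50 N).

## Regression models

Both models treat each of the 101 stance rows as one observation of
(12 features → 3 targets) and each GRF direction independently.

**Stepwise multiple linear regression.** `fitMLR()` runs classical
forward–backward stepwise selection on partial-$F$ p-values (enter below
0.05, remove above 0.10 — the de-facto defaults of the toolbox family such
analyses typically use; both config-exposed), then ordinary least squares
via QR on the selected columns. The intercept is always included and never
a removal candidate; ties break toward the lower column index; a visited-
subset guard enforces termination. Exact fits (zero residual) are handled
explicitly so that selection is invariant to uniform replication of the
data.

**Gaussian process regression.** `fitGPR()` implements an exact GP with
constant basis $H = \mathbf 1$ and the isotropic squared-exponential
kernel $k(f_i, f_j) = \sigma_f^2 \exp(-\tfrac12 \lVert f_i - f_j\rVert^2 /
\sigma_l^2)$:

* features are standardized per column and the response centered (recorded
  in the model and undone at prediction);
* the basis coefficient is profiled out by generalized least squares,
  $\hat\beta = (H^T K_\sigma^{-1} H)^{-1} H^T K_\sigma^{-1} F$ with
  $K_\sigma = K + \sigma^2 I$, computed through the Cholesky factor;
* $(\log\sigma_f, \log\sigma_l, \log\sigma_n)$ jointly maximize the log
  marginal likelihood with analytic gradients (L-BFGS-B, box
  $[-12, 12]$, 60 iterations by default). The envelope theorem makes the
  profiled-$\beta$ gradient identical to the fixed-$\beta$ gradient, so no
  extra term is needed. Initialization: $\sigma_l$ = mean pairwise distance
  of a ≤500-row feature subsample, $\sigma_f$ = response SD, $\sigma^2$ =
  10 % of response variance. On standardized features this start is close
  enough that random restarts are off by default (`nRestarts` adds
  seed-derived perturbed starts);
* the Cholesky of $K_\sigma$ uses adaptive jitter: starting at
  $10^{-10}$ of the mean diagonal, escalating tenfold to at most
  $10^{-4}$, then failing loudly;
* prediction returns $\mu = k_*^T K_\sigma^{-1}(F - H\beta) + \beta$ and
  predictive variance $\mathrm{diag}(k_{**} - k_*^T K_\sigma^{-1} k_*) +
  \sigma^2$ (the observation-noise term is included because prediction
  bands are compared against noisy measured curves; latent-only bands via
  `includeNoise = FALSE`). Tiny negative variances (below numerical noise)
  clip to a floor; anything below $-10^{-8}$ raises an error.

Exactness is enforced in the tests against dense-inverse oracles (posterior
mean, covariance and log marginal likelihood to $10^{-8}$) and against an
independent reference GP implementation on matched parametrizations.

Training cost is cubic in rows, so `fitGPR()` caps the training set
(default 600 rows) by deterministic evenly spaced subsampling of the
stacked step blocks, which stratifies across both steps and stance
percents. At the package's default problem sizes this keeps a full
leave-one-step-out experiment within a few minutes on one CPU while
leaving accuracy unchanged for these smooth, highly redundant curves.

## Evaluation protocol

`loocv()` leaves one *step* out at a time — all 101 rows of a step leave
together, since leaving single rows out would leak the step's neighboring
samples — and refits everything (stepwise selection, GP hyperparameters)
on the remaining steps. Metrics per held-out step and direction:

* MAE on body-mass-normalized forces, N kg⁻¹;
* %RMSE: RMSE divided by the measured step's max-minus-min range, ×100
  (15 % is the field's practical-accuracy criterion);
* adjusted $R^2$ with $n = 101$ and $k$ = the fold's selected predictor
  count for MLR, $k = 12$ for GPR (all twelve channels enter the kernel;
  config-exposed). Negative values are legal and preserved.

Metrics are computed per fold and then averaged (mean ± sample SD, $n-1$
denominator) by `summarizeFolds()`, per movement or pooled across
movements — not pooled into one long curve before computing metrics.
`variabilitySummary()` computes the between-participant SD (SD across
participant-mean curves, averaged over the 101 stance percents) and
within-participant SD (SD across a participant's steps, averaged over
participants and percents) of mass-normalized GRFs.

## Default problem sizes and reproducibility

The default experiment simulates 3 participants × 4 steps × 3 movements
(36 steps; 12 per movement model, 36 for the pooled model) — a desk-scale
version of the 8 × 10 × 3 protocol such studies use. Generator seeds are
derived deterministically from the master seed by (participant, movement,
step) index, so `runExperiment()` is a pure function of its configuration;
rerunning a config byte-identically reproduces every result file, and each
output carries the configuration hash. The multi-seed model-ordering
checks (GPR vs MLR; per-movement vs pooled mediolateral accuracy) use
3 × 3 × 3 datasets over five master seeds; the generator-calibration check
uses the full 8 × 10 scale once.

## Known limitations

* The accuracy figures certify the pipeline on its own synthetic
  emulation; transfer to physical sensors depends on effects the generator
  deliberately omits (see above).
* The GP uses one isotropic length scale (no automatic relevance
  determination) and a constant basis, matching the printed model of the
  analyses it reimplements.
* Stance detection assumes a single stance per recording; trials with
  equal-length competing supra-threshold runs are rejected, not repaired.
* The mediolateral shape calibration targets the *reported* SD pattern;
  it is a statistical emulation, not a biomechanical model of turning.
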