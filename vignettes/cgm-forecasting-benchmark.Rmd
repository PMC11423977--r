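---
title: "Benchmarking deep sequence models for blood glucose forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking deep sequence models for blood glucose forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A continuous glucose monitor (CGM) samples interstitial glucose roughly
every 5 minutes. Forecasting the blood glucose level (BGL) 30 or 60 minutes
ahead from the recent history alone gives patients and closed-loop insulin
systems time to act before hypo- or hyperglycemia develops. Formally, given
the history $(G_t, G_{t-1}, \dots, G_{t-L})$ on a 5-minute grid and a
prediction horizon $p$, a model $M$ produces
$\hat G_{t+p} = M(G_t, \dots, G_{t-L})$. This package benchmarks five deep
architectures for that task — a per-timestep feed-forward network (FFN), a
1-d convolutional network (CNN), a temporal convolutional network (TCN), a
two-layer LSTM, and a transformer-style self-attention network (SAN) —
under a single shared protocol: identical preprocessing, identical
optimization rules, analytical and clinical evaluation, and an explicit
cross-cohort generalization analysis.

Real multi-cohort CGM datasets are access-restricted, so the package ships
a synthetic cohort simulator whose output has the statistical structure the
analysis depends on. Every stage is exercised end-to-end on simulated
cohorts; nothing requires restricted data.

## The synthetic cohort generator

`simulate_trace()` composes five ingredients, in a fixed draw order so that
a `(profile, seed)` pair is perfectly reproducible:

1. **Mean-reverting baseline.** A discrete AR(1) process on the 5-minute
   grid, $d_{t} = \phi\, d_{t-1} + \varepsilon_t$ with $\phi = 0.98$
   (a correlation time of roughly four hours) and innovation variance
   chosen so the stationary spread equals the profile's `basal_sd`. The
   trace is `basal_mean` + $d_t$. CGM-like smoothness and autocorrelation
   are the point; no claim of physiological insulin–glucose kinetics is
   made, and carbohydrate/insulin event channels are deliberately out of
   scope (the benchmark is CGM-only).
2. **Meal-like excursions.** Poisson-timed events (default 3/day), each a
   smooth $\sin^2$ bump of 30–150 mg/dL over 1–3 h.
3. **Sustained hyperglycemic episodes.** Poisson-timed plateaus (default
   2–3.5/week) at 330–390 mg/dL lasting 2.5–6 h with raised-cosine ramps.
   Together with clipping to the sensor range $[40, 400]$ these produce
   the minor high-glucose mode seen in real cohort densities; the dominant
   mode stays in 100–200 mg/dL. The plateau level is kept below the
   400 mg/dL clip because a density peak at the sensor ceiling is best
   read as saturation; the episode rate is an explicit profile field
   rather than a hard-coded claim about how much mass belongs up there.
4. **Sensor noise and clipping.** Additive Gaussian noise (default
   5–6 mg/dL), then clipping to $[40, 400]$.
5. **Missingness.** Per-sample Bernoulli dropouts (default probability
   0.01) and Poisson-timed long outages of 65–240 minutes (default 1/week),
   i.e. both kinds of gap the preprocessing stage must handle.

A closed-loop profile halves `basal_sd` and the hyperglycemic episode rate,
reproducing the tighter, more consistent distributions of cohorts under
automated insulin delivery. Per-patient seeds derive from the cohort master
seed by a fixed splitting rule, so enlarging a cohort never reshuffles
existing patients. Sex and age-group labels are drawn per patient from the
profile's mixing proportions.

`default_profiles("full")` mirrors the four-cohort structure of the
motivating study designs (a small adult cohort with the broadest
distribution, two closed-loop cohorts, and a large all-ages cohort);
`default_profiles("mini")` is the desk-scale version (two cohorts, 8
patients, 2 weeks) used by the examples, tests and the acceptance script.

**What passing tests do and do not show.** The simulator reproduces the
*distributional* features the pipeline depends on (bimodality, mass
placement, closed-loop variance reduction, gap structure, autocorrelated
dynamics). It does not reproduce circadian structure, meal timing patterns,
sensor drift/recalibration artifacts, or inter-patient heterogeneity beyond
the profile fields — so green tests validate the machinery and protocol,
not clinical performance claims on real cohorts.

## Preprocessing

`align_to_grid()` snaps each observed sample to the nearest slot of a
5-minute grid anchored at the first timestamp (ties toward the earlier
slot — the alignment rule has to be fixed somewhere, and earlier-slot
ties keep the map idempotent on gridded input). `impute_and_segment()`
linearly interpolates missing runs of up to 60 minutes and *splits* the
series at longer runs, fabricating nothing inside a long gap; a run of
exactly 60 minutes is still interpolated ("over an hour" read strictly),
and leading/trailing missing slots are dropped.

Normalization is the z-score $Z_t = (G_t - \mu)/\sigma$ with $\mu, \sigma$
pooled over **all training segments of the cohort** (not per patient) and
applied unchanged to validation and test data. The standard deviation uses
the population (divide-by-$n$) convention, fixed once so that the
normalize/de-normalize round trip is exact to numerical precision.

`split_cohort()` resolves a genuine tension between two reasonable
protocols — chronological splitting and patient-level separation — by
using both where each is defendable: the outer train/test split is
patient-level (no test patient ever contributes training windows), while
validation is the chronologically last 20% of each training patient's
data. An `ohio_mode` honors externally predefined per-patient
train/test partitions, with validation still carved chronologically from
the training part.

`make_windows()` emits, for a segment of length $N$, history $L$ and
horizon $p$, exactly $\max(0, N - L - p + 1)$ supervised pairs; windows
never cross segment boundaries. The benchmark default is $L = 24$ steps
(2 h) with horizons of 6 and 12 steps (30 and 60 min), and one
single-output model is trained per horizon — the parameter accounting of
the reference configurations is only consistent with single-output heads,
so a two-headed variant was rejected.

## The five architectures

All five consume a normalized window of shape $(L, 1)$ and emit one
scalar. Configurations are the benchmark's grid-search optima and are
frozen in `model_spec()`; dropout is 0 in every optimal configuration, so
stochastic regularization is not implemented (a nonzero rate is rejected
loudly rather than silently ignored).

* **FFN** — the affine stack 1→32→64→1 applied per timestep with
  rectified-linear activations, forecast read off the final timestep
  (2241 parameters). Since timesteps do not interact, the forward pass
  evaluates the stack at the last step only; the analytic FLOP count still
  charges all $L$ applications.
* **CNN** — two valid 1-d convolutions (kernel 3; 32 then 64 channels)
  with a width-2 max pool between them, global average pooling over time,
  and a 64→32→1 head. Kernel size and pooling are not pinned down by the
  reference parameter counts, so kernel 3 was chosen and the CNN/TCN
  counts are reported but not asserted.
* **TCN** — four residual blocks of causal dilated convolutions (kernel 3,
  channels 16/32/64/64, dilations 1/2/4/8, two convolutions per block, 1×1
  projection on the residual path when channels change) and a 64→1 head on
  the final position. Causality — no leakage past the boundary — is
  property-tested.
* **LSTM** — two stacked layers of 30 hidden units with separate
  input-side and recurrent-side bias vectors per gate, plus a 30→1 head.
  The dual-bias convention is forced by the reference count of 11431
  trainable parameters (a single-bias cell gives 11191); gate
  nonlinearities are the standard sigmoid/tanh.
* **SAN** — affine input projection to width 128, parameter-free
  sinusoidal position encoding, three pre-norm encoder blocks (4 heads,
  fused query/key/value projection, feed-forward 128→512→128, two layer
  normalizations per block), a final layer normalization and a 128→1 head
  on the last position: 595457 parameters, the unique combination matching
  the quoted widths.

Forward and backward passes are written in R against a small set of layer
primitives; every architecture's analytic gradient is checked against
central finite differences in the test suite. The stacked LSTM — the only
architecture trained at scale inside the tests — additionally has a fused
C++ (RcppArmadillo) kernel computing forward, RMSE loss and all gradients
in one call; the test suite asserts bit-level agreement between the fused
and layer-by-layer paths.

`estimate_flops()` counts $2\times$ multiply–accumulates per inference
with convolutions charged one kernel application per timestep
(padded-length convention, so sequence cost is linear in $L$); pooling,
activations and normalizations are free. Published FLOP figures for these
architectures are not reproducible without knowing the measurement tool's
conventions, so no external FLOP value is asserted anywhere.

## Training protocol

`train_model()` minimizes per-batch RMSE on normalized targets with Adam
(moments 0.9/0.999 — framework defaults, since the protocol does not state
them), for up to 100 epochs: per-epoch training loss is the mean of batch
RMSEs, validation RMSE is computed after every epoch, the learning rate
decays by 0.1 after 10 epochs without strict improvement, training stops
after 30 epochs without improvement, and the returned checkpoint is the
parameters achieving the lowest validation RMSE. Decay and stopping
counters run independently and both reset on any strict improvement — the
protocol leaves simultaneous-trigger behavior open, and independent
counters are the simplest rule that honors both patience values.
Optimal learning rates are architecture-specific (FFN 0.01, others 0.001);
optimal batch sizes are cohort-family-specific (small Ohio-like cohorts 16,
large RT-like 512, closed-loop DCLP-like 1024, with CNN/TCN always 16).
`repeat_runs()` executes five seeded repetitions (seeds
`base_seed + 0..4`) and reports mean ± sd per metric.

## Evaluation

`evaluate_metrics()` implements RMSE, MAD, the coefficient of
determination, FIT (percent RMSE improvement over the mean predictor;
algebraically $FIT = (1-\sqrt{1-COD}) \times 100$, an identity the tests
assert to $10^{-9}$) and MADP (mean absolute percentage deviation, defined
only for strictly positive references — enforced as a precondition, since
CGM-range data cannot legitimately contain nonpositive values).

`clarke_zone()` uses the canonical published Clarke Error Grid boundary
inequalities, with boundary ties resolved by the fixed evaluation order
A → E → C → D → B. The implementation is frozen against a 25-point labeled
fixture (5 points per zone, several on boundaries) and checked for
totality/exclusivity over the whole 1-mg/dL lattice of $(0, 400]^2$.
`ceg_analysis()` merges zones into clinically safe (A+B) and unsafe
(C+D+E) fractions; per-repetition pooling is the default aggregation. A
`clamp` option projects raw model outputs onto the sensor range before
classification, since the grid is defined on sensor-range values.

## Generalization analysis

`cross_evaluate()` builds the train-cohort × test-cohort matrix: each
trained model is evaluated on every cohort's test set, with test data
standardized by **its own cohort's training parameters** (models consume
z-scores; the normalization travels with the data, not with the model —
the protocol leaves this open and this choice keeps a foreign model's
input distribution in-range). Each cell reports RMSE and a two-sample
Kolmogorov–Smirnov p-value comparing the cell's residuals against the
residuals of the row's test cohort under its own model; the diagonal is a
self-comparison and reports p = 1 by convention. Which residual pair the
off-diagonal p-values compare is the one genuinely ambiguous point of the
protocol; comparing against the same-test-cohort diagonal residuals is the
reading consistent with the diagonal printing p = 1.

`ks_two_sample()` delegates to the standard exact/asymptotic two-sample
Kolmogorov–Smirnov machinery (exact enumeration when $nm \le 10{,}000$,
asymptotic otherwise), with the exact branch verified against brute-force
enumeration over all $\binom{n+m}{n}$ orderings for all $n, m \le 6$.
Significance is read at 0.05, uncorrected — the protocol applies no
multiple-testing correction across matrix cells, and none is added
silently.

One numerical caveat is made explicit rather than hidden: residuals of
densely overlapping windows are strongly autocorrelated, and the KS test
assumes independent samples, so p-values on full residual vectors are
anti-conservative. `residuals_of()` therefore takes a subsampling
`stride`; the distributional tests in this package use a stride of 40
windows (about 3.3 h), beyond the baseline's correlation time, when
checking null calibration. The default stride is 1 (the plain protocol).

`demographic_slices()` evaluates the full test set (FM) and its female (F)
and male (M) subsets, reporting three RMSEs and three pairwise KS
p-values; the sum-of-squares identity
$RMSE_{FM}^2 = (n_F RMSE_F^2 + n_M RMSE_M^2)/N$ is asserted to $10^{-9}$.
Only the computational protocol is reproduced here; conclusions about
demographic bias depend on real-data composition and are out of scope.

## Orchestration and problem sizes

`run_experiment()` chains simulate → preprocess → train (repetitions) →
metrics/CEG → generalization and writes CSV report tables shaped like the
benchmark's summary tables plus a JSON manifest; reruns with the same
config and master seed are bit-identical. The package's own desk-scale
choices: examples and tests run two 8-patient, 2-week cohorts with reduced
epoch budgets (2–25 epochs depending on the check), which keeps the full
suite and the acceptance script in the minutes range on one CPU while
exercising every stage; the benchmark-faithful protocol (four full-size
cohorts, 100 epochs, 5 repetitions) is expressed by exactly the same
functions with `default_profiles("full")` and a default `train_config()`.
The learning-sanity check trains the LSTM for 25 epochs on the mini
closed-loop cohort over three seeds and requires it to beat the
persistence (last-observed-value) baseline — a deliberately strong naive
competitor at 30-minute horizons — in at least two of three seeds.

## Known limitations

* The simulator is distribution-matched, not physiology-based; transfer of
  benchmark rankings to real cohorts is not claimed.
* CNN/TCN reference parameter counts are unverifiable from published
  information (kernel/pooling details unstated) and are therefore not
  asserted; published FLOPs and wall-clock complexity figures are not
  emulated.
* Training is single-threaded CPU; no GPU path, warmup or gradient
  clipping (none are part of the protocol).
* Nonzero dropout is rejected rather than implemented, as every optimal
  configuration uses 0.
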