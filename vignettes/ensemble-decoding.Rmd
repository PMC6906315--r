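---
title: "Decoding ensemble orientation coding: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding ensemble orientation coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enscode)
```

# The scientific problem

Displays of many oriented bars can be remembered either as individual
items or as a summary — the ensemble mean orientation. `enscode`
implements the analysis machinery to ask whether EEG signals during a
working-memory retention interval carry that summary: an inverted
encoding model (IEM) reconstructs orientation information; temporal
generalization (TG) asks whether the code is one stationary pattern
("stable") or a cascade of time-specific patterns ("dynamic");
cross-condition generalization from single-orientation (SO) displays to
varied-orientation (VO) displays tests whether the never-shown ensemble
mean is represented; and the behavioral models quantify each
participant's reliance on the ensemble.

# The encoding model

Orientation is 180°-periodic; all angles in the package live in
[-90, 90) degrees. Eight channels are centered on the eight stimulus
orientations (-78.75° to 78.75°, 22.5° apart) and respond with
$R = \cos^7(\Delta)$, where $\Delta$ is the wrapped offset from the
channel center in [-90, 90]. With the basis matrix $C$ (channels ×
observations) and signals $B$ (electrodes × observations, per time
point), the forward model is $B = WC$. Training solves
$\hat W = B_1 C_1^\top (C_1 C_1^\top)^{-1}$; testing inverts it as
$\hat C_2 = (\hat W^\top \hat W)^{-1} \hat W^\top B_2$.

Cross-validation uses random partitions into 3 folds, equalized so each
orientation contributes the same trial count per fold (the remainder is
discarded at random); trials are averaged per fold × orientation before
fitting. The whole procedure repeats over (by default) 100 random
partitions and slopes are averaged.

Reconstructions are baseline-corrected (channel mean removed per
observation), circularly shifted so each orientation's own channel sits
at 0° offset, averaged over the eight orientations, and summarized by
the OLS slope of the eight responses on the folded offset axis
(-90, -67.5, -67.5, -45, -45, -22.5, -22.5, 0). All four steps are
linear maps, so internally the per-time-point slope is computed as one
fixed linear functional of the raw 8×8 reconstruction; the tests verify
that this equals the explicitly composed path. The slope's units are
response per degree; a perfect $\cos^7$ reconstruction gives
`r round(ctf_slope(align_and_average(design_matrix(stimulus_orientations()))), 5)`.

**Channel grid reading.** The source methods list the channel angles as
-90° … 67.5° while the stimuli sit at -78.75° … 78.75°. We place the
channel centers *at the stimulus orientations* and read the -90…67.5
grid as the aligned offset axis, so that a trial's orientation
corresponds exactly to the peak of its basis profile. This makes the
noiseless closed loop exact; the alternative (channels offset by
11.25°) would merely shift all profiles by half a grid step.

# Temporal generalization and the stable/dynamic index

TG trains $\hat W$ at time $t_1$ and tests at $t_2$; folds and
iterations are shared across the whole matrix so the diagonal equals the
per-time-point IEM. For each off-diagonal cell, three one-sided
hypotheses are tested across subjects:

* H1: TG(t1,t2) < TG(t1,t1)
* H2: TG(t1,t2) < TG(t2,t2)
* H3: TG(t1,t2) > 0

with *dynamic = H1 ∧ H2* and *stable = ¬H1 ∧ ¬H2 ∧ H3* (mutually
exclusive by construction). The stable (dynamic) index at time $t$ is
the proportion of stable (dynamic) cells within a 310 ms square window
centered on $(t,t)$, excluding cells within ±50 ms of the diagonal
(inclusive) to control the temporal smearing of the 100 ms
moving-average filter; at a 100 Hz decoding rate an interior window
holds 31 × 31 = 961 cells of which 650 are eligible. The window is
truncated at epoch boundaries and the denominator adapts; no padding is
ever used.

**Cell tests.** The source states the per-cell decisions used
permutation tests but not the scheme; it also notes that parametric
t-tests differ from randomization tests by less than 0.01 on average.
Both are exposed: the default is the one-sided paired/one-sample t-test
at α = 0.05 (uncorrected — intentionally, to maximize sensitivity), and
`method = "permutation"` implements the concrete randomization scheme
chosen here: random sign flips of the per-subject difference, group
mean statistic, add-one p-value, flips shared across cells. The
acceptance suite verifies the two agree to < 0.01 on study-structured
synthetic groups.

# Inference

The permutation null shuffles each subject's orientation labels jointly
across all trials, refits the IEM, and recomputes the group one-sample
t; the one-tailed p uses the add-one rule
$p = (1 + \#\{t_{null} \ge t_{obs}\})/(1 + n_{perm})$, which cannot be
zero and is exact under exchangeability. Each permutation refit defaults
to 10 partition iterations rather than 100 — a fidelity/runtime knob;
the null is over label assignments, not partitions, so this only adds
(symmetric) estimator noise. Null distributions are kept per time point
(a pooled option would be easy but is not the default, since slope
variance differs across time). Bootstrap standard errors resample
participants with replacement (default 10,000) and take the SD of the
resample means.

Brain-behavior coupling is summarized by regressing the behavioral
ensemble tendency on the per-subject TG sensitivity averaged over the
200-1000 ms × 200-1000 ms window, reporting R², the regression p, and
the Spearman rank correlation as a robustness check.

# Behavioral models

**Old/new (experiment 1).** Probe similarity to the mean is
$sim(\theta) = 1 - |\theta|/(\pi/2)$. The proportion of "old" responses
over similarity levels is fit with the cumulative Weibull
$W(sim) = \gamma - (\gamma - \delta)e^{-(sim/\alpha)^\beta}$ by
minimizing the binomial negative log-likelihood (constant log-binomial
terms dropped; they do not move the argmin but make reported NLLs
differ from the full pmf by a data-dependent constant). The bounded
optimizer uses α, γ, δ ∈ (0,1) and β ∈ (0,100) — a finite stand-in for
an unbounded slope — with 30 random restarts, β initialized in (0,10).
γ ≥ δ is *not* enforced; inverted fits are flagged, as are boundary
solutions. At $sim = \alpha$ the function sits at $1 - e^{-1}$ (63.2%)
of its amplitude; α is the ensemble-tendency measure.

**Estimation (experiment 2).** Response errors are summarized per
target offset by the circular mean, sign-flipped so positive = toward
the ensemble mean; the tendency is the average over the four targets.
"Precision" is never defined in the source methods; here it is the
reciprocal circular standard deviation (deg⁻¹), with zero-dispersion
samples flagged as infinite. The median split re-codes errors so
positive = toward the mean (resolving an ambiguity in the source: the
split axis is the mean-target axis per trial), splits at the circular
median, and sends ties to "mean" — deterministic and order-independent.
The circular median is computed by unwrapping around the circular mean
and taking the ordinary sample median there (midpoint for even n).

# The synthetic world

The generator inverts the encoding assumption: electrode signals are
$W c + \varepsilon$ with $W$ (electrodes × 8) i.i.d. standard normal
and $c$ the trial's channel-input vector. Its defaults state the
emulated world once:

* **Geometry/timing:** 28 electrodes, 500 Hz native sampling, epochs
  -200..1600 ms (experiment 1 preset) or -200..1000 ms (experiment 2),
  trial counts 1024/288 and 512/512; decoding after a 51-sample boxcar
  and decimation to 100 Hz.
* **Noise:** i.i.d. Gaussian per electrode and sample, `noise_sd = 2`
  (signal amplitudes are order 1, so trial-level SNR is well below 1 and
  decoding relies on smoothing and trial averaging — the moderate-noise
  regime the method is designed for). An optional AR(1) knob exists but
  defaults off. No volume conduction or realistic spectra.
* **Regimes:** `stable` holds one $W$ for the epoch; `dynamic` redraws
  $W$ independently every 100 ms segment (producing diagonal-dominant TG
  matrices); `mixed` averages the two components. Before t = 0 there is
  no tuning contribution. One `weight_schedule` is drawn per subject and
  shared across that subject's conditions — without a shared brain,
  SO-trained weights could not generalize to VO trials at all.
* **VO signals:** the source does not state a generative model for
  ensemble displays. The channel input is
  $\lambda\,basis(mean) + (1-\lambda)\,\overline{basis(items)}$, with
  λ ∈ [0,1] this package's construct (default 0.5). λ = 1 makes a VO
  trial neurally identical to an SO trial at the mean; λ = 0 is a pure
  item mixture, which is still mean-tuned but flatter.
* **Behavior:** old/new memory for each distinct item is
  $(1-w)\,item + w\,mean$ plus von Mises noise (concentration
  `response_kappa = 8` on the doubled-angle circle, a realistic ~12°
  circular SD); the observer says "old" if the probe is within
  `criterion_deg = 10°` (the SO probe-step unit; the source specifies
  no criterion) of any memory item. Estimation responses are
  $target + w(mean - target)$ plus the same noise, so the expected
  error is $-w \cdot target\ offset$. Both `w` and λ can be tied per
  subject to create brain-behavior coupling.
* **Seeds:** every subject, stage and iteration derives a bounded child
  seed from the master seed, so runs are reproducible and
  parallelizable.

**What a green test establishes.** The synthetic world satisfies the
IEM's assumptions *exactly* (linear mixing, Gaussian noise, the very
cos⁷ basis used for decoding). Green tests therefore establish that the
implementation is faithful — closed loops are exact, estimators are
unbiased, type-I error is controlled, regimes are discriminated,
couplings are recovered — not that real EEG satisfies these
assumptions, and not the source's empirical effect sizes, which derive
from a real cohort and are out of reach of a desk-scale simulation.

# Numerical choices

* Matrix inversions go through least-squares solves; rank deficiency is
  detected by QR rank checks and reported with the missing
  orientations. Degenerate zero-variance samples in group tests are
  flagged, not silently significant.
* Boxcar edges use truncated (shrinking) windows — no fabricated data;
  the source's edge behavior is unstated, so deviations from
  zero-padding implementations are expected at the first/last 25
  samples.
* Decimation keeps the first sample of each epoch; no anti-alias filter
  beyond the boxcar (matching the stated preprocessing).
* VO test observations are averaged per mean-orientation bin before
  inversion; by linearity of the inversion this equals per-trial
  reconstruction followed by bin averaging, so the unstated choice in
  the source is inconsequential except for trial subsets. The median
  split operates on trial subsets by construction, so it uses the
  subset's bin averages (equal to averaged trial-level reconstructions).
* The ROI lists ship as packaged JSON. Two source inconsistencies are
  resolved: the experiment 2 frontocentral list prints "F7, F7" (13
  unique labels) and is read as F7, F8; the experiment 1 lists assign
  CP5/CP6 to *both* ROIs and omit CP1/CP2 — they are kept verbatim
  because each printed list has exactly 14 labels.

# Known limitations

* The synthetic montage carries generic electrode labels; the published
  ROI lists apply to recorded montages, so `run_pipeline` maps ROIs to
  electrode index ranges when labels do not match.
* The acceptance-scale type-I simulation uses 2 partition iterations
  per IEM refit; this inflates estimator noise symmetrically but leaves
  the permutation test exact, and is documented as a runtime knob.
* `generate_stimuli` draws each trial's mean uniformly, so very small
  trial counts can leave an orientation bin with fewer trials than
  folds; the partitioner refuses rather than repairs (tests use
  balanced stimulus lists where that matters).
* No multiple-comparison correction anywhere, by design; cluster-based
  correction and Bayesian alternatives are out of scope.
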