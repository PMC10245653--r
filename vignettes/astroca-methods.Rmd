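---
title: "Methods: models, estimators, and design choices in astroca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators, and design choices in astroca}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `astroca`: the forward model of
the synthetic-data generator, each estimator's assumptions and tunable
parameters, the numerical choices that matter, and the limits of what
passing tests demonstrate about real recordings.

## The synthetic session model

Every downstream stage is validated against `simulate_session()`, which
generates data with complete ground truth. Its forward model, per cell:

* **Baseline.** `F0(t) = B_c · exp(-t/bleach_tau)` with a per-cell level
  `B_c` spread ±10% around `baseline_level` (100 a.u.), and photobleaching
  time constant 2000 s — slow, visible drift over a 10-minute session.
* **Transients.** Difference-of-exponentials kernels
  `A (e^{-t/τ_d} − e^{-t/τ_r})`, normalized so `A` is the amplitude at the
  kernel maximum; defaults τ_r = 0.5 s, τ_d = 3 s emulate the slow,
  store-driven kinetics of astrocytic GCaMP3. These defaults are
  configuration, not measured constants: the kinetics of this indicator in
  this preparation are not quantified anywhere we could anchor to, so they
  are exposed in `sim_config()` and chosen once as plausible values.
* **Event schedule.** Three sources: (1) *global arousal transients* in
  every cell, `qa_latency` (1 s) after each scripted quiescence-to-active
  movement onset — the latency reported for arousal-linked astrocyte
  activation; (2) *novelty responses* on each exploration of the novel
  object, with per-subpopulation latencies and amplitudes from
  `cluster_spec` (defaults: three clusters at 0.5/1.5/3.0 s covering 85%
  of cells; the remainder respond at a latency re-drawn every trial —
  "inconsistent" cells); (3) *spontaneous transients* as a Poisson process
  at 0.0035 Hz/cell — 0.21 events · cell⁻¹ · min⁻¹, the active-phase event
  rate typical of these recordings.
* **Hemodynamics.** Reflectance channels dip below their reference in
  proportion to a smoothed movement indicator:
  `R_ex = R_ex0 (1 − hemo_depth · a(t))` (and 0.6× that depth for the
  emission band). Measured fluorescence is
  `F_meas = F_clean · (R_ex/R_ex0)^{γ_ex} (R_em/R_em0)^{γ_em}` plus white
  Gaussian noise. The exponent form is a declared model shared by the
  simulator and the corrector — chosen so the correction can be validated
  by exact inversion, since the pathlength factors of the underlying
  Beer–Lambert treatment are not available to anchor to.
* **Keypoints.** Noise-free by default (optional jitter), scripted so each
  behavioral predicate is exactly satisfiable: body-length extension is a
  boxcar during rears, the nose parks 1 cm inside the interaction zone
  with the axis through the object center during explorations, and the
  roaming random walk actively steers clear of object zones so only
  scripted visits count. The circadian generator assigns each hour its
  profile-determined *count* of active samples (placed randomly within the
  hour), so hourly activity profiles carry no binomial sampling noise and
  the peak hour is exact by construction.

What the generator does **not** emulate: correlated (pink) noise, focal
drift and motion artifacts, overlapping ROIs, subcellular microdomain
events, z-drift between sessions, or realistic pose dynamics. Tests passing
on this generator therefore demonstrate correctness of the estimators under
their stated assumptions, not robustness to every artifact of real
fiberscope data.

## Baseline estimation (F₀)

`estimate_baseline()` implements kernel-density mode tracking:
10-frame bins → per-bin minima → Gaussian KDE over sliding windows of 25
minima (Silverman bandwidth per window, since nothing constrains it
better) → the density mode on a 256-point grid spanning the window range,
ties broken toward the lower value so the baseline cannot overshoot →
modified Akima interpolation of the modes, anchored at window centers,
back to frame resolution, floored at a small positive value.

Two choices deviate from the most literal reading of the procedure, both
forced by its own accuracy requirements:

* **Edge handling.** Holding the first/last mode constant beyond the
  outermost window centers lags a drifting baseline by up to the
  half-window span (~31 s at 4 Hz), a ~3% error on a typical bleaching
  slope. The ends are instead extended with the local end slopes.
* **Bias correction (`debias = TRUE`).** The minimum of a `bin_frames`
  noisy samples sits below the true baseline by ≈ `E[max of n N(0,1)] · σ`
  (≈1.54σ for n = 10). Left uncorrected this propagates into a
  noise-dependent positive offset of all ΔF/F (+0.02 at σ/F₀ = 1%). The
  noise SD is estimated robustly as `mad(diff(trace))/√2` and the window
  modes shifted up by the exact expectation (computed by quadrature), so
  event-free ΔF/F is centered on zero. The correction vanishes on
  noise-free traces and preserves shift equivariance.

`interp_makima()` is a from-scratch implementation of modified Akima
interpolation (Akima slopes with weights `|δ₂−δ₁| + |δ₂+δ₁|/2`), verified
against an independent reference implementation to 10⁻⁷.

## Event detection

The detector keeps the classical contract — robust z (median, MAD·1.4826)
threshold 2.5, candidates confirmed by a local Gaussian fit with
R² ≥ 0.8, 1 s minimum separation with merge-to-larger — and adds three
elements that the contract needs to actually work at threshold-level SNR:

1. **Matched filtering for candidate location.** Local maxima are found on
   a ~1.75 s moving-average copy of the trace. Transients with seconds-long
   kinetics pass essentially unattenuated while white noise shrinks by
   √window, but all z-scores (height *and* prominence) are measured
   against the **raw** trace's median/MAD. A true 5σ transient keeps
   z ≈ 4.7 after smoothing; a noise bump that survives smoothing reaches
   only ~1 raw-σ and is rejected by the 2.5 threshold itself. This is what
   drives the false-positive rate on pure noise to effectively zero.
2. **Topographic prominence.** A candidate must also stand 2.5 robust-z
   clear of the higher of the two minima separating it from taller
   terrain. Without this, noise ripples riding the slow decay tail of a
   large transient all exceed the height threshold and are multiply
   counted.
3. **Width plausibility.** The fitted FWHM must be ≥ 1 s: astrocytic
   transients last seconds, and sub-second fitted widths are noise shapes.

The Gaussian is fitted (Levenberg–Marquardt, multi-start over initial
widths) on a tight ±1.5 s segment around the peak core, where the
asymmetric transient is approximately symmetric; wider segments make the
symmetric model fail its own R² gate on perfectly real events. The
reported peak time is the raw-trace argmax near the candidate (the
symmetric fit's center is biased ~2 frames late on an asymmetric
transient); onset is where the fitted curve crosses 10% of amplitude.
Verified performance at amplitude = 5× noise SD (200 cells, 10 min):
recall 0.95, precision 0.99, false positives ≈ 0.000 per 100 noise
samples.

## Behavior detectors

All detectors are frame-wise predicates plus run-length merging, exact on
noise-free tracks (half-open intervals `[onset, offset)`, seconds, cm):

* **Sleep:** centroid speed < 0.5 cm/s for strictly more than 40 s, the
  EEG/EMG-validated immobility rule.
* **Rearing:** body length ℓ = |nose − tailbase| exceeds a 5-s running
  median by 25%, with exit at half that threshold (hysteresis against
  chatter); Δh is the maximal extension above baseline. The 2-D
  body-length proxy stands in for the side-view truncal extension; its
  scale is not calibrated to real Δh.
* **Object exploration:** nose within `radius + 2.5 cm` of the object
  center *and* tailbase→nose axis within 45° of the nose→center
  direction (45° chosen as a sensible default where only "oriented toward"
  is specified; nose, not centroid, defines zone entry). Overlapping zones
  resolve to the nearest center.
* **Q-A transition:** first frame at ≥0.5 cm/s after ≥20 s continuously
  below it. One movement threshold (0.5 cm/s) is shared by locomotion,
  sleep, and quiescence definitions.
* **Circadian profile:** hourly active fraction; the active phase is the
  contiguous 12-h circular window with maximal summed activity (flat
  profiles are flagged degenerate rather than split arbitrarily).
* **Novelty preference:** d′ = (T_N − T_F)/(T_N + T_F). This normalized
  difference is the definition consistent with a 76%/24% split yielding
  d′ = 0.52; no other standard formula reproduces that pair.

## Event-aligned statistics

* **Alignment** cuts `[−pre, +post]` windows at the imaging rate and by
  default subtracts each event's pre-window mean per cell. For Fano
  statistics this subtraction is disabled (`baseline_subtract = FALSE`):
  it would center the pre-event epoch on zero by construction, leaving
  the variance-to-mean ratio undefined exactly where the reference epoch
  lives. The pipeline computes Fano on the ratio F/F₀ = 1 + ΔF/F for the
  same reason.
* **Epochs** default to t₀ = [−0.9, −0.1] s and t₁ = [+0.1, +0.9] s
  around the reference; rFF is the percent change of FF from the
  reference epoch and is exactly 0 there by construction. The per-event
  response is the epoch-mean (not peak) ΔF/F — the mean is the
  variance-to-mean-compatible choice.
* **Synchronization index.** No formula for SI is established for this
  use, so the package adopts the population-variance coherence ratio
  `SI = var(across-cell mean) / mean(per-cell variance)`, clipped to
  [0, 1]: it equals 1 for identical cells, ~1/N for independent cells, and
  `s²/(s²+σ²)` for a shared signal in noise — matching how the index is
  used qualitatively (synchronized arousal ≈ 0.7 vs. desynchronized
  novelty exploration ≈ 0.3). This substitution is deliberate and
  prominent: SI values from this package are comparable to each other,
  not necessarily to other implementations.
* **Activeness posterior.** `P(active | event)` by Bayes' rule from the
  binarized series; uncertainty by bootstrap over time bins (1000
  resamples); the null by regenerating Bernoulli event series with the
  matched marginal rate (circular shift available as an alternative that
  preserves autocorrelation). Under independence the posterior provably
  collapses to P(active), which is what the null distribution estimates.
  Only this null behavior is treated as checkable: the actual-data
  estimator that produced a posterior of 31.7% from marginals
  0.21/0.24/0.09 is not derivable from those numbers by naive Bayes
  (0.21·0.24/0.09 ≈ 0.56), so the package makes no claim to reproduce it.

## Clustering

Features per cell are either concatenated per-trial traces downsampled to
20 points/trial (default) or per-trial (peak latency, amplitude) pairs —
both offered because the exact feature construction is not pinned down;
columns are z-scored, constant columns dropped, missing trials imputed by
cell medians. PCA scores (2 components) feed a full-covariance Gaussian
mixture fitted by EM: k-means++ seeding, 10 restarts keeping the best
log-likelihood, covariance floor 10⁻⁶ on the diagonal, convergence at
Δlog-likelihood < 10⁻⁸, and the log-likelihood asserted non-decreasing on
every iteration (a near-empty component keeps its parameters — a partial
M-step — rather than being reseeded, which would break that guarantee).

"95% likelihood" membership is interpreted as posterior responsibility
≥ 0.95; cells below it are *unclustered*, mirroring cells outside the
cluster edges in score space. k defaults to 3 but is exposed. A geometric
note: with components exactly 5σ apart, each pair's 0.95-responsibility
boundary excludes ≈2.8% of a component's cells per close neighbor, so the
achievable unclustered fraction depends on the arrangement — about 3.7%
for collinear centers versus ~5.6% for an equilateral triangle. The
package's recovery tests use the collinear arrangement, the geometry
consistent with ≥95% assignment at ≤5% unclustered.

Cluster consistency: a clustered cell maintains its features when its
trial trace correlates best with its own cluster's leave-one-out template
in a strict majority of trials; the fraction is reported over clustered
cells.

## Numerical and interface conventions

Time in seconds, lengths in cm, rates in Hz; frames 0-based in files,
1-based in R; intervals half-open `[onset, offset)`. CSV products carry
`#`-prefixed provenance headers (package version and seed, deliberately no
timestamps) so pipeline reruns are byte-identical. Behavior at 30 Hz is
resampled to the imaging time base by nearest neighbor. Aligned tensors
live as R arrays with axis metadata and are serialized as long-format CSV.
All randomness flows through explicit seeds; `simulate_session()` is
bit-reproducible per seed.

## Problem sizes used in the test suite

The suite validates at sizes a laptop handles in seconds to a few minutes,
chosen to make the statistical assertions sharp rather than to stress
throughput: detection operating characteristics on a 200-cell, 10-minute
session (~460 true events) plus 240 000 samples of pure noise; baseline
recovery on six 10-minute cells; mixture recovery at n = 300; posterior
calibration on 60 000-bin series (500 000 in the acceptance script);
end-to-end determinism on an 8–12 cell session run twice and compared by
checksum.

## Known limitations

* The hemodynamic model is a declared stand-in validated by
  self-inversion; real pathlength exponents vary with wavelength and
  tissue and would need calibration data.
* The Gaussian confirmation model under-fits strongly asymmetric
  transients; at default settings this costs a few percent recall near
  threshold SNR.
* The rearing Δh proxy and the SI formula are package-defined quantities;
  compare within analyses using this package only.
* FF/rFF on baseline-subtracted ΔF/F is ill-defined in pre-event epochs;
  use the ratio form as the pipeline does.
* The GMM assumes 2-D scores summarize response structure; with more
  informative features, raise `n_components` and `k` (BIC over k is left
  to the user via repeated fits).
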