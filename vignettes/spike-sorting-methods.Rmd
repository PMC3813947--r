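---
title: "Sorting oligofiber nerve recordings: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting oligofiber nerve recordings: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligosort)
```

## The problem

A suction electrode on a collagenase-dissociated nerve fascicle records a
handful of fibers on one channel ("oligofiber" recording). Sympathetic
efferents fire in synchronous bursts, so two fibers regularly discharge
within a millisecond of each other and their extracellular spikes sum into
complex waveforms. Conventional waveform clustering either forces these
complexes into the wrong cluster or discards them as outliers — and since the
synchrony is precisely the physiology of interest, discarding them biases
every downstream rate and correlation estimate.

`oligosort` implements a full sorting chain in which outliers are not
discarded but *interrogated*: if an outlier is a cluster's normal spike plus
something else, subtracting the cluster's reference waveform should leave
that something else, and if the residual is either small enough to be noise
or demonstrably present elsewhere in the same recording, the outlier is
returned to its cluster. This "subtraction algorithm" (SA) is data-based: no
generative model of the interferer is assumed, only that it recurs.

## Processing model and assumptions

The chain assumes a single channel of band-passed (10–3000 Hz),
gain-corrected voltage in microvolts at a nominal 10 kHz processing rate
(acquisition may oversample, e.g. at 40 kHz, to avoid peak-alignment jitter;
`resample_recording()` brings it down). All windows are specified in
milliseconds and converted at the recording's rate, so other rates work, but
the canonical geometry at 10 kHz is: 250-sample snippets with the peak at
sample 121 (half-open window from 12 ms before to 13 ms after the peak), a
50-sample feature segment (2 ms before to 3 ms after), and a 32-sample
full-waveform window (1.2 ms before to 2 ms after).

Key statistical assumptions:

* **Noise dominates the amplitude median.** `σₙ = median(|x|)/0.6745` is the
  Gaussian-consistent robust scale estimate; it is accurate while spiking
  occupies a small duty cycle (`spiking_duty_cycle(5, 0.005)` = 0.025) and
  degrades gracefully as activity rises.
* **Within-fiber waveform homogeneity is multivariate-Gaussian-ish.** The
  Hotelling T² cutoff is the `scope` quantile of `p(n−1)/(n−p)·F(p, n−p)`,
  the null distribution of T² with estimated mean and covariance; on null
  Gaussian clusters the retained fraction calibrates to `scope` (the
  acceptance suite checks 99.99% on 10⁶ draws).
* **Interference recurs.** SA's matching criterion is only meaningful for
  residual signals that appear repeatedly in the scan epoch.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `threshold_sigma` | 5 | σₙ | detection threshold multiplier |
| `min_separation` | 1 | ms | detection dead time (well under the 3-ms refractory bound) |
| `active_features` | all six | — | features used for clustering; correlation is often dropped when all fibers share similar biphasic shapes |
| `metric` | cityblock | — | k-means distance; cityblock on features is faster and usually better separated than squared-Euclidean or full-waveform runs |
| `n_restarts` | 10 | — | k-means restarts, best by inertia |
| `t2_scope` | 0.9999 | prob. | homogeneity coverage |
| `sa_sigma_ceiling` | 4 | σₙ | sub-threshold residual ceiling (80% of the detection threshold) |
| `sa_r_min` | 0.95 | — | residual-match correlation bar |
| `sa_mag_tol` | 0.30 | — | relative peak-magnitude tolerance for matches |
| `sa_epoch` | 600 | s | scan epoch |
| `sa_criteria` | `"or"` | — | see below |
| `refractory` | 3 | ms | refractory bound; `clean_fraction` 0.001 |
| `max_modes` | 3 | — | ISI Gaussian mixture order |

`k` (the cluster count) is deliberately user-supplied. In this kind of
recording the operator judges the number of apparent clusters from feature
plots; the package provides silhouette summaries to assist but never
auto-selects `k`.

**OR versus AND.** The two SA retrieval criteria (residual sub-threshold;
residual matched in the recording) are combined as a disjunction by default.
Retrieved residuals are frequently full-amplitude spikes of another active
fiber, which can never be sub-threshold, so a conjunctive reading would make
the matching route unreachable; `sa_criteria = "and"` restores it for users
who want the stricter behavior. The pitfall guard is independent of this
choice: any residual correlating above 0.95 with its *own* cluster reference
(the signature of a double-amplitude outlier) is flagged for review and never
auto-retrieved.

## Single-fiber validation

A unit (T²-selected plus SA-retrieved spikes) is accepted as a single fiber
when (1) fewer than 0.1% of its ISIs violate the 3-ms refractory period, and
(2) its ln-ISI probability density — Scott-binned
(`h = 3.49·s·n^(−1/3)`) from `ln(0.003) = −5.809` to the 99.9th
percentile — is well fitted by a 1–3-mode Gaussian curve whose fitted density
declines promptly toward the refractory bound. "Promptly" is operationalized
as fitted density at `ln(0.003)` below 10% of the smallest mode's peak
(`decline_frac`, configurable and reported with its raw values); an absent
decline betrays merged fibers whose short ISIs were simply never detected.
Preceding-ISI dependence of waveform features (exponential relaxation
`y = y₀ + a·e^{−(x−x₀)/t}` versus linear `y = mx + b`, chosen by AICc subject
to a goodness test) is reported as supporting evidence but does not veto:
many genuine single fibers show no ISI dependence.

Two conventions here deserve a note. First, the t-statistic for the goodness
test uses the standard rooted form `t = r·sqrt((n_b−K−1)/(1−r²))`; an
unrooted variant is sometimes printed in the literature but is not the
classical t-for-correlation statistic. Second, `x₀` in the relaxation model
is fixed at `ln(0.003)` because `a` and `x₀` are jointly unidentifiable
(`a·e^{x₀/t}` is the only identified combination), leaving K = 3 free
parameters.

## Numerical choices

* **Fourier resampling.** `resample_recording()` truncates or zero-pads the
  spectrum and inverts at the new length (splitting or merging the Nyquist
  bin to keep the spectrum Hermitian). This is exactly band-limited and
  linear to machine precision; its one caveat is periodic wrap-around at the
  extreme trace edges.
* **k-means.** Lloyd iterations to zero label changes (cap 300), seeded from
  data-independent RNG so results are reproducible and permutation-stable; an
  emptied cluster is reseeded at the point currently farthest from its
  centroid. Cityblock centroids are per-dimension medians (the L1 minimizer),
  squared-Euclidean centroids are means. Ties in assignment break to the
  lowest cluster index.
* **T² rank handling.** Components below `1e−10` of the leading eigenvalue
  are dropped; selection is one pass (fit once, flag once) — iterating to
  stability would shrink the cutoff progressively and is intentionally not
  the default.
* **SA matching.** The 50-sample residual core is correlated against the
  epoch by one FFT-based cross-correlation plus cumulative window sums (an
  exhaustive per-window `cor()` loop is the test oracle); one local maximum
  is taken per supra-threshold run, and windows within 25 ms of the outlier's
  own position are excluded so nothing matches itself.
* **Gaussian mixture fits.** Nonlinear least squares (`minpack.lm::nlsLM`)
  on (bin midpoint, density) pairs; modes seeded at the k largest histogram
  peaks (greedy, ≥ 2h apart), amplitudes at the peak densities, widths at h,
  with five jittered restarts. Two guards reject degenerate optima: widths
  are floored at one bin width, and a converged solution is discarded unless
  every pair of modes is separated by at least twice the larger width — the
  condition for two Gaussians to produce distinct humps. Without these
  guards, least squares on histogram data (whose bin noise scales with the
  density itself) happily spends extra modes on noise around the peak, and
  AICc — which assumes homoscedastic residuals — rewards it; with them, AICc
  recovers the generating mode count essentially always in the simulation
  suite (50 seeded replicates at n = 5000 across 1–3 modes).
* **Refractory classes.** `clean` (no violations), `marginal` (below 0.1%),
  `violating` (at or above 0.1%); validation accepts clean or marginal,
  i.e. a violating fraction under 0.1%.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` inserts unit-peak biphasic templates (Gaussian rise;
`(1+ahp)·e^{−t/fall} − ahp·e^{−t/τ}` decay; optional rebound), scaled to
`peak_snr · σ`, at uniform-random times with enforced same-group spacing
(default 20 ms), into white or AR(1) Gaussian noise (a recorded no-spiking
trace can be substituted). The default study conditions are four groups at
peak SNR 2, 3, 4 and 6 — spanning the regime where sorting transitions from
impossible to near-perfect — at σ = 10 μV over 120-s test epochs (a 30-min
epoch is just `epoch_s = 1800`). Forced synchrony re-places a fraction
(default 0.5) of one group's spikes within ±1 ms of another group's,
manufacturing overlap complexes.

The generator deliberately omits several features of real recordings:
waveform nonstationarity (real spike features drift with preceding ISI —
exactly what `fit_feature_vs_isi()` measures), electrode drift, correlated
burst-locked firing beyond pairwise synchrony, non-Gaussian ambient
interference, and ISI distributions with refractory structure (insertion
times are uniform, not renewal-process draws). Passing the end-to-end suite
therefore demonstrates the pipeline's mechanics and its SNR dependence, not
performance on drifting or heavily bursting preparations.

## Known limitations

* **Detection is the accuracy floor.** With a 5σₙ threshold, spikes whose
  template peak is at or below ~4σₙ are detected only when noise lifts them
  over the bar, so per-group accuracy saturates well below 1 for such groups
  no matter how good the downstream stages are. Sorting aims at signals
  comfortably above threshold.
* **The r > 0.95 match bar needs large residuals.** For a 50-sample residual
  with white noise on both sides, the expected normalized correlation is
  `SS_t/(SS_t + 49σₙ²)`; reaching 0.95 requires residual energy ≈ 19× the
  window noise energy — for realistic biphasic shapes, a residual peak around
  14σₙ. Overlaps between moderate-SNR fibers are therefore mostly retrieved
  (or not) via the sub-threshold route; the matching route earns its keep
  when the interfering fiber is large. The bar is configurable (`sa_r_min`)
  and in practice is a stringency the operator sets per recording.
* **T² masking under heavy contamination.** A cluster whose outliers all lie
  in one direction (e.g. many same-phase overlaps) inflates the estimated
  covariance along that direction, capping T² below the 99.99% cutoff; the
  single-pass selection then under-flags. The `iterate` escape hatch refits
  after removing flagged points, at the cost of a progressively shrinking
  cutoff.
* **One subtraction, not deconvolution.** SA subtracts exactly one reference;
  triple overlaps or overlaps of two outliers are out of scope by design.
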