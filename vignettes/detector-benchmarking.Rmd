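---
title: "Benchmarking spontaneous PSC detectors: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking spontaneous PSC detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Spontaneous excitatory and inhibitory postsynaptic currents (sEPSCs/sIPSCs)
are brief current deflections — downward at a holding potential near
−70 mV, upward near +10 mV — riding on the noisy baseline of a whole-cell
voltage-clamp recording. How many of them a lab "detects", and how large
they appear, depends strongly on the detection method: visual curation,
plain amplitude thresholds, template matching, robust statistics, or a
trained classifier all disagree, particularly for small events close to the
noise band. `pscbench` provides a common, fully reproducible test bed: a
generative simulator that produces recordings with exact ground truth, four
detector families, and a scoring layer that compares any detector against a
reference annotation with tolerance-window matching.

## The simulator

Events are modeled as biexponential currents
$k(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$, scaled to unit peak, signed by
mode, and placed by a homogeneous Poisson process. Defaults emulate
3-minute gap-free recordings digitized at 20 kHz. Choices a user should
know about:

* **Kinetics.** Defaults are field-typical fast AMPA-receptor kinetics for
  sEPSCs ($\tau_r$ 0.5 ms, $\tau_d$ 4 ms) and GABA$_A$ kinetics for sIPSCs
  ($\tau_r$ 1 ms, $\tau_d$ 12 ms). These are modeling choices, configurable
  per spec; nothing downstream assumes them.
* **Amplitudes.** Log-normal with median 25 pA and log-SD 0.5, truncated
  below 5 pA — the conventional minimum-amplitude floor for counted events.
* **Arrivals.** Homogeneous Poisson at 2 events/s by default (typical rates
  run roughly 0.5–10 Hz), with a 2 ms refractory floor so that ground truth
  stays unambiguous. Overlapping events sum linearly and *every* injected
  event is kept in the ground truth; detectors are scored honestly against
  overlaps they cannot resolve.
* **Noise.** Four parametric components (white noise, mains hum, random-walk
  drift, and step/spike/burst artifacts) rather than replayed recorded
  noise. This reproduces the *kinds* of disturbance real rigs show, but not
  their full empirical variety; a pass on synthetic data therefore bounds
  implementation correctness, not real-world performance.

Every stochastic operation is a pure function of (spec, seed), which is what
makes the end-to-end pipeline bit-reproducible.

## Filtering

The robust detector's band-pass (0.05–50 Hz) and noise-band high-pass
(100 Hz) are 3rd-order Butterworth filters. Two numerical choices matter:

* Filters are designed as **cascaded second-order sections** from the
  analytic prototype poles. The polynomial (b, a) form is numerically
  unusable at a 0.05 Hz corner on 20 kHz data (5·10⁻⁶ of Nyquist); biquads
  are stable there. The band-pass is realized as a high-pass/low-pass
  cascade, whose magnitude is indistinguishable from the transformed
  band-pass when the corners are three decades apart.
* Filtering is **zero-phase** (forward–backward) by default, because events
  are scored by peak time and single-pass IIR filtering shifts peaks. The
  price is a squared magnitude response — attenuation at the corners is
  −6 dB rather than −3 dB — and, for asymmetric events, a residual peak
  shift of a few ms from the smoothing itself. Both effects motivated the
  peak-refinement step below.
* Zero-phase passes use odd-extension padding sized to ~5 time constants of
  the slowest corner so that edge transients decay inside the pad. The
  0.05 Hz corner settles over ~3 s; on recordings much shorter than ~30 s
  its DC rejection is necessarily incomplete.

## The detectors

**MAD (robust threshold).** The trace is band-passed (0.05–50 Hz); the
noise band is the 100 Hz high-passed raw trace; the inclusion threshold is
the median of the filtered trace plus 3.6 × MAD of the noise band for
sIPSCs (minus 2.5 × MAD for sEPSCs). "MAD" defaults to the *mean* absolute
deviation from the median, following the method's detailed description;
the median absolute deviation is available by configuration. Candidates are
local maxima of the filtered trace in the event direction; a 2 ms minimum
separation and a prominence requirement of half the threshold-to-median
distance suppress duplicate maxima on one event, which a literal
"all local maxima" rule would multiply-count. The threshold is compared
against the filtered-trace *peak value*, the quantity the threshold formula
is built from, not against peak-minus-baseline amplitude.

**BTD (baseline threshold).** Gaussian-smoothed trace, noise SD estimated
from a preview stretch at the start of the recording, threshold at
median ± 3 SD. One event per threshold crossing (the detector re-arms only
after the trace falls back below threshold), mirroring commercial threshold
tools. Fixed-length segmentation recomputes median and threshold per
segment, restoring sensitivity under slow drift. The human step of choosing
an "appropriate" threshold is deliberately replaced by the reproducible
multiplier rule; a fixed absolute threshold is available for deliberately
naive baselines.

**TTD (template/threshold).** Seed events are collected with a flat
+30 pA (sIPSC) / −20 pA (sEPSC) threshold, grouped by peak amplitude
(k-means with deterministic quantile starts), and averaged into a small
template bank (three templates by default, 60 ms long — at least five decay
time constants). Candidates at 5 × SD beyond the noise band are screened by
the best Pearson correlation against the bank (cutoff 0.6); a
Clements–Bekkers scaled-template criterion is available behind the same
interface. The rise-time exclusion honors the printed "<30 µs" literally,
which is below one sample at 20 kHz and therefore inert unless raised; it
is configurable because the printed value is likely a misprint for ms.

**MLD (window classifier).** A small 1-D convolutional network (three
blocks of 16/32/64 channels, kernel 9, max-pool 2, global average pooling,
sigmoid head) over 600-sample windows (30 ms at 20 kHz), trained with
binary cross-entropy and Adam (learning rate 10⁻³) for up to 100 epochs
with a 20% stratified hold-out, early stopping on validation loss, and the
best-validation parameters retained. Training windows are balanced at an
event:noise ratio of 1.0. Windows are standardized per window (median/MAD),
so the absolute current scale and holding-current offset cannot leak into
the classifier — detection is provably invariant to DC offsets. The network
is implemented directly on BLAS matrix products inside the package, which
keeps training deterministic given a seed and a single-threaded BLAS, and
CPU training in the minutes range.

**Peak placement and amplitudes (all detectors).** Detection runs on
filtered or smoothed traces, but reported peak times are refined to the
directional extremum of a lightly Gaussian-smoothed (σ = 0.25 ms) copy of
the raw trace near the candidate, and amplitudes are measured there as
peak value minus the pre-peak baseline (the directional extremum in a
window 15→6 ms before the peak). The light smoothing is essential for
point reads: the sample-wise minimum of raw noise in a 9 ms window is
biased by ~3 noise SDs, which would inflate every amplitude by several pA.
Filtered-trace amplitudes are retained alongside (`amplitude_filtered`).
For the sliding classifier the scoring profile is shift-tolerant (a
consequence of global pooling), so its refinement searches the full window
span; candidate maxima of the classifier score must additionally clear a
topographic prominence of 4 logit units, separating genuine neighboring
events (deep score dips between them) from plateau wiggles on one event.

## Matching and scores

Matching is greedy nearest-in-time one-to-one within ±3 ms on peak times;
ties break on the earlier reference event. The tolerance must exceed
filter-induced jitter but stay below typical inter-event intervals; it is
configurable and recorded in every report. The greedy matcher is within one
match of the exhaustive optimal assignment in ≥99% of random small
instances (the optimal oracle ships in the test suite). Precision and
recall use perfect-on-empty conventions (P = 1 when nothing was detected,
R = 1 when there was nothing to detect); F$_\beta$ with β = 0.3 weights
precision over recall and is 0 when both P and R are 0. Amplitude-stratified
scores bin true positives and misses by reference amplitude and false
positives by detected amplitude (10 pA bins to 100 pA plus an overflow
bin); empty bins are undefined (NA), not zero.

## What the shipped checks do and do not show

The acceptance layer runs at the simulator's benchmark conditions:
3-minute 20 kHz sIPSC traces, 2 Hz events, median 25 pA amplitudes, white
noise SD 3 pA. Under those conditions the robust detector with its
published parameters reaches precision ≈ 1 and recall ≈ 0.9 at ±3 ms; the
residual misses are small events whose band-passed peaks fall below the
3.6 × MAD threshold (the zero-phase band-pass attenuates an sIPSC-shaped
peak to ~0.77 of its raw height) plus occasional pairs merged by the 50 Hz
low-pass. The classifier's hold-out AUC ≥ 0.95 and its perfect recovery on
a noise-free trace verify the training and inference plumbing, not
biological performance. Problem sizes in the shipped tests (window counts
near 2,000, a 25-epoch cap with early stopping, 15–60 s traces for
property checks) were chosen as the smallest sizes at which every one of
these quantities is stable across seeds.

## Known limitations

* The simulator does not model series-resistance changes, seal
  degradation, kinetic drift, or cell-type-specific event shapes.
* Overlapping events closer than the 50 Hz low-pass can resolve are
  irrecoverable for the classical detectors by construction; they count as
  misses. The sliding classifier likewise merges events closer than
  roughly its window length (30 ms by default): its pooled score stays
  high across the whole pair, so only one maximum survives.
* The classifier assigns probability 0 to windows whose raw excursion is
  below 2 pA: no countable event fits in them, and their rescaled noise is
  outside the training distribution.
* ABF files are not read directly; recordings must be exported to the
  two-column CSV table or the HDF5 container.
* The inferential statistics used on real datasets (mixed models, survival
  analysis of inter-event intervals) are deliberately out of scope; the
  package exports tidy long-format tables for external statistical
  software instead.
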