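---
title: "Methods: automated EGM duration mapping on the 17-segment model"
author: "egmdur"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated EGM duration mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(egmdur)
```

This vignette documents the model, the parameters, the synthetic-data
generator and the numerical and design choices behind `egmdur`. It states
no empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## The measurement problem

During sinus-rhythm substrate mapping of ischemic ventricular tachycardia,
bipolar electrograms (EGMs) recorded over scar and scar border zone are
low-amplitude, fractionated and prolonged, reflecting slow, asynchronous
conduction through surviving fiber bundles. Prolonged EGM duration is a
surrogate for slow conduction and hence for potential ablation targets.
EGM morphology in scar varies enormously, which defeats estimators built
on fixed morphological templates (peak picking, fixed-amplitude gates). A
local dispersion statistic sidesteps morphology: wherever the signal is
active, its local standard deviation rises, whatever shape the deflections
take.

## The estimator

For a trace $x_1,\dots,x_n$ at sampling rate $f_s$ (default 1000 Hz, i.e.
1 ms per sample):

1. **Zero-phase filtering.** A 4th-order recursive Butterworth bandpass
   (30–250 Hz) and a quality-factor-30 biquad notch (50 Hz default, 60 Hz
   configurable) are each applied forward and backward. Zero phase is not
   optional here: the quantity being measured is *timing*, and a causal
   filter would bias every onset by its group delay. Before filtering,
   the trace is reflect-padded (odd reflection, 300 samples) so edge
   transients of the recursion cannot masquerade as activity at the trace
   boundaries; traces shorter than 300 samples are rejected.
2. **Sliding-SD transform.** $s_i$ is the population standard deviation
   (divide by $k$, not $k-1$) of the samples in a window of $w$ ms centred
   on sample $i$; at the edges the window truncates to the available
   samples, so the curve has the trace's length. Window lengths in ms
   convert to samples by rounding half up.
3. **Threshold detection.** With threshold fraction $\theta$, onset is
   the *first* and offset the *last* index with
   $s_i \ge \theta \max_j s_j$. Both exist whenever the curve has a
   positive maximum (the argmax qualifies). Duration is
   $(\text{offset}-\text{onset}) \cdot 1000/f_s$ ms.
4. **Classification.** An EGM (or a segment mean) is *prolonged* when its
   duration strictly exceeds the cutoff $c$.

A trace whose SD-curve is identically zero carries no detectable activity;
it is flagged `degenerate` with duration 0 rather than raising an error,
so batch runs over $10^5$-point maps never stop.

Two exact properties follow from this construction and are enforced as
tests: the superlevel sets of the SD-curve are nested, so duration is
non-increasing in $\theta$; and the threshold is relative to the curve
maximum, so onset/offset are invariant under positive rescaling of the
trace.

### Parameters

| parameter | meaning | default | validated range |
|---|---|---|---|
| `sd_window_ms` ($w$) | SD-window length, ms | 40 | 10–45 |
| `sd_threshold_frac` ($\theta$) | fraction of SD-curve max | 0.15 | 0.10–0.50 |
| `duration_cutoff_ms` ($c$) | prolongation cutoff, ms | 70 | 60–80 |

Qualitatively, larger $w$ smears the SD-curve and lengthens estimates
(over-estimation at large windows), while larger $\theta$ clips the curve
tails and shortens them (under-estimation at high thresholds). The
defaults are the operating point selected by maximum diagnostic odds ratio
on the validated lattice (5 ms / 0.05 / 5 ms steps over the ranges above).

### Interval semantics

Onset/offset are the first/last crossings over the *whole* trace, not the
contiguous region around the argmax. Consequence: temporally separated
deflections (e.g. a late potential after an isoelectric gap) are bridged
into one interval. This matches the intended use — late fragmented
activity *should* lengthen the measured duration — but it also means the
estimator makes no attempt to detect double potentials as such.

## 17-segment aggregation

The left ventricle is divided by a deterministic geometric rule anchored
on three user-supplied landmarks (apex, base centre, septal direction;
in clinical practice these are set by electrophysiologists). With $t$ the
normalized long-axis coordinate (0 at base, 1 at apex): $t<1/3$ basal,
$t<2/3$ mid, $t<0.85$ apical, else the apex cap (segment 17). The
circumferential angle $\varphi$ is measured from the septal direction,
counterclockwise as seen from the apex. Because the septum spans the
anteroseptal and inferoseptal segments, the septal direction is their
shared boundary: basal and mid rings split at
$\varphi = 0°, 60°, \dots, 300°$ with $[0°,60°)$ anteroseptal; the apical
ring splits at $\pm 45°, 135°, 225°$ so its septal segment is *centred*
on the septal direction. All intervals are half-open on the lower edge,
making the assignment total and deterministic; positions whose long-axis
coordinate lies more than 30 mm (configurable) outside the base–apex
extent raise an out-of-chamber warning and clamp to the nearest ring.

Per segment the package reports the arithmetic mean duration (degenerate
points excluded — zeros from silent traces would bias means downward),
the arithmetic mean voltage, the voltage class of that mean (healthy
> 1.0 mV, border 0.2–1.0 mV boundaries inclusive, dense < 0.2 mV), an
ablation flag (a lesion centre falls in the segment; optionally a lesion
radius pulls in segments containing points within that radius) and the
abnormality flag (mean duration strictly above the cutoff). Voltage class
uses the segment *mean* rather than a point-majority vote; per-point
classes remain available for 3-D colouring.

## Diagnostic statistics and the grid search

Validation correlates abnormality with ablation as a marker of
arrhythmogenic substrate: non-empty segments pool across patients into a
2×2 table (abnormal × ablated), summarized by the diagnostic odds ratio
$\mathrm{DOR} = (TP \cdot TN)/(FN \cdot FP)$ with the Haldane–Anscombe
0.5-correction when a cell is empty, a log-normal 95% CI
$\exp(\ln \mathrm{DOR} \pm z_{\alpha/2}\sqrt{1/TP+1/FN+1/FP+1/TN})$, and a
matching two-sided z-test on $\ln \mathrm{DOR}$. Pooling (rather than
averaging per-patient DORs) is the default because segment counts are
small per patient; a stratified mode is exposed via
`contingency_table(..., pool = FALSE)`.

`grid_search_dor()` evaluates every $(w,\theta,c)$ triple on the lattice.
Filtering does not depend on the triple and runs once per map; SD-curves
are computed once per $(map, w)$; detection once per $(map, w, \theta)$;
each cutoff then reuses the cached per-segment means. The selected
operating point is the lattice argmax; ties break deterministically toward
the smallest $w$, then $\theta$, then $c$.

## The synthetic cohort

The generator exists so that every module is testable end-to-end without
proprietary clinical exports. Defaults mirror the mapped-cohort
conditions: 16 patients, 2000 points per map (clinical high-density maps
average near 8000; 2000 keeps test runtimes moderate at identical
segment-level behaviour), 400 ms single-beat windows at 1 kHz, and a
0.01 mV RMS noise floor.

**Geometry.** A truncated half-ellipsoid endocardial shell (80 mm long
axis, 25 mm basal radius), with points sampled area-uniformly and a
triangulated mesh for display.

**Scar architecture.** Designated scar segments (by default one
basal/mid segment drawn with inferior-basal preference, plus a same-ring
neighbour) place continuous dense-scar cores at their centroids. Each
point's tissue class follows its jittered distance to the nearest core:
dense inside $r_d$, border to $r_b$, healthy beyond, with 4 mm boundary
jitter. Radii are drawn per patient ($r_d \in [14,24]$ mm,
$r_b = r_d + [8,22]$ mm) because infarct extent varies strongly between
patients; the central values (20/38 mm) were calibrated so the cohort's
segment voltage-class fractions land near the clinically reported
healthy/border/dense ≈ 65/25/10 split. A continuous class field was chosen
over a segment-pure one deliberately: real scar does not respect segment
boundaries, and a segment-pure field would make ablated and non-ablated
segments perfectly separable at many parameter triples simultaneously,
collapsing the DOR surface into ties and making parameter selection
meaningless.

**Morphologies.** EGMs are sums of Gaussian-enveloped sinusoids
(component frequencies 80–200 Hz, inside the analysis band): healthy —
1–2 components, 20–45 ms, > 1.2 mV; border — 3–6 staggered components
(fractionation), 70–160 ms, 0.2–1.0 mV; dense — 3–8 components,
70–200 ms, < 0.2 mV. Envelope widths and stagger are rescaled so the
composite's support above 1% of peak matches the requested ground-truth
duration on the sample grid; the realized onset/offset ship with each
trace as the `truth` attribute. Ground truth is thus defined entirely on
the generator side, independent of the detector under test. Peak-to-peak
amplitude is exact (the composite is rescaled before noise is added).

**Ablation.** 7–12 discrete lesion sites per patient are drawn uniformly
at mapping points of the eligible segments (scar + halo by default), so
only a subset of eligible segments is ablated and — because halo segments
are variably diluted with healthy tissue — some ablated segments classify
voltage-healthy or duration-normal, as clinical cohorts report.

**What the generator does not emulate.** No biophysical conduction model
(wavefront direction, activation sequence), no catheter-contact or
projection-geometry artefacts beyond a uniform random projection
distance, no double potentials as a distinct class, no inter-beat
variability. Passing tests therefore demonstrate the estimator's
correctness and the pipeline's statistical machinery under controlled,
realistic-scale conditions — not clinical accuracy on real recordings.

**A deliberate consequence of the noise floor.** With a 0.01 mV RMS
floor, an EGM whose $\theta \max s$ threshold falls below the band-passed
noise SD (≈ 0.0066 mV; roughly amplitudes under 0.25 mV at
$\theta=0.15$) has its onset/offset captured by noise and its duration
saturates toward the window length. Dense-scar EGMs therefore read as
maximally prolonged at low thresholds. This is a property of the
algorithm near the noise floor, not a generator artefact, and it is one
reason dense-scar segments are almost universally classified prolonged.

## Numerical choices

- **Sliding SD** uses cumulative sums ($O(n)$ per trace per window).
  The textbook cancellation of $\overline{x^2}-\bar{x}^2$ is handled by
  globally mean-centring first and directly recomputing the few windows
  whose variance is tiny relative to the cumulative error scale
  ($kv < 10^{-4}\sum x_0^2$), restoring agreement with a naive two-pass
  evaluation to better than $10^{-9}$ relative.
- **Filtering** designs the bandpass with `signal::butter` (order 2 →
  4th-order transfer) and the notch from the constrained biquad (RBJ)
  form; both are applied through one padding-controlled forward-backward
  pass.
- **Thresholding** uses `>=` comparisons throughout; the vectorized
  detection inside the grid search compares `S >= theta * rowmax` with
  exactly the same floating-point expressions as the scalar path, so
  cached and naive evaluations agree bit-for-bit.
- **EAMX round-trip exactness**: doubles are written with 17 significant
  digits (IEEE-754 round-trip), so `read_eamx(write_eamx(m))` reproduces
  all numeric fields bit-exactly.
- **Degenerate inputs**: silent traces (flat zero SD-curve) yield
  duration 0 + flag; empty segments carry class `"empty"` and `NA` flags
  and are excluded from pooled tables; zero cells trigger the Haldane
  correction rather than division by zero.

## Design choices where the design was open

- **Population vs sample SD**: population (divide by $k$). The SD-curve is
  a spread measure, not an estimator of a population parameter; the choice
  is pinned by oracle tests.
- **Window alignment**: centred, truncated at edges. Centring avoids a
  systematic onset bias a trailing window would introduce; truncation
  preserves trace length.
- **Strict inequality** for prolongation (`> c`), applied both per point
  and to segment means.
- **Problem sizes in tests**: the acceptance suite runs the full study
  scale (16 × 2000 points) for the grid search, pipeline determinism and
  segment accounting, and 50–500 replicates for the property and coverage
  tests; unit tests use scaled-down cohorts (3 × 250) where composition,
  not scale, is under test.
- **Trace window length** (not stated by mapping-system exports): 400 ms
  single-beat windows, long enough for the longest dense-scar morphology
  plus margin.

## Known limitations

- Durations of near-noise-floor EGMs saturate toward the trace length
  (see above); they remain correctly *classified* but their numeric
  durations are upper bounds.
- Separated double potentials are bridged into one interval by design;
  the estimator does not report them separately.
- The geometric 17-segment rule replaces expert landmark-driven
  segmentation; disagreement with manual segmentation will move points
  near segment boundaries.
- Wavefront-direction effects on bipolar EGM morphology are outside the
  model, in the generator and the estimator alike.
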