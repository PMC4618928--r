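---
title: "Wavelet-based movement-artifact reduction for ambulatory ECG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-based movement-artifact reduction for ambulatory ECG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swmar)
```

## The problem

Ambulatory ECG from a freely moving animal — the motivating setting is a
girth-belt wearable on horses, with textile electrodes sampling the ECG at
250 Hz and a triaxial accelerometer at 25 Hz — is dominated for large parts
of the recording by movement artifacts (MAs). These arise chiefly from
skin stretch changing the electrode half-cell potential. Their spectrum
overlaps the ECG band, so no fixed filter can remove them; but they are
tied to body movement, which the accelerometer observes independently.

`swmar` implements a pipeline that uses the accelerometer to decide *when*
artifacts can exist and a redundant wavelet decomposition to decide *what*,
within those spans, is artifact:

1. **Preprocessing.** The ECG is band-passed (zero-phase Butterworth,
   0.5–40 Hz); the accelerometer components are upsampled to the ECG rate
   by linear interpolation and combined into the acceleration module
   $ACC = \sqrt{acc_x^2 + acc_y^2 + acc_z^2}$.
2. **QRS detection.** Frame energies of the ECG's second derivative
   (32 ms frames, 50% overlap) are thresholded at the midpoint of the
   medians of per-1.5 s energy maxima (LM) and minima (Lm); maximal
   above-threshold runs become QRS intervals with onset/offset markers.
3. **Motion detection.** The module is compared against the robust
   threshold $T = \mathrm{median}(ACC) + 1.4826\,\mathrm{mad}(ACC)$;
   sustained excursions, confirmed by a strong sample (3 robust SDs),
   become motion intervals, dilated by 0.5 s.
4. **Stationary wavelet decomposition.** The band-passed ECG is
   decomposed with the undecimated (à trous) Haar transform at 5 levels;
   every level's coefficient sequence has the signal's length and the
   transform is exactly invertible and shift-invariant.
5. **Artifact estimation and removal.** Detail coefficients of levels
   1–3 are zeroed outside motion intervals; per level (and for the
   approximation) robust bounds $M_j = \mu_{1j} + \sigma_{1j}$,
   $m_j = \mu_{2j} - \sigma_{2j}$ are computed from per-1 s frame maxima
   and minima with $\mu = \mathrm{median}$,
   $\sigma = 1.4826\,\mathrm{MAD}$. Coefficients beyond the bounds,
   inside motion and outside detected QRS spans, form the artifact's
   coefficients; their inverse transform, gated to the motion intervals,
   is subtracted from the band-passed ECG.

A normalized least-mean-squares (NLMS) adaptive canceller using the
acceleration module as its reference input is included as the comparator,
and an evaluation harness scores both methods on ground-truthed synthetic
recordings.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `low`, `high` | 0.5, 40 | Hz | diagnostic ambulatory ECG band |
| `order` | 4 | — | Butterworth design order; forward–backward application doubles it. Stable at 250 Hz; edge transients handled by 3 s reflect padding |
| `win_ms`, `shift_ms` | 32, 16 | ms | 8/4 samples at 250 Hz; the nominal 30/15 ms is not an integer sample count, 32/16 preserves the 50% overlap exactly |
| `interval_s` | 1.5 | s | extrema interval for the QRS threshold; the longest mean equine RR interval, so each interval holds at least one beat |
| `merge_gap_ms` | 100 | ms | fragments closer than this belong to one complex (equine QRS spacing far exceeds it) |
| `pad_s` | 0.5 | s | motion dilation; electrode-potential recovery outlasts the mechanical burst |
| `strong_k` | 3 | robust SDs | hysteresis seed for motion detection (see below) |
| `close_gap_s`, `min_dur_s` | 0.25, 0.5 | s | morphological cleanup of motion candidates |
| `level` | 5 | — | decomposition depth; at 250 Hz the level-5 detail band is ≈3.9–7.8 Hz, separating QRS detail (levels 1–3) from P/T-scale content |
| `wavelet` | `"haar"` | — | two-tap orthonormal pair; exactly invertible, no edge spreading |
| `frame_s` | 1 | s | extrema frames for the coefficient bounds |
| `mode` | `"full"` | — | subtract whole beyond-threshold coefficients (see below) |
| NLMS `order`, `mu`, `eps` | 32, 0.1, 1e-8 | — | 32 taps ≈ 128 ms of reference memory; step 0.1 trades convergence speed for misadjustment (see below) |

## Design choices

**Full-coefficient subtraction is the default.** Coefficients beyond
$[m_j, M_j]$ are attributed to the artifact. Two subtraction variants are
provided: removing the whole coefficient (`mode = "full"`) or only the
excess beyond the bound (`"exceedance"`). Exceedance looks gentler, but it
caps the residual at the bound itself, i.e. at the scale of a typical
frame extremum — on corrupted segments that residual remains comparable to
the clean signal's peaks and the segment stays artifact-dominated by any
RMS criterion. Full subtraction drives the corrupted coefficients to zero
and lets the untouched within-band coefficients carry the remaining
cardiac content; on the synthetic study it reduces the artifact burden
several-fold where exceedance barely moves it, so it is the default.

**Motion detection needs hysteresis.** $T$ lies exactly one robust
standard deviation above the quiet noise floor (1.4826·MAD estimates the
SD), so ~16% of quiet samples cross it no matter how small the noise is;
isolated crossings, once dilated by 0.5 s, can blanket a quiet record.
A candidate excursion is therefore kept only when it contains at least one
sample 3 robust SDs above the median — the usual robust outlier cut — then
short gaps are closed (0.25 s), brief episodes discarded (0.5 s), and the
pad applied. On synthetic bursts this recovers the burst windows with
Jaccard overlap ≥ 0.85 while a bare threshold-and-dilate rule flags most
of the record. Because the median and MAD are equivariant, detection is
invariant to constant offsets (gravity) and positive rescaling.

**Thresholds are computed after gating, zeros included.** Levels 1–3 are
zeroed outside motion before the frame extrema are collected, so when
motion covers less than half the record the medians at those levels are
zero and every motion-segment detail coefficient outside QRS spans is
treated as artifact. This is accepted deliberately: within strong-movement
spans the fine-scale content is dominated by artifact anyway, and detected
QRS spans are protected (excluded from the artifact estimate at levels
1–3, switchable via `qrs_protect`).

**The artifact estimate is gated to motion at every level.** The
approximation and levels 4–5 are thresholded like the details (switchable
via `threshold_approx`), but no sample outside a motion interval is ever
attributed to the artifact; after reconstruction the estimate is re-gated
in the time domain, so the cleaned ECG is bit-identical to the band-passed
ECG outside motion.

**NLMS reference and step size.** The canceller's reference is the
mean-subtracted acceleration module — the only artifact-correlated
exogenous signal the device records. With the conventional aggressive step
(`mu = 0.5`) the weight updates inherit the large burst errors and spray
misadjustment noise across clean segments, making the output worse than
the input on the synthetic study; `mu = 0.1` converges within seconds on
the linear-mixture fixture while keeping misadjustment small, and is the
default. The comparison with the wavelet pipeline is qualitative (an
ordering), since no reference filter configuration is canonical.

**QRS onset markers sit on the R deflection.** The energy threshold —
the midpoint between median frame-energy maxima and minima — is orders of
magnitude above the energy of a small Q wave, so the onset marker A
triggers where the R upslope's energy crosses it. With the equine
morphology used by the generator (Q centred 45 ms before R) the median
gap between A and the annotated Q onset is ≈56 ms; detection-level
matching uses a ±75 ms tolerance accordingly.

## The synthetic generator

`generate_ecg()` builds each beat as five Gaussian bumps (P, Q, R, S, T)
with an equine-like morphology (R 1 mV, tall T, long P–R offset, mean RR
1.1–1.5 s, 5% RR jitter) — ground-truth QRS intervals fall out exactly.
`generate_accel()` places non-overlapping movement bursts (3–8 s,
2–4 g band-limited 1–5 Hz oscillation, cosine-tapered) on a 1 g gravity
baseline with 0.01 g micro-noise. `inject_artifacts()` adds, inside each
burst dilated by 0.5 s, baseline wander (0.5–3 Hz, amplitude following
the smoothed acceleration excess), smoothed electrode-potential steps
persisting to the window end, and short spikes; the per-record artifact
RMS over its support is calibrated to 3.5–6× the clean RMS so corrupted
segments are visually dominated by artifact. `make_study()` draws
seven subjects with mechanical burst coverage 36–60% of a 600 s record,
which puts the raw MA-affected percentage (windowed-RMS criterion,
1 s windows, threshold = clean overall RMS) in the 40–75% range.

What the generator does *not* emulate: genuine equine rhythm disturbances
(second-degree AV block is common at rest), T-wave variability,
respiration coupling, electrode saturation/clipping, and artifacts that
occur *without* accelerometer correlates (e.g. cable tugs). Passing tests
on this generator therefore demonstrate the pipeline's mechanics —
detection, decomposition, thresholding, reconstruction — under controlled
corruption, not clinical performance on real recordings.

## Numerical choices

- **Boundary rule.** Signals are padded to a multiple of $2^J$ by edge
  replication and transformed with circular convolution; the pad is
  trimmed on reconstruction. This keeps perfect reconstruction (≤1e-9 on
  awkward lengths) and exact shift-invariance.
- **Filter convention.** $\sqrt2$-normalized orthonormal taps at every
  level (lowpass $(1,1)/\sqrt2$, highpass $(1,-1)/\sqrt2$); the inverse
  averages the two redundant phase reconstructions, which is exact for
  untouched coefficients and degrades gracefully for thresholded ones.
- **Degenerate inputs.** Empty series, too-short signals and
  length-mismatched channels raise errors rather than truncating; a
  constant accelerometer yields an empty motion set and the pipeline
  becomes an exact pass-through of the band-passed ECG.
- **Ties and edges.** Interval sets are half-open, 0-based, normalized
  (sorted, merged) on construction; frame grids drop trailing partial
  frames; energy comparisons are strict (`>`), so an all-zero signal
  yields no detections.
- **Problem sizes.** The test suite exercises 60–120 s records for module
  behaviour and the full 7 × 600 s study for end-to-end scoring; the
  transform oracles run on length-64 signals where a naive direct-sum
  implementation is practical.

## Known limitations

- **Robust thresholds break down past 50% corruption.** The per-level
  bounds are medians and MADs of per-second frame extrema over the whole
  record. When more than half of the frames at an un-gated level are
  strongly corrupted — raw MA percentages above roughly 50% under the
  windowed-RMS criterion — the bounds inflate toward the artifact scale
  and sub-threshold artifact passes through. The effect is most visible
  in the approximation: with 5 levels at 250 Hz everything below ≈3.9 Hz,
  including most baseline wander, must be caught by the approximation
  bounds. On the synthetic study, subjects below that corruption level
  see 60–90% relative reduction of the MA-affected percentage; subjects
  above it can see almost none. An expert reading a trace would not flag
  threshold-scale residual wander, which is one reason visual scoring of
  the method can look considerably better than this automatic criterion.
- **Single lead, batch operation.** No multi-lead reconciliation and no
  streaming; thresholds are global per record by construction.
- **The comparator is only an ordering baseline.** The NLMS reference is
  nonlinearly related to the injected artifacts, so its cancellation on
  this generator is modest; conclusions about adaptive filtering in
  general should not be drawn from it.
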