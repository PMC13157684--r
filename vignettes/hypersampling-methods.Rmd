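---
title: "Methods: region-specific hypersampling of multiband fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-specific hypersampling of multiband fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperfmri)
```

## The model

A 2D multiband EPI acquisition with `N_Slice` slices, multiband factor
`MB` and repetition time `TR` acquires `MB` slices simultaneously at each
of

$$N_{Time} = N_{Slice} / MB$$

distinct excitation events per TR, nominally spaced $TR/N_{Time}$ apart.
Volume $k$ (0-based), slice $s$ is sampled at $k\,TR + \delta_s$, where
$\delta_s \in [0, TR)$ is the slice's acquisition offset (BIDS
`SliceTiming` convention, referenced to volume start).

Within an ROI whose physiological pulsation is spatially coherent, every
slice samples *the same* regional waveform, just at a different offset.
Hypersampling exploits this:

1. voxels sharing a slice timing are averaged per volume, giving
   $N_{Time}$ series at rate $1/TR$;
2. each series is first-order detrended (removes scanner drift and
   per-slice baseline differences; without it, baseline steps between
   interleaved groups inject spectral lines at multiples of $1/TR$);
3. the series are interleaved in acquisition order, producing one signal
   at the effective interval $TR/N_{Time}$.

The Nyquist frequency rises $N_{Time}$-fold — e.g. from 0.625 Hz to
5.625 Hz for a 72-slice, MB 8, TR 0.8 s protocol — so cardiac pulsations
that alias under per-volume sampling (`alias_frequency(f, 1/TR)`) appear
at their true frequency.

Two modelling consequences are worth stating explicitly, because the
package's validation rests on them:

* **Averaging attenuation.** The conventional ROI mean ignores slice
  timing: it averages $N_{Time}$ copies of a sinusoid at phases spaced
  $2\pi f\,TR/N_{Time}$, attenuating its amplitude by the Dirichlet factor
  $$A(f) = \frac{|\sin(\pi f\,TR)|}{N_{Time}\,|\sin(\pi f\,TR/N_{Time})|},$$
  implemented in `averaging_attenuation()`. $A \to 1$ as $f \to 0$, which
  is why LFO and respiratory power agree between ROI-mean and hypersampled
  measures (slopes near 1), while cardiac power is attenuated by $A^2$
  (≈ 0.64 at 1 Hz for TR 0.366 s, $N_{Time}=5$ — an inverse slope of
  ≈ 1.56) in the ROI mean. The tests verify the measured power ratio
  against $A^2$ to within 5 % at four frequencies on both emulated
  protocols.
* **Propagation dephasing.** Pulsations travel as waves; a component with
  period $T$ and speed $v$ has wavelength $\lambda = T v$. When $\lambda$
  is not large against the ROI extent, spatial averaging (hypersampled
  *and* plain ROI-mean alike) suffers destructive interference, while
  voxel-wise bandpower — power before any spatial averaging — is
  phase-blind. With physiological speeds (cardiac pulse wave ~1–5 m/s,
  respiratory spread ~0.05–0.1 m/s, LFO effectively coherent at ~10–100 s
  periods) respiration has the shortest wavelength and is attenuated most;
  `propagation_sensitivity()` reproduces this ordering on phantoms.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `tol_s` (`build_timing_table`) | 1 ms | offsets closer than this are one timing group; sub-ms jitter is below physiological relevance |
| `gap_policy` (`hypersample_roi`) | `"interpolate"` | linear fill of timing groups with no ROI voxel; `"strict"` errors on any gap; coverage ≤ half is always an error |
| band edges (`make_bands`) | LFO 0.01–0.1, resp 0.2–0.4, cardiac $f_{card}\pm0.15$ Hz | standard physiological bands; cardiac band tracks the PPG-derived heart frequency |
| PPG search range | 0.6–2.0 Hz | 36–120 bpm, covers resting adult heart rates |
| PPG quality floor | 0.3 | fraction of total (> 0.01 Hz) power in the cardiac band; the floor is configuration, not a published constant |
| motion gate | > 1 mm in > 15 % of volumes fails | strict inequalities at both thresholds, unit-tested at the boundary |
| `n_phase_bins` (segmentation) | 10 | cardiac-cycle bins; a pragmatic default, surfaced in the run report |
| `r_threshold` (segmentation) | 0.5 | split-half correlation cutoff; likewise configuration |

## What the phantom emulates — and what it does not

`generate_phantom()` produces the study substrate: per-compartment sums of
sinusoids (one per physiological band, cardiac optionally with $1/h$
harmonics), sampled exactly at each voxel's slice time, with optional
travelling-wave delays $\tau(v) = d(v, \text{source})/v_{comp}$ (Euclidean
distance in mm), a linear per-slice baseline gradient (exercising the
detrend step), additive white Gaussian noise from a single seed, and a
matched peaked PPG pulse train. Ground truth is the exact continuous-time
in-band power $\sum a^2/2$.

Acquisition presets carry the emulated protocols' parameters: `hcp_like`
(72 slices, MB 8, TR 0.8 s, 488 volumes, 2 mm voxels, $N_{Time}=9$) and
`local_like` (40 slices, MB 8, TR 0.366 s, 500 volumes, 2.5 mm voxels,
$N_{Time}=5$). In-plane grids default to a small 8×8 (tests use 4×4–8×8):
compartment structure along x, full slice coverage along z, which is the
dimension that matters for slice timing. The four-compartment default
layout follows the characteristic regional physiology — cardiac-dominant
artery (amplitudes 0.3/0.4/3 for LFO/resp/cardiac), mixed SSS
(1.2/1/2), LFO-dominant GM (2/0.6/0.5) and WM (0.8/0.25/0.3) — with
strictly distinct per-band amplitudes so that "compartment ordering
recovered" is a well-defined check. Default propagation speeds (cardiac
2 m/s, resp 0.1 m/s, LFO coherent) are physiologically ordered test
conveniences, not measured values.

The phantom deliberately omits BOLD neuronal signal, motion, EPI
distortion and k-space effects. Passing tests therefore demonstrate that
the *algorithmic chain* is correct under its stated assumptions
(coherence, exact timing, stationary rates), not that real arteries will
be segmented with Dice 0.9 — real data adds heart-rate variability,
motion, and partial-volume mixtures the phantom does not model.

## Numerical conventions

* **Periodogram**: one-sided, rectangular window, no zero padding, input
  demeaned; PSD $= |X_k|^2/(f_s N)$ with non-DC, non-Nyquist bins doubled.
  Parseval ($\sum \text{psd}\,\Delta f$ = mean square of the demeaned
  input) is enforced as a test invariant at 1e-6 relative. Welch averaging
  is deliberately not used: absolute power is the quantity of interest and
  segment averaging changes its scale and resolution. The implementation
  is verified against an independent $O(N^2)$ DFT in the tests.
* **Bandpower**: sum of psd·Δf over bins whose *centre* lies in the closed
  band. The edge convention is fixed and stated because absolute power
  comparisons depend on it. Bands containing a multiple of $1/TR$ (possible
  stitching residual lines) trigger a warning; they are never trimmed
  silently.
* **Detrending**: least-squares line on a centred time axis (orthogonal
  basis, no matrix solve needed). Detrending the per-group mean equals
  detrending each voxel first — both are linear — and is V× cheaper; a
  test asserts the commutation. Note that a pure sinusoid is *not* exactly
  invariant under first-order detrending at arbitrary phase (the time-ramp
  is not orthogonal to a sine over whole periods); only the
  midpoint-symmetric phase is, which the tests use.
* **Interleaving** places samples on the nominal uniform grid
  $k\,TR + j\,TR/N_{Time}$; if the true offsets deviate from that grid by
  more than 10 % of the spacing a warning is raised (nominal-grid
  periodogram frequencies would then be biased).
* **Gaps**: timing groups with no ROI voxel are invalid positions,
  repeating with period $N_{Time}$; the default linear interpolation keeps
  the uniform grid the periodogram needs. ROIs covering half or fewer
  groups are rejected outright rather than interpolated into existence.
* **Cardiac phase**: beats are local maxima of the ±0.3 Hz band-passed
  PPG (Butterworth order 2, zero-phase, minimum separation half a cardiac
  period); phase is the elapsed fraction between surrounding beats, and
  times outside the detected beat range are masked, not extrapolated. This
  simple detector stands in for unpublished in-house processing and is
  adequate for clean finger PPG.
* **Volume-level phase** for segmentation is evaluated at the mean slice
  offset of the volume — a simplification; per-slice phase assignment is a
  possible refinement.

## Design choices that were genuinely open

* **Slice ordering**: vendors differ (sequential vs interleaved multiband
  group order); the sidecar is the source of truth and always wins, with
  derived parameters accepted only when they agree within 1 ms per slice.
  The phantom's parameter mode defaults to sequential group order.
* **Group-series normalization**: group series are detrended but *not*
  variance-normalized before stitching; normalization would distort
  absolute bandpower, the core quantity.
* **Regression scale**: hypersampled-vs-reference power comparisons use
  OLS with intercept on raw power (the relationship of interest is a
  proportionality of absolute powers); `log = TRUE` is available.
* **Segmentation split**: the split-half is a seeded random permutation
  into two equal halves; a `"duplicate"` mode (both halves = all volumes)
  exists as a self-check that must return r = 1 exactly.
* **Coverage/motion boundary semantics** are encoded exactly as strict
  inequalities ("more than 15 %", "more than half") and tested at the
  boundary (4/9 fails, 5/9 passes; exactly 15 % passes).

## Problem sizes used by the test-suite and acceptance analyses

Simulated scans keep the presets' full slice counts and volume counts
(488/500) with small in-plane grids (4×4–8×8); the attenuation and
un-aliasing analyses use noiseless single-tone phantoms; amplitude
recovery uses 20 seeds at noise SD 1 (strongest amplitude 3, i.e. SNR 3);
the slope analysis emulates 19 scans with log-normal between-scan
amplitude variability (SD 0.3) and heart rates uniform in 0.9–1.1 Hz;
vessel recovery uses a 2×2×12-voxel vessel in an 8×8×20 grid at cardiac
amplitude 5× noise.

## Known limitations

* **Split-half correlation under strictly periodic sampling.** With a
  heart rate exactly commensurate with TR (e.g. 1.0 Hz at TR 0.366 s),
  volumes landing in the same cardiac-phase bin recur quasi-periodically;
  if that recurrence time resonates with a coherent slow oscillation, the
  LFO leaks systematically into *both* halves' binned waveforms and
  inflates the correlation of non-vascular voxels. Real heart rates are
  neither constant nor TR-commensurate, and the phantom scenario uses
  1.07 Hz; with a 10-bin waveform the null false-positive rate at
  r ≥ 0.5 is still ~5–7 %, which is why search regions should be tight
  (the shipped scenario dilates the true vessel by one voxel, mirroring
  how anatomical search regions are constructed by dilation).
* **No motion handling.** Hypersampling requires uncorrected data (motion
  correction destroys slice timing); the motion gate excludes bad scans,
  it does not fix them.
* **Respiratory estimates in large ROIs** are attenuated by propagation
  dephasing (see above) and should be read as lower bounds.
* **Group-level modelling** (mixed-effects age/sex analyses, FDR) is out
  of scope by design; `write_bandpower_table()` exports the long-format
  table such models consume.
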