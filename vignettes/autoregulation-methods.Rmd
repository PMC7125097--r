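---
title: "Correlation and wavelet-semblance monitoring of cerebrovascular autoregulation"
author: "autoregwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation and wavelet-semblance monitoring of cerebrovascular autoregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autoregwave)
```

## The monitoring problem

Cerebrovascular autoregulation holds cerebral blood flow roughly constant
across a range of arterial blood pressure (ABP). Below the lower limit of
autoregulation (LLA) flow becomes pressure-passive; somewhere above the LLA
there is an optimal pressure (ABPopt) at which vasoreactivity is most
robust. Continuous autoregulation indices estimate the state of this system
from the coupling between ABP and a surrogate of flow or cerebral blood
volume in the slow vasogenic band (0.007–0.05 Hz):

* **PRx** — moving Pearson correlation between 10-s means of ABP and
  intracranial pressure (ICP);
* **COx** — ABP vs NIRS regional oxygen saturation (rSO2, a flow
  surrogate);
* **HVx** — ABP vs NIRS relative total hemoglobin (rTHb, a blood-volume
  surrogate);
* **wPRx / wCOx / wHVx** — the wavelet counterparts: the *semblance*
  (cosine of the wavelet phase difference) between the same channel pairs,
  averaged over the scale–time points whose wavelet coherence is high
  enough to trust.

Pressure-passive coupling is in-phase (index near +1); active
vasoreactivity produces a phase shift (index near or below 0). All six
indices are therefore low above the LLA and rise toward +1 below it.

## Processing chain

1. **Block averaging** (`block_average`): every channel is reduced to
   consecutive, non-overlapping 10-s means. This removes pulse and
   respiratory waveforms; what remains are the slow waves. Any invalid
   sample marks its whole epoch missing.
2. **Correlation indices** (`moving_index`): Pearson correlation over a
   trailing window of 30 epochs (300 s), advanced every epoch. Windows
   with more than 25 % missing epochs, or zero variance, yield missing
   values.
3. **Wavelet indices** (`semblance_index`): complex Morlet continuous
   wavelet transform (centre frequency 6) of each channel on a scale grid
   of 12 voices per octave spanning 0.007–0.05 Hz; cross-spectrum,
   auto-spectra and coherence smoothed in time and scale; phase estimates
   with squared coherence below 0.46 discarded; the cosine of the
   surviving phase differences averaged within the central 300 s of each
   trailing 800-s window, one value per 10-s step.
4. **LLA** (`find_lla`): exhaustive two-segment piecewise regression of
   LDF on ABP over a 1-mmHg breakpoint grid (at least 3 points per
   segment, ABP-sorted pairs); the LLA is the intersection of the two
   least-total-SSE lines, ties broken toward the lower breakpoint.
5. **ABPopt** (`multiwindow_abpopt`): above-LLA (median ABP, mean index)
   pairs from non-overlapping 5-min windows are sorted into half-open
   5-mmHg bins between 20 and 100 mmHg; index values are clipped to
   |r| ≤ 0.99 and Fisher-transformed; a count-weighted quadratic is fitted
   per window for twelve nominal window lengths from 2 to 4 h; the final
   ABPopt is the weighted mean of the window vertices with weight
   `w_len · w_err · w_shape` (length weight falling linearly from 1.0 at
   2 h to 0.5 at 4 h; error weight `1/(1 + RMS fit error)`; shape weight
   1 for a full U, 0.5 for a half U, 0 otherwise).
6. **Evaluation** (`cohort_stats`): per-animal above/below-LLA mean pairs
   feed a paired ROC (Mann–Whitney AUC, Youden cutoff, Clopper–Pearson
   CIs, DeLong comparisons); above-LLA index SDs are compared by paired t;
   wavelet vs correlation ABPopt by Pearson correlation and Bland–Altman
   limits of agreement.

## Design choices worth knowing about

**Windowing by aggregation.** The wavelet transform and its smoothed
coherence are computed once over the full record; the 800-s moving window
with ~500 s of edge rejection is then realized as a moving average of
cos(phase) over the central 300 s of each trailing window. Per-window
transforms trim their edges precisely because each window has its own edge
artifacts; a full-record transform has none away from the record ends
(masked by the cone of influence), so the aggregation view is equivalent
and far cheaper. Record-end epochs inside the cone of influence
(`sqrt(2) · scale`) are excluded.

**Coherence smoothing and the 0.46 gate.** Unsmoothed wavelet coherence is
identically 1, so the gate only means something relative to a smoothing
kernel. We smooth the cross- and auto-spectra with a scale-proportional
Gaussian in time (SD = 3 × scale) and a 0.6-octave boxcar across scales,
calibrated so that two independent noise series exceed coherence 0.46 at
only ~4–5 % of scale–time points — the fixed threshold then behaves like a
significance test. Both widths are exposed in `wavelet_config()`. A window
whose averaging region retains fewer than 10 % of its in-band points is
reported missing rather than averaged from a sliver of survivors
(`min_retained_frac`).

**Correlation window step.** Correlation windows advance every 10 s so
that correlation and wavelet indices share timestamps for the paired
statistics; windows are trailing, stamped at their end.

**Quadratic vertices.** The U-curve fit is a count-weighted least-squares
quadratic on the Fisher-z bin means. Curvature below 1e-10 is classified
as shape `none`; a positive-curvature vertex outside the occupied span is
a `half_u` whose reported vertex is clamped to the span (the optimum is
never extrapolated outside observed pressures). The curve-fit error is the
root mean squared difference between bin means and fitted values.

**Degenerate inputs.** Constant channels give missing correlations, not
errors; a single straight pressure–flow line raises a
degenerate-intersection error (no breakpoint exists); fewer than 4
occupied bins yield no vertex; paired t on zero-variance differences is a
defined error.

## The synthetic piglet cohort

Real piglet recordings are not redistributable, so every claim the
package tests is exercised on a simulator (`generate_recording`) whose
ground truth is known by construction. It emulates the hypotension
experiment: ABP holds at `abp_start` (85 mmHg) for a quarter of the 4-h
recording, then ramps linearly to `abp_end` (25 mmHg), crossing the
planted LLA; vasogenic slow waves (a sum of 8 log-spaced sinusoids in
0.007–0.05 Hz, SD 3 mmHg) ride on the ramp, waxing and waning under a
slow amplitude envelope, because real slow waves are intermittent.

Couplings are *phase lags*, not sign flips: a channel with cosine-profile
c(ABP) receives `c·s + sqrt(1−c²)·q`, where `q` is the quarter-cycle
delayed copy of the slow waves — a pure lag of `acos(c)`. Below the LLA
all channels are pressure-passive (lag 0); above it the volume channels
(rTHb, ICP) develop a lag whose cosine dips to −1 at the planted optimum
(Gaussian activity peak, SD 25 mmHg), and the flow channel (LDF, hence
rSO2) is attenuated toward a residual passivity of 30 % and led by up to a
quarter cycle, most strongly at the optimum (SD 15 mmHg; flow
stabilization is narrower than volume reactivity). The planted optimum is
therefore the argmin of every index's expected value by construction. The
lag is mildly frequency-dependent (slower waves lead more,
`phase_disp_exp = 0.15`), reflecting the high-pass character of
autoregulation.

Two further realism terms matter for the statistics. White observation
noise on each channel sets the sampling noise of the 30-sample
correlations. Smooth *sub-band drifts* (periods ~8–80 min, independent per
channel) emulate systemic trends — CO2, temperature, oximeter baseline —
that corrupt time-domain correlations but lie below the analysis band, so
the wavelet indices ignore them. These drifts are the main reason the
wavelet indices come out less variable, which is also the mechanism
usually offered for that observation in real recordings. An optional
artifact-burst process exists (`artifact_rate_per_h`) but defaults to off.

Defaults were chosen once, on the physiological grounds above, as the
cohort's study conditions: LLA drawn uniformly from 35–55 mmHg per animal,
optimum at LLA + 20 mmHg (mid-span of the autoregulated range), ICP
baseline 10 mmHg, rSO2 = 50 + 20·(LDF − plateau)/plateau clamped to
[0, 100]. Signals are generated at 1 Hz and sample-held to the declared
rate; every analysis consumes 10-s means, which the hold leaves unchanged.

**What the simulator does not model:** pulse and respiratory waveforms
(removed by the averaging anyway), biophysical hemodynamics (no
Windkessel), an upper limit of autoregulation, ICP plateau waves, or
measurement dropouts. Passing tests therefore demonstrate that the
pipeline recovers truth under idealized-but-noisy slow-wave physiology,
not that it is robust to every failure mode of real monitoring data.

## Problem sizes and numerical tolerances

The test suite exercises 4-h recordings at 1 Hz (1440 epochs), a
50-recording cohort for parameter recovery and a 30-animal cohort for the
evaluation statistics; one full animal takes on the order of a second.
Exact oracle equivalences (moving correlation vs the covariance formula,
breakpoint search vs an exhaustive `lm()` scan, quadratic vertices vs
normal equations, AUC vs pairwise concordance, DeLong variance vs
structural-component enumeration, block means vs brute-force slicing) are
asserted at 1e-9 or tighter; wavelet coefficients match a
direct-integration oracle within 2 % away from record ends; analytic
semblance checks use in-phase, anti-phase and quarter-period-lag
sinusoids.

## Reading real data

`read_recording_csv()` ingests the package's CSV schema (`time_s,
abp_mmhg, icp_mmhg, rso2_pct, rthb_au, ldf_au`; blank or NaN for missing)
and infers the sample rate from the time column; mapping a public deposit
onto that schema is the user's responsibility, since column conventions
vary between archives.

## Known limitations

* The weight formulas of the multi-window ABPopt combination follow the
  published description qualitatively (shorter windows and better, fuller
  U-shapes weigh more); the exact published coefficients are not public,
  so the defaults here are declared, pluggable choices.
* The 0.46 coherence threshold is taken as given; its operating
  characteristics depend on the smoothing kernel, which is why the kernel
  here is calibrated against the independence null and both are exposed
  as configuration.
* Only the final per-recording ABPopt is produced (one optimum per
  hypotension run), not a continuously updating trace.
* The SD-reduction contrast for the COx/wCOx pair is the weakest of the
  three under the default cohort: simulated COx is strongly attenuated by
  rSO2 noise, which caps its own variability. The contrast's direction is
  stable; its paired-t significance at n = 30 is not guaranteed for every
  seed.
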