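---
title: "Methods: multitaper band-power contrasts and bootstrap ROI statistics for iEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multitaper band-power contrasts and bootstrap ROI statistics for iEEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ieegpower)
```

## The analysis in one paragraph

Given multi-channel depth-electrode (sEEG) recordings spanning consecutive
drug conditions — here baseline, a subanesthetic ketamine infusion, and a
propofol bolus — the pipeline conditions the raw signal (notch, resample,
detrend, exclude, bipolar montage), estimates a multitaper spectrogram per
derived channel, averages raw power over the windows falling entirely
inside each condition, converts to decibels, and differences conditions
bin by bin. Per-channel dB differences are aggregated over frequency
bands, channels are grouped by coarse anatomical region, and each (region,
band, contrast) cell is summarised by its channel-pooled mean with a
percentile-bootstrap 95% CI; a cell is called an *increase* when the whole
interval is above zero, a *decrease* when below, and *no change*
otherwise. Every stage is deterministic given the run seed.

## Signal conditioning

**Chain order is fixed**: notch → resample → detrend → exclusion →
bipolar. Intervals are half-open `[start, end)` in seconds with
zero-based sample index `floor(t·fs)`, so adjacent epochs never share a
sample.

**Notch.** Line noise at 60 Hz and every harmonic below Nyquist is removed
with a zero-phase band-stop per harmonic: a 4th-order Butterworth with
±1.8 Hz edges whose forward–backward (magnitude-squared) response is
applied in the frequency domain; a time-domain `filtfilt` realization is
available (`method = "filtfilt"`) and agrees away from the signal edges.
The edge width was chosen so the two-pass response is ≥30 dB down within
±1 Hz of each harmonic yet changes the spectrum by <1 dB at 3 Hz or more
away. A second-order notch biquad cannot achieve both at once — its
magnitude rises only first-order in the frequency offset — which is why a
higher-order band-stop is used.

**Resampling** (2000 → 500 Hz by default) is FFT-domain: the spectrum is
truncated at the new Nyquist with a short raised-cosine rolloff (top 8% of
the new band), with one second of reflection padding against edge
wrap-around. This is zero-phase, has exactly unit passband gain, and
leaves the PSD of content below the rolloff untouched; time-domain
polyphase resamplers we measured had either passband gain errors or weak
alias stopbands. Output length is `round(n · target_fs / fs)`.

**Detrending** removes the least-squares straight line per channel over
the *entire* recording (not piecewise), leaving exactly zero residual mean
and slope; it is idempotent.

**Exclusion and montage.** Channels flagged `excluded` in the channel
table (the stand-in for visual artifact screening) are dropped before
montage derivation. The bipolar montage pairs adjacent surviving contacts
on the same shank (positions p, p+1; 1 = deepest): derived trace = deeper
minus shallower, derived label = the deeper contact's label (the common
sEEG convention), derived id `"shank:p-p+1"`. An excluded contact breaks
the chain — pairs are never bridged across a gap; this conservative choice
avoids derivations across long inter-contact distances. A shank with
fewer than two survivors contributes nothing (warning, not error). The
derived count per shank therefore equals the number of surviving adjacent
position pairs, which the tests verify against exhaustive enumeration.

## Multitaper estimation

Windows of `T = 2` s slide in steps of 1.5 s ("0.5 s overlap" is read
literally as seconds of overlap, not 50%; a fractional reading is
available via `overlap_unit = "fraction"`). Each window is tapered with
the `K = 5` leading discrete prolate spheroidal sequences for `NW = 3`,
computed from the classical symmetric tridiagonal eigenproblem; taper
energy concentrations come from the sinc kernel and are strictly
decreasing, with the leading concentration above 0.99. Per-taper
periodograms are averaged with **uniform weights** — no adaptive
(Thomson) weighting, matching common Chronux-style usage; adaptive
weighting, jackknife spectral CIs and coherence are out of scope.

Scaling is one-sided density in units²/Hz: interior bins doubled, DC and
Nyquist not, so the PSD integral over `[0, fs/2]` equals the signal
variance (the tests check this to 5% for white noise, and that a unit
sinusoid's mass stays within the half-bandwidth `W = NW/T = 1.5` Hz).
Frequency resolution is `1/T = 0.5` Hz; the full analysis bandwidth is
`2NW/T = 3` Hz. Trailing samples that do not fill a window are discarded;
window count is `floor((dur − T)/step) + 1`.

**Condition means and contrasts.** A window belongs to a condition only if
it lies entirely inside that condition's interval (a 1 ns tolerance
absorbs floating-point boundary error); straddling windows belong to
nothing. Raw power is averaged arithmetically over assigned windows, then
converted to dB (`10·log10`; exact zeros map to a −300 dB floor with a
warning; negative power is an error). Band aggregation over the half-open
`[f_lo, f_hi)` grid — so adjacent bands such as beta 15–25 and gamma 25–55
never share a bin — defaults to the **mean per-bin dB difference**. A
**sum-over-bins** mode exists because summing, rather than averaging, dB
differences across bins (and possibly windows) is the only way per-ROI
contrasts can reach hundreds of dB, as published tables in this literature
sometimes show; the package implements both and asserts neither as the
only correct reading. The mode is recorded in every output row.

## ROI statistics

Fine DKT-40 labels map to 15 coarse groups (14 for the propofol analysis,
which lacks striatum coverage); the maps ship both in code
(`dkt_label_map()`) and as editable TSVs under `inst/extdata/`. Channels
with unmapped labels are dropped with a logged count.

For each (ROI, band, contrast), channels pooled across subjects are the
resampling unit: `n_boot = 10,000` resamples with replacement, percentile
(2.5th, 97.5th) interval of the resampled means. Percentile — not BCa —
is the minimal reading of "bootstrap CI"; subject-level resampling is
deliberately not the default because the pooled-channel analysis treats
channels as the unit. Per-cell seeds derive from the run seed plus the
cell index, so results are reproducible and independent of evaluation
order. **No multiple-comparison correction** is applied: the analysis
reports effect sizes with CIs rather than p-values, and the manifest
records this. Contrast spectra (`roi_spectrum()`) reuse the same engine
at every frequency bin, resampling whole channels so the replicate
spectra stay smooth.

Degenerate cases behave as expected: a constant value vector yields a
point interval at that value; a single-channel ROI yields a degenerate CI
at that channel's own spectrum; an empty ROI is an error.

## The synthetic generator

The generator emulates the recording context of the motivating study:
2000 Hz sampling; condition epochs of 300 s baseline, 840 s ketamine,
235 s propofol (the modal published per-subject durations); 10 shanks ×
10 contacts per subject covering all 15 coarse regions; a 1/f background;
60 Hz line noise with harmonics; and condition-dependent band-limited
power changes assigned by anatomical label, with 10 subjects per study.

**Background**: Gaussian noise spectrally shaped to `(f² + f_knee²)^{−β/2}`
with β = 2 and a 0.3 Hz knee by default. The knee bounds infra-slow power
the way amplifier high-pass filtering and the physiology of recorded field
potentials do; an unbounded `f^{−2}` law concentrates so much power below
0.5 Hz that far-sidelobe leakage visibly biases mid-band estimates, which
is unrealistic as well as inconvenient. The log–log slope above the knee
is −β exactly by construction.

**Line noise** shares its phase across contacts of a subject with a ±20%
per-contact amplitude jitter, so bipolar derivation cancels most but not
all of it — as in real recordings.

**Effect injection** targets an exact band-power ratio `r = 10^{Δ/10}`
over a condition interval, with a 2 s cosine ramp at the edges (invisible
to a 2 s estimation window). Increases add an independent band-limited
Gaussian process with power `(r − 1)·P_band`, where `P_band` is measured
from the trace itself; decreases scale the trace's own band content
(extracted with a zero-phase brick-wall mask) by `√r`. Subtracting an
*independent* process cannot reduce power, so suppression necessarily
operates on the signal's own band content; both paths leave out-of-band
power untouched. Per-subject seeds derive from the master seed plus a
counter, so multi-subject studies are reproducible and bit-identical under
a fixed config.

**What the generator does not emulate**: epileptiform discharges, volume
conduction and spatial correlation between shanks, pharmacokinetic drug
dynamics, non-stationarity within a condition, and heterogeneous
per-subject electrode plans. Passing tests therefore demonstrate estimator
and inference calibration under a controlled forward model, not robustness
to every artifact of clinical recordings. Published per-ROI dB statistics
from patient data are estimator outputs on recordings that are not
available, and are not targets; the generator mirrors only the *sign
topography* of the reported drug effects (frontal gamma up under ketamine
then reversed, occipital alpha down then further down, posteromedial
3–4 Hz up under both drugs), with moderate magnitudes of our choosing
(default +6/−8/+3 dB relative to baseline).

## Calibration checks: design choices worth knowing

Two properties of the multitaper estimator shape how parameter-recovery
checks must be designed, and both are visible in real analyses too:

- **Band-edge kernel bias.** The estimate at a bin averages the true
  spectrum over ±W = 1.5 Hz. Bins within W of a band-limited effect's edge
  therefore see a diluted ratio, and a narrow band such as 3–4 Hz has *no*
  interior bins. Recovery checks consequently inject effects whose support
  is padded by W beyond the analysed band, so every analysed bin's kernel
  sits wholly inside the affected region; without padding the recovered
  mean is biased toward zero by an amount that depends on band width. The
  unpadded default effects remain appropriate for sign-level topography
  checks.
- **Sidelobe leakage floor.** Power reaching a bin through the averaged
  taper sidelobes (a fraction of order 10⁻³ of the energy a few bandwidths
  away, more from the very energetic infra-slow range) sets a floor under
  deep suppressions: attenuating the bare 1/f background by 15 dB cannot
  be observed at 15 dB. The suppression check therefore attenuates an
  alpha *rhythm* standing 10 dB above background — the physiologically
  meaningful scenario — which keeps the residual above the leakage floor.
  A related visible effect: strongly suppressing a big low-frequency
  rhythm slightly lowers neighbouring-band estimates (fractions of a dB)
  because less of its power leaks there.

**Independence and the bootstrap.** Adjacent bipolar channels derived from
a common contact share that contact's noise; their band-power estimates
correlate (≈ 0.25 for chained pairs). The channel-resampling bootstrap —
which mirrors the published procedure — assumes exchangeable channels, and
under that correlation its CIs are somewhat anti-conservative (no-change
rates near 0.89 instead of 0.95 in our measurements). The type-I-control
checks therefore use electrode plans with two contacts per shank, whose
derived channels are independent, isolating the property being tested;
the correlation itself is a genuine limitation of channel-level
resampling on chained montages and would equally affect analyses of real
recordings. Subject-level resampling (`bootstrap_roi_ci` on per-subject
summaries) is the usual remedy when it matters.

## Numerical and bookkeeping details

- DPSS polarity: symmetric tapers have positive mean; antisymmetric tapers
  a positive leading lobe. Orthonormality holds to 10⁻⁸ (measured ~10⁻¹⁵),
  and taper k has exactly k−1 sign changes.
- `K ≤ 2NW` is enforced; super-resolution tapers are poorly concentrated.
- EDF export quantizes to 16 bits over each channel's range (relative
  error ≤ 2 quantization steps round trip); constant channels get a unit
  physical range to avoid division by zero. Partial trailing data records
  are dropped with a warning.
- The spectral container persists as an `.rds` with documented fields
  (`power`, `freqs`, `times`, `params`).
- The audit treats published per-subject bipolar counts as inputs: the
  ketamine cohort sums to 824 as printed, while the seven propofol
  subjects' counts sum to 607 against a printed 606 — the audit flags,
  and does not resolve, such discrepancies.

## Problem sizes used by the test suite

Unit and acceptance tests run at sizes chosen as the smallest that leave
the measured property unchanged: calibration checks use 1–5 minutes of
single-channel signal; end-to-end recovery uses one 10-contact shank with
two 300 s epochs at the full 2000 Hz rate (exercising the complete
conditioning chain including 4× downsampling); bootstrap coverage uses 500
Monte-Carlo replicates of n = 100; null-classification control uses 300
generator runs of 60 two-contact shanks at 250 Hz with 24 s epochs; and
the topography check uses 20 seeded two-subject studies with three 40 s
conditions. The full-size default study (10 subjects × 100 contacts ×
1375 s at 2000 Hz) runs through exactly the same code paths.
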