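---
title: "Quantifying NREMS oscillations: spectra, spindles, slow oscillations and their coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NREMS oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleeplfp)
```

## The analysis problem

Local field potential (LFP) and EEG recordings of non-rapid-eye-movement
sleep (NREMS) contain three oscillatory signatures of thalamocortical
origin: the slow oscillation (SO, 0.5–1.5 Hz), reflecting the alternation
of cortical active ("UP") and silent ("DOWN") states; delta waves
(1.5–4 Hz); and sleep spindles, waxing–waning 9–16 Hz bursts generated in
the thalamus and paced by the inhibitory reticular nucleus. Genotype or
intervention effects in rodent sleep studies are typically read out as
(i) shifts in normalized band power, (ii) changes in discrete spindle
events (density, amplitude, intra-spindle frequency), and (iii) changes in
how spindle onsets phase-lock to the SO. `sleeplfp` implements this whole
chain as a tested, deterministic pipeline operating on a recording plus an
epoch-based hypnogram, together with a synthetic generator that provides
exact ground truth for every stage.

All intervals are half-open `[start, end)`, sample `i` (1-based) of a
trace maps to time `start_time_s + (i-1)/fs`, and times are seconds as
doubles. Vigilance states are scored per whole 4 s epoch; epochs are never
subdivided, and artifact or unknown epochs break NREMS runs rather than
extend them.

## Consolidated NREMS

Analyses are restricted to consolidated NREMS: maximal runs of NREMS
epochs *strictly longer* than 20 s (a five-epoch, 20 s run is excluded;
six epochs are included). The strict inequality is a deliberate reading of
the ">20 s" convention. Signal is cut per bout and windows of any
downstream computation never span bout boundaries.

## Spectral quantification

Power spectra are computed on raw signal as the squared-magnitude FFT of
consecutive non-overlapping 4 s rectangular windows (0.25 Hz resolution),
each window offset-corrected by subtracting its mean; remainder samples at
the end of a bout are dropped. No taper or overlap is used — the estimator
is the plain squared FFT, and all windows are averaged with equal weight
regardless of which bout or recording day they come from (per-segment
weighting is not applied; with roughly equal bout lengths the difference
is negligible, and the windowed average is the simplest estimator
consistent with equal-epoch scoring).

The averaged spectrum is normalized by its sum between 0 and 35 Hz
(the 35.00 Hz bin inclusive) and expressed in percent, making spectra
comparable across animals and amplifier gains. Band powers are sums of
density bins with a half-open `(lo, hi]` assignment, so the 1.5 Hz bin
shared by the SO (0.5–1.5 Hz) and delta (1.5–4 Hz) bands counts toward the
lower band only and adjacent bands partition the axis exactly; a band
starting at 0 Hz also includes the 0 Hz bin. With this rule the band sum
approximates the continuous integral to within one bin width.

The delta time course used for pharmacological interventions takes the
per-epoch delta-band area (one 4 s window per epoch of consolidated
NREMS), splits the baseline and post-injection epoch series in temporal
order into bins of identical epoch counts (12 and 36 by default; remainder
epochs go to the earliest bins — a deterministic tie-break), averages each
bin and normalizes everything by the mean of the first two baseline bins.

## Spindle detection

Detection runs on the squared power of the band-passed "enlarged sigma"
band (9–16 Hz), computed with a zero-phase (forward–backward) Hamming FIR
filter whose order follows from a 2 Hz transition width (≥53 dB stop-band
per pass). The raw squared signal oscillates at twice the carrier
frequency and would fragment any threshold crossing, so a 100 ms centered
moving average is applied before thresholding; the length is exposed as
`smooth_s`. This smoothing is the one necessary interpolation of the
method: some amount of envelope extraction is implied by thresholding
"sigma power", and 100 ms (one spindle cycle) is the shortest window that
removes the carrier ripple without merging distinct events.

The threshold is `mean + 1.5 × SD` of the envelope restricted to all
consolidated-NREMS samples of the recording — a single per-signal
threshold, not per bout, and population SD (at the sample sizes involved
the sample/population distinction is far below any other source of
variation). No amplitude normalization is applied before detection.

Within each bout, maximal supra-threshold runs become events if the
band-passed signal inside the run completes at least three full cycles
(counted from zero crossings: `floor((crossings − 1)/2)`); a
fixed-duration variant (240 ms ≈ 3 cycles at 12.5 Hz) is available via
`min_cycles_mode = "fixed"`. The cycle criterion is applied to the
supra-threshold core, before boundary extension — the stricter of the two
possible orderings. Event boundaries then extend to the nearest zero
crossing of the filtered trace before the onset and after the offset.
Events that overlap or are separated by less than 10 ms are fused,
transitively; fusion is final (the cycle criterion is not re-applied).
Events touching the first or last sample of their bout are discarded.

Each event is characterized by its mean sigma power between onset and
offset (µV²) and by its intra-spindle frequency: the in-band peak of the
magnitude FFT of the event segment, zero-padded to 0.25 Hz resolution,
computed on the band-passed segment by default (the raw segment is
available by flag; band-passing prevents SO/delta leakage from dominating
short windows). A peak counts as *distinguishable* only if it is a local
maximum at least twice the median magnitude of the in-band bins more than
2 Hz away from it. Excluding a ±2 Hz zone around the peak from the
reference level matters: a 0.5 s spindle's spectral mainlobe spans several
Hz, so a median over the whole band would be dominated by the peak's own
mainlobe and even clean bursts would be rejected. Events without a
distinguishable peak carry `NA` frequency and are excluded from
frequency averages (their share is reported).

## Slow-oscillation detection

The signal is low-passed at 2 Hz (zero-phase FIR, 1 Hz transition).
Within each bout, every consecutive pair of a negative half-wave followed
by a positive half-wave — delimited by zero crossings — yields a
candidate with trough `(x1, y1)`, peak `(x2, y2)` and the bounding
crossing times. Candidates are selected as SO events when all three
criteria hold: trough-to-peak time within [0.5, 2] s (inclusive, the
natural reading of "comprised between"); `y1` more negative than 2/3 of
the mean trough `Y1`; and peak-to-peak `y2 − y1` at least 2/3 of the mean
`Y2 − Y1`. The means are taken over **all** candidates of the recording's
NREMS (not per bout, and not only over large cycles — an open choice
documented here). All three criteria are ratios or time-based, so the
selection is exactly invariant under amplitude scaling.

The "SO period" used downstream is `[zc_pre, zc_post]` — from the zero
crossing before the trough to the crossing after the peak, one full
falling-zero-to-falling-zero cycle. This is our concrete definition of the
event extent (the selection criteria themselves do not fix one) and it is
exposed through the result columns rather than hard-wired.

## Phase coupling

Spindles are paired to SO events when at least 95% of the spindle interval
falls inside a single SO period (the SO of maximal overlap; ties go to the
earlier one). The SO phase at each included spindle onset is the argument
of the analytic signal (Hilbert transform) of the 2 Hz low-passed trace,
computed per NREMS bout so that FFT edge effects stay at bout margins.
The convention is 0° at the SO positive peak and ±180° at the trough, so
the rising trough-to-peak flank spans (−180°, 0°) — the cortical active
state (AS) — and [0°, 180°] is the silent state (SS), with the boundary
phases 0° and 180° assigned to SS (half-open convention). LFP polarity
depends on referencing; `invert_polarity = TRUE` flips the mapping.
Occurrence histograms tile (−180°, 180°] with half-open 30° bins by
default (the width is configurable; no canonical value exists).

One geometric property of the 95% containment rule deserves emphasis: a
spindle whose onset falls shortly before the end of an SO period cannot be
95% contained in it, so onset phases in roughly (10°, 90°) are
structurally under-represented among *included* spindles. This is the
rule's purpose — it selects spindles nested in an SO — but it means a
uniformly phased spindle population does not return an exactly 50% AS
share through the filter. Tests of phase-estimator neutrality therefore
measure phases at detected onsets without the containment pairing
(`min_overlap = 0`), while preference-recovery tests run the full
filtered pipeline.

## The synthetic generator

`generate_recording()` builds, deterministically from one master seed and
a single RNG stream: a 1/f^a Gaussian background (default a = 1, 30 µV
RMS) everywhere; and, within NREMS bouts only, an SO sinusoid (0.6 Hz,
150 µV), a delta-band (1.5–4 Hz) filtered-noise component (50 µV RMS) and
discrete spindle bursts, all tapered over 1 s at bout edges. Spindles are
Hann-enveloped sinusoids (`make_spindle_waveform()`: exact peak amplitude,
zero ends, ≥3 carrier cycles enforced), injected additively — no
amplitude coupling to the SO beyond the onset-phase preference, the
simplest structure the downstream analyses require. Counts are Poisson at
`spindle_rate` per NREMS minute; carriers are drawn at 11 ± 0.5 Hz
(clamped to 9–16 Hz), durations at 0.7 ± 0.08 s, amplitudes jittered ±10%
around `spindle_amp`. Onset phases are von Mises draws (`phase_kappa = 0`
gives the circular uniform) around `phase_pref_deg`, default −150° — the
early active state shortly after the trough, where rodent spindle onsets
concentrate. Placement rejects spindles that would leave the bout core or
come within 0.25 s of another spindle (25 retries, then the event is
skipped, counted and warned about).

Ground-truth spindle `onset_s`/`offset_s` are the **half-maximum points**
of the injected envelope; the nominal support (zero-amplitude edges) is
reported separately. The support edges carry literally no signal, so no
detector — or human scorer — could mark them; the half-max extent is the
observable event, and the drawn SO phase is anchored to it. Detector onset
accuracy (median ≈ 30 ms on the default conditions) is measured against
these observable onsets.

Defaults were fixed once, before any detector tuning, from the recording
conditions the analysis assumes (1 kHz sampling, 4 s epochs, the band
definitions above) plus amplitude/rate choices representative of rodent
cortical LFP; the SO frequency (0.6 Hz) and spindle duration (0.7 s) were
additionally checked analytically so that spindles fit inside SO periods
often enough for the coupling stage to be testable. What the generator
does *not* emulate: non-stationary spindle grouping (infra-slow
modulation), SO–delta waveform asymmetry, amplitude–phase coupling,
movement or electrode artifacts, and multi-channel volume conduction.
Passing tests therefore demonstrate correctness of the *computations*
under the stated signal model, not detector performance on real data.

The presets encode the qualitative contrasts the pipeline is meant to
resolve: `wt_s1` (spindle-rich, SO-dominated), `ko_s1` (spindle rate and
amplitude strongly reduced, SO reduced, delta over-represented — a
low-threshold-calcium-channel-knockout-like phenotype) and `wt_pfc`
(SO-dominated with weak spindles). Preset rates and amplitudes are free
parameters chosen for testability, not claims about mouse physiology.

## Group statistics

`group_compare()` follows the reporting convention of two-group
electrophysiology studies: Shapiro–Wilk normality screen (α = 0.05 —
the screen level is not canonical and is exposed), then Student's t-test
for normal data or Mann–Whitney (unpaired) / Wilcoxon signed-rank
(paired) otherwise. When more than two comparisons share a data set the
Bonferroni-adjusted α is reported alongside each test — for the three
canonical bands, 0.05/3 ≈ 0.017.

## Numerical choices and degenerate inputs

* FIR orders come from `3.3 × fs / transition` (Hamming); filters are
  applied forward–backward with odd edge extension, so passband gain is
  squared (ripple negligible) and stop-band attenuation doubles.
* The Hilbert transform zeroes negative FFT frequencies; phases are
  mapped to (−180°, 180°] with −180° folded to +180°.
* Zero crossings are linearly interpolated between samples; event times
  inherit that sub-sample precision.
* A constant window has zero spectral power; normalizing an all-zero
  spectrum is an error, as is a hypnogram without NREMS, an empty
  threshold input, or a band with inverted edges. An empty candidate set
  yields an empty SO table with `NA` summary and a warning, and an empty
  phase set yields an empty histogram.
* Equal-epoch binning distributes remainder epochs to the earliest bins.

## Problem sizes in the test suite

The shipped tests exercise the full pipeline on scenes of 1–38 minutes of
synthetic NREMS at the native 1 kHz (shorter or lower-rate scenes where
only the algebra is at stake), sizes chosen so the whole suite documents
the method's behaviour — recovery, calibration, invariances — while
remaining quick to run routinely. The acceptance script
(`scripts/acceptance.R`) regenerates every reported quantity from scratch
at those same sizes.

## Known limitations

* Thresholding is per recording; drifting sigma power across a long
  recording would bias detection toward high-power episodes.
* The intra-frequency "distinguishable peak" rule is an explicit
  interpretation (prominence ≥2× the out-of-mainlobe in-band median);
  other reasonable rules shift the reported share of frequency-carrying
  events.
* The SO period definition (full cycle between falling zero crossings) is
  one of several defensible extents; coupling fractions depend on it
  through the containment filter, as discussed above.
* Hypnograms are taken as ground truth; no artifact rejection beyond the
  epoch labels is attempted.
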