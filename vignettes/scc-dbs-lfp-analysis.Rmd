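---
title: "Estimating acute DBS effects on subcallosal cingulate LFP spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating acute DBS effects on subcallosal cingulate LFP spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

During implantation of deep brain stimulation (DBS) leads in the
subcallosal cingulate (SCC) of patients with treatment-resistant
depression, local field potentials (LFPs) can be recorded from the same
quadripolar leads (contacts `L1..L4`, `R1..R4`, ventral to dorsal) that
later deliver chronic therapy. A stimulation *cycle* consists of one
minute of rest (PRE), three minutes of unilateral high-frequency
stimulation at a single contact, and another minute of rest (POST).
Because stimulation saturates the amplifiers, only the peri-stimulation
minutes are usable; the scientific question is whether the POST spectrum
differs from the PRE spectrum, per canonical frequency band, when
stimulating the contact that later proves clinically effective.

`scclfp` implements that estimation chain end to end, plus the group-level
inference, the clinical response definitions, and a synthetic-data
generator with known ground truth that stands in for patient recordings,
which are not publicly available.

## Signal conditioning

The pipeline order is fixed and deliberately mirrors standard intracranial
practice:

1. **Zero-phase bandpass, 1–50 Hz.** A 4th-order Butterworth bandpass is
   applied forward and backward (`signal::filtfilt`), so the net phase
   response is zero and effective attenuation is 8th-order. The band stops
   at 50 Hz, below mains interference, so no notch filter is needed.
2. **Decimation to 128 Hz.** After band-limiting, integer rate ratios
   (e.g. 1024 Hz) reduce to stride selection; non-integer native rates
   (e.g. 1525 Hz) are resampled exactly in the Fourier domain. A 60 s
   epoch is always `round(60 × 128) = 7680` samples.
3. **Artifact pruning (discard, not blank).** A sidecar table of
   half-open intervals `[start_s, end_s)` — curated annotations, or the
   helper `detect_artifacts()` applying the >100 µV, >250 ms rule — marks
   corrupt stretches. Flagged samples are *removed* and the survivors
   concatenated; zero-filling would inject spurious spectral structure.
   An annotation on either electrode of a bipolar pair invalidates the
   pair, since a differential sample is corrupt if either contact is.
4. **Bipolar differentials.** The analysis signal for center contact *c*
   is `(c−1) − (c+1)` (e.g. `L1 − L3` around `L2`), cancelling the common
   reference and common-mode noise. Edge contacts (`L1/L4/R1/R4`) have
   one neighbour only; cycles stimulating them are reported as missing
   rather than analyzed, which is why group sample sizes vary.
5. **Epoching.** PRE is `[stim_on − 60 s, stim_on)`, POST is
   `[stim_off, stim_off + 60 s)`. The PRE window abuts stimulation onset
   with no guard gap — whether a gap was intended upstream is
   undocumented, so the simplest reading is used and stated here. After
   pruning, PRE and POST may retain different lengths; everything
   downstream tolerates that.

Splices created by discard-style pruning inject a small amount of
broadband energy. The default is plain concatenation; a `splice_guard_s`
option widens every annotation symmetrically for sensitivity analyses
(default 0).

## Spectral estimation and the relative-change statistic

Each epoch is decomposed with a complex-Morlet continuous wavelet
transform on a fixed grid of 200 frequencies linearly spaced on
[1, 50] Hz (≈0.246 Hz apart; the grid, not its rounded spacing, is
canonical). The wavelet is implemented as a frequency-domain Gaussian of
width `f0 / n_cycles` centred at each analysis frequency, with
`n_cycles = 6` — the conventional compromise between temporal and
spectral resolution at LFP frequencies — and normalized so a
unit-amplitude sinusoid attains unit peak modulus at its own frequency at
every grid point. CWT *moduli* (not squared power) are the working
quantity; a `use_power` switch squares them for sensitivity analyses.

For each frequency row the acute effect is summarized by the
median-based relative change

$$\mathrm{rc}(v_\mathrm{POST}, v_\mathrm{PRE}) =
\frac{\mathrm{median}(v_\mathrm{POST}) - \mathrm{median}(v_\mathrm{PRE})}
     {\mathrm{median}(v_\mathrm{PRE})},$$

a dimensionless, scale-invariant quantity (−0.5 means the typical
magnitude halved). Its sampling uncertainty is assessed with a bootstrap:
time points are resampled with replacement independently within PRE and
within POST (paired resampling is impossible once pruning makes the
epochs unequal in length), the statistic is evaluated per replicate, and
a percentile interval at 95% is formed. The reported per-frequency
estimate is the CI *midpoint*, `(ci_min + ci_max)/2`, by construction.
Percentile intervals were chosen as the simplest defensible flavour; the
CI level, replicate count (default 1000, minimum 100) and seed are
recorded in every output.

Two numerical points deserve note:

* The bootstrap is implemented by sampling *order statistics* of the
  resampled indices (Beta-distributed uniforms mapped onto the sorted
  row) rather than materializing each resample. The replicate medians are
  exactly distributed as naive resampling medians — the unit tests verify
  this against the closed-form binomial law — at O(1) rather than O(n)
  per replicate, which is what makes 200 frequencies × 1000 replicates
  per cycle affordable without compiled code.
* CWT magnitudes are temporally autocorrelated and the iid bootstrap
  ignores this, so per-frequency intervals are anticonservative for real
  oscillations. This matches the upstream design; an optional
  moving-block bootstrap (`block_len`) is provided but off by default.

Finally the 200 CI midpoints are averaged within delta [1, 4), theta
[4, 8), alpha [8, 15), beta [15, 30) and gamma [30, 50] Hz — half-open
bands, gamma closed at the top, so each shared edge belongs to exactly
one band — reducing each cycle to five numbers.

## Group inference

Band-change samples across patients are small (n ≈ 10–14) and
non-gaussian (a Kolmogorov–Smirnov check, `ks_nongaussianity()`, is
provided as an advisory), so all inference is exact and nonparametric:

* **One sample against zero**, per hemisphere × contact role × band.
  The default is the exact two-tailed Wilcoxon signed-rank test; p-values
  come from a generating-function convolution that enumerates all `2^n`
  sign patterns implicitly and exactly, with mid-ranks for ties and zeros
  dropped. An exact rank-sum test of the sample against an equal-length
  zero pseudo-sample (`rank_sum_vs_zero_exact()`, subset-sum enumeration
  of all `choose(2n, n)` assignments) is also provided because the
  one-sample-versus-zero question is sometimes posed that way; the output
  table records which method produced each row. Published W statistics
  for this design exceed the signed-rank maximum `n(n+1)/2`, so the
  upstream test identity is not recoverable from the reported values —
  implementing both and labelling the choice is the faithful resolution.
* **Effective versus ineffective**, per hemisphere × band, as an exact
  signed-rank test on within-patient differences.
* **Multiplicity** is controlled per contrast over the five bands:
  Bonferroni, `0.05 / 5 = 0.01`. Contrasts are not pooled into one
  family.
* **Effect sizes** are Hedges' g with the small-sample correction
  `J = 1 − 3/(4n − 5)`; the exact variant used is stated so reported
  values are reproducible.
* Group statistics are restricted to 6-month responders; patients whose
  effective contact admits no differential are simply absent from the
  affected cells, with the missing count reported.

`correlate_with_outcome()` relates per-patient band changes to time to
stable response, reporting both Pearson and Spearman coefficients since
the appropriate choice at n ≈ 11 is debatable.

## Clinical definitions

Response is a ≥50% decrease from baseline on the 17-item Hamilton
Depression Rating Scale (HDRS17) at 6 months; exactly 50% counts (all
published classifications are consistent with either boundary reading).
Time to stable response is the first week opening three consecutive
weeks at criterion; it is `NA` when no such run exists or the weekly
series is unavailable. Cohort summaries use sample (n−1) standard
deviations, which is the convention that reproduces the published
baseline column of the reference cohort (mean 23.8, SD 2.8, 11/14
responders; time to stable response over 13 non-missing values 19.9,
SD 20). One published summary cell — the 6-month column's "9.6 (4.5)" —
is inconsistent with its own column values, which recompute to ≈9.3
(4.1); the package reproduces the computation rather than the printed
cell.

## What the synthetic generator does and does not emulate

`synthesize_cycle()` / `synthesize_cohort()` generate EDF+ cohorts with
the statistical structure the analysis assumes:

* a shared common-mode 1/f background (default SD 20 µV, slope χ = 1,
  flattened below 0.5 Hz) that bipolar derivation cancels, plus
  independent per-contact 1/f components (SD 1 µV) that it does not;
* five band-limited oscillations per contact (default amplitude 10 µV
  each, flat across each band's interior with raised-cosine edges), whose
  POST amplitudes on ipsilateral contacts are scaled by configurable
  multipliers — so the ground-truth band change is `multiplier − 1` under
  moduli and `multiplier² − 1` under squared power, and both are written
  to `truth.json`;
* amplifier saturation (±500 µV clipped square wave with per-channel
  gain jitter) throughout the stimulation interval, with guard
  annotations ±2 s around the transitions because the saturation edges
  ring through the zero-phase filter in both directions;
* Poisson artifact transients (default 0.3/min per channel, ±150 µV,
  0.5 s) that are both injected into the signal and written to
  `artifacts.csv` with a 0.25 s pad.

The default cohort reproduces the reference design: 14 patients, 11
responders, 4 analyzed cycles each (effective and ineffective contacts
per hemisphere, order randomized), 8 channels — hence
14 × 8 × 4 × 2 = 896 nominal epochs — at a native 1024 Hz. Responders
carry the asymmetric effect profile (left effective:
θ 0.5, α 0.5, β 0.7, γ 0.7; right effective: β 0.7, γ 0.7; ineffective
contacts similar but without the left-theta effect), non-responders null
effects. Three deliberate degeneracies exercise the error paths: one
patient's left effective contact is `L4` (no differential), one
non-responder's PRE epoch is fully annotated as artifact, and one
patient lacks the weekly HDRS17 series.

The generator emulates *stationary* oscillations with fresh realizations
per analyzed window; it does not model volume conduction, electrode
impedance drift, non-stationary rhythms, cross-frequency coupling, or
stimulation waveform physics. Passing recovery tests therefore
demonstrates that the estimation chain is unbiased and correctly plumbed
under its own assumptions — not that those assumptions hold in patients.

One consequence of real time–frequency physics survives in synthesis:
Morlet bandwidth grows with frequency, so a suppressed band leaks into
the neighbouring band's edge frequencies. With beta and gamma suppressed
on the right, upper-alpha grid points inherit a small but *consistent*
negative change, which an exact sign-sensitive test at n = 11 can flag
despite a negligible magnitude. Specificity checks in the tests
therefore use leakage-free cells (delta bilaterally, right theta);
magnitude-based acceptance uses the ±0.1 recovery tolerance.

## Problem sizes in the test and acceptance runs

The shipped suites size their simulations to be informative yet
routinely runnable on one core: single-cycle recovery uses 20 seeds at
500 bootstrap replicates; null CI coverage uses 500 simulated frequency
rows of 500 points; cohort-level pattern checks synthesize and analyze
three full default cohorts; module tests use a 4-patient cohort. The
acceptance script repeats the same computations at similar sizes from a
single command-line seed.

## Known limitations

* The EDF+ layer implements the subset of the container the pipeline
  needs (16-bit records, one annotation signal with timekeeping TALs,
  mixed-rate reads); it is not a general-purpose EDF library.
* Exact rank-sum enumeration switches to the tie-corrected normal
  approximation beyond a combined sample of 60 — irrelevant at this
  design's n but worth knowing for reuse.
* Bootstrap CIs inherit the iid-in-time assumption discussed above.
* The during-stimulation interval is unanalyzable by design (amplifier
  saturation); no attempt is made to recover it.
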