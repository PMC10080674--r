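---
title: "Narrowband 2D FT-ICR MS: model, processing choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Narrowband 2D FT-ICR MS: model, processing choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icr2d)
```

## The experiment being modeled

Two-dimensional mass spectrometry correlates precursor and fragment ions
without isolation. An encoding pulse pair separated by an incremented
delay $t_1$ modulates each precursor's post-encoding cyclotron radius at
its own cyclotron frequency $f_p$; since electron capture dissociation
(ECD) is radius-dependent, the abundance of every fragment is amplitude-
modulated along $t_1$ at $f_p$. Fourier transforming each detection
transient (over $t_2$) and then each frequency channel (over $t_1$) yields
a 2D spectrum: fragment $m/z$ horizontally, precursor cyclotron frequency
vertically.

The package's test system is a pair of 26-residue histone H3 tail
constructs with identical sequence (`ATKAARKSAPATGGVKKPHRYRPGGK`, both
biotinylated on the appended C-terminal K), one acetylated at K7 and one
trimethylated at K16. Acetylation adds 42.0106 Da, trimethylation
42.0470 Da, so the intact 6+ precursors differ by $m/z$ 0.006 — 2.7 Hz in
cyclotron frequency — and are unresolvable in the vertical dimension of
any practical 2D acquisition. The scientific point the package
operationalizes is that *fragment-population statistics* in the vertical
dimension recover this 2.7 Hz gap anyway, well below the spectral point
spacing.

## The signal model

`simulate_2d()` generates

$$s(t_1, t_2) = \sum_{p,f} A_{pf}\, g(2\pi f_p^{fold} t_1)\,
  e^{-\lambda t_1}\, \cos(2\pi f_f t_2 + \varphi(f_f))\, e^{-t_2/\tau_2}
  + \varepsilon(t_1, t_2)$$

* **Modulation law.** $g(x) = (1+\cos x)/2$ for fragment channels and
  $1-g$ for the surviving precursor, so the two channels are exactly in
  antiphase and conserve total ion signal. Radius-dependent ECD yield has
  no published closed form; the raised cosine is the minimal law
  reproducing the observed phenomenology (modulated fragment ridges,
  antiphase precursor self-peak). The modulation phase at $t_1 = 0$ is
  fixed at maximal fragmentation, $g(0) = 1$.
* **Coherence decay.** Ion packets dephase during the encoding delay;
  this is modeled as a single exponential $e^{-\lambda t_1}$ on every
  channel with $\lambda = 20\,\mathrm{s^{-1}}$ by default (a ~50 ms
  characteristic time). Decay is deliberately *not* applied per-$t_2$:
  the observable consequence of narrowing the vertical band — S/N loss
  with longer $t_1$, without horizontal peak broadening — follows from a
  $t_1$-only envelope.
* **Detection.** Each row is a damped cosine; $\tau_2 = 0.5$ s by
  default (unmeasured; only trends, never absolute resolving powers, are
  asserted against it). A quadratic phase $\varphi(f)$ can be injected to
  exercise the phase-correction path.
* **Noise.** I.i.d. Gaussian, seeded. The default
  `noise_sd = 0.05` (precursor amplitude 1, mean fragment efficiency
  0.05) puts fragment-peak S/N at order $10^2$ on desk-scale grids,
  matching the instrument's observed range qualitatively.
* **Fragment set.** Complete ECD $c$/$z^{\bullet}$ ladders of both
  peptides at the requested charges, restricted to species whose
  cyclotron frequency falls inside the pulse band and the detected
  window — species outside the band are simply not excited/detected, as
  on the instrument. Per-fragment efficiencies are drawn once (seeded,
  ±50% uniform) and shared across the two peptides for the same
  (kind, length, charge), since equal sequences fragment equally.

### Vertical undersampling and foldovers

The vertical dimension samples $t_1$ at $\Delta t_1 = 1/(2 f_N)$ for a
Nyquist band $f_N$ far below the precursor frequencies. Bands of width
$f_N$ are counted from the lowest pulse frequency; a precursor at
219.272 kHz folds 14/36/72/144 times in the 10/4/2/1 kHz presets. Within
a band the apparent frequency direction alternates with band parity (the
standard orientation alternation of real undersampling); simulator and
demodulator share one convention, pinned by round-trip tests. The
simulator generates the *demodulated* modulation directly — the folded
frequency from `fold_frequency()` — which is equivalent to the digital
demodulation step of the instrument workflow.

## Processing choices

`ft_2d()` applies, in provenance-recorded order: sine-bell apodization
(maximum at 0.15 of the record; squared variant available for 1D spectra),
zero-filling, row-wise FFT, quadratic horizontal phase correction and real
part, optional SANE-style low-rank denoising of the $t_1$ interferogram,
column-mean removal, vertical apodization and FFT, linear vertical phase,
and demodulation of the vertical axis to true frequencies.

Numerical choices worth knowing:

* **Zero-fill counting.** A "zero-fill" here doubles the number of
  spectral points across the half-band (FFT length $2 n 2^{zf}$, half
  kept), so the 10 kHz preset with $N = 1024$ increments and one vertical
  fill gives 2048 points at 4.9 Hz per point, and a 512k-point transient
  with one horizontal fill gives 1,048,576 points. This convention makes
  point spacings and grid sizes agree simultaneously.
* **Absorption vs magnitude.** Absorption mode is the default
  everywhere. The real part is taken *between* the two transforms: this
  confines each species' dispersive component to the horizontal axis and
  keeps vertical lines symmetric, which matters because the correlation
  statistic is a vertical line-center average. Magnitude mode shares the
  pipeline and takes moduli instead (phase-free when no model is given).
* **Column-mean removal.** The raised-cosine modulation has a DC term
  that would put a ridge at vertical frequency zero; subtracting column
  means suppresses it without touching the modulation peak.
* **SANE-style denoising.** The published algorithm is specified by
  citation only; the contract implemented is a seeded randomized rank-$r$
  SVD along $t_1$ with one subspace-refinement pass (the first-pass signal
  estimate re-injected as probe vectors). Rank-$\le r$ data are
  reproduced exactly; the default rank 30 comfortably covers the few
  modulation components per precursor.
* **Phase determination.** `fit_phase()` projects a reference MS/MS
  transient onto each known peak frequency (a single-frequency Fourier
  sum), which sidesteps the bin-offset phase error of reading the phase
  at a grid maximum, then unwraps the per-peak phases against a running
  polynomial prediction and least-squares fits the quadratic. The
  constant coefficient is identifiable only modulo $2\pi$, which is
  physically irrelevant.
* **Baseline.** Rolling median (window 1/50 of the profile) with linear
  edge extrapolation; removes offsets exactly and slow ramps to <1%.
* **Centroiding and line fits.** Three-point parabola on linear
  intensities for picking; Lorentzian least squares (window ±3 estimated
  FWHM, Levenberg–Marquardt) for refined centers. Noise is estimated as
  1.4826×MAD of signal-free regions. Fits whose RMS residual exceeds
  3× the noise floor are flagged — the flag doubles as an unresolved-
  doublet detector.

## The analysis layer

* **Added-up spectrum**: horizontal scans at the precursor isotope rows,
  baseline-corrected and summed; in narrowband mode the rows' noise is
  uncorrelated, so S/N grows as $\sqrt{n}$.
* **Assignment and coverage**: nearest-mass matching against both
  ladders within a ppm tolerance. Fragments containing no modified
  residue are identical in both peptides (category 1, "shared");
  fragments containing exactly one variable site differ by a full
  modification mass (category 2); fragments containing both sites differ
  by trimethyl − acetyl = 36.4 mDa (category 3). Coverage counts
  supported inter-residue bonds out of $L-1 = 25$.
* **Label-free quantification**: intensity fractions over
  (kind, length, charge)-matched assignment pairs, aggregated by
  unweighted mean. Fractions are scale-invariant by construction.
* **Correlation populations**: per assigned fragment, the vertical scan
  at its horizontal position is baseline-corrected and Lorentzian-fitted;
  fitted centers are grouped **only** by the horizontal mass category —
  vertical positions are the measured outcome, never a grouping input.
  By default only category-2 fragments are used: category-3 members are
  36.4 mDa apart and horizontally unresolved except on very long records,
  so their vertical scans mix both precursors (measurably biasing the
  group gap — reproduced and excluded by the residual flag and the
  category filter).
* **Decay envelope**: block maxima of the per-$t_1$ amplitude of the
  precursor channel, fitted to $A e^{-\lambda t_1}$.

## Problem sizes and defaults

Desk-scale defaults are 16,384-point detection records × 1024 encoding
increments (the full-size 512k-point record is available via
`detect_points = 524288L`). These sizes keep a complete
simulate–process–analyze cycle under a minute while leaving the vertical
dimension at full experimental resolution — the vertical axis is the
scientific subject; the horizontal record length only needs to resolve
neighboring fragments. The per-scan overhead default (0.65 s) was chosen
once because, with the 0.734 s full-size transient, it reproduces the
published per-preset acquisition durations; the ≈4 min duration increase
from 50 to 500 µs increments is overhead-independent.

A narrowband *horizontal* window (heterodyne reference `detect_f0` with a
reduced `detect_rate`) emulates long-record resolution over a small m/z
range: an 8192-point window at 4 kHz spans 2 s and resolves the ~2 Hz
splitting of a category-3 pair, which the tests use to demonstrate
36.4 mDa assignment and quantification at desk scale.

## What the synthetic data does and does not show

The generator reproduces: amplitude modulation at folded precursor
frequencies, antiphase precursor/fragment channels, exponential coherence
loss, damped detection transients, white noise, undersampled vertical
sampling with the printed foldover counts, and isotopologue-exact
fragment masses. It does **not** model: space-charge frequency shifts,
magnetron/trapping sidebands, isotope envelopes of the *transient* itself
(fragments are simulated monoisotopically; isotope fine structure enters
through the chemistry layer), scan-to-scan variability, or correlated
(harmonic) noise. Passing tests therefore validate the *processing and
statistics*, not instrument physics: absolute resolving powers and S/N of
real spectra depend on $\tau_2$, pressure and space charge, and only
their qualitative trends (S/N decreasing as the band narrows at fixed
decay) are asserted.

Printed reference values have two known internal inconsistencies, both
recorded rather than tuned away: the published precursor $m/z$ 493.9466
is ~2 mDa/charge above the mass computed from the declared construct, and
the two published z13(3+) $m/z$ values differ by 14.0177 rather than the
also-published 14.0157 (= 42.047/3). The package treats compositions and
conventions as normative; the frequency calibration is anchored at the
printed (493.9466, 219,272 Hz) pair so frequency-domain statements match
the published ones.

## Known limitations

* The z-ion convention is fixed to $z^{\bullet}$ (radical, $y - \mathrm{NH_2}$);
  even-electron $z'$ species, b/y ladders, internal fragments and neutral
  losses are out of scope.
* Quadratic frequency-to-mass calibration is supported but the default is
  the one-term law; no calibration constants beyond the single anchor are
  published for this system.
* `correlation_populations()` fits one Lorentzian per scan; deliberately
  no multi-peak deconvolution (the method's point is that single-line
  statistics suffice below the grid spacing).
* The pipeline's added-up spectrum uses the simulator's ground-truth
  precursor rows; on real data the rows would come from a precursor-scan
  peak pick.
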