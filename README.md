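# icr2d

Simulation and analysis of narrowband **two-dimensional FT-ICR mass
spectrometry** (2D MS) for near-isobaric modified peptides, built around
the canonical test case of two histone H3 tail peptides with the same
sequence, one acetylated (Δm = 42.0106 Da) and one trimethylated
(Δm = 42.0470 Da). The two constructs differ by only 36.4 mDa
(m/z 0.006 at 6+, i.e. 2.7 Hz in cyclotron frequency), far below the
point spacing of the precursor dimension — yet 2D MS can still correlate
every fragment with its precursor, quantify the two proteoforms label-free,
and localize the modifications.

## Who this is for

Mass spectrometrists and methods developers who want a tested, fully
synthetic workbench for 2D FT-ICR MS data processing: every stage from the
pulse-sequence signal model to the final correlation statistics is
reproducible code with known ground truth, so processing choices
(apodization, zero-filling, phase correction, low-rank denoising, line
fitting) can be validated quantitatively instead of on unrepeatable
instrument data.

## The model in brief

In 2D MS, an encoding pulse pair separated by a delay t₁ modulates each
precursor's post-encoding radius at its cyclotron frequency f_p. Because
electron capture dissociation (ECD) yield is radius-dependent, fragment
abundance follows

    s(t₁, t₂) = Σ A · g(2π f_p t₁) · e^(−λ t₁) · cos(2π f_f t₂ + φ(f_f)) · e^(−t₂/τ₂) + ε

with raised-cosine modulation g(x) = (1 + cos x)/2 for fragment channels
(1 − g for the surviving precursor), coherence decay λ (default 20 s⁻¹,
a ~50 ms characteristic time), and a damped detection transient per row.
A 2D Fourier transform turns this into a spectrum whose horizontal axis is
the fragment m/z and whose vertical axis is the precursor cyclotron
frequency. The vertical dimension is deliberately undersampled
(narrowband): a precursor near 219.27 kHz sampled with a 4 kHz Nyquist
band folds 36 times; the demodulator restores true frequencies from the
band index.

Key measured quantities: FWHM, resolving power (centroid/FWHM), S/N
(height over 1.4826·MAD), Lorentzian line fits of vertical precursor
scans, sequence coverage from c/z• ladder assignment, label-free
fractions from paired fragment intensities, and the mean vertical
frequency gap between the fragment populations of the two peptides.

## Worked example

```r
library(icr2d)

pair <- fixture_suite("histone_pair")
pair$k7ac
#> <peptide> K7 Ac: ATKAARKSAPATGGVKKPHRYRPGGK (26 residues)
#>   modifications: acetyl@7, biotinyl@26

# the near-isobaric pair: 0.006 m/z at 6+, 2.7 Hz in cyclotron frequency
(monoisotopic_mass(pair$k16me3) - monoisotopic_mass(pair$k7ac)) / 6
#> [1] 0.006064252
mz_to_frequency(493.9466) - mz_to_frequency(493.9466 + 0.0061)
#> [1] 2.708016

# isotopologue fine structure of the precursor M+1 cluster
pat <- isotopologue_pattern(peptide_formula(pair$k7ac), max_shift = 1)
100 * isotope_share(pat, 1, c("2H", "15N", "17O", "33S"))
#> [1] 12.88878      # ~13% of M+1 is not 13C, spread over > 9 mDa

# full synthetic experiment: simulate, process, assign, quantify, correlate
res <- run_pipeline(list(preset = "nb4k", seed = 1L))
writeLines(readLines(res$files[["summary"]])[2:7])
#> species simulated: 201
#> peaks picked: 208, assigned: 140
#> coverage: K7 Ac=92%, K16 3m=100%
#> quant fractions: K16 3m=0.501, K7 Ac=0.499
#> precursor population gap: 2.772 Hz
#> decay rate: 21.56 1/s
```

The last three lines are the headline result: an equimolar mixture
quantifies to 0.50/0.50; the fragment populations of the two peptides
separate by ≈2.7 Hz in the precursor dimension even though the grid
spacing is 2.0 Hz and the peptides are unresolved; and the coherence
decay rate injected by the generator (20 s⁻¹) is recovered from the
precursor-channel envelope.

## Layout

- `R/` — ion chemistry (peptides, ECD c/z• ladders, isotopologue fine
  structure), ICR geometry (calibration, foldovers, acquisition duration),
  the 2D signal generator, the processing chain, peak metrology, and the
  correlation/quantification layer.
- `vignettes/narrowband-2d-ms.Rmd` — the methods vignette: model
  assumptions, parameter choices, and known limitations.
- `tests/testthat/` — unit, property and acceptance suites.
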