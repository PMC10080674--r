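# Shared fixtures and lazily-built simulation objects (cached so the
# heavier seeded simulations are generated once per test run).

histone_pair <- fixture_suite("histone_pair")

pair_ladder <- function(charges = 1:3) {
  rbind(fragment_ladder(histone_pair$k7ac, charges = charges,
                        pair_with = histone_pair$k16me3),
        fragment_ladder(histone_pair$k16me3, charges = charges,
                        pair_with = histone_pair$k7ac))
}

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- builder()
  .sim_cache[[key]]
}

# Equimolar two-peptide nb4k run at the desk-scale grid (16,384 x 1024):
# the conditions of the precursor-population analysis.
nb4k_run <- function() cached("nb4k_run", function() {
  plan <- simulation_plan(
    peptides = list(
      list(peptide = histone_pair$k7ac, charge = 6, abundance = 1),
      list(peptide = histone_pair$k16me3, charge = 6, abundance = 1)),
    params = acquisition_preset("nb4k"), seed = 101)
  tr <- simulate_2d(plan)
  spec <- ft_2d(tr, zero_fill_h = 0L, zero_fill_v = 1L)
  prec_f <- unique(tr$ground_truth$f_v_true)
  added <- added_up_spectrum(spec, prec_f)
  peaks <- pick_peaks(added, snr_threshold = 5)
  asg <- assign_fragments(peaks, pair_ladder(), tol_ppm = 300, cal = tr$cal)
  list(tr = tr, spec = spec, added = added, peaks = peaks, asg = asg,
       prec_f = prec_f)
})

# Small single-precursor run for metrology checks.
small_run <- function() cached("small_run", function() {
  plan <- simulation_plan(
    peptides = list(list(peptide = histone_pair$k7ac, charge = 6,
                         abundance = 1)),
    params = acquisition_preset("nb4k", detect_points = 2048L),
    fragment_charges = 2L, efficiency_spread = 0, noise_sd = 0.003,
    seed = 42)
  tr <- simulate_2d(plan)
  spec <- ft_2d(tr, zero_fill_h = 0L, zero_fill_v = 1L)
  list(tr = tr, spec = spec)
})

# Minimal hand-built spectrum2d for scan-arithmetic tests.
fake_spectrum <- function(matrix, v_axis, h_axis) {
  structure(list(matrix = matrix, v_axis = v_axis, h_axis = h_axis,
                 h_axis_mz = rep(NA_real_, length(h_axis)),
                 cal = calibration(), params = NULL, band_index = 0L,
                 provenance = list(list(step = "synthetic"))),
            class = "spectrum2d")
}

# Ideal peak list constructed from a fragment ladder (optionally with some
# fragments removed), for assignment and coverage tests.
ladder_peaks <- function(ladder, drop = NULL, height = 1) {
  lad <- unique(ladder[, c("kind", "length", "charge", "mz")])
  if (!is.null(drop))
    lad <- lad[!(paste(lad$kind, lad$length) %in% drop), , drop = FALSE]
  data.frame(centroid = mz_to_frequency(lad$mz, calibration()),
             mz = lad$mz, height = height, fwhm = 1,
             resolving_power = lad$mz, snr = 100,
             index = seq_len(nrow(lad)), edge = FALSE)
}

# A noiseless Lorentzian scan profile on an integer-like axis.
lorentz_profile <- function(x0, w, A = 1, b = 0, n = 201, dx = 1,
                            noise_sd = 0, seed = 1) {
  x <- (0:(n - 1)) * dx
  y <- A * (w / 2)^2 / ((x - x0)^2 + (w / 2)^2) + b
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(n, sd = noise_sd)
  }
  structure(list(axis = x, intensity = y, orientation = "vertical",
                 source = 0), class = "scan_profile")
}
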