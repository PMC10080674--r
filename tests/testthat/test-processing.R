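test_that("sine-bell window peaks at max_position and vanishes at the ends", {
  w <- apodize(rep(1, 1001), max_position = 0.15)
  expect_equal(w[151], 1, tolerance = 1e-9)   # u = 0.15
  expect_identical(which.max(w), 151L)
  expect_equal(w[1], 0)
  expect_equal(w[1001], 0, tolerance = 1e-12)
  # discrete mean matches the analytic integral of sin(pi h(u)): 2/pi
  expect_equal(mean(w), 2 / pi, tolerance = 3e-3)
  # squared variant and matrix orientation
  expect_equal(apodize(rep(1, 1001), 0.15, power = 2), w^2)
  m <- matrix(1, 4, 1001)
  expect_equal(apodize(m, 0.15)[2, ], w)
  expect_error(apodize(1:10, max_position = 0), "inside")
  expect_error(apodize(1:10, max_position = 1), "inside")
})

test_that("zero filling appends zeros and preserves centroids", {
  x <- sin(1:1024 / 7)
  expect_identical(zero_fill(x, 0), x)
  z <- zero_fill(x, 1)
  expect_length(z, 2048)
  expect_identical(z[1025:2048], rep(0, 1024))
  # centroid of a spectral peak is invariant under zero-filling
  t <- (0:1023) / 1024
  sig <- apodize(cos(2 * pi * 100.37 * t) * exp(-2 * t))
  cen <- function(s) {
    n <- length(s)
    S <- Mod(fft(s))[1:(n / 2)]
    prof <- structure(list(axis = (0:(n / 2 - 1)) * 1024 / n, intensity = S,
                           orientation = "horizontal", source = 0),
                      class = "scan_profile")
    pick_peaks(prof, 3)$centroid[1]
  }
  expect_equal(cen(zero_fill(sig, 2)), cen(zero_fill(sig, 1)),
               tolerance = 0.05)  # Hz, well under the 0.5 Hz fine spacing
})

test_that("2D transform recovers every ground-truth peak on all presets", {
  for (nm in c("nb10k", "nb4k", "nb2k", "nb1k")) {
    plan <- simulation_plan(
      peptides = list(list(peptide = histone_pair$k7ac, charge = 6,
                           abundance = 1)),
      params = acquisition_preset(nm, detect_points = 2048L,
                                  n_increments = 256L),
      fragment_charges = 2L, efficiency_spread = 0, noise_sd = 0, seed = 3)
    tr <- simulate_2d(plan)
    spec <- ft_2d(tr, zero_fill_h = 0L, zero_fill_v = 1L)
    dv <- spec$v_axis[2] - spec$v_axis[1]
    dh <- spec$h_axis[2] - spec$h_axis[1]
    gt <- tr$ground_truth[tr$ground_truth$channel == "fragment", ]
    # keep fragments resolved from their neighbors at this record length
    d <- outer(gt$f_h, tr$ground_truth$f_h, function(a, b) abs(a - b))
    gt <- gt[apply(d, 1, function(r) sort(r)[2] > 4 * dh), , drop = FALSE]
    expect_gt(nrow(gt), 10)
    k <- which.min(abs(spec$v_axis - gt$f_v_true[1]))  # shared precursor row
    v_err <- h_err <- numeric(nrow(gt))
    for (i in seq_len(nrow(gt))) {
      # vertical: the column at the fragment peaks at the true precursor f
      j <- which.min(abs(spec$h_axis - gt$f_h[i]))
      i_max <- which.max(spec$matrix[, j])
      v_err[i] <- abs(spec$v_axis[i_max] - gt$f_v_true[i])
      # horizontal: the precursor row has a local maximum at the fragment
      win <- max(1, j - 4):min(ncol(spec$matrix), j + 4)
      j_max <- win[which.max(spec$matrix[k, win])]
      h_err[i] <- abs(spec$h_axis[j_max] - gt$f_h[i])
    }
    expect_lt(max(v_err), 1.5 * dv)
    expect_lt(max(h_err), 1.5 * dh)
    # demodulated axis puts the precursor in the printed fold band
    expect_identical(spec$band_index,
                     fold_frequency(219270, tr$params)$band_index)
  }
})

test_that("nb4k vertical grid is 2.0 Hz over 2048 points after one fill", {
  run <- small_run()
  expect_identical(nrow(run$spec$matrix), 2048L)
  expect_equal(run$spec$v_axis[2] - run$spec$v_axis[1], 2.0,
               tolerance = 0.03)
})

test_that("magnitude mode bounds absorption mode pointwise", {
  plan <- simulation_plan(
    peptides = list(list(peptide = histone_pair$k7ac, charge = 6,
                         abundance = 1)),
    params = acquisition_preset("nb4k", detect_points = 512L,
                                n_increments = 64L),
    fragment_charges = 2L, noise_sd = 0.01, seed = 8)
  tr <- simulate_2d(plan)
  ab <- ft_2d(tr, zero_fill_h = 0L, zero_fill_v = 0L)
  mg <- ft_2d(tr, zero_fill_h = 0L, zero_fill_v = 0L, mode = "magnitude")
  expect_true(all(mg$matrix >= ab$matrix - 1e-9))
  # magnitude mode stands alone without a phase model and is nonnegative
  mg0 <- ft_2d(tr, phase = NULL, zero_fill_h = 0L, zero_fill_v = 0L,
               mode = "magnitude")
  expect_true(all(mg0$matrix >= 0))
  expect_error(ft_2d(tr, phase = NULL), "phase model")
})

test_that("processing provenance fully determines the output", {
  run <- small_run()
  again <- ft_2d(run$tr, zero_fill_h = 0L, zero_fill_v = 1L)
  expect_identical(run$spec$matrix, again$matrix)
  expect_identical(run$spec$provenance, again$provenance)
  steps <- vapply(run$spec$provenance, `[[`, character(1), "step")
  expect_true(all(c("apodize_h", "fft_h", "phase_h", "fft_v",
                    "demodulate_v") %in% steps))
})

test_that("injected quadratic phase is recovered from the reference record", {
  ph <- c(2e-10, 3e-5, 0.4)
  plan <- simulation_plan(
    peptides = list(list(peptide = histone_pair$k7ac, charge = 6,
                         abundance = 1)),
    params = acquisition_preset("nb4k", detect_points = 8192L),
    fragment_charges = 1:2, phase_h = ph, noise_sd = 0, seed = 1)
  ref <- simulate_reference_msms(plan)
  pm <- fit_phase(ref$signal, ref$rate, ref$ground_truth$f_h, ref$f0)
  expect_equal(pm$h[1], ph[1], tolerance = 0.01)
  expect_equal(pm$h[2], ph[2], tolerance = 0.01)
  # the fitted phase function agrees over the band modulo 2 pi
  f <- seq(8e4, 3.4e5, length.out = 200)
  derr <- (pm$h[1] - ph[1]) * f^2 + (pm$h[2] - ph[2]) * f +
    (pm$h[3] - ph[3])
  derr <- Arg(exp(1i * derr))
  expect_lt(max(abs(derr)), 0.02)

  # zero injected phase: near-zero coefficients
  plan0 <- simulation_plan(
    peptides = list(list(peptide = histone_pair$k7ac, charge = 6,
                         abundance = 1)),
    params = acquisition_preset("nb4k", detect_points = 8192L),
    fragment_charges = 1:2, noise_sd = 0, seed = 1)
  ref0 <- simulate_reference_msms(plan0)
  pm0 <- fit_phase(ref0$signal, ref0$rate, ref0$ground_truth$f_h, ref0$f0)
  f <- seq(8e4, 3.4e5, length.out = 50)
  expect_lt(max(abs(pm0$h[1] * f^2 + pm0$h[2] * f + pm0$h[3])), 0.05)

  # three exact phase samples reproduce their quadratic exactly
  f3 <- c(1e5, 2e5, 3e5)
  truth <- c(1.3e-10, -2e-5, 0.7)
  phi3 <- truth[1] * f3^2 + truth[2] * f3 + truth[3]
  pm3 <- fit_phase_quadratic(f3, Arg(exp(1i * phi3)))
  expect_equal(pm3$h, truth, tolerance = 1e-9)
})

test_that("low-rank denoising is exact at true rank and reduces noise", {
  set.seed(31)
  U <- matrix(rnorm(128 * 3), 128, 3)
  V <- matrix(rnorm(3 * 400), 3, 400)
  X <- U %*% V
  expect_equal(sane_denoise(X, rank = 5, seed = 2), X, tolerance = 1e-6)
  expect_error(sane_denoise(X, rank = 0), "rank")
  expect_error(sane_denoise(X, rank = 128), "rank")
  expect_identical(sane_denoise(X + 1, 5, seed = 7),
                   sane_denoise(X + 1, 5, seed = 7))  # deterministic
})

test_that("denoising the t1 interferogram lowers the spectral noise floor
           without moving peak centroids", {
  plan <- simulation_plan(
    peptides = list(list(peptide = histone_pair$k7ac, charge = 6,
                         abundance = 1)),
    params = acquisition_preset("nb10k", detect_points = 2048L,
                                n_increments = 256L),
    fragment_charges = 2L, efficiency_spread = 0, noise_sd = 0.02, seed = 12)
  tr <- simulate_2d(plan)
  raw <- ft_2d(tr, zero_fill_h = 0L, zero_fill_v = 1L)
  den <- ft_2d(tr, zero_fill_h = 0L, zero_fill_v = 1L, denoise_rank = 30,
               denoise_seed = 12)
  frag <- tr$ground_truth[tr$ground_truth$channel == "fragment", ][4, ]
  s_raw <- baseline_correct(extract_scan(raw, "vertical", frag$f_h))
  s_den <- baseline_correct(extract_scan(den, "vertical", frag$f_h))
  noise_of <- function(s) 1.4826 * mad(s$intensity, constant = 1)
  expect_gt(noise_of(s_raw) / noise_of(s_den), 2)
  c_raw <- pick_peaks(s_raw, 4)$centroid[1]
  c_den <- pick_peaks(s_den, 4)$centroid[1]
  dv <- s_raw$axis[2] - s_raw$axis[1]
  expect_lt(abs(c_raw - c_den), 0.1 * dv)
})

test_that("baseline correction removes offsets and ramps, keeps peaks", {
  n <- 2000
  flat <- baseline_correct(rep(3.7, n))
  expect_equal(flat, rep(0, n), tolerance = 1e-12)
  ramp <- seq(0, 5, length.out = n)
  expect_lt(max(abs(baseline_correct(ramp))), 0.01 * 5)
  x <- seq_len(n)
  peak <- 10 * exp(-((x - 1000) / 2)^2)   # narrow against the 1/50 window
  corr <- baseline_correct(peak)
  expect_equal(max(corr), 10, tolerance = 0.02)
})
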