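#' Sine-bell apodization
#'
#' Multiplies a transient by w(u) = sin(pi h(u))^power, where h maps
#' \[0, 1\] piecewise-linearly onto \[0, 1\] with h(max_position) = 1/2, so
#' the window peaks at the given fraction of the record — an early maximum
#' (default 0.15) suits decaying signals. `power = 2` gives the squared
#' ("square sine-bell") variant used for 1D spectra.
#'
#' @param signal numeric vector, or matrix (apodized along `along`).
#' @param max_position fraction in (0, 1) where the window peaks.
#' @param power window exponent (1 = sine-bell, 2 = squared).
#' @param along for matrices: 2 apodizes each row (the t2 dimension),
#'   1 each column (the t1 dimension).
#' @return same shape as `signal`.
#' @export
apodize <- function(signal, max_position = 0.15, power = 1, along = 2) {
  if (max_position <= 0 || max_position >= 1)
    stop("max_position must be inside (0, 1)")
  if (is.matrix(signal)) {
    n <- if (along == 2) ncol(signal) else nrow(signal)
    w <- sine_bell(n, max_position, power)
    return(if (along == 2) sweep(signal, 2, w, `*`) else signal * w)
  }
  signal * sine_bell(length(signal), max_position, power)
}

sine_bell <- function(n, max_position = 0.15, power = 1) {
  u <- seq(0, 1, length.out = n)
  h <- ifelse(u <= max_position, u / (2 * max_position),
              0.5 + (u - max_position) / (2 * (1 - max_position)))
  sin(pi * h)^power
}

#' Zero-filling
#'
#' Appends zeros to a transient, doubling its length per fill; the spectral
#' grid spacing halves with each fill while peak widths (set by the
#' acquisition time) are unchanged.
#'
#' @param signal numeric vector or matrix (filled along `along`).
#' @param times number of doublings (0 = identity).
#' @param along for matrices: 2 pads rows, 1 pads columns.
#' @return extended signal.
#' @export
zero_fill <- function(signal, times = 1L, along = 2) {
  stopifnot(times >= 0)
  if (times == 0) return(signal)
  if (is.matrix(signal)) {
    if (along == 2) {
      pad <- matrix(0, nrow(signal), ncol(signal) * (2^times - 1))
      return(cbind(signal, pad))
    }
    pad <- matrix(0, nrow(signal) * (2^times - 1), ncol(signal))
    return(rbind(signal, pad))
  }
  c(signal, rep(0, length(signal) * (2^times - 1)))
}

#' Phase model for absorption-mode spectra
#'
#' Quadratic phase along the horizontal (fragment) frequency axis,
#' phi(f) = a f^2 + b f + c, and a linear coefficient along the vertical
#' axis. Applying `exp(-i phi(f))` to the complex spectrum and taking the
#' real part yields the absorption-mode spectrum.
#'
#' @param h numeric `c(a, b, c)` horizontal quadratic coefficients.
#' @param v vertical linear coefficient.
#' @export
phase_model <- function(h = c(0, 0, 0), v = 0) {
  stopifnot(length(h) == 3, all(is.finite(h)), is.finite(v))
  structure(list(h = h, v = v), class = "phase_model")
}

eval_phase_h <- function(model, f) model$h[1] * f^2 + model$h[2] * f + model$h[3]

#' Fit the horizontal phase model from a reference transient
#'
#' Estimates the phase of each known peak by projecting the reference
#' time-domain record onto the peak's exact frequency (a single-frequency
#' Fourier sum, immune to bin-offset phase error), unwraps the per-peak
#' phases in frequency order against a running quadratic prediction, and
#' least-squares fits phi(f) = a f^2 + b f + c. Three exact phase samples
#' reproduce their quadratic exactly (see [fit_phase_quadratic()]).
#'
#' @param signal real reference transient (e.g. from
#'   [simulate_reference_msms()]).
#' @param rate sampling rate, Hz.
#' @param peak_freqs frequencies of the known peaks, Hz (absolute).
#' @param f0 heterodyne reference frequency of the record, Hz.
#' @return a [phase_model].
#' @export
fit_phase <- function(signal, rate, peak_freqs, f0 = 0) {
  stopifnot(is.numeric(signal), length(peak_freqs) >= 3)
  t <- (seq_along(signal) - 1) / rate
  f <- sort(peak_freqs)
  phi <- vapply(f, function(fk)
    Arg(sum(signal * exp(-2i * pi * (fk - f0) * t))), numeric(1))
  fit_phase_quadratic(f, phi)
}

#' @rdname fit_phase
#' @param f frequencies of the phase samples, Hz.
#' @param phi wrapped phase samples, radians.
#' @export
fit_phase_quadratic <- function(f, phi) {
  stopifnot(length(f) == length(phi), length(f) >= 3)
  ord <- order(f)
  f <- f[ord]; phi <- phi[ord]
  # sequential unwrap against a running polynomial prediction
  for (i in seq_along(phi)[-1]) {
    pred <- if (i == 2) phi[1] else {
      deg <- min(i - 2, 2)
      X <- outer(f[1:(i - 1)], 0:deg, `^`)
      co <- stats::lm.fit(X, phi[1:(i - 1)])$coefficients
      co[is.na(co)] <- 0
      sum(co * f[i]^(0:deg))
    }
    phi[i] <- phi[i] - 2 * pi * round((phi[i] - pred) / (2 * pi))
  }
  fit <- stats::lm(phi ~ I(f^2) + f, data = data.frame(f = f, phi = phi))
  co <- stats::coef(fit)
  phase_model(h = unname(c(co["I(f^2)"], co["f"], co["(Intercept)"])))
}

#' Randomized low-rank (SANE-style) denoising along t1
#'
#' Rank-r denoising of the t1 interferogram: a seeded randomized
#' range-finder projects the matrix onto r (+ oversampling) directions,
#' the first-pass signal estimate is re-injected as additional probe
#' vectors (one subspace-refinement pass), and the rank-r truncated SVD of
#' the projected matrix is returned. Noiseless data of true rank <= r are
#' reproduced exactly; for noisy data the noise floor drops roughly by the
#' ratio of retained to total dimensions while peak positions are
#' preserved.
#'
#' @param interferogram numeric matrix (t1 rows x frequency columns).
#' @param rank retained rank r (>= 1, < number of rows).
#' @param oversample extra random probes.
#' @param seed RNG seed (fixed seed => deterministic output).
#' @return denoised matrix, same shape.
#' @export
sane_denoise <- function(interferogram, rank, oversample = 8L, seed = 1L) {
  X <- interferogram
  stopifnot(is.matrix(X))
  if (rank < 1) stop("rank must be >= 1")
  if (rank >= nrow(X)) stop("rank must be smaller than the row count")
  set.seed(seed)
  k <- min(rank + oversample, nrow(X) - 1L, ncol(X))
  ch <- function(A) Conj(t(A))          # Hermitian transpose (real or complex)
  Omega <- matrix(stats::rnorm(ncol(X) * k), ncol(X), k)
  Y <- X %*% Omega                      # first-pass range estimate
  Y <- X %*% (ch(X) %*% Y)              # re-inject signal estimate (power pass)
  Q <- qr.Q(qr(Y))
  B <- ch(Q) %*% X                      # k x ncol
  sv <- svd(B, nu = rank, nv = rank)
  r <- min(rank, length(sv$d))
  (Q %*% sv$u[, seq_len(r), drop = FALSE]) %*%
    (sv$d[seq_len(r)] * ch(sv$v[, seq_len(r), drop = FALSE]))
}

#' 2D Fourier transform to a phase-corrected absorption-mode spectrum
#'
#' Processing chain: sine-bell apodization and Fourier transform of each
#' detection transient (rows), horizontal phase correction and real part;
#' optional SANE-style denoising of the resulting t1 interferogram; column
#' mean removal (suppresses the modulation's DC ridge); sine-bell
#' apodization and Fourier transform along t1 per column, vertical phase
#' and real part; and demodulation of the vertical axis back to true
#' frequencies via [unfold_frequency()]. Each zero-fill doubles the number
#' of spectral points across the corresponding half-band.
#'
#' @param transient a `transient2d` from [simulate_2d()].
#' @param phase a [phase_model]; required for absorption mode.
#' @param mode `"absorption"` (phase-corrected real part, the default) or
#'   `"magnitude"`.
#' @param zero_fill_h,zero_fill_v zero-fills per dimension.
#' @param apod_max sine-bell maximum position.
#' @param band_index foldover count used to demodulate the vertical axis
#'   (default: taken from the transient's ground truth).
#' @param denoise_rank if non-NULL, [sane_denoise()] rank applied to the
#'   t1 interferogram.
#' @param denoise_seed seed for the denoiser.
#' @param apod_v apodize the vertical dimension too.
#' @return object of class `spectrum2d`: `matrix` (vertical x horizontal,
#'   absorption intensities), `v_axis` (true Hz, ascending), `h_axis`
#'   (Hz), `h_axis_mz`, `cal`, `band_index`, `provenance`.
#' @export
ft_2d <- function(transient, phase = phase_model(), zero_fill_h = 1L,
                  zero_fill_v = 1L, apod_max = 0.15, band_index = NULL,
                  denoise_rank = NULL, denoise_seed = 1L, apod_v = TRUE,
                  mode = c("absorption", "magnitude")) {
  stopifnot(inherits(transient, "transient2d"))
  mode <- match.arg(mode)
  if (mode == "absorption" && is.null(phase))
    stop("absorption mode needs a phase model; pass mode = \"magnitude\" otherwise")
  params <- transient$params
  X <- transient$matrix
  if (!all(is.finite(X))) stop("transient contains non-finite values")
  if (is.null(band_index)) {
    bi <- unique(transient$ground_truth$band_index)
    if (length(bi) != 1)
      stop("ground truth spans several fold bands; supply band_index")
    band_index <- bi
  }
  prov <- list()
  # --- horizontal: apodize, FFT per row, phase (kept complex) ---
  Xw <- apodize(X, apod_max, along = 2)
  prov <- c(prov, list(list(step = "apodize_h", max_position = apod_max)))
  Lh <- 2L * ncol(X) * 2^zero_fill_h
  P <- matrix(0, Lh, nrow(X))
  P[seq_len(ncol(X)), ] <- t(Xw)
  Fh <- stats::mvfft(P)[seq_len(Lh / 2), , drop = FALSE]  # bins x t1-rows
  h_axis <- params$detect_f0 + (0:(Lh / 2 - 1)) * params$detect_rate / Lh
  prov <- c(prov, list(list(step = "fft_h", zero_fills = zero_fill_h)))
  if (!is.null(phase)) {
    # absorption interferogram: real part after horizontal phase; this also
    # confines each species' dispersive component to the horizontal axis so
    # vertical lines stay symmetric
    Fh <- Fh * exp(-1i * eval_phase_h(phase, h_axis))
    I1 <- t(Re(Fh))
    prov <- c(prov, list(list(step = "phase_h", coefficients = phase$h)))
  } else {
    I1 <- t(Mod(Fh))                    # magnitude interferogram
    prov <- c(prov, list(list(step = "magnitude_h")))
  }
  rm(Fh, P, Xw)
  # --- optional low-rank denoising of the t1 interferogram ---
  if (!is.null(denoise_rank)) {
    I1 <- sane_denoise(I1, rank = denoise_rank, seed = denoise_seed)
    prov <- c(prov, list(list(step = "sane_denoise", rank = denoise_rank,
                              seed = denoise_seed)))
  }
  # --- vertical: mean removal, apodize, FFT per column, phase ---
  I1 <- sweep(I1, 2, colMeans(I1), `-`)
  prov <- c(prov, list(list(step = "subtract_column_means")))
  if (apod_v) {
    I1 <- apodize(I1, apod_max, along = 1)
    prov <- c(prov, list(list(step = "apodize_v", max_position = apod_max)))
  }
  Lv <- 2L * nrow(I1) * 2^zero_fill_v
  fs1 <- 1 / params$t1_increment
  v_folded <- (0:(Lv / 2 - 1)) * fs1 / Lv   # within [0, fN)
  vert_phase <- if (is.null(phase)) NULL else exp(-1i * phase$v * v_folded)
  # block-wise vertical transform keeps the complex workspace bounded
  M <- matrix(0, Lv / 2, ncol(I1))
  block <- max(1L, floor(4e6 / Lv))
  for (s in seq(1L, ncol(I1), by = block)) {
    cols <- s:min(s + block - 1L, ncol(I1))
    Pv <- matrix(0, Lv, length(cols))
    Pv[seq_len(nrow(I1)), ] <- I1[, cols, drop = FALSE]
    Fv <- stats::mvfft(Pv)[seq_len(Lv / 2), , drop = FALSE]
    M[, cols] <- if (mode == "magnitude") Mod(Fv)
                 else Re(if (is.null(vert_phase)) Fv else Fv * vert_phase)
  }
  prov <- c(prov, list(list(step = "fft_v", zero_fills = zero_fill_v)))
  if (!is.null(phase))
    prov <- c(prov, list(list(step = "phase_v", coefficient = phase$v)))
  prov <- c(prov, list(list(step = paste0(mode, "_mode"))))
  rm(I1)
  v_axis <- unfold_frequency(v_folded, band_index, params)
  if (band_index %% 2 == 1) {           # mirrored band: flip to ascending
    ord <- order(v_axis)
    v_axis <- v_axis[ord]
    M <- M[ord, , drop = FALSE]
  }
  prov <- c(prov, list(list(step = "demodulate_v", band_index = band_index)))
  structure(list(matrix = M, v_axis = v_axis, v_folded = sort(v_folded),
                 h_axis = h_axis,
                 h_axis_mz = ifelse(h_axis > 0, frequency_to_mz(pmax(h_axis, 1e-9),
                                                                transient$cal), NA),
                 cal = transient$cal, params = params,
                 band_index = band_index, provenance = prov),
            class = "spectrum2d")
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf("<spectrum2d> %d x %d (vertical x horizontal)\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  vertical: %.1f-%.1f Hz (%.3g Hz/pt, band %d)\n",
              min(x$v_axis), max(x$v_axis),
              x$v_axis[2] - x$v_axis[1], x$band_index))
  cat(sprintf("  horizontal: %.0f-%.0f Hz; %d processing steps\n",
              min(x$h_axis), max(x$h_axis), length(x$provenance)))
  invisible(x)
}

#' Robust baseline correction of a 1D scan
#'
#' Subtracts a slowly varying baseline estimated by a rolling median
#' (window a configurable fraction of the profile, default 1/50), with the
#' edge regions extrapolated linearly from the adjacent baseline so flat
#' offsets and slow ramps are removed without edge artifacts.
#'
#' @param profile a `scan_profile` (see [extract_scan()]) or numeric
#'   vector.
#' @param window_frac rolling window length as a fraction of the profile.
#' @return same type as `profile`, baseline-subtracted.
#' @export
baseline_correct <- function(profile, window_frac = 1 / 50) {
  y <- if (inherits(profile, "scan_profile")) profile$intensity else profile
  n <- length(y)
  k <- max(3L, 2L * floor(n * window_frac / 2) + 1L)  # odd window
  base <- as.numeric(stats::runmed(y, k, endrule = "median"))
  w <- (k - 1L) / 2L
  if (n > 3 * w && w >= 2) {            # linear edge extrapolation
    for (side in c("lo", "hi")) {
      idx <- if (side == "lo") seq_len(w) else (n - w + 1L):n
      ref <- if (side == "lo") (w + 1L):min(n, 3L * w) else
        max(1L, n - 3L * w + 1L):(n - w)
      fit <- stats::lm.fit(cbind(1, ref), base[ref])
      base[idx] <- fit$coefficients[1] + fit$coefficients[2] * idx
    }
  }
  out <- y - base
  if (inherits(profile, "scan_profile")) {
    profile$intensity <- out
    profile
  } else out
}
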