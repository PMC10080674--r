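#' Narrowband 2D acquisition parameters
#'
#' One row of the narrowband sampling geometry: the vertical (precursor)
#' dimension samples the encoding delay t1 at increments dt1 = 1/(2 fN) for
#' a Nyquist band of width fN; precursor frequencies far above fN alias
#' ("fold") into the band. The horizontal (fragment) dimension is a
#' conventional detection transient.
#'
#' @param nyquist_vertical vertical Nyquist frequency fN, Hz.
#' @param t1_increment encoding-delay increment dt1, s; must equal
#'   1/(2 fN).
#' @param n_increments number N of t1 increments.
#' @param pulse_f_low,pulse_f_high frequency range of all pulses, Hz.
#' @param detect_points number of points in each detection transient.
#' @param detect_rate horizontal sampling rate, Hz (default: 2 x
#'   pulse_f_high, the broadband rate).
#' @param detect_f0 heterodyne reference frequency for the horizontal
#'   dimension, Hz; non-zero values narrow the detected band to
#'   [detect_f0, detect_f0 + detect_rate/2].
#' @param per_scan_overhead summed per-scan durations (accumulation,
#'   transfer, irradiation, pulses, delays), s.
#' @return object of class `acq_params`.
#' @export
acquisition_params <- function(nyquist_vertical, t1_increment, n_increments,
                               pulse_f_low, pulse_f_high,
                               detect_points = 16384L,
                               detect_rate = 2 * pulse_f_high,
                               detect_f0 = 0,
                               per_scan_overhead = 0.65) {
  stopifnot(n_increments >= 2, pulse_f_low < pulse_f_high,
            nyquist_vertical > 0, detect_points >= 2)
  if (abs(t1_increment * 2 * nyquist_vertical - 1) > 1e-9)
    stop("t1_increment must equal 1/(2 * nyquist_vertical)")
  structure(list(nyquist_vertical = nyquist_vertical,
                 t1_increment = t1_increment,
                 n_increments = as.integer(n_increments),
                 pulse_f_low = pulse_f_low, pulse_f_high = pulse_f_high,
                 detect_points = as.integer(detect_points),
                 detect_rate = detect_rate, detect_f0 = detect_f0,
                 per_scan_overhead = per_scan_overhead),
            class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("<acq_params> fN=%g kHz, dt1=%g us, N=%d, pulses %.3f-%.3f kHz\n",
              x$nyquist_vertical / 1e3, x$t1_increment * 1e6, x$n_increments,
              x$pulse_f_low / 1e3, x$pulse_f_high / 1e3))
  cat(sprintf("  detection: %d points at %g kHz (f0=%g kHz), overhead %.2f s/scan\n",
              x$detect_points, x$detect_rate / 1e3, x$detect_f0 / 1e3,
              x$per_scan_overhead))
  invisible(x)
}

# Narrowband presets: vertical Nyquist band, t1 increment, pulse range.
# Detection defaults to the desk-scale 16,384-point transient; pass
# detect_points = 524288L for the full-size record.
PRESETS <- list(
  nb10k = list(fN = 10e3, dt1 = 50e-6, f_low = 74660, f_high = 357143),
  nb4k  = list(fN = 4e3,  dt1 = 125e-6, f_low = 72171, f_high = 357143),
  nb2k  = list(fN = 2e3,  dt1 = 250e-6, f_low = 73895, f_high = 357143),
  nb1k  = list(fN = 1e3,  dt1 = 500e-6, f_low = 74402, f_high = 357143)
)

#' @rdname acquisition_params
#' @param name preset name: `"nb10k"`, `"nb4k"`, `"nb2k"`, `"nb1k"`.
#' @param ... overrides passed to [acquisition_params()]
#'   (`detect_points`, `detect_rate`, `detect_f0`, `n_increments`, ...).
#' @export
acquisition_preset <- function(name, ...) {
  if (!name %in% names(PRESETS)) stop("unknown preset: ", name)
  p <- PRESETS[[name]]
  args <- list(nyquist_vertical = p$fN, t1_increment = p$dt1,
               n_increments = 1024L, pulse_f_low = p$f_low,
               pulse_f_high = p$f_high)
  args[names(list(...))] <- list(...)
  do.call(acquisition_params, args)
}

#' Vertical-axis resolution bookkeeping
#'
#' Point spacing, maximum encoding delay, and the transform-limited minimum
#' peak FWHM of the vertical (precursor) dimension. Each zero-fill doubles
#' the number of spectral points across the folded band \[0, fN\], so the
#' spacing is fN / (N 2^zero_fills); the minimum peak FWHM 1/(N dt1) is set
#' by the maximum encoding delay and is independent of zero-filling.
#'
#' @param params an `acq_params`.
#' @param zero_fills number of vertical zero-fills (default 1).
#' @return list with `spacing_hz`, `n_points`, `max_t1_s`, `min_fwhm_hz`.
#' @examples
#' vertical_axis(acquisition_preset("nb10k"))  # 4.9 Hz spacing, 19.5 Hz FWHM
#' @export
vertical_axis <- function(params, zero_fills = 1L) {
  stopifnot(inherits(params, "acq_params"), zero_fills >= 0)
  n_pts <- params$n_increments * 2^zero_fills
  list(spacing_hz = params$nyquist_vertical / n_pts,
       n_points = n_pts,
       max_t1_s = params$n_increments * params$t1_increment,
       min_fwhm_hz = 1 / (params$n_increments * params$t1_increment))
}

#' Total acquisition duration of a 2D data set
#'
#' T = N (overhead + T_detect) + dt1 N (N - 1) / 2: every scan pays the
#' fixed per-scan overhead plus the detection transient, and the linearly
#' incremented encoding delay sums to a term growing as O(N^2). Narrowing
#' the vertical band (larger dt1) therefore lengthens the experiment even
#' at fixed N.
#'
#' @param params an `acq_params`.
#' @param detect_length length of one detection transient, s (default:
#'   detect_points / detect_rate).
#' @return duration in seconds.
#' @export
acquisition_duration <- function(params,
                                 detect_length = params$detect_points /
                                   params$detect_rate) {
  N <- params$n_increments
  N * (params$per_scan_overhead + detect_length) +
    params$t1_increment * N * (N - 1) / 2
}
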