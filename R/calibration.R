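#' Cyclotron frequency / m-z calibration
#'
#' In FT-ICR MS the (reduced) cyclotron frequency is inversely proportional
#' to m/z. Two calibration modes are supported:
#' \itemize{
#'   \item one-term: f = A / (m/z), the ideal cyclotron law;
#'   \item quadratic: m/z = A / f + B / f^2, the standard two-term internal
#'     calibration used for frequency-to-mass conversion.
#' }
#' The default constant anchors f(m/z 493.9466, 6+) = 219,272 Hz, the
#' monoisotopic 6+ precursor of the acetylated histone-peptide construct.
#'
#' @param A first calibration coefficient (Hz x Th for one-term mode).
#' @param B second coefficient (quadratic mode only; 0 gives one-term).
#' @return object of class `calibration`.
#' @examples
#' cal <- calibration()
#' mz_to_frequency(493.9466, cal)      # 219272 Hz
#' frequency_to_mz(219272, cal)
#' @export
calibration <- function(A = 493.9466 * 219272, B = 0) {
  stopifnot(A > 0)
  structure(list(mode = if (B == 0) "one-term" else "quadratic",
                 A = A, B = B), class = "calibration")
}

#' Fit a quadratic calibration from anchor points
#'
#' Solves m/z = A/f + B/f^2 exactly from two (f, m/z) anchors, or by least
#' squares from more.
#' @param f frequencies (Hz).
#' @param mz matching m/z values.
#' @return a `calibration` in quadratic mode.
#' @export
fit_calibration <- function(f, mz) {
  stopifnot(length(f) == length(mz), length(f) >= 2)
  X <- cbind(1 / f, 1 / f^2)
  coef <- qr.solve(X, mz)
  calibration(A = coef[1], B = coef[2])
}

#' @rdname calibration
#' @param mz m/z value(s), Th.
#' @param cal a `calibration`.
#' @export
mz_to_frequency <- function(mz, cal = calibration()) {
  stopifnot(all(mz > 0))
  if (cal$mode == "one-term") return(cal$A / mz)
  # invert mz = A/f + B/f^2: quadratic in u = 1/f
  vapply(mz, function(m) {
    disc <- cal$A^2 + 4 * cal$B * m
    u <- if (cal$B != 0) (-cal$A + sqrt(disc)) / (2 * cal$B) else m / cal$A
    1 / u
  }, numeric(1))
}

#' @rdname calibration
#' @param f frequency value(s), Hz.
#' @export
frequency_to_mz <- function(f, cal = calibration()) {
  stopifnot(all(f > 0))
  if (cal$mode == "one-term") cal$A / f else cal$A / f + cal$B / f^2
}
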