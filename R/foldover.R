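#' Narrowband foldover arithmetic
#'
#' With the vertical dimension sampled at dt1 = 1/(2 fN), a precursor at
#' true frequency f_true aliases into the band \[0, fN\]. Bands of width fN
#' are counted upward from the lowest pulse frequency: band n covers
#' \[pulse_f_low + n fN, pulse_f_low + (n+1) fN\]. Within a band the
#' apparent (reduced) frequency runs forward for even n and is mirrored for
#' odd n, the usual orientation alternation of real undersampling. The
#' band index n is the number of foldovers; `unfold_frequency()` restores
#' the true frequency given the band index.
#'
#' @param f_true true frequency, Hz (>= pulse_f_low).
#' @param params an `acq_params` (supplies `pulse_f_low` and fN).
#' @return `fold_frequency()`: list with `band_index`, `reduced_frequency`
#'   (in \[0, fN\]), `band_f_low`, `band_f_high`.
#' @examples
#' p <- acquisition_preset("nb4k")
#' fold_frequency(219270, p)$band_index   # 36
#' @export
fold_frequency <- function(f_true, params) {
  fN <- params$nyquist_vertical
  lo <- params$pulse_f_low
  if (any(f_true < lo)) stop("f_true below pulse_f_low")
  band <- floor((f_true - lo) / fN)
  r <- f_true - lo - band * fN
  reduced <- ifelse(band %% 2 == 0, r, fN - r)
  list(band_index = as.integer(band), reduced_frequency = reduced,
       band_f_low = lo + band * fN, band_f_high = lo + (band + 1) * fN)
}

#' @rdname fold_frequency
#' @param reduced reduced (apparent) frequency in \[0, fN\].
#' @param band_index number of foldovers.
#' @export
unfold_frequency <- function(reduced, band_index, params) {
  fN <- params$nyquist_vertical
  stopifnot(all(reduced >= -1e-9), all(reduced <= fN + 1e-9))
  even <- band_index %% 2 == 0
  r <- reduced * even + (fN - reduced) * (1 - even)
  params$pulse_f_low + band_index * fN + r
}
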