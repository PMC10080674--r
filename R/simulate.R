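#' Simulation plan for a narrowband 2D MS experiment
#'
#' Forward model of the two-pulse encoding experiment: during the encoding
#' delay t1 each precursor accrues phase at its cyclotron frequency, so its
#' post-encoding radius — and hence its ECD fragment yield — is modulated
#' at that frequency. The fragment channels follow the raised-cosine law
#' g(x) = (1 + cos x)/2 (maximal fragmentation at t1 = 0) and the
#' surviving-precursor channel follows 1 - g, their sum being conserved.
#' Loss of ion-packet coherence during t1 multiplies every channel by
#' exp(-lambda t1); each detection transient is a damped cosine with decay
#' time tau2; white Gaussian noise is added point-wise.
#'
#' Fragments are auto-selected from the ECD c/z* ladders of the listed
#' peptides, keeping species whose cyclotron frequency falls inside both
#' the pulse band and the detected horizontal window. Per-fragment
#' efficiencies are drawn once (seeded) and shared across peptides for the
#' same (kind, length, charge), as for a peptide pair with equal
#' fragmentation behavior.
#'
#' @param peptides list of `list(peptide =, charge =, abundance =)`.
#' @param params an `acq_params` (see [acquisition_preset()]).
#' @param cal a [calibration].
#' @param fragment_charges charges emitted for fragments.
#' @param fragment_kinds subset of `c("c", "z")`.
#' @param frag_efficiency mean fragment amplitude relative to precursor
#'   abundance.
#' @param efficiency_spread half-width of the uniform per-fragment
#'   efficiency jitter (fraction of `frag_efficiency`; 0 = constant).
#' @param decay_rate coherence decay rate lambda along t1, 1/s.
#' @param tau2 horizontal damping time constant, s.
#' @param noise_sd additive white-noise standard deviation (intensity
#'   units; precursor abundance 1 gives signal amplitudes of order
#'   `frag_efficiency`). The default 0.05 yields fragment-peak S/N of
#'   order 10^2 on desk-scale grids, the instrument's observed range.
#' @param phase_h quadratic horizontal phase coefficients `c(a, b, c)` of
#'   phi(f) = a f^2 + b f + c (radians; f in Hz).
#' @param include_precursor include the surviving-precursor channels.
#' @param seed RNG seed for efficiencies and noise.
#' @return object of class `sim_plan`.
#' @export
simulation_plan <- function(peptides, params, cal = calibration(),
                            fragment_charges = 1:3,
                            fragment_kinds = c("c", "z"),
                            frag_efficiency = 0.05,
                            efficiency_spread = 0.5,
                            decay_rate = 20, tau2 = 0.5,
                            noise_sd = 0.05, phase_h = c(0, 0, 0),
                            include_precursor = TRUE, seed = 1L) {
  stopifnot(inherits(params, "acq_params"), inherits(cal, "calibration"),
            decay_rate >= 0, noise_sd >= 0, tau2 > 0)
  for (p in peptides)
    stopifnot(inherits(p$peptide, "peptide"), p$charge >= 1, p$abundance > 0)
  structure(list(peptides = peptides, params = params, cal = cal,
                 fragment_charges = fragment_charges,
                 fragment_kinds = fragment_kinds,
                 frag_efficiency = frag_efficiency,
                 efficiency_spread = efficiency_spread,
                 decay_rate = decay_rate, tau2 = tau2,
                 noise_sd = noise_sd, phase_h = phase_h,
                 include_precursor = include_precursor,
                 seed = as.integer(seed)),
            class = "sim_plan")
}

# Enumerate the species (fragment and precursor channels) of a plan, with
# horizontal/vertical frequencies, amplitudes and phases.
plan_species <- function(plan) {
  params <- plan$params
  cal <- plan$cal
  f_win_lo <- max(params$pulse_f_low, params$detect_f0)
  f_win_hi <- min(params$pulse_f_high,
                  params$detect_f0 + params$detect_rate / 2)
  pair <- if (length(plan$peptides) == 2)
    lapply(plan$peptides, `[[`, "peptide") else NULL
  rows <- list()
  # seeded, shared per-fragment efficiencies
  set.seed(plan$seed + 1L)
  eff_cache <- new.env(parent = emptyenv())
  eff_of <- function(kind, len, z) {
    key <- paste(kind, len, z)
    if (is.null(eff_cache[[key]]))
      eff_cache[[key]] <- plan$frag_efficiency *
        stats::runif(1, 1 - plan$efficiency_spread, 1 + plan$efficiency_spread)
    eff_cache[[key]]
  }
  for (pp in plan$peptides) {
    f_prec <- mz_to_frequency(peptide_mz(pp$peptide, pp$charge), cal)
    if (f_prec < params$pulse_f_low || f_prec > params$pulse_f_high)
      stop("precursor frequency outside pulse band: ", f_prec)
    fold <- fold_frequency(f_prec, params)
    lad <- fragment_ladder(pp$peptide, kinds = plan$fragment_kinds,
                           charges = plan$fragment_charges,
                           pair_with = if (!is.null(pair))
                             pair[[which(vapply(pair, function(q)
                               !identical(q, pp$peptide), logical(1)))[1]]])
    lad$f_h <- mz_to_frequency(lad$mz, cal)
    lad <- lad[lad$f_h >= f_win_lo & lad$f_h <= f_win_hi, , drop = FALSE]
    for (i in seq_len(nrow(lad))) {
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pp$peptide$name, channel = "fragment",
        kind = lad$kind[i], length = lad$length[i], charge = lad$charge[i],
        category = lad$category[i], mz = lad$mz[i], f_h = lad$f_h[i],
        f_v_true = f_prec, f_v_folded = fold$reduced_frequency,
        band_index = fold$band_index,
        amplitude = pp$abundance * eff_of(lad$kind[i], lad$length[i],
                                          lad$charge[i]))
    }
    if (plan$include_precursor &&
        f_prec >= f_win_lo && f_prec <= f_win_hi) {
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pp$peptide$name, channel = "precursor",
        kind = "M", length = length(pp$peptide), charge = pp$charge,
        category = NA_integer_, mz = peptide_mz(pp$peptide, pp$charge),
        f_h = f_prec, f_v_true = f_prec,
        f_v_folded = fold$reduced_frequency, band_index = fold$band_index,
        amplitude = pp$abundance)
    }
  }
  out <- do.call(rbind, rows)
  a <- plan$phase_h
  out$phase <- a[1] * out$f_h^2 + a[2] * out$f_h + a[3]
  rownames(out) <- NULL
  out
}

#' Simulate a 2D transient
#'
#' Generates the t1 x t2 real-valued transient matrix
#' s(t1, t2) = sum_species A g(2 pi f_v^fold t1) exp(-lambda t1)
#' cos(2 pi (f_h - f0) t2 + phi) exp(-t2 / tau2) + noise, with g the
#' raised cosine for fragment channels and 1 - g for surviving precursors.
#' Vertical frequencies are the folded (demodulated) precursor frequencies
#' under the shared band/parity convention of [fold_frequency()].
#'
#' @param plan a `sim_plan`.
#' @return object of class `transient2d`: list with `matrix`
#'   (n_increments x detect_points), `params`, `cal`, `ground_truth`
#'   (the species table), `plan`, `seed`.
#' @export
simulate_2d <- function(plan) {
  stopifnot(inherits(plan, "sim_plan"))
  params <- plan$params
  sp <- plan_species(plan)
  N <- params$n_increments
  n2 <- params$detect_points
  t1 <- (0:(N - 1)) * params$t1_increment
  t2 <- (0:(n2 - 1)) / params$detect_rate
  decay1 <- exp(-plan$decay_rate * t1)
  decay2 <- exp(-t2 / plan$tau2)
  # vertical profiles: N x K
  V <- vapply(seq_len(nrow(sp)), function(k) {
    g <- (1 + cos(2 * pi * sp$f_v_folded[k] * t1)) / 2
    if (sp$channel[k] == "precursor") g <- 1 - g
    sp$amplitude[k] * g * decay1
  }, numeric(N))
  # horizontal profiles: K x n2
  H <- t(vapply(seq_len(nrow(sp)), function(k)
    cos(2 * pi * (sp$f_h[k] - params$detect_f0) * t2 + sp$phase[k]) * decay2,
    numeric(n2)))
  S <- V %*% H
  if (plan$noise_sd > 0) {
    set.seed(plan$seed)
    S <- S + matrix(stats::rnorm(N * n2, sd = plan$noise_sd), N, n2)
  }
  structure(list(matrix = S, params = params, cal = plan$cal,
                 ground_truth = sp, plan = plan, seed = plan$seed),
            class = "transient2d")
}

#' @export
print.transient2d <- function(x, ...) {
  cat(sprintf("<transient2d> %d x %d (t1 x t2), %d species, seed %d\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$ground_truth), x$seed))
  invisible(x)
}

#' Simulate a reference MS/MS transient (single scan, known phase)
#'
#' One-row analogue of [simulate_2d()]: all fragment channels at full
#' amplitude with the plan's quadratic horizontal phase injected, as a
#' stand-in for the reference tandem spectra used to determine phase
#' coefficients.
#'
#' @param plan a `sim_plan` (its `phase_h` is the injected phase).
#' @return list with `signal` (length detect_points), `rate`, `f0`,
#'   `ground_truth` (species table), `tau2`.
#' @export
simulate_reference_msms <- function(plan) {
  stopifnot(inherits(plan, "sim_plan"))
  params <- plan$params
  sp <- plan_species(plan)
  sp <- sp[sp$channel == "fragment", , drop = FALSE]
  t2 <- (0:(params$detect_points - 1)) / params$detect_rate
  decay2 <- exp(-t2 / plan$tau2)
  sig <- rep(0, params$detect_points)
  for (k in seq_len(nrow(sp)))
    sig <- sig + sp$amplitude[k] *
      cos(2 * pi * (sp$f_h[k] - params$detect_f0) * t2 + sp$phase[k]) * decay2
  if (plan$noise_sd > 0) {
    set.seed(plan$seed)
    sig <- sig + stats::rnorm(length(sig), sd = plan$noise_sd)
  }
  list(signal = sig, rate = params$detect_rate, f0 = params$detect_f0,
       ground_truth = sp, tau2 = plan$tau2)
}
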