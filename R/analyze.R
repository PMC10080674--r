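#' Added-up fragment spectrum over precursor isotope rows
#'
#' Extracts the horizontal fragment scan at each requested precursor row,
#' baseline-corrects each, and sums them. Because in narrowband mode the
#' isotope rows are not adjacent, their noise is uncorrelated and the sum
#' gains S/N roughly as sqrt(number of rows) — the 2D analogue of a tandem
#' spectrum acquired with isolation of the whole isotopic envelope.
#'
#' @param spec a `spectrum2d`.
#' @param coordinates vertical-axis values (Hz) of the precursor rows
#'   (e.g. the M..M+3 isotope rows).
#' @param baseline baseline-correct each scan before summing.
#' @param window_frac baseline window fraction (see [baseline_correct()]).
#' @return a `scan_profile` (horizontal orientation; `source` is the first
#'   coordinate).
#' @export
added_up_spectrum <- function(spec, coordinates, baseline = TRUE,
                              window_frac = 1 / 50) {
  stopifnot(inherits(spec, "spectrum2d"), length(coordinates) >= 1)
  scans <- lapply(coordinates, function(cc) {
    s <- extract_scan(spec, "horizontal", cc)
    if (baseline) s <- baseline_correct(s, window_frac) else s
  })
  total <- Reduce(`+`, lapply(scans, `[[`, "intensity"))
  out <- scans[[1]]
  out$intensity <- total
  out
}

#' Assign picked peaks to ECD fragment ladders
#'
#' Nearest-mass matching of picked peaks against the combined c/z* ladders
#' of a peptide pair, within a ppm tolerance. Ties at equal ppm error
#' between category-1 (unmodified in both peptides) ladder entries are
#' labeled `"shared"`. Sequence coverage per peptide is the fraction of
#' inter-residue bonds supported by at least one assigned c or z fragment
#' (L - 1 bonds for an L-mer).
#'
#' @param peaks data.frame from [pick_peaks()] on a horizontal scan; the
#'   `centroid` column is in Hz unless an `mz` column is present.
#' @param ladder combined data.frame from [fragment_ladder()] for both
#'   peptides (with `pair_with` categories).
#' @param tol_ppm assignment tolerance, ppm.
#' @param cal a [calibration] to convert Hz centroids to m/z (ignored if
#'   `peaks$mz` exists).
#' @return list with `assignments` (peak + fragment + `peptide`
#'   attribution + `error_ppm`), `unassigned` (peaks with no match), and
#'   `coverage` (named fraction per peptide).
#' @export
assign_fragments <- function(peaks, ladder, tol_ppm = 5, cal = NULL) {
  stopifnot(tol_ppm > 0)
  if (!"mz" %in% names(peaks)) {
    if (is.null(cal)) stop("supply a calibration or an mz column")
    peaks$mz <- frequency_to_mz(peaks$centroid, cal)
  }
  n_pep <- unique(ladder$peptide)
  assigned <- list(); un <- list()
  for (i in seq_len(nrow(peaks))) {
    ppm <- (peaks$mz[i] - ladder$mz) / ladder$mz * 1e6
    best <- which.min(abs(ppm))
    if (!length(best) || abs(ppm[best]) > tol_ppm) {
      un[[length(un) + 1L]] <- peaks[i, , drop = FALSE]
      next
    }
    ties <- which(abs(abs(ppm) - abs(ppm[best])) < 1e-9)
    pep <- if (length(ties) > 1 && all(ladder$category[ties] == 1L))
      "shared" else ladder$peptide[best]
    row <- cbind(peaks[i, , drop = FALSE],
                 ladder[best, c("kind", "length", "charge", "formula",
                                "mz", "category"), drop = FALSE] |>
                   stats::setNames(c("kind", "length", "charge", "formula",
                                     "frag_mz", "category")))
    row$peptide <- pep
    row$error_ppm <- ppm[best]
    assigned[[length(assigned) + 1L]] <- row
  }
  assignments <- if (length(assigned)) do.call(rbind, assigned) else NULL
  L <- max(ladder$length) + 1L
  coverage <- vapply(n_pep, function(pn) {
    if (is.null(assignments)) return(0)
    a <- assignments[assignments$peptide %in% c(pn, "shared"), , drop = FALSE]
    if (!nrow(a)) return(0)
    bonds <- ifelse(a$kind == "c", a$length, L - a$length)
    length(unique(bonds)) / (L - 1)
  }, numeric(1))
  list(assignments = assignments,
       unassigned = if (length(un)) do.call(rbind, un) else NULL,
       coverage = coverage)
}

#' Label-free relative quantification from paired fragment intensities
#'
#' Pairs assignments of the same (kind, length, charge) fragment across
#' the two peptides — category-3 pairs separated by the 36.4 mDa
#' trimethyl-minus-acetyl offset, and optionally category-2 pairs
#' separated by a full modification mass — and reports per-pair intensity
#' fractions plus the site-level aggregate (unweighted mean with sd).
#' Fractions are invariant under global intensity rescaling.
#'
#' @param assignments data.frame from [assign_fragments()].
#' @param categories fragment categories to use (default 2 and 3).
#' @param intensity column of `assignments` holding peak intensity.
#' @return list with `pairs` (per-pair fractions) and `summary`
#'   (per-peptide mean fraction, sd, n); `summary` fractions sum to 1.
#' @export
quantify <- function(assignments, categories = c(2L, 3L),
                     intensity = "height") {
  a <- assignments[!is.na(assignments$category) &
                     assignments$category %in% categories &
                     assignments$peptide != "shared", , drop = FALSE]
  peps <- sort(unique(a$peptide))
  if (length(peps) == 1L) {            # single-proteoform sample
    summary <- data.frame(peptide = peps, fraction = 1, sd = NA_real_,
                          n_pairs = 0L)
    return(list(pairs = NULL, summary = summary))
  }
  if (length(peps) != 2L)
    stop("quantification needs assignments for one or two peptides")
  key <- paste(a$kind, a$length, a$charge)
  pairs <- list()
  for (k in unique(key)) {
    sub <- a[key == k, , drop = FALSE]
    if (length(unique(sub$peptide)) != 2L) next
    i1 <- sub[[intensity]][match(peps[1], sub$peptide)]
    i2 <- sub[[intensity]][match(peps[2], sub$peptide)]
    pairs[[length(pairs) + 1L]] <- data.frame(
      kind = sub$kind[1], length = sub$length[1], charge = sub$charge[1],
      category = sub$category[1],
      fraction_1 = i1 / (i1 + i2), fraction_2 = i2 / (i1 + i2))
  }
  if (!length(pairs)) stop("no complete fragment pairs to quantify")
  pairs <- do.call(rbind, pairs)
  names(pairs)[names(pairs) == "fraction_1"] <- paste0("fraction_", peps[1])
  names(pairs)[names(pairs) == "fraction_2"] <- paste0("fraction_", peps[2])
  fr <- c(mean(pairs[[5]]), mean(pairs[[6]]))
  summary <- data.frame(peptide = peps, fraction = fr,
                        sd = c(stats::sd(pairs[[5]]), stats::sd(pairs[[6]])),
                        n_pairs = nrow(pairs))
  list(pairs = pairs, summary = summary)
}

#' Precursor-frequency populations of assigned fragments
#'
#' For each assigned fragment, extracts the vertical precursor scan at the
#' fragment's horizontal position, baseline-corrects it, and fits a
#' Lorentzian to its dominant peak; the fitted centers are grouped by the
#' fragment's peptide attribution (from the horizontal mass category
#' alone — the vertical positions are the measured outcome, never an input
#' to the grouping). Reports per-group means, their difference, and
#' whether the group ranges overlap. This is how precursor-fragment
#' correlation is measured below the vertical grid spacing even when the
#' precursors are unresolved.
#'
#' @param spec a `spectrum2d`.
#' @param assignments data.frame from [assign_fragments()] (rows with
#'   `peptide == "shared"` are ignored).
#' @param position column with the horizontal coordinate (Hz) of each
#'   fragment (default the picked `centroid`).
#' @param categories fragment categories used (default 2: fragments whose
#'   pair members are a full modification mass apart and therefore
#'   resolved horizontally; category-3 members 36.4 mDa apart overlap
#'   unless the horizontal record is very long, mixing both precursors in
#'   one scan).
#' @param min_per_group minimum fragments per peptide group.
#' @param exclude_flagged drop non-converged fits and fits whose RMS
#'   residual exceeds the noise floor (the overlap criterion): scans
#'   contaminated by a horizontally coinciding species carry both
#'   precursor modulations and would bias the group means.
#' @return list with `fits` (per-fragment fitted vertical centers),
#'   `group_means`, `mean_difference` (Hz), `group_sd`, `overlap`
#'   (logical).
#' @export
correlation_populations <- function(spec, assignments, position = "centroid",
                                    categories = 2L, min_per_group = 2L,
                                    exclude_flagged = TRUE) {
  a <- assignments[assignments$peptide != "shared" &
                     assignments$category %in% categories, , drop = FALSE]
  fits <- list()
  for (i in seq_len(nrow(a))) {
    scan <- extract_scan(spec, "vertical", a[[position]][i])
    scan <- baseline_correct(scan)
    pks <- pick_peaks(scan, snr_threshold = 3)
    if (!nrow(pks)) next
    fit <- lorentzian_fit(scan, pks[1, , drop = FALSE])
    fits[[length(fits) + 1L]] <- data.frame(
      peptide = a$peptide[i], kind = a$kind[i], length = a$length[i],
      charge = a$charge[i], f_vertical = fit$centroid,
      converged = fit$converged, residual_flag = fit$residual_flag)
  }
  if (!length(fits)) stop("no fragment yielded a vertical fit")
  fits <- do.call(rbind, fits)
  if (exclude_flagged) {
    keep <- fits$converged & !fits$residual_flag
    if (sum(keep) >= 2 * min_per_group) fits <- fits[keep, , drop = FALSE]
  }
  counts <- table(fits$peptide)
  if (length(counts) < 2 || any(counts < min_per_group))
    stop("need at least ", min_per_group, " fitted fragments per peptide")
  grp <- split(fits$f_vertical, fits$peptide)
  means <- vapply(grp, mean, numeric(1))
  rng <- lapply(grp, range)
  overlap <- rng[[1]][1] <= rng[[2]][2] && rng[[2]][1] <= rng[[1]][2]
  list(fits = fits, group_means = means,
       mean_difference = abs(diff(means))[[1]],
       group_sd = vapply(grp, stats::sd, numeric(1)),
       overlap = overlap)
}

#' Coherence-decay rate from the precursor channel
#'
#' Computes the per-t1 amplitude of a horizontal frequency channel (single
#' -bin Fourier sum per row), extracts the upper envelope of the radius
#' -modulation oscillation by block maxima, and fits A exp(-lambda t1) to
#' the envelope. The fitted lambda estimates the coherence decay rate of
#' the ion packet (1/s; a rate of 20 1/s corresponds to a ~50 ms
#' characteristic time / ~35 ms half-life).
#'
#' @param transient a `transient2d`.
#' @param f_channel horizontal frequency of the channel, Hz (default: the
#'   first precursor channel in the ground truth).
#' @param block envelope block length in t1 samples (should span at least
#'   one modulation period).
#' @return list with `rate` (1/s), `envelope` (data.frame t1, amplitude),
#'   `fit` (nls object or NULL for a flat envelope).
#' @export
decay_envelope <- function(transient, f_channel = NULL, block = 8L) {
  stopifnot(inherits(transient, "transient2d"))
  params <- transient$params
  if (is.null(f_channel)) {
    gt <- transient$ground_truth
    prec <- gt[gt$channel == "precursor", , drop = FALSE]
    if (!nrow(prec)) stop("no precursor channel in ground truth")
    f_channel <- prec$f_h[1]
  }
  n2 <- ncol(transient$matrix)
  t2 <- (0:(n2 - 1)) / params$detect_rate
  e <- exp(-2i * pi * (f_channel - params$detect_f0) * t2)
  amp <- Mod(transient$matrix %*% e)[, 1]
  t1 <- (0:(nrow(transient$matrix) - 1)) * params$t1_increment
  nb <- floor(length(amp) / block)
  idx <- vapply(seq_len(nb), function(b) {
    sel <- ((b - 1) * block + 1):(b * block)
    sel[which.max(amp[sel])]
  }, integer(1))
  env <- data.frame(t1 = t1[idx], amplitude = amp[idx])
  # log-linear start, then exponential least squares
  pos <- env$amplitude > 0
  slope <- stats::coef(stats::lm(log(amplitude) ~ t1, data = env[pos, ]))[[2]]
  start <- list(A = max(env$amplitude), r = max(-slope, 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(amplitude ~ A * exp(-r * t1), data = env,
                      start = start, lower = c(A = 0, r = 0)),
    error = function(e) NULL)
  rate <- if (is.null(fit)) max(-slope, 0) else stats::coef(fit)[["r"]]
  list(rate = rate, envelope = env, fit = fit)
}
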