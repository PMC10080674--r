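#' Isotopologue fine structure of an elemental formula
#'
#' Enumerates, per nominal isotope shift (M, M+1, ... M+max_shift), every
#' distinct heavy-isotope substitution combination, with its exact mass and
#' abundance from the pinned isotope table. Within one nominal peak this
#' resolves the fine structure: e.g. the M+1 cluster of a large
#' biotinylated peptide splits into 13C, 2H, 15N, 17O and 33S isotopologues
#' spanning more than 9 mDa, with the non-13C species contributing about
#' 13% of the cluster's abundance.
#'
#' Abundances are normalized so the returned pattern (shifts 0..max_shift)
#' sums to 1; within a nominal shift, fine-structure abundances sum to that
#' shift's total.
#'
#' @param formula formula string or named element-count vector.
#' @param max_shift largest nominal shift (integer >= 0) to enumerate.
#' @return an `isotope_pattern`: list with `fine` (data.frame `shift`,
#'   `label`, `mass`, `abundance`) and `peaks` (per-shift aggregate with
#'   abundance-weighted mean mass).
#' @examples
#' isotopologue_pattern("CH4", max_shift = 1)
#' @export
isotopologue_pattern <- function(formula, max_shift = 2L) {
  stopifnot(max_shift >= 0)
  f <- parse_formula(formula)
  base_mass <- sum(f * MONO_MASS[names(f)])
  # configs: list of (shift, log_abundance_rel, delta_mass, label parts)
  configs <- data.frame(shift = 0L, logab = 0, dmass = 0, label = "",
                        stringsAsFactors = FALSE)
  for (el in names(f)) {
    el_cfg <- element_configs(el, f[[el]], max_shift)
    # convolve, pruning shifts beyond max_shift
    n1 <- nrow(configs); n2 <- nrow(el_cfg)
    idx1 <- rep(seq_len(n1), times = n2)
    idx2 <- rep(seq_len(n2), each = n1)
    sh <- configs$shift[idx1] + el_cfg$shift[idx2]
    keep <- sh <= max_shift
    configs <- data.frame(
      shift = sh[keep],
      logab = configs$logab[idx1][keep] + el_cfg$logab[idx2][keep],
      dmass = configs$dmass[idx1][keep] + el_cfg$dmass[idx2][keep],
      label = paste0(configs$label[idx1][keep],
                     ifelse(configs$label[idx1][keep] != "" &
                              el_cfg$label[idx2][keep] != "", "+", ""),
                     el_cfg$label[idx2][keep]),
      stringsAsFactors = FALSE)
  }
  ab <- exp(configs$logab)
  ab <- ab / sum(ab)
  fine <- data.frame(shift = configs$shift,
                     label = ifelse(configs$label == "", "monoisotopic",
                                    configs$label),
                     mass = base_mass + configs$dmass,
                     abundance = ab, stringsAsFactors = FALSE)
  fine <- fine[order(fine$shift, fine$mass), , drop = FALSE]
  rownames(fine) <- NULL
  peaks <- do.call(rbind, lapply(split(fine, fine$shift), function(d)
    data.frame(shift = d$shift[1],
               mass = sum(d$mass * d$abundance) / sum(d$abundance),
               abundance = sum(d$abundance))))
  rownames(peaks) <- NULL
  structure(list(fine = fine, peaks = peaks, formula = formula_string(f)),
            class = "isotope_pattern")
}

# All heavy-substitution count vectors for `n` atoms of element `el` with
# total nominal shift <= max_shift. Relative abundance (vs all-light) in
# log space: log multinomial coefficient + sum k_i log(p_i / p_0).
element_configs <- function(el, n, max_shift) {
  tab <- ISOTOPE_TABLE[[el]]
  heav <- tab[-1, , drop = FALSE]
  heav <- heav[heav$shift <= max_shift & heav$abundance > 0, , drop = FALSE]
  if (!nrow(heav))
    return(data.frame(shift = 0L, logab = 0, dmass = 0, label = "",
                      stringsAsFactors = FALSE))
  # per-heavy-isotope max count bounded by shift budget and atom count
  kmax <- pmin(floor(max_shift / heav$shift), n)
  grid <- expand.grid(lapply(kmax, function(k) 0:k))
  tot_sub <- rowSums(grid)
  tot_shift <- as.integer(as.matrix(grid) %*% heav$shift)
  keep <- tot_shift <= max_shift & tot_sub <= n
  grid <- grid[keep, , drop = FALSE]
  tot_sub <- tot_sub[keep]; tot_shift <- tot_shift[keep]
  p0 <- tab$abundance[1]
  logab <- vapply(seq_len(nrow(grid)), function(i) {
    k <- as.numeric(grid[i, ])
    lgamma(n + 1) - lgamma(n - tot_sub[i] + 1) - sum(lgamma(k + 1)) +
      sum(k * log(heav$abundance / p0))
  }, numeric(1))
  dmass <- as.numeric(as.matrix(grid) %*% (heav$mass - tab$mass[1]))
  label <- vapply(seq_len(nrow(grid)), function(i) {
    k <- as.numeric(grid[i, ])
    nz <- which(k > 0)
    paste0(heav$label[nz], ifelse(k[nz] > 1, k[nz], ""), collapse = "+")
  }, character(1))
  data.frame(shift = tot_shift, logab = logab, dmass = dmass, label = label,
             stringsAsFactors = FALSE)
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("<isotope_pattern> ", x$formula, "\n", sep = "")
  print(x$peaks)
  invisible(x)
}

#' Share of a nominal isotope peak carried by given substitution types
#'
#' Fraction of one nominal shift's total abundance contributed by
#' isotopologues involving any of the named heavy isotopes (e.g. the
#' non-13C share of M+1: `c("2H", "15N", "17O", "33S")`).
#'
#' @param pattern an `isotope_pattern`.
#' @param shift nominal shift to interrogate.
#' @param isotopes character vector of heavy-isotope labels.
#' @return fraction in [0, 1].
#' @export
isotope_share <- function(pattern, shift, isotopes) {
  fine <- pattern$fine[pattern$fine$shift == shift, , drop = FALSE]
  if (!nrow(fine)) stop("no isotopologues at shift ", shift)
  hit <- vapply(strsplit(fine$label, "+", fixed = TRUE), function(parts)
    any(sub("[0-9]+$", "", parts) %in% isotopes), logical(1))
  sum(fine$abundance[hit]) / sum(fine$abundance)
}
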