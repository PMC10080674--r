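#' Elemental formulas
#'
#' Formulas are named integer vectors of element counts (e.g.
#' `c(C = 2, H = 3, N = 1, O = 1)` for a glycine residue). These helpers
#' parse Hill-style formula strings, combine formulas, and compute the
#' monoisotopic (most-abundant-isotope) mass.
#'
#' @param x a formula string such as `"C2H3NO"`, or a named numeric vector
#'   of element counts.
#' @return `parse_formula()` returns a named integer vector;
#'   `formula_add()` the element-wise sum; `formula_string()` a compact
#'   Hill-order string.
#' @examples
#' parse_formula("C2H2O")            # acetyl delta
#' monoisotopic_mass("C2H2O")        # 42.0106 Da
#' @export
parse_formula <- function(x) {
  if (is.numeric(x)) {
    counts <- x
    bad <- setdiff(names(counts), names(ISOTOPE_TABLE))
    if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    return(counts[counts != 0])
  }
  stopifnot(is.character(x), length(x) == 1L)
  s <- gsub("\\s", "", x)
  if (s == "") return(stats::setNames(numeric(0), character(0)))
  toks <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
  if (nchar(paste(toks, collapse = "")) != nchar(s))
    stop("cannot parse formula: ", x)
  counts <- numeric(0)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (n == "") 1 else as.numeric(n)
    if (!el %in% names(ISOTOPE_TABLE))
      stop("unknown element symbol: ", el)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) + n
  }
  counts
}

#' @rdname parse_formula
#' @param ... formulas (strings or named count vectors) to sum.
#' @export
formula_add <- function(...) {
  parts <- lapply(list(...), parse_formula)
  els <- unique(unlist(lapply(parts, names)))
  out <- stats::setNames(numeric(length(els)), els)
  for (p in parts) out[names(p)] <- out[names(p)] + p
  out[out != 0]
}

#' @rdname parse_formula
#' @export
formula_string <- function(x) {
  f <- parse_formula(x)
  hill <- c(intersect(c("C", "H"), names(f)),
            sort(setdiff(names(f), c("C", "H"))))
  paste0(vapply(hill, function(el) {
    n <- f[[el]]
    paste0(el, if (n != 1) n else "")
  }, character(1)), collapse = "")
}

#' Monoisotopic mass
#'
#' Sum of most-abundant-isotope atomic masses over a formula, peptide, or
#' named modification. Peptides include their terminal groups (H2O for a
#' free amine / free acid chain) and all modification deltas.
#'
#' @param entity a formula string, a named element-count vector, a
#'   [peptide] object, or a modification name from the built-in table.
#' @return mass in Da.
#' @examples
#' monoisotopic_mass("C2H2O")     # acetyl, 42.0106
#' monoisotopic_mass("C3H6")      # trimethyl, 42.0470
#' @export
monoisotopic_mass <- function(entity) {
  if (inherits(entity, "peptide"))
    return(monoisotopic_mass(peptide_formula(entity)))
  if (is.character(entity) && length(entity) == 1L &&
      entity %in% names(MODIFICATIONS))
    return(monoisotopic_mass(MODIFICATIONS[[entity]]))
  f <- parse_formula(entity)
  sum(f * MONO_MASS[names(f)])
}

#' Mass-to-charge ratio of a protonated species
#'
#' @param neutral_mass neutral monoisotopic mass in Da.
#' @param z positive charge (number of protons added).
#' @return m/z in Th (Da per charge).
#' @export
mz_of <- function(neutral_mass, z) {
  stopifnot(z >= 1)
  (neutral_mass + z * PROTON_MASS) / z
}
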