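#' Peptides with site-specific modifications
#'
#' A `peptide` is an ordered amino-acid sequence plus a list of
#' site-specific modifications (position, name). Terminal groups default to
#' a free amine (H) and free acid (OH), so the neutral chain mass is the
#' residue sum plus H2O plus all modification deltas.
#'
#' `parse_peptide()` accepts either a plain sequence with an explicit
#' modification list, or a bracket notation embedding modifications in the
#' sequence: `"ATKAAR[K+ac]SAPATGGVKKPHRYRPGG[K+bio]"` marks an acetyl on
#' the bracketed K and a biotinyl on the final K. Recognized modification
#' names/aliases: acetyl/ac, trimethyl/me3/3m, biotinyl/bio.
#'
#' @param spec sequence string, optionally with `[X+mod]` brackets.
#' @param modifications list of `list(position =, name =)` pairs (or a
#'   2-column data.frame) applied on top of any bracket annotations.
#' @param name label for the peptide.
#' @return an object of class `peptide` with fields `name`, `residues`
#'   (character vector), `modifications` (data.frame `position`, `name`).
#' @examples
#' p <- parse_peptide("ATKAARKSAPATGGVKKPHRYRPGGK",
#'                    modifications = list(list(position = 7, name = "acetyl"),
#'                                         list(position = 26, name = "biotinyl")),
#'                    name = "K7 Ac")
#' monoisotopic_mass(p)
#' @export
parse_peptide <- function(spec, modifications = list(), name = "peptide") {
  stopifnot(is.character(spec), length(spec) == 1L)
  residues <- character(0)
  mods <- data.frame(position = integer(0), name = character(0))
  i <- 1L
  chars <- strsplit(spec, "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(j)) stop("unbalanced '[' in peptide spec")
      tok <- paste(chars[(i + 1):(j - 1)], collapse = "")
      parts <- strsplit(tok, "+", fixed = TRUE)[[1]]
      residues <- c(residues, parts[1])
      if (length(parts) > 1) {
        nm <- resolve_modification(parts[2])
        mods <- rbind(mods, data.frame(position = length(residues), name = nm))
      }
      i <- j + 1L
    } else {
      residues <- c(residues, ch)
      i <- i + 1L
    }
  }
  if (length(modifications)) {
    if (is.data.frame(modifications)) {
      extra <- modifications
    } else {
      extra <- do.call(rbind, lapply(modifications, function(m)
        data.frame(position = as.integer(m$position),
                   name = resolve_modification(m$name))))
    }
    extra$name <- vapply(extra$name, resolve_modification, character(1))
    mods <- rbind(mods, extra)
  }
  bad <- setdiff(residues, names(AMINO_ACIDS))
  if (length(bad)) stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  if (nrow(mods)) {
    if (any(mods$position < 1 | mods$position > length(residues)))
      stop("modification position out of range [1, ", length(residues), "]")
    if (anyDuplicated(mods$position))
      stop("at most one modification per position")
    mods <- mods[order(mods$position), , drop = FALSE]
    rownames(mods) <- NULL
  }
  structure(list(name = name, residues = residues, modifications = mods,
                 n_term = "H", c_term = "OH"),
            class = "peptide")
}

resolve_modification <- function(nm) {
  nm <- tolower(nm)
  if (!nm %in% names(MODIFICATION_ALIASES))
    stop("unknown modification: ", nm,
         " (known: ", paste(unique(MODIFICATION_ALIASES), collapse = ", "), ")")
  unname(MODIFICATION_ALIASES[nm])
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", x$name, ": ", paste(x$residues, collapse = ""),
      " (", length(x$residues), " residues)\n", sep = "")
  if (nrow(x$modifications))
    cat("  modifications: ",
        paste(sprintf("%s@%d", x$modifications$name, x$modifications$position),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.peptide <- function(x) length(x$residues)

#' Elemental composition of a peptide (or a sub-span of it)
#'
#' @param p a [peptide].
#' @param span integer range of residue positions (default: whole chain).
#' @param terminal logical; include the terminal H2O of the intact chain.
#' @return named element-count vector, including modification deltas whose
#'   site falls inside `span`.
#' @export
peptide_formula <- function(p, span = seq_along(p$residues), terminal = TRUE) {
  stopifnot(inherits(p, "peptide"))
  f <- Reduce(function(a, b) formula_add(a, b), AMINO_ACIDS[p$residues[span]])
  if (nrow(p$modifications)) {
    inside <- p$modifications$position %in% span
    for (nm in p$modifications$name[inside]) f <- formula_add(f, MODIFICATIONS[[nm]])
  }
  if (terminal) f <- formula_add(f, c(H = 2, O = 1))
  f
}

#' Precursor m/z of a peptide at charge z
#' @inheritParams peptide_formula
#' @param z positive charge.
#' @export
peptide_mz <- function(p, z) mz_of(monoisotopic_mass(p), z)

#' Built-in fixtures: the acetylated / trimethylated histone-peptide pair
#' and the four narrowband acquisition presets
#'
#' `fixture_suite("histone_pair")` returns the two 26-residue histone H3
#' tail constructs (the 24-mer spanning H3 residues 21-44 with an appended
#' C-terminal GK carrying a biotinyl): "K7 Ac" acetylated at K7 and
#' "K16 3m" trimethylated at K16. `fixture_suite("nb10k")` (`nb4k`,
#' `nb2k`, `nb1k`) returns the matching narrowband acquisition preset.
#'
#' @param name fixture name: `"histone_pair"`, `"nb10k"`, `"nb4k"`,
#'   `"nb2k"`, or `"nb1k"`.
#' @param ... passed on to [acquisition_preset()] for the preset fixtures.
#' @return a list of two [peptide]s, or an `acq_params` object.
#' @export
fixture_suite <- function(name, ...) {
  switch(name,
    histone_pair = {
      seqs <- "ATKAARKSAPATGGVKKPHRYRPGGK"
      list(
        k7ac = parse_peptide(seqs, name = "K7 Ac",
          modifications = list(list(position = 7, name = "acetyl"),
                               list(position = 26, name = "biotinyl"))),
        k16me3 = parse_peptide(seqs, name = "K16 3m",
          modifications = list(list(position = 16, name = "trimethyl"),
                               list(position = 26, name = "biotinyl"))))
    },
    nb10k = acquisition_preset("nb10k", ...),
    nb4k = acquisition_preset("nb4k", ...),
    nb2k = acquisition_preset("nb2k", ...),
    nb1k = acquisition_preset("nb1k", ...),
    stop("unknown fixture: ", name)
  )
}
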