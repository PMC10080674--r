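#' ECD c / z-radical fragment ladders
#'
#' Electron capture dissociation cleaves the backbone N-Calpha bond, giving
#' amide-terminated N-terminal c fragments and radical C-terminal z*
#' fragments. Conventions used here:
#' \itemize{
#'   \item c_n neutral = sum of residues 1..n + NH3;
#'   \item z*_m neutral = y_m neutral - NH2, where y_m neutral = sum of
#'     residues (L-m+1)..L + H2O;
#'   \item m/z = (neutral + z * 1.007276) / z.
#' }
#' Mass closure: c_n + z*_(L-n) = M + NH3 - NH2 = M + 1.00783 Da for every
#' cleavage site.
#'
#' When a second peptide of the pair is supplied, each fragment is labeled
#' with its mass-difference category for the pair: category 1 contains no
#' modified residue in either peptide (identical masses), category 2
#' contains a modification site in exactly one of the two (masses ~42 Da
#' apart), category 3 contains the acetyl site in one and the trimethyl
#' site in the other (masses 36.4 mDa apart).
#'
#' @param p a [peptide].
#' @param kinds subset of `c("c", "z")` (z means the z-radical ion).
#' @param charges integer vector of positive charges to emit.
#' @param pair_with optional second [peptide] for category labeling.
#' @return data.frame with columns `peptide`, `kind`, `length`, `charge`,
#'   `formula` (Hill string), `neutral_mass`, `mz`, `category` (NA without
#'   `pair_with`).
#' @examples
#' pair <- fixture_suite("histone_pair")
#' lad <- fragment_ladder(pair$k7ac, charges = 1:3, pair_with = pair$k16me3)
#' head(lad)
#' @export
fragment_ladder <- function(p, kinds = c("c", "z"), charges = 1L,
                            pair_with = NULL) {
  stopifnot(inherits(p, "peptide"), all(kinds %in% c("c", "z")),
            all(charges >= 1))
  L <- length(p$residues)
  nh3 <- c(N = 1, H = 3)
  nh2 <- c(N = 1, H = 2)
  rows <- list()
  for (kind in kinds) {
    for (n in seq_len(L - 1)) {
      span <- if (kind == "c") 1:n else (L - n + 1):L
      f <- peptide_formula(p, span = span, terminal = FALSE)
      f <- if (kind == "c") formula_add(f, nh3)
           else { # y neutral minus NH2
             g <- formula_add(f, c(H = 2, O = 1))
             g[names(nh2)] <- g[names(nh2)] - nh2
             g[g != 0]
           }
      mass <- monoisotopic_mass(f)
      cat_lab <- if (is.null(pair_with)) NA_integer_
                 else fragment_category(p, pair_with, kind, n)
      for (z in charges) {
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = p$name, kind = kind, length = n, charge = z,
          formula = formula_string(f), neutral_mass = mass,
          mz = mz_of(mass, z), category = cat_lab)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Scheme of the three mass-difference categories for a peptide pair with
# one variable modification each (shared modifications are ignored).
fragment_category <- function(p, q, kind, n) {
  L <- length(p$residues)
  span <- if (kind == "c") 1:n else (L - n + 1):L
  vp <- variable_sites(p, q)
  vq <- variable_sites(q, p)
  in_p <- length(vp) && any(vp %in% span)
  in_q <- length(vq) && any(vq %in% span)
  if (in_p && in_q) 3L else if (in_p || in_q) 2L else 1L
}

# Modification positions of p that are not matched (same position+name) in q.
variable_sites <- function(p, q) {
  mp <- p$modifications; mq <- q$modifications
  if (!nrow(mp)) return(integer(0))
  keys_q <- if (nrow(mq)) paste(mq$position, mq$name) else character(0)
  mp$position[!(paste(mp$position, mp$name) %in% keys_q)]
}

#' Export a fragment ladder as CSV
#'
#' @param ladder data.frame from [fragment_ladder()].
#' @param path output file path.
#' @export
write_fragments_csv <- function(ladder, path) {
  utils::write.csv(ladder, path, row.names = FALSE)
  invisible(path)
}
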