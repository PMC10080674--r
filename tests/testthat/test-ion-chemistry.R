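test_that("peptide parsing validates residues and modification positions", {
  p <- parse_peptide("ATKAARKSAPATGGVKKPHRYRPGGK",
                     modifications = list(list(position = 7, name = "acetyl"),
                                          list(position = 26, name = "biotinyl")),
                     name = "K7 Ac")
  expect_s3_class(p, "peptide")
  expect_length(p, 26)
  expect_equal(p$modifications$position, c(7L, 26L))
  expect_equal(p$modifications$name, c("acetyl", "biotinyl"))

  # bracket notation gives the same construct
  pb <- parse_peptide("ATKAAR[K+ac]SAPATGGVKKPHRYRPG[G][K+bio]")
  expect_equal(pb$modifications, p$modifications)
  expect_equal(pb$residues, p$residues)

  # no modifications: plain chain, mass = residues + H2O
  p0 <- parse_peptide("GAG")
  expect_equal(nrow(p0$modifications), 0)
  expect_equal(monoisotopic_mass(p0),
               2 * monoisotopic_mass("C2H3NO") + monoisotopic_mass("C3H5NO") +
                 monoisotopic_mass("H2O"))

  expect_error(parse_peptide("ATKB"), "unknown residue")
  expect_error(parse_peptide("ATK",
                             modifications = list(list(position = 27,
                                                       name = "acetyl"))),
               "out of range")
  expect_error(parse_peptide("ATK",
                             modifications = list(list(position = 1, name = "ac"),
                                                  list(position = 1, name = "bio"))),
               "one modification per position")
  expect_error(parse_peptide("ATK",
                             modifications = list(list(position = 1,
                                                       name = "phospho"))),
               "unknown modification")
})

test_that("monoisotopic masses match the modification and residue values", {
  expect_equal(monoisotopic_mass("acetyl"), 42.0106, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("trimethyl"), 42.047, tolerance = 1e-4)
  # glycine residue, summed from the pinned atomic masses
  expect_equal(monoisotopic_mass("C2H3NO"), 57.02146, tolerance = 1e-5)
  expect_error(monoisotopic_mass("Xx7"), "unknown element")
  # the two histone constructs are near-isobaric: one trimethyl-acetyl apart
  dm <- monoisotopic_mass(histone_pair$k16me3) -
    monoisotopic_mass(histone_pair$k7ac)
  expect_equal(dm, monoisotopic_mass("C3H6") - monoisotopic_mass("C2H2O"))
})

test_that("fragment ladders follow the c / z-radical conventions", {
  ladd <- fragment_ladder(histone_pair$k7ac, charges = 1:3,
                          pair_with = histone_pair$k16me3)
  lad3m <- fragment_ladder(histone_pair$k16me3, charges = 1:3,
                           pair_with = histone_pair$k7ac)
  # z13(3+) differs by trimethyl/3 between the constructs (category 2)
  z13a <- subset(ladd, kind == "z" & length == 13 & charge == 3)
  z13b <- subset(lad3m, kind == "z" & length == 13 & charge == 3)
  expect_equal(z13b$mz - z13a$mz, 42.04695 / 3, tolerance = 1e-4)
  expect_equal(z13a$category, 2L)
  # c6 precedes both modification sites: identical in the pair (category 1)
  c6a <- subset(ladd, kind == "c" & length == 6 & charge == 1)
  c6b <- subset(lad3m, kind == "c" & length == 6 & charge == 1)
  expect_equal(c6a$mz, c6b$mz)
  expect_equal(c6a$category, 1L)
  # c16 contains both sites: the 36.4 mDa category-3 offset
  c16a <- subset(ladd, kind == "c" & length == 16 & charge == 1)
  c16b <- subset(lad3m, kind == "c" & length == 16 & charge == 1)
  expect_equal(c16b$neutral_mass - c16a$neutral_mass, 0.0364, tolerance = 1e-3)
  expect_equal(c16a$category, 3L)
})

test_that("c + z mass closure holds at every cleavage site", {
  for (pep in histone_pair) {
    lad <- fragment_ladder(pep, charges = 1L)
    M <- monoisotopic_mass(pep)
    L <- length(pep)
    closure <- vapply(seq_len(L - 1), function(n) {
      cn <- subset(lad, kind == "c" & length == n)$neutral_mass
      zm <- subset(lad, kind == "z" & length == L - n)$neutral_mass
      cn + zm - M
    }, numeric(1))
    # c_n + z*_(L-n) = M + NH3 - NH2 = M + 1.00783, constant across n
    expect_equal(closure, rep(1.00783, L - 1), tolerance = 1e-4)
  }
})

test_that("category-3 pairs differ by exactly trimethyl - acetyl per charge", {
  delta <- monoisotopic_mass("C3H6") - monoisotopic_mass("C2H2O")
  ladd <- fragment_ladder(histone_pair$k7ac, charges = 1:3,
                          pair_with = histone_pair$k16me3)
  lad3m <- fragment_ladder(histone_pair$k16me3, charges = 1:3,
                           pair_with = histone_pair$k7ac)
  cat3 <- subset(ladd, category == 3)
  expect_gt(nrow(cat3), 10)
  for (i in seq_len(nrow(cat3))) {
    match_row <- subset(lad3m, kind == cat3$kind[i] &
                          length == cat3$length[i] & charge == cat3$charge[i])
    expect_equal(match_row$mz - cat3$mz[i], delta / cat3$charge[i],
                 tolerance = 1e-9)
  }
})

# Brute-force oracle: enumerate every per-atom isotope assignment of a
# small formula and aggregate probability mass by (shift, exact mass).
brute_force_pattern <- function(formula, max_shift) {
  f <- parse_formula(formula)
  atoms <- rep(names(f), times = f)
  tabs <- lapply(atoms, function(el) ISOTOPE_TABLE_test[[el]])
  grid <- expand.grid(lapply(tabs, function(tab) seq_len(nrow(tab))))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    sel <- as.integer(grid[i, ])
    sh <- sum(vapply(seq_along(sel), function(j) tabs[[j]]$shift[sel[j]],
                     integer(1)))
    if (sh > max_shift) next
    mass <- sum(vapply(seq_along(sel), function(j) tabs[[j]]$mass[sel[j]],
                       numeric(1)))
    prob <- prod(vapply(seq_along(sel), function(j)
      tabs[[j]]$abundance[sel[j]], numeric(1)))
    key <- sprintf("%d|%.9f", sh, mass)
    out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) + prob
  }
  df <- data.frame(key = names(out), p = unlist(out))
  df$p <- df$p / sum(df$p)
  df[order(df$key), ]
}
ISOTOPE_TABLE_test <- getFromNamespace("ISOTOPE_TABLE", "icr2d")

test_that("isotopologue fine structure matches brute-force enumeration", {
  for (fml in c("CH4", "C2H3NO", "H2OS")) {
    for (ms in 0:2) {
      pat <- isotopologue_pattern(fml, max_shift = ms)
      got <- data.frame(
        key = sprintf("%d|%.9f", pat$fine$shift, pat$fine$mass),
        p = pat$fine$abundance)
      got <- got[order(got$key), ]
      want <- brute_force_pattern(fml, ms)
      expect_equal(got$key, want$key)
      expect_equal(got$p, unname(want$p), tolerance = 1e-9)
    }
  }
})

test_that("isotope patterns are normalized even for very large formulas", {
  # ~10,000 atoms
  pat <- isotopologue_pattern(c(C = 4000, H = 5000, N = 600, O = 390, S = 10),
                              max_shift = 3)
  expect_equal(sum(pat$fine$abundance), 1, tolerance = 1e-9)
  expect_equal(sum(pat$peaks$abundance), 1, tolerance = 1e-9)
  # fine structure sums to its shift total
  for (s in 0:3)
    expect_equal(sum(pat$fine$abundance[pat$fine$shift == s]),
                 pat$peaks$abundance[pat$peaks$shift == s])
})

test_that("precursor M+1 cluster: ~13% non-13C share spread over > 9 mDa", {
  fml <- peptide_formula(histone_pair$k7ac)
  pat <- isotopologue_pattern(fml, max_shift = 1)
  share <- isotope_share(pat, 1, c("2H", "15N", "17O", "33S"))
  expect_equal(100 * share, 13, tolerance = 1.5 / 13)  # within 1.5 points
  m1 <- pat$fine[pat$fine$shift == 1, ]
  expect_gt(diff(range(m1$mass)), 9e-3)   # 2H vs 15N substitution spread
  expect_setequal(m1$label, c("13C", "2H", "15N", "17O", "33S"))
})

test_that("fragment CSV export round-trips", {
  lad <- fragment_ladder(histone_pair$k7ac, charges = 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fragments_csv(lad, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(lad))
  expect_equal(back$mz, lad$mz, tolerance = 1e-12)
})
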