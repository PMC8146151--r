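# Peptide and protein mass arithmetic, and isoelectric points.
#
# Masses are neutral (uncharged). Peptide masses for fingerprint matching
# are monoisotopic by MALDI-TOF convention; whole-protein molecular weights
# are average-isotope and reported in kDa.

.residue_mass_vector <- function(mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  tab <- residue_masses()
  stats::setNames(tab[[mode]], tab$residue)
}

.mod_delta <- function(modification, mode) {
  tab <- modification_deltas()
  row <- tab[tab$modification == modification, ]
  if (nrow(row) != 1L) stop("unknown modification: ", modification)
  list(delta = row[[mode]], target = row$target)
}

#' Neutral peptide mass
#'
#' Computes the neutral mass of a peptide as the sum of its residue masses
#' plus one water, with optional fixed and variable modifications. Fixed
#' modifications are applied to every target residue; variable modifications
#' to the stated count of target residues.
#'
#' @param seq Amino-acid string (20 standard residues).
#' @param fixed_mods Character vector of fixed modification names applied to
#'   every target residue (default `"carbamidomethyl"`, targeting C).
#' @param variable_mod_count Number of variable oxidation events to apply
#'   (targets M); must not exceed the number of target residues.
#' @param variable_mod Name of the variable modification (default
#'   `"oxidation"`).
#' @param mode `"monoisotopic"` (default) or `"average"`.
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass("G", fixed_mods = character())  # glycine: 75.03203 Da
#' @export
peptide_mass <- function(seq, fixed_mods = "carbamidomethyl",
                         variable_mod_count = 0L,
                         variable_mod = "oxidation",
                         mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  chars <- .check_residues(seq, what = "peptide")
  rm <- .residue_mass_vector(mode)
  water <- if (mode == "monoisotopic") WATER_MONO else WATER_AVG
  mass <- sum(rm[chars]) + water
  for (fm in fixed_mods) {
    md <- .mod_delta(fm, mode)
    mass <- mass + md$delta * sum(chars == md$target)
  }
  if (variable_mod_count > 0L) {
    md <- .mod_delta(variable_mod, mode)
    n_target <- sum(chars == md$target)
    if (variable_mod_count > n_target) {
      stop("variable_mod_count (", variable_mod_count,
           ") exceeds available target residues (", n_target, ")")
    }
    mass <- mass + md$delta * variable_mod_count
  }
  unname(mass)
}

#' Average protein molecular weight in kDa
#'
#' Average-isotope molecular weight of an unmodified protein or segment,
#' reported in kDa. Rounding to one decimal matches the usual "p47.8"-style
#' labelling of calculated capsid-protein weights.
#'
#' @param seq Amino-acid string.
#' @return Molecular weight in kDa.
#' @export
protein_average_mw <- function(seq) {
  chars <- .check_residues(seq, what = "protein")
  rm <- .residue_mass_vector("average")
  (sum(rm[chars]) + WATER_AVG) / 1000
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch charge model: the N-terminus and the side chains of
#' H, K and R contribute `+1/(1 + 10^(pH - pKa))`; the C-terminus and the
#' side chains of D, E, C and Y contribute `-1/(1 + 10^(pKa - pH))`.
#'
#' @param seq Amino-acid string.
#' @param pH pH value (may be a vector).
#' @param pka Named pKa vector as returned by [pka_table()].
#' @return Net charge (same length as `pH`).
#' @export
net_charge <- function(seq, pH, pka = pka_table()) {
  chars <- .check_residues(seq, what = "peptide")
  counts <- table(factor(chars, levels = AA20))
  pos <- c(nterm = 1, H = unname(counts["H"]), K = unname(counts["K"]),
           R = unname(counts["R"]))
  neg <- c(cterm = 1, D = unname(counts["D"]), E = unname(counts["E"]),
           C = unname(counts["C"]), Y = unname(counts["Y"]))
  charge <- numeric(length(pH))
  for (g in names(pos)) {
    if (pos[[g]] > 0)
      charge <- charge + pos[[g]] / (1 + 10^(pH - pka[[g]]))
  }
  for (g in names(neg)) {
    if (neg[[g]] > 0)
      charge <- charge - neg[[g]] / (1 + 10^(pka[[g]] - pH))
  }
  charge
}

#' Isoelectric point
#'
#' pH at which the net charge of the peptide is zero, located by bisection
#' on \[0, 14\]. The charge function is strictly decreasing in pH, so the
#' zero crossing is unique.
#'
#' @inheritParams net_charge
#' @param tol Bisection tolerance on pH (default 1e-4).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pka = pka_table(), tol = 1e-4) {
  lo <- 0
  hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(seq, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Vectorized peptide masses for all subsequences of one parent, via
# cumulative sums. Used by the digestion and matching machinery so that
# per-peptide calls stay O(1).
.interval_masses <- function(chars, starts, ends,
                             mode = "monoisotopic",
                             carbamidomethyl = TRUE) {
  rm <- .residue_mass_vector(mode)
  water <- if (mode == "monoisotopic") WATER_MONO else WATER_AVG
  cs <- c(0, cumsum(rm[chars]))        # cs[i+1] = mass of residues 1..i
  base <- cs[ends + 1L] - cs[starts] + water
  if (carbamidomethyl) {
    md <- .mod_delta("carbamidomethyl", mode)
    cc <- c(0L, cumsum(chars == md$target))
    base <- base + md$delta * (cc[ends + 1L] - cc[starts])
  }
  unname(base)
}

.interval_residue_counts <- function(chars, starts, ends, residue) {
  cc <- c(0L, cumsum(chars == residue))
  unname(cc[ends + 1L] - cc[starts])
}
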