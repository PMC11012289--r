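# Physicochemical quantities used for hit prioritisation: formula masses,
# adduct m/z, Lipinski counts, topological polar surface area, lipophilic
# efficiency. Structure handling goes through OpenBabel (ChemmineOB);
# the mass tables and the S/P polar-surface corrections are embedded.

# IUPAC standard atomic weights (abridged, conventional values) and
# monoisotopic masses of the principal isotope, for the elements common in
# drug-like molecules.
ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38, Se = 78.971,
  Br = 79.904, I = 126.904
)
MONOISOTOPIC_MASSES <- c(
  H = 1.0078250319, B = 11.0093054, C = 12, N = 14.0030740052,
  O = 15.9949146221, F = 18.9984031627, Na = 22.9897692820, Mg = 23.9850417,
  Si = 27.9769265, P = 30.97376151, S = 31.97207069, Cl = 34.96885271,
  K = 38.9637064864, Ca = 39.9625909, Fe = 55.9349375, Zn = 63.9291420,
  Se = 79.9165218, Br = 78.9183376, I = 126.904473
)

#' Parse a molecular formula string
#'
#' Order-agnostic parse of formulas like `"C17H18N2O4S"`; an element without
#' an explicit count has count 1, repeated elements are summed.
#'
#' @param text Molecular formula.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C17H18N2O4S")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    abort("`text` must be a single non-empty formula string.")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    abort(paste0("cannot parse formula: ", text))
  }
  elem <- sub("[0-9]*$", "", tokens)
  cnt <- as.integer(sub("^[A-Za-z]+", "", tokens))
  cnt[is.na(cnt)] <- 1L
  unknown <- setdiff(elem, names(ATOMIC_WEIGHTS))
  if (length(unknown) > 0) {
    abort(paste0("unknown element symbol: ", paste(unknown, collapse = ", ")))
  }
  counts <- tapply(cnt, elem, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  if (sum(out) < 1) abort("formula must contain at least one atom.")
  out
}

#' Average (standard) molecular weight of a formula
#'
#' Sum of count times IUPAC standard atomic weight, reported to 2 decimals.
#'
#' @param formula A formula string or the output of [parse_formula()].
#' @return Molecular weight in g/mol (2 decimals).
#' @examples
#' average_mw("C17H18N2O4S")
#' @export
average_mw <- function(formula) {
  f <- if (is.character(formula)) parse_formula(formula) else formula
  round(sum(ATOMIC_WEIGHTS[names(f)] * f), 2)
}

#' Monoisotopic mass of a formula
#'
#' @inheritParams average_mw
#' @return Monoisotopic mass in Da (unrounded).
#' @export
monoisotopic_mass <- function(formula) {
  f <- if (is.character(formula)) parse_formula(formula) else formula
  sum(MONOISOTOPIC_MASSES[names(f)] * f)
}

#' Monoisotopic adduct m/z
#'
#' Monoisotopic mass of the neutral molecule plus the monoisotopic mass of
#' the neutral adduct atom (H or Na), without electron-mass correction --
#' the convention of routine HRMS "calc'd" values. Reported to 4 decimals.
#'
#' @inheritParams average_mw
#' @param adduct `"M+H"` or `"M+Na"`.
#' @return m/z in Da (4 decimals).
#' @examples
#' adduct_mz("C17H18N2O4S", "M+Na")
#' @export
adduct_mz <- function(formula, adduct = c("M+H", "M+Na")) {
  adduct <- match.arg(adduct)
  add <- switch(adduct, "M+H" = MONOISOTOPIC_MASSES[["H"]],
                "M+Na" = MONOISOTOPIC_MASSES[["Na"]])
  round(monoisotopic_mass(formula) + add, 4)
}

# ---- SMILES descriptors through OpenBabel ---------------------------------

# Run f once per SMILES on the OpenBabel molecule object.
ob_each <- function(smiles, f) {
  lapply(smiles, function(s) {
    ChemmineOB::forEachMol("SMILES", s, f)[[1]]
  })
}

ob_smarts_count <- function(mol, pattern) {
  ChemmineOB::smartsSearch_OB(list(mol), pattern, uniqueMatches = TRUE)
}

# Ertl polar-surface-area contributions of sulfur and phosphorus atom types,
# used to convert between the S/P-inclusive and N/O-only TPSA conventions.
# Patterns are single-atom SMARTS keyed on connectivity (X counts H), total
# H and charge; contributions in square Angstrom.
SP_TPSA_PATTERNS <- c(
  "[SX2H0+0;A]" = 25.30,  # thioether  S(-*)-*
  "[SX1H0+0;A]" = 32.09,  # S=*
  "[SX3H0+0;A]" = 19.21,  # sulfoxide  S(-*)(-*)=*
  "[SX4H0+0;A]" = 8.38,   # sulfone    S(-*)(-*)(=*)=*
  "[SX2H1+0;A]" = 38.80,  # thiol      S(H)-*
  "[sX2H0+0]"   = 28.24,  # aromatic s
  "[sX3H0+0]"   = 21.70,  # aromatic s with exocyclic double bond
  "[PX3H0+0;A]" = 13.59,  # P(-*)(-*)-*
  "[PX2H0+0;A]" = 34.14,  # P(-*)=*
  "[PX4H0+0;A]" = 9.81,   # P(-*)(-*)(-*)=*
  "[PX4H1+0;A]" = 23.47   # P(H)(-*)(-*)=*
)

#' Lipinski hydrogen-bond acceptor and donor counts
#'
#' The rule-of-five convention: acceptors are the nitrogen and oxygen atoms,
#' donors are the hydrogens attached to nitrogen or oxygen.
#'
#' @param smiles Character vector of SMILES.
#' @return Tibble with `smiles`, `hba`, `hbd`.
#' @examples
#' lipinski_counts(c("O", "C"))
#' @export
lipinski_counts <- function(smiles) {
  res <- ob_each(smiles, function(mol) {
    hba <- ob_smarts_count(mol, "[#7,#8]")
    hbd <- ob_smarts_count(mol, "[#7H1,#8H1]") +
      2 * ob_smarts_count(mol, "[#7H2,#8H2]") +
      3 * ob_smarts_count(mol, "[#7H3,#8H3]")
    c(hba = hba, hbd = hbd)
  })
  tibble(smiles = smiles,
         hba = as.integer(vapply(res, `[[`, numeric(1), "hba")),
         hbd = as.integer(vapply(res, `[[`, numeric(1), "hbd")))
}

#' Topological polar surface area
#'
#' Ertl fragment-contribution TPSA. The default convention includes the
#' sulfur and phosphorus atom-type contributions (a sulfone sulfur adds
#' 8.38 square Angstrom); set `include_sulfur_phosphorus = FALSE` for the
#' N/O-only convention.
#'
#' @param smiles Character vector of SMILES.
#' @param include_sulfur_phosphorus Include the S/P terms (default TRUE).
#' @return Numeric TPSA in square Angstrom (2 decimals).
#' @examples
#' tpsa("ONC(=O)Cc1ccccc1S(=O)(=O)N1CCc2ccccc2C1")
#' @export
tpsa <- function(smiles, include_sulfur_phosphorus = TRUE) {
  res <- ob_each(smiles, function(mol) {
    full <- ChemmineOB::prop_OB(mol)$TPSA
    if (include_sulfur_phosphorus) return(full)
    sp <- sum(vapply(names(SP_TPSA_PATTERNS), function(p) {
      ob_smarts_count(mol, p) * SP_TPSA_PATTERNS[[p]]
    }, numeric(1)))
    full - sp
  })
  round(vapply(res, identity, numeric(1)), 2)
}

#' Structure-derived property bundle
#'
#' One-stop descriptor table for a set of structures: formula, average
#' molecular weight, Lipinski counts, TPSA (S/P-inclusive) and the OpenBabel
#' octanol-water logP (a stand-in where no measured or modelled LogD is
#' supplied; flagged by the `logp_source` column).
#'
#' @param smiles Character vector of SMILES.
#' @return Tibble with one row per structure.
#' @export
mol_properties <- function(smiles) {
  res <- ob_each(smiles, function(mol) ChemmineOB::prop_OB(mol))
  props <- bind_rows(res)
  lip <- lipinski_counts(smiles)
  tibble(
    smiles = smiles,
    formula = props$formula,
    mw = round(props$MW, 2),
    hba = lip$hba,
    hbd = lip$hbd,
    tpsa = round(props$TPSA, 2),
    logp = props$logP,
    logp_source = "openbabel_logp"
  )
}

#' Lipophilic efficiency
#'
#' `LipE = pIC50 - LogD`, the standard potency-per-lipophilicity score,
#' reported to 2 decimals.
#'
#' @param pic50 Potency (-log10 IC50 in molar), typically from the
#'   fluorescence assay.
#' @param logd Distribution coefficient (or logP stand-in).
#' @return LipE (2 decimals).
#' @examples
#' lipe(6.50, 1.65)
#' @export
lipe <- function(pic50, logd) {
  round(pic50 - logd, 2)
}
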