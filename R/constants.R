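# Amino-acid bookkeeping shared across the package.

#' Canonical amino acids and atom nomenclature
#'
#' `AA_CANONICAL` holds the three-letter codes of the 20 canonical amino
#' acids. `AA_ATOM_ORDER` maps each code to its heavy atoms in canonical PDB
#' atom-name order (backbone N, CA, C, O first, then the side chain).
#' `AA_SYMMETRIC_ATOMS` lists side-chain atom pairs that are chemically
#' indistinguishable (carboxylate oxygens, guanidinium nitrogens, aromatic
#' ring carbons); both labelings are tried during superposition so that
#' arbitrary naming cannot inflate an RMSD. `AA_CATALYTIC_POOL` is the set of
#' 11 polar/charged residues that dominate catalytic sites.
#'
#' @name aa-constants
#' @keywords internal
NULL

AA_CANONICAL <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

.bb <- c("N", "CA", "C", "O")

AA_ATOM_ORDER <- list(
  ALA = c(.bb, "CB"),
  ARG = c(.bb, "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c(.bb, "CB", "CG", "OD1", "ND2"),
  ASP = c(.bb, "CB", "CG", "OD1", "OD2"),
  CYS = c(.bb, "CB", "SG"),
  GLN = c(.bb, "CB", "CG", "CD", "OE1", "NE2"),
  GLU = c(.bb, "CB", "CG", "CD", "OE1", "OE2"),
  GLY = .bb,
  HIS = c(.bb, "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c(.bb, "CB", "CG1", "CG2", "CD1"),
  LEU = c(.bb, "CB", "CG", "CD1", "CD2"),
  LYS = c(.bb, "CB", "CG", "CD", "CE", "NZ"),
  MET = c(.bb, "CB", "CG", "SD", "CE"),
  PHE = c(.bb, "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c(.bb, "CB", "CG", "CD"),
  SER = c(.bb, "CB", "OG"),
  THR = c(.bb, "CB", "OG1", "CG2"),
  TRP = c(.bb, "CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2",
          "CZ3", "CH2"),
  TYR = c(.bb, "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c(.bb, "CB", "CG1", "CG2")
)

# Chemically indistinguishable atom labelings. Each element is a "flip
# group": a set of atom-name pairs that are swapped together by one
# symmetry operation (e.g. the aromatic ring flip exchanges CD1/CD2 and
# CE1/CE2 simultaneously). Alternative labelings of a residue are generated
# by applying any subset of its flip groups.
AA_SYMMETRIC_ATOMS <- list(
  ASP = list(list(c("OD1", "OD2"))),
  GLU = list(list(c("OE1", "OE2"))),
  ARG = list(list(c("NH1", "NH2"))),
  PHE = list(list(c("CD1", "CD2"), c("CE1", "CE2"))),
  TYR = list(list(c("CD1", "CD2"), c("CE1", "CE2")))
)

# The 11 polar and charged residue types generally observed in catalytic
# sites; the synthetic generator samples templates from this pool.
AA_CATALYTIC_POOL <- c(
  "ARG", "LYS", "ASP", "GLU", "ASN", "GLN", "HIS", "SER", "THR", "TYR", "CYS"
)

#' Named equivalence-rule presets
#'
#' Residue-type equivalence rules used when enumerating correspondences:
#' `"none"` (strict identity), `"YF_IL"` (tyrosine/phenylalanine and
#' isoleucine/leucine interchangeable) and `"YF_IV"`
#' (tyrosine/phenylalanine and isoleucine/valine interchangeable). Both
#' non-trivial presets are provided because published descriptions of this
#' kind of equivalence differ on the aliphatic pair.
#'
#' @param name One of `"none"`, `"YF_IL"`, `"YF_IV"`, or a list of
#'   two-element character vectors giving unordered interchangeable pairs.
#' @return A list of unordered amino-acid pairs (possibly empty).
#' @examples
#' equivalenceRules("YF_IL")
#' @export
equivalenceRules <- function(name = "none") {
  if (is.list(name)) {
    ok <- all(vapply(name, function(p)
      length(p) == 2L && all(p %in% AA_CANONICAL), logical(1)))
    if (!ok) stop("equivalence pairs must be 2-element canonical AA vectors")
    return(lapply(name, sort))
  }
  switch(match.arg(name, c("none", "YF_IL", "YF_IV")),
    none  = list(),
    YF_IL = list(c("PHE", "TYR"), c("ILE", "LEU")),
    YF_IV = list(c("PHE", "TYR"), c("ILE", "VAL"))
  )
}

# TRUE iff residue types a and b may be matched under the rules.
.typesCompatible <- function(a, b, rules) {
  if (a == b) return(TRUE)
  p <- sort(c(a, b))
  any(vapply(rules, function(r) identical(r, p), logical(1)))
}

#' Round half away from zero
#'
#' Fixed-precision reporting helper: rounds `x` to `digits` decimals with
#' halves going away from zero (base `round()` rounds halves to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' roundHalfUp(0.125, 2)
#' @export
roundHalfUp <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
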