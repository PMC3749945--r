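# Reference tables: amino-acid identities, modified-residue parents,
# van der Waals radii, and the flexibility ordering used for composition plots.

#' Standard amino-acid three-letter codes
#'
#' The 20 standard residue types, in alphabetical order of the
#' three-letter code.
#'
#' @return Character vector of length 20.
#' @export
standard_aa <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

#' One-letter codes for the standard amino acids
#' @return Named character vector mapping three-letter to one-letter codes.
#' @export
aa_one_letter <- function() {
  c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
    GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
    MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
    TYR = "Y", VAL = "V")
}

# Common chemically modified residues mapped to their parent type, so that a
# selenomethionine (say) still counts as an observed residue of the chain.
.modified_aa <- c(
  MSE = "MET", FME = "MET", SEC = "CYS", CSO = "CYS", CSD = "CYS",
  CME = "CYS", OCS = "CYS", CSX = "CYS", SEP = "SER", TPO = "THR",
  PTR = "TYR", MLY = "LYS", M3L = "LYS", KCX = "LYS", LLP = "LYS",
  PYL = "LYS", HYP = "PRO", PCA = "GLU", HIC = "HIS", MLZ = "LYS",
  AIB = "ALA", DAL = "ALA", SAR = "GLY"
)

#' Map modified residue names to their parent amino acid
#'
#' @param res_name Character vector of three-letter residue names.
#' @return Character vector with modified residues (e.g. `MSE`) replaced by
#'   their parent (`MET`); unknown names are returned unchanged.
#' @export
map_modified_residue <- function(res_name) {
  hit <- match(res_name, names(.modified_aa))
  out <- res_name
  out[!is.na(hit)] <- unname(.modified_aa[hit[!is.na(hit)]])
  out
}

.water_names <- c("HOH", "WAT", "DOD", "H2O")

#' Van der Waals radii for SASA calculations
#'
#' Element-keyed heavy-atom radii (Angstrom).  Protein elements use Bondi
#' radii; the Zn, Ca and Na ion radii are the CHARMM22 Lennard-Jones
#' Rmin/2 values so that coordinated ions can be included in a surface
#' calculation.  Hydrogens are listed but excluded from SASA by default.
#'
#' @return Named numeric vector of radii in Angstrom, keyed by element symbol.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90, P = 1.80,
    H = 1.20, D = 1.20,
    ZN = 1.09, CA = 1.367, "NA" = 1.3638, MG = 1.185, K = 1.764,
    CL = 2.27, FE = 0.65, MN = 0.80, CU = 0.812, F = 1.47,
    BR = 1.85, I = 1.98)
}

#' Amino acids ordered by chain flexibility
#'
#' Ordering used to display composition and enrichment profiles: from the
#' most order-promoting (rigid, hydrophobic) to the most disorder-promoting
#' (flexible, charged/polar) residue types, following the classical
#' flexibility/disorder-propensity ranking.
#'
#' @return Character vector of the 20 three-letter codes, rigid first.
#' @export
flexibility_order <- function() {
  c("TRP", "CYS", "PHE", "ILE", "TYR", "VAL", "LEU", "HIS", "MET", "ALA",
    "THR", "ARG", "GLY", "GLN", "SER", "ASN", "PRO", "ASP", "GLU", "LYS")
}

# Element symbol from a PDB atom name when the element column is absent or
# blank.  An atom named like a metal is only an ion when its residue carries
# the same name (e.g. residue "ZN" atom "ZN"), so that CA alpha-carbons are
# not mistaken for calcium.
.element_from_name <- function(name, res_name = NULL) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- c("ZN", "CA", "NA", "MG", "CL", "FE", "MN", "CU", "BR", "SE", "K")
  out <- substr(nm, 1L, 1L)
  if (!is.null(res_name)) {
    ion <- nm %in% two & toupper(res_name) == nm
    out[ion] <- nm[ion]
  }
  out[nm == "SE"] <- "SE"   # selenomethionine SE atom
  out
}
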