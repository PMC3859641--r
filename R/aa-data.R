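# Amino-acid lookup tables and packaged reference data.

AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA1 <- setNames(names(AA3), unname(AA3))

#' One- and three-letter amino-acid code conversion
#'
#' @param x Character vector of three-letter (`aa321`) or one-letter
#'   (`aa123`) residue codes.
#' @return Character vector of converted codes; unknown codes become `NA`.
#' @export
aa321 <- function(x) unname(AA3[toupper(x)])

#' @rdname aa321
#' @export
aa123 <- function(x) unname(AA1[toupper(x)])

#' Packaged van der Waals radii
#'
#' Heavy-atom van der Waals radii in Angstrom, by element symbol. Values are
#' the conventional Bondi set for protein heavy atoms plus a few common
#' hetero elements. Override by passing a modified copy to the accessibility
#' functions.
#'
#' @return Named numeric vector (Angstrom).
#' @export
vdw_radii <- function() {
  c(
    C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    MG = 1.73, ZN = 1.39, CA = 2.31, MN = 1.97, FE = 1.94, NI = 1.63,
    CU = 1.40, CO = 1.92, CD = 1.58, "NA" = 2.27, K = 2.75
  )
}

#' Packaged maximal accessible surface areas per residue
#'
#' Reference maxima (Angstrom squared) for relative solvent accessibility,
#' following the extended Gly-X-Gly tripeptide convention. RSA is the residue
#' ASA divided by this reference, as a percentage capped at 100.
#'
#' @return Named numeric vector over the 20 standard one-letter codes.
#' @export
rsa_reference <- function() {
  c(
    A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
    Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
    L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
    S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
  )
}

#' Ligand class map
#'
#' Reads the packaged (or a user-supplied) YAML file grouping PDB hetero
#' residue codes into ligand classes used for site-to-ligand association:
#' energy currency & electron carriers (ATP, NAD, FAD, ...) and bivalent
#' metal ions (Mg2+, Zn2+, ...).
#'
#' @param path YAML file; defaults to the packaged map.
#' @return Named list of character vectors (class -> hetero residue codes).
#' @export
ligand_classes <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ligand_classes.yaml",
                                package = "ubistruct", mustWork = TRUE)
  cls <- yaml::read_yaml(path)
  lapply(cls, function(x) toupper(as.character(x)))
}

# Background amino-acid weights used by the synthetic sequence sampler
# (rough globular-protein composition, lysine handled separately).
BACKGROUND_AA_FREQ <- c(
  A = 0.085, R = 0.050, N = 0.043, D = 0.055, C = 0.018, Q = 0.039,
  E = 0.065, G = 0.072, H = 0.023, I = 0.058, L = 0.095, M = 0.022,
  F = 0.040, P = 0.046, S = 0.068, T = 0.055, W = 0.013, Y = 0.033,
  V = 0.070
)
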