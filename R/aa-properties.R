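# Amino-acid property tables.
#
# The structural "volume change" feature of the CoDP model is the absolute
# difference in the number of non-hydrogen side-chain atoms between the
# wild-type and the mutant residue. The counts below follow the standard
# residue topologies of the PDB chemical component dictionary (glycine has no
# side chain; tryptophan's 10 heavy atoms are the maximum).

.AA_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

# Standard side-chain heavy-atom names (PDB nomenclature), one vector per
# residue type. The heavy-atom counts are the lengths of these vectors; the
# element of each atom is the first character of its name (C/N/O/S).
.SIDE_CHAIN_ATOMS <- list(
  A = c("CB"),
  R = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  N = c("CB", "CG", "OD1", "ND2"),
  D = c("CB", "CG", "OD1", "OD2"),
  C = c("CB", "SG"),
  Q = c("CB", "CG", "CD", "OE1", "NE2"),
  E = c("CB", "CG", "CD", "OE1", "OE2"),
  G = character(0),
  H = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  I = c("CB", "CG1", "CG2", "CD1"),
  L = c("CB", "CG", "CD1", "CD2"),
  K = c("CB", "CG", "CD", "CE", "NZ"),
  M = c("CB", "CG", "SD", "CE"),
  F = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  P = c("CB", "CG", "CD"),
  S = c("CB", "OG"),
  T = c("CB", "OG1", "CG2"),
  W = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  Y = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  V = c("CB", "CG1", "CG2")
)

.HEAVY_ATOMS <- vapply(.SIDE_CHAIN_ATOMS, length, integer(1))

.check_aa <- function(aa, arg = "aa") {
  if (!is.character(aa) || any(is.na(aa)) || any(nchar(aa) != 1L)) {
    stop("codp_invalid_amino_acid: `", arg,
         "` must be one-letter amino-acid codes", call. = FALSE)
  }
  bad <- setdiff(unique(aa), names(.AA_THREE))
  if (length(bad)) {
    stop("codp_invalid_amino_acid: not a canonical amino-acid code: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(aa)
}

#' Side-chain heavy-atom count of a residue type
#'
#' Number of non-hydrogen atoms in the side chain of a canonical amino acid,
#' per the standard residue topology (glycine = 0, tryptophan = 10).
#'
#' @param aa Character vector of one-letter amino-acid codes (the 20 canonical
#'   types). Ambiguous or non-standard codes (`B`, `Z`, `X`, `U`, ...) are
#'   rejected with an error.
#' @return Integer vector of heavy-atom counts.
#' @examples
#' side_chain_heavy_atoms(c("G", "W", "R"))
#' @export
side_chain_heavy_atoms <- function(aa) {
  .check_aa(aa)
  unname(.HEAVY_ATOMS[aa])
}

#' Side-chain heavy-atom change of a substitution
#'
#' Absolute difference in side-chain heavy-atom counts between the wild-type
#' and mutant residue; the structure-derived volume-change proxy used as a
#' predictor in the CoDP model.
#'
#' @param wt,mut One-letter amino-acid codes (vectors recycle as usual).
#' @return Non-negative integer vector, between 0 and 10 (the maximum is
#'   attained by a glycine/tryptophan exchange).
#' @examples
#' delta_heavy_atoms("G", "R")  # 7, e.g. the G566R variant
#' delta_heavy_atoms("E", "K")  # 0, e.g. the E1193K variant
#' @export
delta_heavy_atoms <- function(wt, mut) {
  .check_aa(wt, "wt")
  .check_aa(mut, "mut")
  abs(side_chain_heavy_atoms(mut) - side_chain_heavy_atoms(wt))
}

#' Amino-acid property table
#'
#' The packaged per-residue constants as a data frame, suitable for export
#' (see [write_codp_tsv()]) and cross-checking.
#'
#' @return A data frame with columns `one_letter`, `three_letter`,
#'   `heavy_atoms`, one row per canonical amino acid.
#' @export
aa_property_table <- function() {
  data.frame(
    one_letter = names(.AA_THREE),
    three_letter = unname(.AA_THREE),
    heavy_atoms = unname(.HEAVY_ATOMS),
    stringsAsFactors = FALSE
  )
}

# three-letter -> one-letter lookup used by the structure module
.aa_one_from_three <- function(three) {
  m <- match(toupper(three), .AA_THREE)
  out <- names(.AA_THREE)[m]
  out
}
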