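#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes in alphabetical order. This
#' ordering also fixes the residue-to-integer mapping used by the random
#' sequence generator: integer `k` (0--19) maps to `amino_acids[k + 1]`.
#'
#' @format Character vector of length 20.
#' @export
amino_acids <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Mean per-residue volumes
#'
#' Mean volumes of amino-acid residues in folded proteins (Zamyatnin, 1972),
#' in cubic Angstroms. Chain volume is computed as the sum of per-residue
#' entries, so it depends on composition only, not on conformation - the same
#' convention applies to experimental structures and to models.
#'
#' @format Named numeric vector (one-letter codes), units Angstrom^3.
#' @export
residue_volumes <- c(
  A =  88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
  Q = 143.8, E = 138.4, G =  60.1, H = 153.2, I = 166.7,
  L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
  S =  89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)

#' Hydrophobic residue set
#'
#' Residues counted as hydrophobic when computing surface hydrophobicity
#' (the fraction of total solvent-accessible area contributed by these
#' residue types): Ala, Val, Leu, Ile, Met, Phe, Trp, Cys, Pro.
#'
#' @format Character vector of one-letter codes.
#' @export
hydrophobic_residues <- c("A", "V", "L", "I", "M", "F", "W", "C", "P")

# van der Waals radii (Angstrom) for heavy elements; hydrogens are ignored.
vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)

#' Names of the eleven structural variables
#'
#' Internal column names of a feature table and the corresponding display
#' names used in exported CSV summaries: net charge (elementary charges),
#' volume (A^3), surface area (A^2), coil / beta / alpha residue counts,
#' their percentages of chain length, percentage of secondary structure
#' (%alpha + %beta) and surface hydrophobicity (fraction in [0,1]).
#'
#' @return Named character vector: names are internal column names, values
#'   the display names.
#' @export
feature_variables <- function() {
  c(net_charge = "Net charge",
    volume = "Volume",
    surface = "Surface",
    coil = "Coil",
    beta = "Beta",
    alpha = "Alpha",
    pct_alpha = "% Alpha",
    pct_beta = "% Beta",
    pct_coil = "% Coil",
    pct_secondary = "% Secondary structure",
    surface_hydrophobicity = "Surface hydrophobicity")
}
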