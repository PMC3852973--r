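# Isotope-averaged masses. Observed species in limited proteolysis are
# 15-30 kDa intact masses reported to 0.1 kDa, so average (not monoisotopic)
# masses are the right currency throughout.

# average residue (i.e. dehydrated) masses in daltons
.AA_AVERAGE <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

WATER_MASS <- 18.01524
DISULFIDE_LOSS <- 2.016  # two hydrogens per S-S bond

#' Average residue mass table
#'
#' The standard isotope-averaged residue masses used by the mass engine,
#' as a tibble. The same table is shipped as a plain-text file at
#' `system.file("extdata", "aa_average_masses.csv", package = "domainmapr")`.
#'
#' @return A tibble with columns `residue` and `mass_da` (dehydrated residue
#'   mass in daltons).
#' @export
aa_average_masses <- function() {
  tibble(residue = names(.AA_AVERAGE), mass_da = unname(.AA_AVERAGE))
}

#' Isotope-averaged mass of a peptide
#'
#' Sums standard average residue masses, adds one water for the free termini,
#' and subtracts 2.016 Da per declared disulfide bond. Cysteines are treated
#' as reduced by default; at 0.1 kDa reporting precision the disulfide
#' correction is negligible for the fragments this package targets.
#'
#' @param residues Upper-case one-letter amino-acid string (canonical 20 only).
#' @param include_water Add the terminal water (default `TRUE`); `FALSE` gives
#'   the residue-sum mass useful for concatenation arithmetic.
#' @param n_disulfides Number of disulfide bonds, each lowering the mass by
#'   2.016 Da. Must not exceed `floor(#Cys / 2)`.
#' @return Mass in daltons.
#' @examples
#' peptide_mass("")        # 18.015, water only
#' peptide_mass("ACDEFG")
#' @export
peptide_mass <- function(residues, include_water = TRUE, n_disulfides = 0) {
  stopifnot(is.character(residues), length(residues) == 1L,
            n_disulfides >= 0)
  if (nchar(residues) > 0) check_residues(residues, "peptide")
  chars <- chars_of(residues)
  if (n_disulfides > floor(sum(chars == "C") / 2)) {
    abort("n_disulfides exceeds floor(cysteine count / 2)")
  }
  sum(.AA_AVERAGE[chars]) +
    (if (include_water) WATER_MASS else 0) -
    n_disulfides * DISULFIDE_LOSS
}

#' Is the initiator methionine retained?
#'
#' Bacterial methionine aminopeptidase removes the initiator Met when the
#' penultimate residue has a small side chain (Ala, Cys, Gly, Pro, Ser, Thr,
#' Val); otherwise the Met stays on the mature chain. This rule reproduces
#' the observed N-termini of recombinant constructs: a chain starting
#' Met-Leu keeps the Met (Edman read "MLEV"), a chain starting Met-Ser loses
#' it (read "STPD").
#'
#' @param penultimate Single canonical residue letter following the initiator
#'   Met.
#' @return `TRUE` if the Met is retained.
#' @examples
#' met_retained("L") # TRUE
#' met_retained("S") # FALSE
#' @export
met_retained <- function(penultimate) {
  stopifnot(is.character(penultimate), length(penultimate) == 1L,
            nchar(penultimate) == 1L)
  if (!penultimate %in% AA_LETTERS) {
    abort(sprintf("invalid residue letter '%s'", penultimate))
  }
  !penultimate %in% c("A", "C", "G", "P", "S", "T", "V")
}

#' Mass of an expressed construct
#'
#' Average mass of the mature expressed chain of a construct (initiator-Met
#' processing already applied by [build_constructs()]).
#'
#' @param construct A single-row construct tibble from [build_constructs()].
#' @param n_disulfides Declared disulfide bonds, see [peptide_mass()].
#' @return Mass in daltons.
#' @export
construct_mass <- function(construct, n_disulfides = 0) {
  stopifnot(is.data.frame(construct), nrow(construct) == 1L,
            "chain" %in% names(construct))
  peptide_mass(construct$chain, n_disulfides = n_disulfides)
}
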