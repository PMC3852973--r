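#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select group_by ungroup summarise
#'   row_number bind_rows left_join across n
#' @importFrom stats lm coef predict sd setNames rnorm runif
NULL

# round half-up at `digits` decimals; base round() rounds half-to-even, which
# does not match how printed tables round masses such as 0.25 -> 0.3
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Report a mass in kDa at table precision
#'
#' Converts daltons to kilodaltons and rounds half-up, matching the precision
#' at which intact masses and theoretical masses are printed in proteolysis
#' tables (one decimal by default).
#'
#' @param mass_da Numeric vector of masses in daltons.
#' @param digits Decimal places to keep, default 1.
#' @return Numeric vector in kDa.
#' @examples
#' kda(27929.7) # 27.9
#' @export
kda <- function(mass_da, digits = 1) {
  round_half_up(mass_da / 1000, digits)
}

# canonical one-letter amino-acid alphabet
AA_LETTERS <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

check_residues <- function(residues, what = "sequence") {
  stopifnot(is.character(residues), length(residues) == 1L)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_LETTERS)
  if (length(bad) > 0) {
    abort(sprintf(
      "non-canonical residue '%s' at position %d of %s",
      chars[bad[1]], bad[1], what
    ), class = "domainmapr_residue_error")
  }
  invisible(residues)
}

chars_of <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
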