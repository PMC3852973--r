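# Cleavage specificity rules. A protease spec names the residues C-terminal
# to which the scissile bond is cut quickly (p1_fast) or much more slowly
# (p1_slow; for V8/Glu-C the Asp class is 100-300x slower than Glu), the P1'
# residues that block cleavage outright (classically Pro), and P1' residues
# that demote an otherwise fast site to the slow class (for Glu-C, bonds
# into another acidic residue are cleaved far more slowly; this is what makes
# a Glu-Glu-Ser context cut after the *second* Glu). Thermolysin-like
# enzymes recognise the P1' side instead: `p1prime_target` lists P1'
# residues *before* which the bond is cut, evaluated positionally.

#' Shipped protease specificity rules
#'
#' @return A named list of protease specs (`v8`, `trypsin`, `elastase`,
#'   `thermolysin`), each a list with fields `name`, `p1_fast`, `p1_slow`,
#'   `p1prime_block`, `p1prime_slow`, `p1prime_target`.
#' @examples
#' protease_specs()$v8
#' @export
protease_specs <- function() {
  spec <- function(name, p1_fast = character(), p1_slow = character(),
                   p1prime_block = character(), p1prime_slow = character(),
                   p1prime_target = character()) {
    stopifnot(length(intersect(p1_fast, p1_slow)) == 0)
    list(name = name, p1_fast = p1_fast, p1_slow = p1_slow,
         p1prime_block = p1prime_block, p1prime_slow = p1prime_slow,
         p1prime_target = p1prime_target)
  }
  list(
    v8 = spec("v8", p1_fast = "E", p1_slow = "D",
              p1prime_block = "P", p1prime_slow = c("E", "D")),
    trypsin = spec("trypsin", p1_fast = c("K", "R"), p1prime_block = "P"),
    elastase = spec("elastase", p1_fast = c("A", "V", "S", "G", "L", "I")),
    thermolysin = spec("thermolysin",
                       p1prime_target = c("I", "L", "V", "F", "M", "A"))
  )
}

#' Load protease specs from a JSON table
#'
#' @param path JSON file: an object mapping protease names to objects with
#'   any of the fields of [protease_specs()].
#' @return Named list of protease specs.
#' @export
read_protease_specs <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("protease spec file not found: '%s'", path),
          class = "domainmapr_io_error")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  purrr::imap(raw, function(x, nm) {
    fields <- c("p1_fast", "p1_slow", "p1prime_block", "p1prime_slow",
                "p1prime_target")
    out <- c(list(name = nm),
             purrr::map(setNames(fields, fields),
                        ~ as.character(x[[.x]] %||% character())))
    if (length(intersect(out$p1_fast, out$p1_slow)) > 0) {
      abort(sprintf("protease '%s': p1_fast and p1_slow overlap", nm),
            class = "domainmapr_schema_error")
    }
    out
  })
}

resolve_protease <- function(protease) {
  if (is.character(protease)) {
    specs <- protease_specs()
    if (!protease %in% names(specs)) {
      abort(sprintf("unknown protease '%s' (shipped: %s)",
                    protease, paste(names(specs), collapse = ", ")),
            class = "domainmapr_schema_error")
    }
    specs[[protease]]
  } else if (is.list(protease) && !is.null(protease$name)) {
    protease
  } else {
    abort("protease must be a shipped name or a spec list")
  }
}

#' Enumerate candidate cleavage sites on a chain
#'
#' Returns every bond position at which the protease can cut, in ascending
#' order. A site is reported by its P1 position: the bond cut lies between
#' residues `p1_pos` and `p1_pos + 1`. The last residue is never a site.
#'
#' @param chain Residue string (canonical letters).
#' @param protease Shipped protease name or a spec list, see
#'   [protease_specs()].
#' @param include_slow Also return slow-class sites (default `FALSE`: fast
#'   sites only, the default for deducing limited-proteolysis products).
#' @return A tibble with columns `p1_pos` (integer), `p1_residue`, and
#'   `rate_class` (`"fast"` or `"slow"`).
#' @examples
#' cleavage_sites("AEKA", "v8")      # one fast site at position 2
#' cleavage_sites("AKPA", "trypsin") # Pro blocks: no sites
#' @export
cleavage_sites <- function(chain, protease, include_slow = FALSE) {
  stopifnot(is.character(chain), length(chain) == 1L)
  if (nchar(chain) == 0) {
    abort("empty chain", class = "domainmapr_range_error")
  }
  check_residues(chain, "chain")
  spec <- resolve_protease(protease)
  chars <- chars_of(chain)
  n <- length(chars)
  if (n == 1L) {
    return(tibble(p1_pos = integer(), p1_residue = character(),
                  rate_class = character()))
  }
  p1 <- chars[-n]
  p1prime <- chars[-1]
  if (length(spec$p1prime_target) > 0) {
    # P1'-directed enzyme (thermolysin-like): cut before target residues
    is_site <- p1prime %in% spec$p1prime_target
    rate <- rep("fast", n - 1L)
  } else {
    fast <- p1 %in% spec$p1_fast
    slow <- p1 %in% spec$p1_slow
    demoted <- fast & p1prime %in% spec$p1prime_slow
    rate <- ifelse(fast & !demoted, "fast", "slow")
    is_site <- fast | slow
  }
  blocked <- p1prime %in% spec$p1prime_block
  keep <- is_site & !blocked
  out <- tibble(p1_pos = which(keep),
                p1_residue = p1[keep],
                rate_class = rate[keep])
  if (!include_slow) out <- out[out$rate_class == "fast", , drop = FALSE]
  out
}
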