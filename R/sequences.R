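#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that upper-cases and
#' validates residues against the 20 canonical letters and returns a tidy
#' one-row-per-record tibble.
#'
#' @param path Path to a FASTA file (multi-record; wrapped or unwrapped lines).
#' @return A tibble with columns `id` (first word of the header),
#'   `residues` and `description` (full header line).
#' @examples
#' fa <- system.file("extdata", "app695.fasta", package = "domainmapr")
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: '%s'", path),
          class = "domainmapr_io_error")
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) {
    abort(sprintf("no FASTA records in '%s'", path),
          class = "domainmapr_io_error")
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  residues <- toupper(as.character(set))
  for (i in seq_along(residues)) {
    check_residues(residues[i], sprintf("record '%s'", ids[i]))
  }
  tibble(id = ids, residues = unname(residues), description = headers)
}

#' Build expressed constructs over a reference sequence
#'
#' A construct is a sub-chain of a reference protein expressed with an
#' optional initiator methionine and an optional C-terminal tag. Positions on
#' the reference ("reference numbering", e.g. Leu18 of a 695-residue
#' reference) and positions on the expressed chain ("local numbering") are
#' kept in a dual system; [local_to_reference()] converts between them.
#'
#' Initiator-Met processing is applied here: the mature `chain` starts with
#' Met only when `init_met` is `TRUE` *and* [met_retained()] holds for the
#' first segment residue.
#'
#' @param defs A data frame with columns `id`, `parent`, `ref_start`,
#'   `ref_end`, `init_met` (logical) and `ctag` (C-terminal tag residues,
#'   may be `""` or `NA`).
#' @param sequences A tibble of reference sequences from [read_fasta()].
#' @return A tibble with one row per construct: the definition columns plus
#'   `met_kept`, `chain` (mature expressed chain), `n_met` (0 or 1),
#'   `parent_len`, `chain_len` and `parent_residues`.
#' @examples
#' seqs <- tibble::tibble(id = "toy", residues = "MSLEKAAGTRW",
#'                        description = "toy")
#' defs <- tibble::tibble(id = "c1", parent = "toy", ref_start = 2,
#'                        ref_end = 9, init_met = TRUE, ctag = "HHHHHH")
#' build_constructs(defs, seqs)
#' @export
build_constructs <- function(defs, sequences) {
  req <- c("id", "parent", "ref_start", "ref_end", "init_met", "ctag")
  missing_cols <- setdiff(req, names(defs))
  if (length(missing_cols) > 0) {
    abort(sprintf("construct table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "domainmapr_schema_error")
  }
  defs <- as_tibble(defs)
  defs$ctag[is.na(defs$ctag)] <- ""
  out <- purrr::pmap(defs[req], function(id, parent, ref_start, ref_end,
                                         init_met, ctag) {
    pseq <- sequences$residues[match(parent, sequences$id)]
    if (is.na(pseq)) {
      abort(sprintf("construct '%s': parent sequence '%s' not found",
                    id, parent), class = "domainmapr_schema_error")
    }
    if (!(ref_start >= 1 && ref_start <= ref_end &&
          ref_end <= nchar(pseq))) {
      abort(sprintf(
        "construct '%s': interval %d-%d outside parent '%s' (length %d)",
        id, ref_start, ref_end, parent, nchar(pseq)),
        class = "domainmapr_schema_error")
    }
    if (nzchar(ctag)) check_residues(ctag, sprintf("tag of '%s'", id))
    segment <- substr(pseq, ref_start, ref_end)
    met_kept <- isTRUE(init_met) && met_retained(substr(segment, 1, 1))
    chain <- paste0(if (met_kept) "M" else "", segment, ctag)
    tibble(
      id = id, parent = parent, ref_start = as.integer(ref_start),
      ref_end = as.integer(ref_end), init_met = isTRUE(init_met),
      ctag = ctag, met_kept = met_kept, chain = chain,
      n_met = as.integer(met_kept),
      parent_len = as.integer(ref_end - ref_start + 1),
      chain_len = nchar(chain),
      parent_residues = pseq
    )
  })
  bind_rows(out)
}

#' Read construct definitions from a TSV or JSON config
#'
#' @param path Path to a tab-separated table or a JSON array of objects with
#'   fields `id`, `parent`, `ref_start`, `ref_end`, `init_met`, `ctag`.
#' @param sequences Reference sequences, see [build_constructs()].
#' @return A construct tibble, see [build_constructs()].
#' @export
read_constructs <- function(path, sequences) {
  if (!file.exists(path)) {
    abort(sprintf("construct table not found: '%s'", path),
          class = "domainmapr_io_error")
  }
  defs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_tsv(path, show_col_types = FALSE)
  }
  build_constructs(defs, sequences)
}

pick_construct <- function(constructs, id) {
  row <- constructs[constructs$id == id, , drop = FALSE]
  if (nrow(row) != 1L) {
    abort(sprintf("construct '%s' not found (or duplicated)", id),
          class = "domainmapr_schema_error")
  }
  row
}

#' Map local (expressed-chain) positions to reference numbering
#'
#' Positions on the parent segment map affinely onto the reference; the
#' initiator Met and tag residues are not reference positions and come back
#' as the markers `"met"` / `"tag"` with `ref_pos = NA`.
#'
#' @param construct A single-row construct tibble.
#' @param local_pos Integer vector of 1-based positions on the expressed
#'   chain.
#' @return A tibble with columns `local_pos`, `kind` (`"met"`, `"parent"` or
#'   `"tag"`) and `ref_pos` (integer, `NA` for met/tag).
#' @examples
#' seqs <- tibble::tibble(id = "toy", residues = "MSLEKAAGTRW",
#'                        description = "toy")
#' cons <- build_constructs(
#'   tibble::tibble(id = "c1", parent = "toy", ref_start = 3, ref_end = 9,
#'                  init_met = TRUE, ctag = ""), seqs)
#' local_to_reference(cons, c(1, 2))
#' @export
local_to_reference <- function(construct, local_pos) {
  stopifnot(is.data.frame(construct), nrow(construct) == 1L)
  local_pos <- as.integer(local_pos)
  if (any(local_pos < 1L | local_pos > construct$chain_len)) {
    abort(sprintf("local position out of range 1..%d", construct$chain_len),
          class = "domainmapr_range_error")
  }
  parent_hi <- construct$n_met + construct$parent_len
  kind <- dplyr::case_when(
    local_pos <= construct$n_met ~ "met",
    local_pos <= parent_hi ~ "parent",
    TRUE ~ "tag"
  )
  ref_pos <- ifelse(kind == "parent",
                    construct$ref_start + local_pos - construct$n_met - 1L,
                    NA_integer_)
  tibble(local_pos = local_pos, kind = kind, ref_pos = as.integer(ref_pos))
}

#' Map reference positions to local (expressed-chain) numbering
#'
#' Inverse of [local_to_reference()] on the parent segment.
#'
#' @param construct A single-row construct tibble.
#' @param ref_pos Integer vector of reference positions within
#'   `ref_start..ref_end`.
#' @return Integer vector of local positions.
#' @export
reference_to_local <- function(construct, ref_pos) {
  stopifnot(is.data.frame(construct), nrow(construct) == 1L)
  ref_pos <- as.integer(ref_pos)
  if (any(ref_pos < construct$ref_start | ref_pos > construct$ref_end)) {
    abort(sprintf("reference position outside %d..%d",
                  construct$ref_start, construct$ref_end),
          class = "domainmapr_range_error")
  }
  ref_pos - construct$ref_start + 1L + construct$n_met
}
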