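# Integrate fragment calls across constructs, proteases and time points into
# an ordered rigid-core / flexible-linker map of the analyzed span. Rigid
# cores are the union of fragments that persist to the final digestion time
# point; the gaps between them are flexible linkers wherever cleavage was
# observed, otherwise undetermined.

#' Merge persistent fragment intervals into rigid cores
#'
#' The union of persistent fragment intervals, merged when overlapping or
#' adjacent, gives the maximal protease-resistant cores. Consensus across
#' proteases falls out of the union: the outermost persistent termini per
#' core win, with the individual fragments retained as provenance.
#'
#' @param labels Data frame of stability labels with columns `ref_start`,
#'   `ref_end` and logical `persistent` (rows with `persistent = FALSE` are
#'   ignored; the column may be omitted, in which case all rows count).
#' @return A tibble of disjoint intervals (`ref_start`, `ref_end`) in
#'   ascending order, with a list-column `fragments` holding the row indices
#'   of the contributing labels.
#' @examples
#' rigid_cores(tibble::tibble(ref_start = c(18, 18, 286, 295, 388),
#'                            ref_end   = c(192, 227, 524, 510, 524),
#'                            persistent = TRUE))
#' @export
rigid_cores <- function(labels) {
  labels <- as_tibble(labels)
  if (!"persistent" %in% names(labels)) labels$persistent <- TRUE
  labels$.row <- seq_len(nrow(labels))
  keep <- labels[labels$persistent, , drop = FALSE]
  if (nrow(keep) == 0) {
    return(tibble(ref_start = integer(), ref_end = integer(),
                  fragments = list()))
  }
  stopifnot(all(keep$ref_start <= keep$ref_end))
  keep <- keep[order(keep$ref_start, keep$ref_end), , drop = FALSE]
  starts <- keep$ref_start
  ends <- keep$ref_end
  out_s <- integer()
  out_e <- integer()
  members <- list()
  cur_s <- starts[1]
  cur_e <- ends[1]
  cur_m <- keep$.row[1]
  if (nrow(keep) > 1) {
    for (i in 2:nrow(keep)) {
      if (starts[i] <= cur_e + 1L) {   # overlapping or adjacent
        cur_e <- max(cur_e, ends[i])
        cur_m <- c(cur_m, keep$.row[i])
      } else {
        out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
        members <- c(members, list(cur_m))
        cur_s <- starts[i]; cur_e <- ends[i]; cur_m <- keep$.row[i]
      }
    }
  }
  out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
  members <- c(members, list(cur_m))
  tibble(ref_start = as.integer(out_s), ref_end = as.integer(out_e),
         fragments = members)
}

# nested persistent fragments sharing one terminus mark the differential
# segment as partially flexible: the shorter stable species shows that the
# extra segment of the longer one can eventually be trimmed away
partial_flex_subdomains <- function(labels) {
  labels <- as_tibble(labels)
  if (!"persistent" %in% names(labels)) labels$persistent <- TRUE
  keep <- labels[labels$persistent, , drop = FALSE]
  out <- list()
  if (nrow(keep) >= 2) {
    for (i in seq_len(nrow(keep) - 1)) {
      for (j in (i + 1):nrow(keep)) {
        a <- keep[i, ]; b <- keep[j, ]
        if (a$ref_start == b$ref_start && a$ref_end != b$ref_end) {
          lo <- min(a$ref_end, b$ref_end); hi <- max(a$ref_end, b$ref_end)
          out[[length(out) + 1]] <- tibble(
            ref_start = lo + 1L, ref_end = hi, side = "C-terminal")
        } else if (a$ref_end == b$ref_end && a$ref_start != b$ref_start) {
          lo <- min(a$ref_start, b$ref_start)
          hi <- max(a$ref_start, b$ref_start)
          out[[length(out) + 1]] <- tibble(
            ref_start = lo, ref_end = hi - 1L, side = "N-terminal")
        }
      }
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(ref_start = integer(), ref_end = integer(),
                  side = character()))
  }
  res[!duplicated(res), , drop = FALSE]
}

#' Classify the analyzed span into cores, linkers and undetermined gaps
#'
#' Gaps between cores (and between the span edges and the outermost cores)
#' are labeled `flexible-linker` when cleavage evidence falls inside the gap
#' or at its boundary bonds -- a cut there is direct evidence of protease
#' accessibility -- and `undetermined` otherwise.
#'
#' @param cores Tibble of disjoint rigid-core intervals from [rigid_cores()].
#' @param span Length-2 integer vector, the analyzed reference interval.
#' @param cut_bonds Integer vector of observed cleavage bond positions (P1
#'   reference positions; the bond lies between `p` and `p + 1`). Default
#'   none.
#' @param subdomains Optional tibble of partial-flexibility sub-intervals
#'   (from nested persistent fragments), attached as provenance.
#' @return A `domain_map`: a tibble of ordered intervals tiling the span,
#'   with columns `ref_start`, `ref_end`, `label` (`rigid-core`,
#'   `flexible-linker`, `undetermined`) and `evidence` (list-column).
#' @export
classify_map <- function(cores, span, cut_bonds = integer(),
                         subdomains = NULL) {
  stopifnot(length(span) == 2L, span[1] <= span[2])
  cores <- as_tibble(cores)
  if (nrow(cores) > 1 &&
      any(cores$ref_start[-1] <= cores$ref_end[-nrow(cores)])) {
    abort("cores overlap; run rigid_cores() first",
          class = "domainmapr_schema_error")
  }
  if (nrow(cores) > 0 &&
      (min(cores$ref_start) < span[1] || max(cores$ref_end) > span[2])) {
    abort("cores extend outside the analyzed span",
          class = "domainmapr_schema_error")
  }
  if (!"fragments" %in% names(cores)) {
    cores$fragments <- rep(list(integer()), nrow(cores))
  }
  edges <- c(span[1] - 1L,
             if (nrow(cores) > 0) rbind(cores$ref_start - 1L, cores$ref_end),
             span[2])
  rows <- list()
  bounds <- matrix(c(edges[-length(edges)] + 1L, edges[-1]), ncol = 2)
  core_idx <- if (nrow(cores) > 0) seq(2, by = 2, length.out = nrow(cores))
              else integer()
  k <- 0
  for (i in seq_len(nrow(bounds))) {
    lo <- bounds[i, 1]; hi <- bounds[i, 2]
    if (lo > hi) next
    if (i %in% core_idx) {
      k <- which(core_idx == i)
      rows[[length(rows) + 1]] <- tibble(
        ref_start = lo, ref_end = hi, label = "rigid-core",
        evidence = list(cores$fragments[[k]]))
    } else {
      hit <- cut_bonds[cut_bonds >= lo - 1L & cut_bonds <= hi]
      lab <- if (length(hit) > 0) "flexible-linker" else "undetermined"
      rows[[length(rows) + 1]] <- tibble(
        ref_start = lo, ref_end = hi, label = lab,
        evidence = list(as.integer(hit)))
    }
  }
  map <- bind_rows(rows)
  new_domain_map(map, span = as.integer(span),
                 subdomains = subdomains %||%
                   tibble(ref_start = integer(), ref_end = integer(),
                          side = character()))
}

new_domain_map <- function(map, span, subdomains) {
  structure(map, span = span, subdomains = subdomains,
            class = c("domain_map", class(map)))
}

#' Assemble a domain map from fragment calls
#'
#' High-level driver: takes rank-1 fragment calls (with a `persistent`
#' column flagging fragments that survive the longest digestion time point),
#' merges the persistent intervals into rigid cores, collects cleavage
#' evidence from every call terminus that is a protease site, and classifies
#' the analyzed span. Nested persistent fragments sharing a terminus are
#' recorded as partial-flexibility subdomains (attribute `"subdomains"`).
#'
#' @param calls Fragment-call tibble from [infer_fragments()]; needs
#'   `ref_start`, `ref_end`, `cterm_kind`, `nterm_met`, `local_start` and
#'   ideally a logical `persistent` column (missing = all persistent).
#' @param span Analyzed reference interval (length 2); default the union of
#'   the intervals spanned by the calls' constructs, taken from the calls'
#'   `construct_id` and `constructs` if supplied, else the range of the call
#'   intervals themselves.
#' @param constructs Optional construct tibble used to derive the default
#'   span.
#' @param overrides Optional tibble (`ref_start`, `ref_end`, `label`) of
#'   user annotations (e.g. crystal-structure-refined boundaries) replacing
#'   the computed intervals; applied verbatim after classification.
#' @return A `domain_map`, see [classify_map()].
#' @export
assemble_domains <- function(calls, span = NULL, constructs = NULL,
                             overrides = NULL) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) {
    abort("no fragment calls to assemble", class = "domainmapr_schema_error")
  }
  if (!"persistent" %in% names(calls)) calls$persistent <- TRUE
  if (is.null(span)) {
    span <- if (!is.null(constructs)) {
      used <- constructs[constructs$id %in% calls$construct_id, ]
      c(min(used$ref_start), max(used$ref_end))
    } else {
      c(min(calls$ref_start), max(calls$ref_end))
    }
  }
  cores <- rigid_cores(calls)
  subs <- partial_flex_subdomains(calls)
  # observed cleavage bonds: protease-site C-termini, and N-termini that are
  # not the construct N-terminus (an internal Edman start implies a cut
  # immediately before it)
  cterm_bonds <- calls$ref_end[calls$cterm_kind == "protease-site"]
  internal_start <- !calls$nterm_met & calls$local_start > 1L
  nterm_bonds <- calls$ref_start[internal_start] - 1L
  map <- classify_map(cores, span,
                      cut_bonds = sort(unique(c(cterm_bonds, nterm_bonds))),
                      subdomains = subs)
  if (!is.null(overrides)) {
    ov <- as_tibble(overrides)
    stopifnot(all(c("ref_start", "ref_end", "label") %in% names(ov)))
    for (i in seq_len(nrow(ov))) {
      hit <- map$ref_start == ov$ref_start[i] & map$ref_end == ov$ref_end[i]
      if (any(hit)) map$label[hit] <- ov$label[i]
    }
  }
  map
}

#' @export
print.domain_map <- function(x, ...) {
  span <- attr(x, "span")
  cat(sprintf("Domain map over reference %d..%d\n", span[1], span[2]))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %4d-%4d  %s\n", x$ref_start[i], x$ref_end[i], x$label[i]))
  }
  subs <- attr(x, "subdomains")
  if (!is.null(subs) && nrow(subs) > 0) {
    cat("partial flexibility (nested persistent fragments):\n")
    for (i in seq_len(nrow(subs))) {
      cat(sprintf("  %4d-%4d  (%s differential segment)\n",
                  subs$ref_start[i], subs$ref_end[i], subs$side[i]))
    }
  }
  invisible(x)
}

#' Export a domain map
#'
#' Writes the map as a BED-like TSV in 1-based inclusive protein coordinates
#' (columns `start`, `end`, `label`, `evidence`) and/or as schema-versioned
#' JSON.
#'
#' @param map A `domain_map`.
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @return The map, invisibly.
#' @export
write_domain_map <- function(map, tsv = NULL, json = NULL) {
  flat <- tibble(
    start = map$ref_start, end = map$ref_end, label = map$label,
    evidence = purrr::map_chr(map$evidence,
                              ~ paste(.x, collapse = ","))
  )
  if (!is.null(tsv)) readr::write_tsv(flat, tsv)
  if (!is.null(json)) {
    subs <- attr(map, "subdomains")
    payload <- list(
      schema_version = "1.0",
      span = attr(map, "span"),
      intervals = flat,
      partial_flexibility = subs
    )
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(map)
}
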