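# Deduce fragment boundaries from an Edman N-terminal read plus an intact
# mass. The N-terminus is located by exact string match of the read on the
# expressed chain; every protease site downstream (plus the construct
# C-terminus, tag included) is a candidate C-terminus; candidates are scored
# by the difference between observed and theoretical mass.

#' Locate an Edman read on an expressed chain
#'
#' @param read Residue string of at least 3 residues (a typical Edman read is
#'   3-6 cycles).
#' @param construct A single-row construct tibble, or a plain chain string.
#' @return Integer vector of all exact-match local start positions, ascending
#'   (empty when the read does not occur; the caller decides severity).
#' @examples
#' locate_nterm("AAA", "AAAA") # 1 2
#' @export
locate_nterm <- function(read, construct) {
  stopifnot(is.character(read), length(read) == 1L)
  if (nchar(read) < 3) {
    abort("Edman read must have at least 3 residues",
          class = "domainmapr_schema_error")
  }
  check_residues(read, "Edman read")
  chain <- if (is.data.frame(construct)) construct$chain else construct
  # lookahead so that overlapping occurrences are all reported
  hits <- gregexpr(sprintf("(?=%s)", read), chain, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer() else as.integer(hits)
}

site_notation <- function(construct, local_end) {
  chain <- construct$chain
  ref <- local_to_reference(construct, local_end)
  lab <- function(pos, refpos, kind) {
    p <- substr(chain, pos, pos)
    if (kind == "parent") sprintf("%s(%d)", p, refpos) else sprintf("%s[%s]", p, kind)
  }
  if (local_end >= construct$chain_len) return("construct C-terminus")
  nxt <- local_to_reference(construct, local_end + 1L)
  sprintf("%s↓%s",
          lab(local_end, ref$ref_pos, ref$kind),
          lab(local_end + 1L, nxt$ref_pos, nxt$kind))
}

#' Infer a fragment's boundaries from one observation
#'
#' For every exact match of the Edman read and every legal C-terminus (each
#' downstream protease P1 position on the parent segment -- a fragment is
#' never shorter than its read -- plus the construct C-terminus including any
#' tag), the theoretical average mass is computed and candidates are ranked
#' by how well they explain the observed intact mass.
#'
#' Ranking: candidates are ordered by `|delta_mass|` (ties broken towards the
#' smaller fragment), except that candidates whose theoretical mass exceeds
#' `observed * (1 + tolerance)` are ranked after all others. Intact masses of
#' undigested species systematically err high (adducts, incomplete
#' desolvation), not low by many hundred daltons, so a deduced sequence
#' heavier than the measurement plus its error cannot be the species that was
#' weighed. When no candidate is within tolerance the top-ranked call is
#' still returned with `within_tolerance = FALSE` -- the "nearest possible
#' site" fallback used when a printed mass sits between two sites.
#'
#' @param construct Single-row construct tibble from [build_constructs()].
#' @param protease Protease name or spec list.
#' @param edman_read N-terminal read (>= 3 residues).
#' @param observed_mass Observed intact mass in daltons (> 0).
#' @param tolerance Relative mass tolerance (default 0.01, i.e. 1%).
#' @param include_slow Include slow-class protease sites as candidate
#'   C-termini (default `FALSE`).
#' @return A tibble of ranked `FragmentCall`s: local and reference
#'   boundaries, `nterm_met` / `cterm_tag` markers, `cterm_kind`
#'   (`"protease-site"` or `"construct-terminus"`), `site` in
#'   `"E(524)↓T(525)"` notation, `theoretical_mass` (Da),
#'   `theoretical_kda`, `delta_mass` (observed - theoretical),
#'   `within_tolerance`, and `rank`.
#' @examples
#' seqs <- tibble::tibble(id = "toy",
#'   residues = "MLKAAAEGGGTTEAAAAK", description = "toy")
#' cons <- build_constructs(
#'   tibble::tibble(id = "c1", parent = "toy", ref_start = 2, ref_end = 18,
#'                  init_met = FALSE, ctag = ""), seqs)
#' infer_fragment(cons, "v8", "LKA", 1100)
#' @export
infer_fragment <- function(construct, protease, edman_read, observed_mass,
                           tolerance = 0.01, include_slow = FALSE) {
  stopifnot(is.data.frame(construct), nrow(construct) == 1L)
  if (!is.numeric(observed_mass) || observed_mass <= 0) {
    abort("observed_mass must be positive",
          class = "domainmapr_schema_error")
  }
  spec <- resolve_protease(protease)
  starts <- locate_nterm(edman_read, construct)
  if (length(starts) == 0) {
    abort(sprintf("Edman read '%s' not found on construct '%s'",
                  edman_read, construct$id),
          class = "domainmapr_read_not_found")
  }
  chain <- construct$chain
  parent_hi <- construct$n_met + construct$parent_len
  sites <- cleavage_sites(chain, spec, include_slow = include_slow)
  # tags are not cleavable segments: candidate protease termini stay on the
  # parent segment (the parent/tag junction bond included)
  site_ends <- sites$p1_pos[sites$p1_pos <= parent_hi]
  read_len <- nchar(edman_read)

  cand <- purrr::map(starts, function(s) {
    ends <- site_ends[site_ends >= s + read_len - 1L]
    tibble(
      local_start = s,
      local_end = c(ends, construct$chain_len),
      cterm_kind = c(rep("protease-site", length(ends)),
                     "construct-terminus")
    )
  })
  cand <- bind_rows(cand)
  cand <- cand[!duplicated(cand[c("local_start", "local_end")]), ]

  cand$theoretical_mass <- purrr::map2_dbl(
    cand$local_start, cand$local_end,
    function(s, e) peptide_mass(substr(chain, s, e))
  )
  cand$delta_mass <- observed_mass - cand$theoretical_mass
  cand$within_tolerance <- abs(cand$delta_mass) <= tolerance * observed_mass
  overshoot <- cand$theoretical_mass > observed_mass * (1 + tolerance)
  ord <- order(overshoot, abs(cand$delta_mass), cand$local_end)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))

  start_map <- local_to_reference(construct, cand$local_start)
  end_map <- local_to_reference(construct, cand$local_end)
  nterm_met <- start_map$kind == "met"
  # a fragment beginning at the retained initiator Met covers the parent from
  # the construct's first parent residue
  ref_start <- ifelse(nterm_met, construct$ref_start, start_map$ref_pos)
  cterm_tag <- end_map$kind == "tag"
  ref_end <- ifelse(cterm_tag, construct$ref_end, end_map$ref_pos)

  first_res <- substr(chain, cand$local_start, cand$local_start)
  last_res <- substr(chain, cand$local_end, cand$local_end)
  deduced <- sprintf(
    "%s%s%d..%s%d%s",
    ifelse(nterm_met, "M+", ""),
    ifelse(nterm_met, substr(chain, cand$local_start + 1L,
                             cand$local_start + 1L), first_res),
    ref_start,
    ifelse(cterm_tag, "", last_res),
    ref_end,
    ifelse(cterm_tag, paste0("+", construct$ctag), "")
  )

  tibble(
    construct_id = construct$id,
    protease = spec$name,
    edman_read = edman_read,
    observed_mass = observed_mass,
    tolerance = tolerance,
    rank = cand$rank,
    local_start = cand$local_start,
    local_end = cand$local_end,
    nterm_met = nterm_met,
    ref_start = as.integer(ref_start),
    ref_end = as.integer(ref_end),
    cterm_tag = cterm_tag,
    cterm_kind = cand$cterm_kind,
    site = purrr::map_chr(cand$local_end, ~ site_notation(construct, .x)),
    theoretical_mass = cand$theoretical_mass,
    theoretical_kda = kda(cand$theoretical_mass),
    delta_mass = cand$delta_mass,
    within_tolerance = cand$within_tolerance,
    deduced = deduced
  )
}

#' Infer fragments for a table of observations
#'
#' Vectorised driver over a tidy observation table; extra columns (fragment
#' ids, time points, persistence flags, ...) are carried through to the
#' output, so the result feeds [assemble_domains()] directly.
#'
#' @param observations Data frame with columns `construct_id`, `protease`,
#'   `edman_read`, `observed_mass` (Da; a column named `observed_mass_da` is
#'   also accepted) and optionally `tolerance` per row.
#' @param constructs Construct tibble from [build_constructs()].
#' @param tolerance Default relative mass tolerance for rows without their
#'   own.
#' @param include_slow See [infer_fragment()].
#' @param top_only Keep only the rank-1 call per observation (default);
#'   `FALSE` returns the full ranked candidate lists.
#' @return A tibble of fragment calls with an `obs` row index.
#' @export
infer_fragments <- function(observations, constructs, tolerance = 0.01,
                            include_slow = FALSE, top_only = TRUE) {
  obs <- as_tibble(observations)
  if ("observed_mass_da" %in% names(obs) && !"observed_mass" %in% names(obs)) {
    obs$observed_mass <- obs$observed_mass_da
  }
  req <- c("construct_id", "protease", "edman_read", "observed_mass")
  missing_cols <- setdiff(req, names(obs))
  if (length(missing_cols) > 0) {
    abort(sprintf("observation table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "domainmapr_schema_error")
  }
  if (nrow(obs) == 0) {
    abort("observation table is empty", class = "domainmapr_schema_error")
  }
  extra <- setdiff(names(obs), c(req, "observed_mass_da", "tolerance"))
  calls <- purrr::map(seq_len(nrow(obs)), function(i) {
    row <- obs[i, ]
    tol <- if ("tolerance" %in% names(obs) && !is.na(row$tolerance)) {
      row$tolerance
    } else {
      tolerance
    }
    out <- infer_fragment(
      pick_construct(constructs, row$construct_id), row$protease,
      row$edman_read, row$observed_mass,
      tolerance = tol, include_slow = include_slow
    )
    out$obs <- i
    for (cl in extra) out[[cl]] <- row[[cl]]
    if (top_only) out[out$rank == 1L, , drop = FALSE] else out
  })
  out <- bind_rows(calls)
  select(out, "obs", dplyr::everything())
}
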