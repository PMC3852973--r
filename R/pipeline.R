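# End-to-end driver: files in, report bundle out. Deterministic given
# identical inputs; every validation failure aborts with a distinct message
# before any output is written.

#' Build a pipeline configuration
#'
#' @param fasta Path to the reference FASTA.
#' @param constructs Path to the construct table (TSV or JSON).
#' @param observations Path to the proteolysis observation TSV
#'   (`construct_id`, `protease`, `edman_read`, `observed_mass_da`, optional
#'   `tolerance`, `persistent`, extra columns pass through).
#' @param out_dir Output directory (created if missing).
#' @param hydro Optional path to a hydrodynamics CSV (`construct_id`,
#'   `mw_rh_kda`, `mw_sls_kda`, `mw_th_kda`).
#' @param protease_specs Optional path to a protease-spec JSON replacing the
#'   shipped rules.
#' @param tolerance Relative mass tolerance (default 0.01).
#' @param include_slow Include slow-class sites (default `FALSE`).
#' @param monomer_tol,rigid_max,flexible_min Classification thresholds, see
#'   [classify_hydro()].
#' @param span Optional analyzed reference span (length 2).
#' @param overrides Optional domain-map label overrides, see
#'   [assemble_domains()].
#' @param seed Integer seed recorded in the report (the deduction pipeline
#'   itself is deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta, constructs, observations, out_dir,
                            hydro = NULL, protease_specs = NULL,
                            tolerance = 0.01, include_slow = FALSE,
                            monomer_tol = 0.2, rigid_max = 1.5,
                            flexible_min = 1.8, span = NULL,
                            overrides = NULL, seed = 1) {
  stopifnot(tolerance > 0, monomer_tol > 0, rigid_max > 0, flexible_min > 0)
  structure(
    list(fasta = fasta, constructs = constructs, observations = observations,
         out_dir = out_dir, hydro = hydro, protease_specs = protease_specs,
         tolerance = tolerance, include_slow = include_slow,
         monomer_tol = monomer_tol, rigid_max = rigid_max,
         flexible_min = flexible_min, span = span, overrides = overrides,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose fields mirror the arguments of
#'   [pipeline_config()]; relative paths are resolved against the file's
#'   directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: '%s'", path),
          class = "domainmapr_io_error")
  }
  raw <- jsonlite::fromJSON(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p) || is.na(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  do.call(pipeline_config, c(
    list(fasta = fix(raw$fasta), constructs = fix(raw$constructs),
         observations = fix(raw$observations),
         out_dir = raw$out_dir %||% file.path(base, "out"),
         hydro = fix(raw$hydro), protease_specs = fix(raw$protease_specs)),
    raw[intersect(names(raw),
                  c("tolerance", "include_slow", "monomer_tol", "rigid_max",
                    "flexible_min", "span", "seed"))]
  ))
}

#' Run the full domain-mapping pipeline
#'
#' Reads the reference sequence(s), constructs and proteolysis observations,
#' deduces each fragment's boundaries, assembles the rigid-core /
#' flexible-linker map, optionally classifies a hydrodynamics table, and
#' writes a report bundle to `out_dir`: `fragment_calls.tsv`,
#' `domain_map.tsv`, `domain_map.json` and (when hydrodynamic data are
#' given) `hydro_classified.tsv`. Progress is logged to stderr; outputs are
#' byte-identical across re-runs on identical inputs.
#'
#' @param config A `pipeline_config` or a path to a JSON config.
#' @return Invisibly, a list with `calls`, `map`, `hydro` (or `NULL`) and
#'   `constructs`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) message("[domainmapr] ", sprintf(...))

  for (f in c("fasta", "constructs", "observations")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      abort(sprintf("input '%s' missing or not found: '%s'",
                    f, config[[f]] %||% "<null>"),
            class = "domainmapr_io_error")
    }
  }
  log_msg("reading sequences from %s", config$fasta)
  seqs <- read_fasta(config$fasta)
  log_msg("building constructs from %s", config$constructs)
  constructs <- read_constructs(config$constructs, seqs)
  log_msg("reading observations from %s", config$observations)
  obs <- readr::read_tsv(config$observations, show_col_types = FALSE)
  if (nrow(obs) == 0) {
    abort("observation table is empty", class = "domainmapr_schema_error")
  }
  if (!is.null(config$protease_specs)) {
    # user rules replace the shipped table for every lookup in this run
    specs <- read_protease_specs(config$protease_specs)
    obs$protease <- purrr::map(obs$protease, function(p) {
      specs[[p]] %||% abort(sprintf("unknown protease '%s' in custom specs", p),
                            class = "domainmapr_schema_error")
    })
  }

  calls <- infer_fragments(obs, constructs, tolerance = config$tolerance,
                           include_slow = config$include_slow)
  n_flag <- sum(!calls$within_tolerance)
  log_msg("deduced %d fragments (%d outside mass tolerance)",
          nrow(calls), n_flag)

  map <- assemble_domains(calls, span = config$span, constructs = constructs,
                          overrides = config$overrides)
  log_msg("domain map: %d rigid core(s), %d flexible linker(s)",
          sum(map$label == "rigid-core"), sum(map$label == "flexible-linker"))

  hydro <- NULL
  if (!is.null(config$hydro)) {
    if (!file.exists(config$hydro)) {
      abort(sprintf("hydro table not found: '%s'", config$hydro),
            class = "domainmapr_io_error")
    }
    hydro <- classify_hydro(
      readr::read_csv(config$hydro, show_col_types = FALSE),
      monomer_tol = config$monomer_tol, rigid_max = config$rigid_max,
      flexible_min = config$flexible_min
    )
    log_msg("classified %d hydrodynamic measurement(s)", nrow(hydro))
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  calls_out <- calls
  calls_out$protease <- purrr::map_chr(
    calls_out$protease, ~ if (is.list(.x)) .x$name else as.character(.x))
  readr::write_tsv(calls_out, file.path(config$out_dir, "fragment_calls.tsv"))
  write_domain_map(map,
                   tsv = file.path(config$out_dir, "domain_map.tsv"),
                   json = file.path(config$out_dir, "domain_map.json"))
  if (!is.null(hydro)) {
    readr::write_tsv(hydro, file.path(config$out_dir, "hydro_classified.tsv"))
  }
  log_msg("report bundle written to %s", config$out_dir)
  invisible(list(calls = calls, map = map, hydro = hydro,
                 constructs = constructs))
}

#' Paths to the bundled example data
#'
#' The packaged worked example: the 695-residue human APP reference
#' sequence, the expressed-construct table, the published proteolysis
#' observations (Edman reads plus intact masses), the published
#' hydrodynamics table and a synthetic GPC standards table.
#'
#' @param file Name of a file under the package's `extdata/`, or `NULL` to
#'   list them all.
#' @return A path, or a character vector of available file names.
#' @examples
#' domainmapr_example()
#' @export
domainmapr_example <- function(file = NULL) {
  base <- system.file("extdata", package = "domainmapr")
  if (is.null(file)) return(dir(base))
  path <- file.path(base, file)
  if (!file.exists(path)) {
    abort(sprintf("no packaged file '%s'", file),
          class = "domainmapr_io_error")
  }
  path
}
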