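# Ground-truthed simulators. The generator emulates the experimental logic
# of limited proteolysis: multi-domain chains whose rigid cores resist
# digestion while acidic/hydroxyl-rich linkers are protease-accessible;
# intact masses with multiplicative MALDI-scale noise; GPC/SLS readouts in
# which the MW_rh / MW_SLS ratio encodes flexibility; and BLI dilution
# series. All generators are pure functions of (parameters, seed).

# roughly database-average residue frequencies for folded cores
.CORE_FREQ <- c(
  A = 0.083, R = 0.055, N = 0.041, D = 0.054, C = 0.014, E = 0.067,
  Q = 0.039, G = 0.071, H = 0.023, I = 0.059, L = 0.097, K = 0.058,
  M = 0.024, F = 0.039, P = 0.047, S = 0.066, T = 0.053, W = 0.011,
  Y = 0.029, V = 0.069
)

# linkers modelled on an acidic domain: D/E/S/T-enriched, little hydrophobic
.LINKER_FREQ <- c(
  D = 0.15, E = 0.30, S = 0.20, T = 0.15, G = 0.10, A = 0.05, P = 0.05
)

#' Generate a synthetic multi-domain protein with known architecture
#'
#' Rigid domains are drawn with a balanced globular composition; linkers are
#' enriched in Asp/Glu/Ser/Thr (acidic-domain-like) and carry fixed
#' Glu/Ser edge motifs (`ESSS`...`ESE`) so that Glu-directed proteolysis can
#' trim right up to the domain edges, as it does on real flexible linkers,
#' and so that the nearest competing cleavage site is several residues --
#' hence several hundred daltons -- away from the true one. Deterministic
#' per seed.
#'
#' @param n_domains Number of rigid domains (>= 1).
#' @param domain_len_range,linker_len_range Length ranges (inclusive) in
#'   residues; linkers need at least 8 residues for their edge motifs.
#' @param seed Integer seed.
#' @return A `synthetic_truth` list: `parent` (sequence tibble),
#'   `construct` (single-row construct tibble spanning the chain),
#'   `domain_map` (truth intervals with `label` `rigid-core` /
#'   `flexible-linker`), `linkers`, noise defaults (`mass_sd`, `ve_sd`,
#'   `sls_sd`), `flexible` (any linker present), `shape_ratio` (true
#'   MW_rh/MW_SLS ratio drawn from the flexible or rigid regime) and `seed`.
#' @examples
#' truth <- gen_protein(n_domains = 2, seed = 1)
#' truth$domain_map
#' @export
gen_protein <- function(n_domains = 2, domain_len_range = c(120, 200),
                        linker_len_range = c(40, 70), seed = 1) {
  stopifnot(n_domains >= 1, linker_len_range[1] >= 8)
  withr::with_seed(seed, {
    d_len <- sample(domain_len_range[1]:domain_len_range[2], n_domains,
                    replace = TRUE)
    n_link <- n_domains - 1
    l_len <- if (n_link > 0) {
      sample(linker_len_range[1]:linker_len_range[2], n_link, replace = TRUE)
    } else {
      integer()
    }
    draw <- function(n, freq) {
      paste(sample(names(freq), n, replace = TRUE, prob = freq),
            collapse = "")
    }
    segs <- character(0)
    labels <- character(0)
    for (i in seq_len(n_domains)) {
      segs <- c(segs, draw(d_len[i], .CORE_FREQ))
      labels <- c(labels, "rigid-core")
      if (i <= n_link) {
        middle <- draw(l_len[i] - 7L, .LINKER_FREQ)
        segs <- c(segs, paste0("ESSS", middle, "ESE"))
        labels <- c(labels, "flexible-linker")
      }
    }
    lens <- nchar(segs)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    residues <- paste(segs, collapse = "")
    flexible <- n_link > 0
    shape_ratio <- if (flexible) runif(1, 1.8, 2.8) else runif(1, 1.0, 1.3)

    parent <- tibble(id = sprintf("SYN_seed%d", seed), residues = residues,
                     description = sprintf("synthetic %d-domain protein", n_domains))
    construct <- build_constructs(
      tibble(id = parent$id, parent = parent$id, ref_start = 1L,
             ref_end = nchar(residues), init_met = FALSE, ctag = ""),
      parent
    )
    dm <- tibble(ref_start = as.integer(starts), ref_end = as.integer(ends),
                 label = labels)
    structure(
      list(parent = parent, construct = construct, domain_map = dm,
           linkers = dm[dm$label == "flexible-linker", c("ref_start", "ref_end")],
           mass_sd = 0.003, ve_sd = 0.01, sls_sd = 0.03,
           flexible = flexible, shape_ratio = shape_ratio, seed = seed),
      class = "synthetic_truth"
    )
  })
}

in_intervals <- function(pos, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(pos)))
  purrr::map_lgl(pos, function(p) {
    any(p >= intervals$ref_start & p <= intervals$ref_end)
  })
}

#' Simulate a limited-proteolysis time course
#'
#' Cleavage happens only at accessible sites: bonds adjacent to a flexible
#' linker (P1 or P1' inside a linker). A deterministic two-class kinetic
#' model is used: a site is cut once `k * t >= ln 2`, with `k = k_fast` for
#' fast sites and `k_fast / rate_factor` for the slow class (the slow class
#' is 100-300x slower, so at a 24 h end point only fast sites have fired).
#' Fragments large enough to be seen on a gel are reported at each time
#' point with first-four-residue Edman reads and intact masses carrying
#' multiplicative Gaussian noise. Pieces lying wholly inside a linker are
#' transient -- the protease keeps nibbling fully flexible peptides -- and
#' are absent from the final time point, so the `persistent` fragments (the
#' ones still present at the end point) are exactly the rigid cores bounded
#' by their nearest accessible sites.
#'
#' @param truth A `synthetic_truth` from [gen_protein()].
#' @param protease Protease name or spec (default `"v8"`, matching the
#'   acidic linker composition).
#' @param time_points Sampling times in hours, ascending.
#' @param seed Seed for the mass noise (default the truth's own seed).
#' @param mass_sd Relative intact-mass noise sd (default from `truth`,
#'   0.003 = 0.3%, MALDI scale).
#' @param k_fast Fast-site rate constant in 1/h.
#' @param rate_factor Fold slow-down of the slow site class.
#' @param min_frag_mass_da Smallest fragment reported (gel detection limit).
#' @return A tibble of observations: `time_point`, `construct_id`,
#'   `protease`, `edman_read`, `observed_mass`, `persistent`, plus the
#'   ground-truth interval (`true_start`, `true_end`).
#' @export
simulate_digest <- function(truth, protease = "v8",
                            time_points = c(0.25, 1, 24),
                            seed = truth$seed, mass_sd = truth$mass_sd,
                            k_fast = 1, rate_factor = 200,
                            min_frag_mass_da = 3000) {
  stopifnot(inherits(truth, "synthetic_truth"), all(diff(time_points) > 0))
  spec <- resolve_protease(protease)
  chain <- truth$construct$chain
  sites <- cleavage_sites(chain, spec, include_slow = TRUE)
  accessible <- sites[in_intervals(sites$p1_pos, truth$linkers) |
                        in_intervals(sites$p1_pos + 1L, truth$linkers), ]
  k <- ifelse(accessible$rate_class == "fast", k_fast, k_fast / rate_factor)
  cut_time <- log(2) / k

  frag_at <- function(t, final = FALSE) {
    cuts <- sort(accessible$p1_pos[cut_time <= t])
    bounds <- c(0L, cuts, nchar(chain))
    fr <- tibble(true_start = utils::head(bounds, -1) + 1L,
                 true_end = utils::tail(bounds, -1))
    if (final) {
      # wholly-flexible pieces keep being nibbled and are gone by the end
      # point; only core-containing fragments remain as stable bands
      linker_only <- purrr::map2_lgl(fr$true_start, fr$true_end, function(s, e) {
        any(s >= truth$linkers$ref_start & e <= truth$linkers$ref_end)
      })
      fr <- fr[!linker_only, , drop = FALSE]
    }
    fr
  }
  last_frags <- frag_at(max(time_points), final = TRUE)
  withr::with_seed(seed, {
    out <- purrr::map(time_points, function(t) {
      fr <- frag_at(t, final = t == max(time_points))
      fr$time_point <- t
      fr
    })
    out <- bind_rows(out)
    out$theoretical <- purrr::map2_dbl(
      out$true_start, out$true_end,
      ~ peptide_mass(substr(chain, .x, .y))
    )
    out <- out[out$theoretical >= min_frag_mass_da, , drop = FALSE]
    out$observed_mass <- out$theoretical *
      (1 + rnorm(nrow(out), 0, mass_sd))
    out$edman_read <- substring(chain, out$true_start, out$true_start + 3L)
    out$persistent <- purrr::map2_lgl(
      out$true_start, out$true_end,
      ~ any(last_frags$true_start == .x & last_frags$true_end == .y)
    )
    tibble(
      time_point = out$time_point,
      construct_id = truth$construct$id,
      protease = spec$name,
      edman_read = out$edman_read,
      observed_mass = out$observed_mass,
      persistent = out$persistent,
      true_start = out$true_start,
      true_end = out$true_end
    )
  })
}

#' Simulate GPC / SLS readouts for synthetic constructs
#'
#' `MW_SLS` is the true mass with 3% multiplicative noise (typical SLS
#' triplicate spread); the retention volume is the one the calibration
#' assigns to `true mass x true shape ratio`, plus Gaussian volume noise.
#' Rigid constructs carry true ratios in 1.0-1.3, flexible ones 1.8-2.8.
#'
#' @param truths A `synthetic_truth` or list of them.
#' @param cal A `gpc_calibration`.
#' @param seed Integer seed.
#' @param sls_sd,ve_sd Noise levels (defaults from the truths).
#' @return A tibble per construct: `construct_id`, `mw_th_kda`, `ve_ml`,
#'   `mw_rh_kda`, `mw_sls_kda`, `shape_ratio` (measured), `true_ratio` and
#'   `flexible` (truth).
#' @export
simulate_gpc_sls <- function(truths, cal, seed = 1, sls_sd = NULL,
                             ve_sd = NULL) {
  if (inherits(truths, "synthetic_truth")) truths <- list(truths)
  stopifnot(inherits(cal, "gpc_calibration"))
  withr::with_seed(seed, {
    rows <- purrr::map(truths, function(tr) {
      s_sd <- sls_sd %||% tr$sls_sd
      v_sd <- ve_sd %||% tr$ve_sd
      true_kda <- construct_mass(tr$construct) / 1000
      mw_sls_kda <- true_kda * (1 + rnorm(1, 0, s_sd))
      ve <- ve_for_mw(true_kda * tr$shape_ratio, cal) + rnorm(1, 0, v_sd)
      mw_rh_kda <- mw_rh(ve, cal)
      tibble(
        construct_id = tr$construct$id,
        mw_th_kda = true_kda,
        ve_ml = ve,
        mw_rh_kda = mw_rh_kda,
        mw_sls_kda = mw_sls_kda,
        shape_ratio = mw_rh_kda / mw_sls_kda,
        true_ratio = tr$shape_ratio,
        flexible = tr$flexible
      )
    })
    bind_rows(rows)
  })
}

#' Simulate a steady-state BLI dilution series
#'
#' Equilibrium responses over a 2-fold analyte dilution series following the
#' one-site isotherm, with Gaussian read noise; `kd_um = NA` simulates a
#' non-binding pair (flat responses at noise level).
#'
#' @param kd_um Dissociation constant in uM, or `NA` for no binding.
#' @param rmax_nm Saturation response in nm.
#' @param conc_um Analyte concentrations (default the 40 to 0.625 uM 2-fold
#'   series).
#' @param noise_sd Response noise sd in nm.
#' @param replicates Replicates per concentration.
#' @param seed Integer seed.
#' @return A tibble with columns `conc_um`, `response_nm`, `replicate`.
#' @export
simulate_bli <- function(kd_um = 5, rmax_nm = 1, conc_um = 40 / 2^(0:6),
                         noise_sd = 0.01, replicates = 3, seed = 1) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(conc_um = conc_um,
                               replicate = seq_len(replicates))
    mean_resp <- if (is.na(kd_um)) {
      rep(0, nrow(grid))
    } else {
      rmax_nm * grid$conc_um / (kd_um + grid$conc_um)
    }
    grid$response_nm <- mean_resp + rnorm(nrow(grid), 0, noise_sd)
    grid[, c("conc_um", "response_nm", "replicate")]
  })
}
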