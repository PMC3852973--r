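# Hydrodynamic characterisation: GPC calibration and the apparent
# (hydrodynamic-radius based) molecular weight MW_rh; absolute molecular
# weight from static light scattering in the single-angle
# Rayleigh-Gans-Debye limit (MW_SLS); oligomeric state from MW_SLS vs the
# theoretical mass; shape/flexibility from the ratio MW_rh / MW_SLS; a
# co-elution interaction test; and steady-state BLI isotherm fitting.

#' Fit a GPC calibration line
#'
#' Least-squares fit of `log10(MW in Da)` on retention volume (ml), the
#' standard semi-log size-exclusion calibration. Larger molecules elute
#' earlier, so a well-behaved column gives a negative slope; a positive
#' slope triggers a warning.
#'
#' @param standards Data frame with columns `name`, `mw_da`, `ve_ml`
#'   (at least 3 standards with distinct retention volumes).
#' @return A `gpc_calibration` object: list with `slope`, `intercept`,
#'   `r_squared`, `standards` and the underlying `lm` fit.
#' @examples
#' std <- tibble::tibble(name = c("a", "b", "c", "d"),
#'                       mw_da = c(66430, 29000, 12384, 6511),
#'                       ve_ml = c(1.62, 1.89, 2.17, 2.38))
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards) {
  standards <- as_tibble(standards)
  req <- c("mw_da", "ve_ml")
  if (!all(req %in% names(standards))) {
    abort("standards need columns mw_da and ve_ml",
          class = "domainmapr_schema_error")
  }
  if (nrow(standards) < 3) {
    abort("at least 3 calibration standards are required",
          class = "domainmapr_schema_error")
  }
  if (length(unique(standards$ve_ml)) < 2) {
    abort("degenerate calibration: all retention volumes identical",
          class = "domainmapr_schema_error")
  }
  fit <- lm(log10(mw_da) ~ ve_ml, data = standards)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) {
    warn("calibration slope is non-negative; larger molecules should elute earlier")
  }
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         standards = standards, fit = fit),
    class = "gpc_calibration"
  )
}

#' @export
print.gpc_calibration <- function(x, ...) {
  cat(sprintf(
    "GPC calibration: log10(MW/Da) = %.4f %+.4f * Ve(ml)  (R^2 = %.4f, %d standards)\n",
    x$intercept, x$slope, x$r_squared, nrow(x$standards)))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x A `gpc_calibration`.
#' @param ... Unused.
#' @method tidy gpc_calibration
#' @export
tidy.gpc_calibration <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = unname(summary(x$fit)$coefficients[, "Std. Error"]))
}

#' @rdname fit_calibration
#' @method glance gpc_calibration
#' @export
glance.gpc_calibration <- function(x, ...) {
  tibble(r.squared = x$r_squared, n_standards = nrow(x$standards),
         slope = x$slope, intercept = x$intercept)
}

#' Apparent molecular weight from retention volume
#'
#' @param ve_ml Retention volume(s) in ml.
#' @param cal A `gpc_calibration`.
#' @return MW_rh in kDa.
#' @export
mw_rh <- function(ve_ml, cal) {
  stopifnot(inherits(cal, "gpc_calibration"))
  10^(cal$slope * ve_ml + cal$intercept) / 1000
}

#' Retention volume expected for a given apparent mass
#'
#' Inverse of [mw_rh()]; used by the GPC simulator.
#'
#' @param mw_kda Apparent mass in kDa.
#' @param cal A `gpc_calibration`.
#' @return Retention volume in ml.
#' @export
ve_for_mw <- function(mw_kda, cal) {
  stopifnot(inherits(cal, "gpc_calibration"))
  (log10(mw_kda * 1000) - cal$intercept) / cal$slope
}

#' Absolute molecular weight from static light scattering
#'
#' Single-angle Rayleigh-Gans-Debye limit appropriate for proteins well
#' below the light wavelength: `M = R90 / (K * (dn/dc)^2 * c)` per elution
#' slice, averaged across the peak weighted by concentration.
#'
#' @param slices Data frame with columns `r90` (excess Rayleigh ratio) and
#'   `c_g_per_ml` (concentration from the RI detector), one row per elution
#'   slice; a single-row input is the single-reading case.
#' @param k_optical Instrument optical constant excluding the `(dn/dc)^2`
#'   factor (mol cm^2 g^-2 scale absorbed into the detector calibration).
#' @param dndc Refractive index increment in ml/g; 0.185 is the standard
#'   protein value.
#' @return MW_SLS in kDa.
#' @export
mw_sls <- function(slices, k_optical, dndc = 0.185) {
  slices <- as_tibble(slices)
  if (!all(c("r90", "c_g_per_ml") %in% names(slices))) {
    abort("slices need columns r90 and c_g_per_ml",
          class = "domainmapr_schema_error")
  }
  if (any(slices$c_g_per_ml <= 0) || any(slices$r90 <= 0) ||
      k_optical <= 0 || dndc <= 0) {
    abort("SLS inputs must be positive", class = "domainmapr_schema_error")
  }
  mw_da <- slices$r90 / (k_optical * dndc^2 * slices$c_g_per_ml)
  stats::weighted.mean(mw_da, slices$c_g_per_ml) / 1000
}

#' Oligomeric state from absolute vs theoretical mass
#'
#' `monomer` when MW_SLS is within `tol` (relative) of MW_th, `dimer` when
#' within `tol` of twice MW_th, otherwise `other`.
#'
#' @param mw_sls_kda,mw_th_kda Absolute and theoretical masses in kDa
#'   (vectorised).
#' @param tol Relative tolerance, default 0.2.
#' @return Character vector: `"monomer"`, `"dimer"` or `"other"`.
#' @examples
#' oligomeric_state(72.2, 69.1) # monomer
#' @export
oligomeric_state <- function(mw_sls_kda, mw_th_kda, tol = 0.2) {
  stopifnot(all(mw_sls_kda > 0), all(mw_th_kda > 0), tol > 0)
  ratio <- mw_sls_kda / mw_th_kda
  dplyr::case_when(
    abs(ratio - 1) <= tol ~ "monomer",
    abs(ratio - 2) <= 2 * tol ~ "dimer",
    TRUE ~ "other"
  )
}

#' Shape / flexibility class from the MW_rh / MW_SLS ratio
#'
#' A compact globular protein elutes at the volume its true mass predicts
#' (ratio near 1); flexible or extended chains drag a much larger
#' hydrodynamic radius (ratio well above 1). Thresholds default to the
#' empirical gap between the two regimes: rigid constructs sit at or below
#' about 1.3, flexible ones at or above about 1.85.
#'
#' @param shape_ratio `MW_rh / MW_SLS` (vectorised).
#' @param rigid_max Ratios at or below this are `rigid-compact`
#'   (default 1.5).
#' @param flexible_min Ratios at or above this are `flexible-extended`
#'   (default 1.8); in between is `elongated`.
#' @return Character vector of shape classes.
#' @examples
#' classify_shape(c(1.0, 1.7, 2.6))
#' @export
classify_shape <- function(shape_ratio, rigid_max = 1.5,
                           flexible_min = 1.8) {
  stopifnot(all(shape_ratio > 0), rigid_max < flexible_min)
  dplyr::case_when(
    shape_ratio <= rigid_max ~ "rigid-compact",
    shape_ratio >= flexible_min ~ "flexible-extended",
    TRUE ~ "elongated"
  )
}

#' Classify a table of hydrodynamic measurements
#'
#' Adds `shape_ratio`, `oligomeric_state` and `shape_class` columns to a
#' per-construct table of MW_rh / MW_SLS / MW_th values.
#'
#' @param measurements Data frame with columns `mw_rh_kda`, `mw_sls_kda`,
#'   `mw_th_kda` (extra columns pass through).
#' @param monomer_tol,rigid_max,flexible_min Thresholds, see
#'   [oligomeric_state()] and [classify_shape()].
#' @return The input tibble with the three classification columns added.
#' @export
classify_hydro <- function(measurements, monomer_tol = 0.2,
                           rigid_max = 1.5, flexible_min = 1.8) {
  m <- as_tibble(measurements)
  req <- c("mw_rh_kda", "mw_sls_kda", "mw_th_kda")
  if (!all(req %in% names(m))) {
    abort(sprintf("hydro table needs columns %s", paste(req, collapse = ", ")),
          class = "domainmapr_schema_error")
  }
  m |>
    mutate(
      shape_ratio = .data$mw_rh_kda / .data$mw_sls_kda,
      oligomeric_state = oligomeric_state(.data$mw_sls_kda, .data$mw_th_kda,
                                          tol = monomer_tol),
      shape_class = classify_shape(.data$shape_ratio, rigid_max = rigid_max,
                                   flexible_min = flexible_min)
    )
}

#' Co-elution interaction test
#'
#' Two species that associate elute earlier as the larger complex; a mixture
#' eluting at an intermediate volume between the individual peaks shows no
#' strong interaction. Interaction is called only when the mixture elutes
#' earlier than both components by more than `tol`.
#'
#' @param ve_a,ve_b Retention volumes (ml) of the isolated species.
#' @param ve_mix Retention volume (ml) of the mixture.
#' @param tol Volume tolerance in ml (default 0.01).
#' @return `TRUE` if an interaction is indicated.
#' @examples
#' coelution_test(1.78, 1.83, 1.82) # FALSE: intermediate volume
#' @export
coelution_test <- function(ve_a, ve_b, ve_mix, tol = 0.01) {
  stopifnot(ve_a > 0, ve_b > 0, ve_mix > 0, tol >= 0)
  ve_mix < min(ve_a, ve_b) - tol
}

#' Steady-state BLI binding analysis
#'
#' Fits the hyperbolic one-site isotherm `R_eq = Rmax * C / (Kd + C)` to
#' equilibrium responses over an analyte dilution series and decides whether
#' a binding affinity is measurable at all: not measurable when the fit
#' fails, when the fitted Kd lies above the highest tested concentration, or
#' when the fitted amplitude does not rise above three times the replicate
#' noise.
#'
#' @param series Data frame with columns `conc_um` and `response_nm`, and
#'   optionally `replicate`; at least 4 distinct concentrations.
#' @param c_max Highest concentration considered tested (default
#'   `max(conc_um)`).
#' @return A `bli_fit` object: list with `kd_um`, `rmax_nm`, `measurable`,
#'   `noise_sd`, `converged`, `series` and the `nls` fit (or `NULL`).
#' @examples
#' ser <- simulate_bli(kd_um = 5, rmax_nm = 1, noise_sd = 0.01, seed = 1)
#' bli_steady_state(ser)
#' @export
bli_steady_state <- function(series, c_max = NULL) {
  series <- as_tibble(series)
  if (!all(c("conc_um", "response_nm") %in% names(series))) {
    abort("BLI series needs columns conc_um and response_nm",
          class = "domainmapr_schema_error")
  }
  if (length(unique(series$conc_um)) < 4) {
    abort("at least 4 analyte concentrations are required",
          class = "domainmapr_schema_error")
  }
  c_max <- c_max %||% max(series$conc_um)
  noise_sd <- if ("replicate" %in% names(series) &&
                  length(unique(series$replicate)) > 1) {
    series |>
      group_by(.data$conc_um) |>
      summarise(s = sd(.data$response_nm), .groups = "drop") |>
      (\(d) mean(d$s, na.rm = TRUE))()
  } else {
    NA_real_
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response_nm ~ rmax * conc_um / (kd + conc_um),
      data = series,
      start = list(rmax = max(series$response_nm),
                   kd = stats::median(series$conc_um)),
      lower = c(rmax = 0, kd = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) {
    kd <- NA_real_; rmax <- NA_real_; converged <- FALSE
  } else {
    est <- coef(fit)
    kd <- unname(est["kd"]); rmax <- unname(est["rmax"]); converged <- TRUE
  }
  if (is.na(noise_sd)) {
    noise_sd <- if (converged) sd(stats::residuals(fit)) else
      sd(series$response_nm)
  }
  measurable <- converged && is.finite(kd) && kd <= c_max &&
    is.finite(rmax) && rmax >= 3 * noise_sd
  structure(
    list(kd_um = kd, rmax_nm = rmax, measurable = measurable,
         noise_sd = noise_sd, converged = converged, c_max = c_max,
         series = series, fit = fit),
    class = "bli_fit"
  )
}

#' @export
print.bli_fit <- function(x, ...) {
  if (x$measurable) {
    cat(sprintf("BLI steady-state fit: Kd = %.3g uM, Rmax = %.3g nm (measurable)\n",
                x$kd_um, x$rmax_nm))
  } else {
    cat(sprintf(
      "BLI steady-state fit: no measurable affinity up to %.3g uM (noise sd %.3g nm)\n",
      x$c_max, x$noise_sd))
  }
  invisible(x)
}

#' @rdname bli_steady_state
#' @param x A `bli_fit`.
#' @param ... Unused.
#' @method tidy bli_fit
#' @export
tidy.bli_fit <- function(x, ...) {
  tibble(term = c("kd_um", "rmax_nm"), estimate = c(x$kd_um, x$rmax_nm))
}

#' @rdname bli_steady_state
#' @method glance bli_fit
#' @export
glance.bli_fit <- function(x, ...) {
  tibble(kd_um = x$kd_um, rmax_nm = x$rmax_nm, measurable = x$measurable,
         noise_sd = x$noise_sd, converged = x$converged,
         n_conc = length(unique(x$series$conc_um)))
}
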