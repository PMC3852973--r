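# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_segment geom_point geom_line
#'   geom_rect geom_text scale_y_continuous labs theme_minimal
NULL

#' Plot a domain map
#'
#' One horizontal track in reference coordinates: rigid cores as thick
#' blocks, linkers and undetermined gaps as thin bars, partial-flexibility
#' subdomains as hatched overlays above the track.
#'
#' @param object A `domain_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot domain_map
#' @export
autoplot.domain_map <- function(object, ...) {
  d <- tibble(
    start = object$ref_start, end = object$ref_end, label = object$label,
    ymin = ifelse(object$label == "rigid-core", -0.35, -0.08),
    ymax = ifelse(object$label == "rigid-core", 0.35, 0.08)
  )
  subs <- attr(object, "subdomains")
  p <- ggplot(d) +
    geom_rect(aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                  ymin = .data$ymin, ymax = .data$ymax,
                  fill = .data$label)) +
    geom_text(aes(x = (.data$start + .data$end) / 2, y = 0.55,
                  label = sprintf("%d-%d", .data$start, .data$end)),
              size = 3) +
    scale_y_continuous(limits = c(-1, 1), breaks = NULL) +
    labs(x = "reference position", y = NULL, fill = NULL,
         title = "Rigid-core / flexible-linker map") +
    theme_minimal()
  if (!is.null(subs) && nrow(subs) > 0) {
    p <- p + geom_segment(
      data = subs,
      aes(x = .data$ref_start, xend = .data$ref_end, y = -0.6, yend = -0.6),
      linewidth = 2, lineend = "butt", colour = "grey40"
    )
  }
  p
}

#' Plot a GPC calibration
#'
#' Standards and the fitted semi-log line.
#'
#' @param object A `gpc_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gpc_calibration
#' @export
autoplot.gpc_calibration <- function(object, ...) {
  std <- object$standards
  grid <- tibble(ve_ml = seq(min(std$ve_ml), max(std$ve_ml),
                             length.out = 100))
  grid$log_mw <- object$slope * grid$ve_ml + object$intercept
  ggplot(std, aes(x = .data$ve_ml, y = log10(.data$mw_da))) +
    geom_line(data = grid, aes(y = .data$log_mw), colour = "steelblue") +
    geom_point(size = 2) +
    labs(x = "retention volume (ml)", y = "log10 MW (Da)",
         title = sprintf("GPC calibration (R² = %.3f)",
                         object$r_squared)) +
    theme_minimal()
}

#' Plot a BLI steady-state fit
#'
#' Equilibrium responses against analyte concentration with the fitted
#' one-site isotherm (when the fit converged).
#'
#' @param object A `bli_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bli_fit
#' @export
autoplot.bli_fit <- function(object, ...) {
  ser <- object$series
  p <- ggplot(ser, aes(x = .data$conc_um, y = .data$response_nm)) +
    geom_point(alpha = 0.7) +
    labs(x = "analyte concentration (µM)",
         y = "equilibrium response (nm)",
         title = if (object$measurable) {
           sprintf("BLI isotherm: Kd = %.2g µM", object$kd_um)
         } else {
           "BLI: no measurable affinity"
         }) +
    theme_minimal()
  if (object$converged) {
    grid <- tibble(conc_um = seq(0, max(ser$conc_um), length.out = 200))
    grid$response_nm <- object$rmax_nm * grid$conc_um /
      (object$kd_um + grid$conc_um)
    p <- p + geom_line(data = grid, colour = "steelblue")
  }
  p
}
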