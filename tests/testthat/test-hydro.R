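exact_standards <- function(slope = -1.3, intercept = 7, ve = c(1.6, 1.9, 2.2, 2.4)) {
  tibble::tibble(name = paste0("s", seq_along(ve)), ve_ml = ve,
                 mw_da = 10^(slope * ve + intercept))
}

test_that("calibration recovers an exact line and rejects degenerate input", {
  std <- exact_standards()
  # summary.lm's "essentially perfect fit" note is expected on exact data
  cal <- suppressWarnings(fit_calibration(std))
  expect_equal(cal$slope, -1.3, tolerance = 1e-9)
  expect_equal(cal$intercept, 7, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  # predicting a standard's Ve returns that standard's MW
  expect_equal(mw_rh(std$ve_ml, cal), std$mw_da / 1000, tolerance = 1e-9)

  expect_error(fit_calibration(std[1:2, ]),
               class = "domainmapr_schema_error")
  expect_error(fit_calibration(tibble::tibble(
    name = c("a", "b", "c"), mw_da = c(1e4, 2e4, 3e4), ve_ml = rep(2, 3))),
    class = "domainmapr_schema_error")
  expect_warning(fit_calibration(tibble::tibble(
    name = c("a", "b", "c"), mw_da = c(1e4, 2e4, 3e4),
    ve_ml = c(1.5, 1.9, 2.3))), "slope")
})

test_that("noisy retention volumes still recover standard masses within 5%", {
  withr::with_seed(101, {
    std <- exact_standards()
    noisy <- std
    noisy$ve_ml <- noisy$ve_ml + rnorm(nrow(std), 0, 0.01)
    cal <- fit_calibration(noisy)
    rec <- mw_rh(std$ve_ml, cal) * 1000
    expect_true(all(abs(rec - std$mw_da) / std$mw_da < 0.05))
  })
})

test_that("mw_rh is monotone decreasing in Ve and inverts via ve_for_mw", {
  cal <- suppressWarnings(fit_calibration(exact_standards()))
  ve <- seq(1.5, 2.5, by = 0.1)
  expect_true(all(diff(mw_rh(ve, cal)) < 0))
  expect_equal(ve_for_mw(mw_rh(ve, cal), cal), ve, tolerance = 1e-9)
})

test_that("single-angle RGD mass is exact on constructed readings", {
  k <- 2e-7; dndc <- 0.185
  mw <- 27000
  c1 <- 5e-4
  reading <- tibble::tibble(r90 = k * dndc^2 * c1 * mw, c_g_per_ml = c1)
  expect_equal(mw_sls(reading, k, dndc), 27.0, tolerance = 1e-9)

  # doubling the concentration at fixed scattering halves the mass
  half <- tibble::tibble(r90 = reading$r90, c_g_per_ml = 2 * c1)
  expect_equal(mw_sls(half, k, dndc), 13.5, tolerance = 1e-9)

  # peak average equals the per-slice value when MW is constant
  conc <- c(1, 3, 5, 3, 1) * 1e-4
  peak <- tibble::tibble(r90 = k * dndc^2 * conc * mw, c_g_per_ml = conc)
  expect_equal(mw_sls(peak, k, dndc), 27.0, tolerance = 1e-9)

  expect_error(mw_sls(tibble::tibble(r90 = 1, c_g_per_ml = 0), k),
               class = "domainmapr_schema_error")
})

test_that("oligomeric state separates monomers from dimers", {
  expect_equal(oligomeric_state(72.2, 69.1), "monomer")
  withr::with_seed(5, {
    x <- runif(20, 5, 200)
    expect_true(all(oligomeric_state(1 * x, x) == "monomer"))
    expect_true(all(oligomeric_state(2 * x, x) == "dimer"))
    expect_true(all(oligomeric_state(3.5 * x, x) == "other"))
  })
})

test_that("shape classification is monotone with visible thresholds", {
  expect_equal(classify_shape(27 / 27.0), "rigid-compact")
  expect_equal(classify_shape(88 / 33.6), "flexible-extended")
  expect_equal(classify_shape(1.0), "rigid-compact")
  r <- seq(0.8, 3, by = 0.05)
  cls <- classify_shape(r)
  ord <- c("rigid-compact", "elongated", "flexible-extended")
  expect_true(all(diff(match(cls, ord)) >= 0))  # monotone in r
  # thresholds are arguments, not constants
  expect_equal(classify_shape(1.6, rigid_max = 1.7), "rigid-compact")
})

test_that("co-elution logic calls interaction only on earlier elution", {
  expect_false(coelution_test(1.78, 1.83, 1.82, 0.01))  # intermediate
  expect_false(coelution_test(1.8, 1.8, 1.8, 0.01))     # no shift
  expect_true(coelution_test(1.8, 1.85, 1.60, 0.01))    # clearly earlier
})

test_that("BLI steady-state fit recovers Kd and flags flat series", {
  ser <- simulate_bli(kd_um = 5, rmax_nm = 1, noise_sd = 0.01, seed = 2)
  fit <- bli_steady_state(ser)
  expect_true(fit$measurable)
  expect_lt(abs(fit$kd_um - 5) / 5, 0.2)

  flat <- simulate_bli(kd_um = NA, rmax_nm = 0, noise_sd = 0.01, seed = 3)
  nofit <- bli_steady_state(flat)
  expect_false(nofit$measurable)

  # zero-noise isotherm is recovered exactly
  clean <- simulate_bli(kd_um = 2.5, rmax_nm = 0.8, noise_sd = 0,
                        replicates = 1, seed = 4)
  exact <- bli_steady_state(clean)
  expect_equal(exact$kd_um, 2.5, tolerance = 1e-6)
  expect_equal(exact$rmax_nm, 0.8, tolerance = 1e-6)

  expect_error(bli_steady_state(ser[ser$conc_um > 10, ]),
               class = "domainmapr_schema_error")
})

test_that("tidy and glance methods expose fit summaries", {
  std <- exact_standards()
  std$ve_ml <- std$ve_ml + c(0.004, -0.003, 0.002, -0.002)
  cal <- fit_calibration(std)
  expect_equal(tidy(cal)$term, c("intercept", "slope"))
  expect_equal(glance(cal)$n_standards, 4L)

  fit <- bli_steady_state(simulate_bli(seed = 6))
  expect_equal(tidy(fit)$term, c("kd_um", "rmax_nm"))
  expect_true(is.logical(glance(fit)$measurable))
})
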