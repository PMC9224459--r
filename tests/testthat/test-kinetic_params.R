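test_that("half-life and D-value match the published first-order table", {
  expect_equal(half_life(log(2)), 1.0)
  expect_equal(d_value(2.303), 1.0)
  expect_equal(round(half_life(lipase_ps_k), 2),
               c(`40` = 50.97, `50` = 35.19, `60` = 23.98, `70` = 15.75))
  expect_equal(round(d_value(lipase_ps_k)),
               c(`40` = 169, `50` = 117, `60` = 80, `70` = 52))
  expect_equal(d_value(lipase_ps_k) / half_life(lipase_ps_k),
               rep(2.303 / log(2), 4), ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(half_life(0), "k > 0")
  expect_error(d_value(-1), "k > 0")
})

test_that("z-value recovers constructed and published slopes", {
  # exact tenfold drop per 10 degC
  z10 <- z_value(c(40, 50, 60, 70), 10^(4 - (1:4)))
  expect_equal(z10$z, 10, tolerance = 1e-12)
  # constructed slope -1/25
  tt <- c(40, 50, 60, 70)
  z25 <- z_value(tt, 10^(3 - tt / 25))
  expect_equal(z25$z, 25, tolerance = 1e-10)
  # published first-order rates
  zps <- z_value(tt, d_value(unname(lipase_ps_k)))
  expect_equal(zps$z, 58.8, tolerance = 0.005)
  expect_equal(zps$slope, -0.0170, tolerance = 0.005)
  expect_error(z_value(40, 10), "two distinct")
})

test_that("z-value is invariant to rescaling D and to the D vs t1/2 choice", {
  tt <- c(40, 50, 60, 70)
  k <- unname(lipase_ps_k)
  base <- z_value(tt, d_value(k))$z
  expect_equal(z_value(tt, 7.3 * d_value(k))$z, base, tolerance = 1e-12)
  expect_equal(z_value(tt, half_life(k))$z, base, tolerance = 1e-12)
})

test_that("reliable life matches the published Weibull table", {
  expect_equal(reliable_life(2.303, 1), 1.0)
  tr <- reliable_life(palatase_bn$b, palatase_bn$n)
  # 60 and 70 degC reproduce the printed values closely; 40 degC carries
  # the rounding of the printed (b, n) inputs
  expect_equal(tr[3], 29.70, tolerance = 1e-3)
  expect_equal(tr[4], 20.07, tolerance = 1e-3)
  expect_equal(tr[1], 41.97, tolerance = 0.005)
  expect_error(reliable_life(0, 2), "b > 0")
})

test_that("residual activity at the reliable life is always ~10%", {
  withr::with_seed(13, {
    for (i in 1:30) {
      b <- 10^stats::runif(1, -8, -1)
      n <- stats::runif(1, 0.5, 5)
      tr <- reliable_life(b, n)
      expect_equal(evaluate_model("weibull", c(b = b, n = n), tr),
                   exp(-2.303), tolerance = 1e-10)
    }
  })
})

test_that("z' reproduces the natural-log regression and its log10 analogue", {
  tt <- c(40, 50, 60, 70)
  tr <- c(41.97, 31.57, 29.70, 20.07)
  zp_ln <- z_prime(tt, tr, log_base = "ln")
  expect_equal(zp_ln$z_prime, 43.9, tolerance = 0.005)
  expect_equal(zp_ln$slope, -0.0228, tolerance = 0.01)
  # log10 convention, checked against the closed-form OLS slope
  zp_10 <- z_prime(tt, tr, log_base = "log10")
  expect_equal(zp_10$z_prime, 1 / abs(ols_slope(tt, log10(tr))), tolerance = 1e-12)
  expect_equal(zp_10$z_prime, 101.25, tolerance = 1e-4)
  # exact tenfold drop per 10 degC
  expect_equal(z_prime(tt, 10^(4 - (1:4)), log_base = "log10")$z_prime, 10,
               tolerance = 1e-12)
})

test_that("log-logistic b(T) fit recovers exact and published parameters", {
  tt <- c(40, 50, 60, 70)
  # noiseless self-consistency
  b_exact <- log(1 + exp(0.25 * (tt - 100)))
  ll <- fit_log_logistic(tt, b_exact)
  expect_true(ll$converged)
  expect_equal(ll$k_prime, 0.25, tolerance = 1e-6)
  expect_equal(ll$T_c, 100, tolerance = 1e-5)
  # value at T = Tc is ln 2
  expect_equal(log(1 + exp(0)), log(2))
  # published Weibull scales
  llp <- fit_log_logistic(tt, palatase_bn$b)
  expect_equal(llp$k_prime, 0.2483, tolerance = 0.005)
  expect_equal(llp$T_c, 98.89, tolerance = 0.005)
  expect_equal(llp$r2, 0.9305, tolerance = 0.005)
  expect_error(fit_log_logistic(40, 1), "two points")
})

test_that("kinetic_summary assembles the branch matching the model", {
  fits_fo <- purrr::map2_dfr(c(40, 50, 60, 70), unname(lipase_ps_k), function(tc, k) {
    fit_model(noiseless_curve("first_order", c(k = k), temperature_C = tc),
              "first_order") |>
      dplyr::mutate(temperature_C = tc, .before = 1)
  })
  ks <- kinetic_summary(fits_fo)
  expect_s3_class(ks, "kinetic_summary")
  expect_equal(ks$per_temperature$t_half, unname(half_life(lipase_ps_k)),
               tolerance = 1e-6)
  expect_equal(ks[["z"]]$z, 58.8, tolerance = 0.005)
  expect_null(ks[["z_prime"]])

  fits_wb <- purrr::pmap_dfr(palatase_bn, function(temperature_C, b, n) {
    fit_model(noiseless_curve("weibull", c(b = b, n = n),
                              times = default_time_grid(),
                              temperature_C = temperature_C), "weibull") |>
      dplyr::mutate(temperature_C = temperature_C, .before = 1)
  })
  kw <- kinetic_summary(fits_wb, zprime_base = "ln")
  expect_equal(kw$per_temperature$t_R,
               reliable_life(palatase_bn$b, palatase_bn$n), tolerance = 1e-4)
  expect_equal(kw[["z_prime"]]$z_prime, 43.9, tolerance = 0.01)
  expect_null(kw[["z"]])
  expect_true(kw$log_logistic$converged)
})
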