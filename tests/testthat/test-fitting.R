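test_that("goodness-of-fit statistics follow their definitions", {
  g <- goodness_of_fit(c(1.0, 0.5), c(1.0, 0.6), p = 1)
  expect_equal(g$chi2, 0.0100)
  expect_equal(g$sem, 0.0050)

  y <- c(1, 0.8, 0.5, 0.2)
  perfect <- goodness_of_fit(y, y, p = 2)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$sem, 0)

  flat <- goodness_of_fit(y, rep(mean(y), 4), p = 1)
  expect_equal(flat$r2, 0)

  expect_error(goodness_of_fit(y, y, p = 4), "more observations")
  expect_error(goodness_of_fit(y, y[1:3], p = 1), "equal length")
})

test_that("chi2 and sem keep their exact degrees-of-freedom relation", {
  set.seed(42)
  for (i in 1:10) {
    m <- sample(5:40, 1)
    p <- sample(1:4, 1)
    y <- stats::runif(m)
    pred <- y + stats::rnorm(m, 0, 0.05)
    g <- goodness_of_fit(y, pred, p)
    expect_equal(g$chi2 * (m - p), g$sem * m, tolerance = 1e-14)
  }
})

test_that("noiseless curves are recovered exactly", {
  d <- noiseless_curve("first_order", c(k = 0.02))
  f <- fit_model(d, "first_order")
  expect_true(f$converged)
  expect_equal(f$estimates[[1]][["k"]], 0.02, tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$chi2, 0, tolerance = 1e-12)

  d2 <- noiseless_curve("weibull", c(b = 9.37e-5, n = 2.981),
                        times = default_time_grid())
  f2 <- fit_model(d2, "weibull")
  est <- f2$estimates[[1]]
  expect_equal(est[["b"]], 9.37e-5, tolerance = 1e-6)
  expect_equal(est[["n"]], 2.981, tolerance = 1e-6)
})

test_that("refitting a model to its own predictions is idempotent", {
  set.seed(7)
  tt <- default_time_grid()
  d <- tibble::tibble(
    temperature_C = 40, time_min = rep(tt, 3), replicate = rep(1:3, each = length(tt)),
    activity = evaluate_model("weibull", c(b = 1.54e-5, n = 3.461), rep(tt, 3)) +
      stats::rnorm(3 * length(tt), 0, 0.02)
  )
  f1 <- fit_model(d, "weibull")
  pred <- tibble::tibble(
    time_min = d$time_min,
    activity = evaluate_model("weibull", f1$estimates[[1]], d$time_min)
  )
  f2 <- fit_model(pred, "weibull")
  expect_equal(f2$estimates[[1]], f1$estimates[[1]], tolerance = 1e-6)
})

test_that("the Weibull model outfits first-order on shape-n decay", {
  set.seed(123)
  tt <- default_time_grid()
  truth <- evaluate_model("weibull", c(b = 1.97e-7, n = 4.357), rep(tt, 3))
  d <- tibble::tibble(time_min = rep(tt, 3), activity = truth +
                        stats::rnorm(length(truth), 0, 0.02))
  fw <- fit_model(d, "weibull")
  ff <- fit_model(d, "first_order")
  expect_true(fw$r2 > ff$r2)
})

test_that("fit_model validates its inputs", {
  expect_error(fit_model(tibble::tibble(x = 1), "first_order"), "time_min")
  d <- tibble::tibble(time_min = c(0, 10), activity = c(1, NA))
  expect_error(fit_model(d, "first_order"), "non-finite")
  few <- tibble::tibble(time_min = c(0, 10, 20), activity = exp(-0.02 * c(0, 10, 20)))
  expect_error(fit_model(few, "distinct_isoenzymes"), "too few observations")
})

test_that("fitting does not disturb the caller's random-number stream", {
  d <- noiseless_curve("first_order", c(k = 0.02))
  set.seed(5)
  before <- stats::runif(1)
  set.seed(5)
  invisible(fit_model(d, "first_order"))
  after <- stats::runif(1)
  expect_identical(before, after)
})

make_fit_row <- function(model_id, temperature_C, estimates, std_errors,
                         r2, chi2 = (1 - r2) * 1e-2, converged = TRUE) {
  n_par <- length(estimates)
  tibble::tibble(
    temperature_C = temperature_C, model_id = model_id, converged = converged,
    estimates = list(estimates), std_errors = list(std_errors),
    r2 = r2, chi2 = chi2, sem = chi2 * 0.9, m = 39, p = n_par,
    residuals = list(numeric(0))
  )
}

test_that("selection rejects by the physical criteria with named reasons", {
  fits <- dplyr::bind_rows(
    make_fit_row("first_order", 40, c(k = 0.0136), c(k = 1e-4), 0.99),
    make_fit_row("distinct_isoenzymes", 40,
                 c(A_L = 0.5, A_S = 0.5, k_L = 0.02, k_R = 0.0200),
                 c(A_L = 0.1, A_S = 0.1, k_L = 1e-3, k_R = 1e-3), 0.991),
    make_fit_row("two_fraction", 40, c(a = -0.2, k_L = 0.02, k_R = 0.01),
                 c(a = 0.1, k_L = 1e-3, k_R = 1e-3), 0.995),
    make_fit_row("series_type", 40, c(alpha_1 = 0.4, k_1 = 0.05, k_2 = 0.01),
                 c(alpha_1 = NA, k_1 = NA, k_2 = NA), NA_real_,
                 chi2 = NA_real_, converged = FALSE)
  )
  v <- select_model(fits)
  get <- function(mid, col) v[[col]][v$model_id == mid]
  expect_equal(get("distinct_isoenzymes", "reason"), "equal_rate_constants")
  expect_equal(get("two_fraction", "reason"), "negative_params")
  expect_equal(get("series_type", "reason"), "no_convergence")
  expect_equal(get("first_order", "status"), "accepted")
  expect_equal(sum(v$status == "accepted"), 1L)
})

test_that("a Weibull fit with n within SE of 1 reduces to first-order", {
  fits <- dplyr::bind_rows(
    make_fit_row("first_order", 40, c(k = 0.0136), c(k = 1e-4), 0.990),
    make_fit_row("weibull", 40, c(b = 0.013, n = 1.02), c(b = 1e-3, n = 0.05), 0.991)
  )
  v <- select_model(fits)
  expect_equal(v$reason[v$model_id == "weibull"], "reduces_to_first_order")
  expect_equal(v$model_id[v$status == "accepted"], "first_order")
})

test_that("the sole surviving model is accepted regardless of rank", {
  fits <- dplyr::bind_rows(
    make_fit_row("first_order", 40, c(k = 0.0136), c(k = 1e-4), 0.70),
    make_fit_row("weibull", 40, c(b = -0.01, n = 2), c(b = 1e-3, n = 0.1), 0.99)
  )
  v <- select_model(fits)
  expect_equal(v$model_id[v$status == "accepted"], "first_order")
})

test_that("clearly better statistics win outside the indistinguishable band", {
  fits <- dplyr::bind_rows(
    make_fit_row("first_order", 40, c(k = 0.05), c(k = 1e-3), 0.75),
    make_fit_row("weibull", 40, c(b = 1.9e-7, n = 4.4), c(b = 1e-8, n = 0.2), 0.99)
  )
  v <- select_model(fits)
  expect_equal(v$model_id[v$status == "accepted"], "weibull")
  expect_equal(v$reason[v$model_id == "first_order"], "low_r2_high_error")
})

test_that("empty fit sets are refused", {
  expect_error(select_model(tibble::tibble()), "empty")
})
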