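# Derived kinetic quantities: half-life, decimal reduction time, z-value,
# reliable life, z'-value, and the log-logistic temperature model for the
# Weibull scale parameter.

#' Half-life of a first-order inactivation process
#'
#' Time for the residual activity to fall to 50%, t1/2 = ln(2)/k.
#'
#' @param k First-order rate constant, min^-1, positive. Vectorized.
#' @return Half-life in minutes.
#' @examples
#' half_life(0.0136)  # 50.97 min
#' @export
half_life <- function(k) {
  if (any(k <= 0)) stop("half_life requires k > 0", call. = FALSE)
  log(2) / k
}

#' Decimal reduction time (D-value)
#'
#' Time for a 90% reduction of the initial activity under first-order
#' kinetics, D = 2.303/k (2.303 = ln 10 to the field's conventional three
#' decimals).
#'
#' @inheritParams half_life
#' @return D-value in minutes.
#' @examples
#' d_value(0.0136)  # 169.3 min
#' @export
d_value <- function(k) {
  if (any(k <= 0)) stop("d_value requires k > 0", call. = FALSE)
  2.303 / k
}

#' z-value from D-values across temperatures
#'
#' The temperature increase producing a tenfold change in the decimal
#' reduction time: ordinary least squares of log10(D) on temperature, with
#' z = -1/slope.
#'
#' @param temperature_C Temperatures in degrees Celsius (>= 2 distinct).
#' @param d D-values in minutes, positive.
#' @return A list: `z` (degrees C), `slope`, `intercept`, `r2` of the
#'   regression.
#' @examples
#' z_value(c(40, 50, 60, 70), d_value(c(0.0136, 0.0197, 0.0289, 0.0440)))
#' @export
z_value <- function(temperature_C, d) {
  stopifnot(length(temperature_C) == length(d))
  if (length(unique(temperature_C)) < 2) {
    stop("z_value needs at least two distinct temperatures", call. = FALSE)
  }
  if (any(d <= 0)) stop("z_value requires positive D-values", call. = FALSE)
  fit <- stats::lm(log10(d) ~ temperature_C)
  slope <- stats::coef(fit)[[2]]
  if (slope == 0) stop("zero slope: z-value undefined", call. = FALSE)
  list(
    z = -1 / slope, slope = slope, intercept = stats::coef(fit)[[1]],
    r2 = suppressWarnings(summary(fit)$r.squared)
  )
}

#' Reliable life of a Weibull inactivation process
#'
#' The Weibull analogue of the D-value: the 90th percentile of the failure
#' (inactivation) time distribution, t_R = (2.303/b)^(1/n). The residual
#' activity at t_R is exp(-2.303), i.e. ~10%.
#'
#' @param b Weibull scale, min^-n, positive. Vectorized.
#' @param n Weibull shape, positive.
#' @return Reliable life in minutes.
#' @examples
#' reliable_life(1.97e-7, 4.357)  # 41.97 min
#' @export
reliable_life <- function(b, n) {
  if (any(b <= 0) || any(n <= 0)) {
    stop("reliable_life requires b > 0 and n > 0", call. = FALSE)
  }
  (2.303 / b)^(1 / n)
}

#' z'-value from reliable-life values across temperatures
#'
#' Temperature sensitivity of the Weibull reliable life, defined
#' analogously to the z-value: least-squares regression of log(t_R) on
#' temperature, z' = 1/|slope|. The standard convention uses base-10
#' logarithms (`log_base = "log10"`, the default); `log_base = "ln"`
#' performs the regression in natural log, a convention also found in the
#' inactivation literature.
#'
#' @param temperature_C Temperatures in degrees Celsius (>= 2 distinct).
#' @param t_r Reliable-life values in minutes, positive.
#' @param log_base `"log10"` (default) or `"ln"`.
#' @return A list: `z_prime` (degrees C), `slope`, `intercept`, `r2`, and
#'   the `log_base` used.
#' @examples
#' z_prime(c(40, 50, 60, 70), c(41.97, 31.57, 29.70, 20.07), log_base = "ln")
#' @export
z_prime <- function(temperature_C, t_r, log_base = c("log10", "ln")) {
  log_base <- match.arg(log_base)
  stopifnot(length(temperature_C) == length(t_r))
  if (length(unique(temperature_C)) < 2) {
    stop("z_prime needs at least two distinct temperatures", call. = FALSE)
  }
  if (any(t_r <= 0)) stop("z_prime requires positive t_R values", call. = FALSE)
  ly <- if (log_base == "log10") log10(t_r) else log(t_r)
  fit <- stats::lm(ly ~ temperature_C)
  slope <- stats::coef(fit)[[2]]
  if (slope == 0) stop("zero slope: z'-value undefined", call. = FALSE)
  list(
    z_prime = 1 / abs(slope), slope = slope,
    intercept = stats::coef(fit)[[1]], r2 = suppressWarnings(summary(fit)$r.squared),
    log_base = log_base
  )
}

#' Log-logistic temperature dependence of the Weibull scale
#'
#' Fits b(T) = ln(1 + exp(k' (T - Tc))) to per-temperature Weibull scale
#' estimates. Tc marks the temperature above which inactivation proceeds
#' at a significant rate; k' is the steepness of the rise of b(T) beyond
#' it. Because b typically spans several orders of magnitude across a
#' moderate temperature range, the default objective is least squares on
#' the log scale (ln b vs ln model), initialized from the exponential
#' regime (b ~ exp(k'(T - Tc)) when k'(T - Tc) << 0, i.e. the log-linear
#' regression of ln b on T); `scale = "linear"` minimizes untransformed
#' residuals instead.
#'
#' @param temperature_C Temperatures in degrees Celsius (>= 2 points).
#' @param b Weibull scale values, min^-n, positive.
#' @param scale Residual scale for the objective: `"log"` (default) or
#'   `"linear"`.
#' @return A list: `k_prime` (per degree C), `T_c` (degrees C), `r2` (on
#'   the chosen residual scale), `converged`.
#' @examples
#' fit_log_logistic(c(40, 50, 60, 70), c(1.97e-7, 1.54e-5, 9.37e-5, 4.22e-4))
#' @export
fit_log_logistic <- function(temperature_C, b, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  stopifnot(length(temperature_C) == length(b))
  if (length(b) < 2) stop("fit_log_logistic needs at least two points", call. = FALSE)
  if (any(b <= 0)) stop("fit_log_logistic requires positive b values", call. = FALSE)
  tt <- temperature_C
  init_fit <- stats::lm(log(b) ~ tt)
  kp0 <- stats::coef(init_fit)[[2]]
  tc0 <- -stats::coef(init_fit)[[1]] / kp0
  model_fn <- function(p) log(1 + exp(p[1] * (tt - p[2])))
  resid_fn <- function(p) {
    pred <- model_fn(p)
    if (scale == "log") {
      if (any(pred <= 0)) return(rep(1e6, length(b)))
      log(b) - log(pred)
    } else {
      b - pred
    }
  }
  res <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = c(kp0, tc0), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )),
    error = function(e) NULL
  )
  if (is.null(res) || !res$info %in% 1:4) {
    return(list(k_prime = kp0, T_c = tc0, r2 = NA_real_, converged = FALSE))
  }
  pred <- model_fn(res$par)
  obs <- if (scale == "log") log(b) else b
  fitv <- if (scale == "log") log(pred) else pred
  r2 <- 1 - sum((obs - fitv)^2) / sum((obs - mean(obs))^2)
  list(k_prime = res$par[1], T_c = res$par[2], r2 = r2, converged = TRUE)
}

#' Per-temperature and cross-temperature kinetic summary
#'
#' Assembles the derived kinetic quantities for the accepted model from a
#' fit table: per temperature, the rate parameters and half-life/D-value
#' (first-order) or reliable life and alpha (Weibull); across
#' temperatures, the z-value (first-order) or z'-value and log-logistic
#' b(T) parameters (Weibull).
#'
#' @param fits Rows of [fit_models()] output for one (accepted) model.
#' @param zprime_base Log base for the z' regression, `"log10"` or `"ln"`.
#' @return A list of class `kinetic_summary`: `model_id`, `per_temperature`
#'   (tibble), and the cross-temperature scalars that apply
#'   (`z`, or `z_prime` and `log_logistic`).
#' @export
kinetic_summary <- function(fits, zprime_base = c("log10", "ln")) {
  zprime_base <- match.arg(zprime_base)
  stopifnot(is.data.frame(fits), nrow(fits) >= 1)
  mid <- unique(fits$model_id)
  if (length(mid) != 1) stop("fits must contain a single model", call. = FALSE)
  temps <- fits$temperature_C
  est <- fits$estimates

  if (mid == "weibull") {
    b <- purrr::map_dbl(est, "b")
    n <- purrr::map_dbl(est, "n")
    per <- tibble::tibble(
      temperature_C = temps, r2 = fits$r2, b = b, n = n,
      t_R = reliable_life(b, n), alpha = weibull_to_alpha(b, n)
    )
    zp <- if (length(unique(temps)) >= 2) z_prime(temps, per$t_R, zprime_base) else NULL
    ll <- if (length(unique(temps)) >= 2) fit_log_logistic(temps, b) else NULL
    out <- list(model_id = mid, per_temperature = per, z_prime = zp, log_logistic = ll)
  } else {
    rate_sym <- switch(mid,
      first_order = "k", nth_order = "k", fractional_conversion = "k",
      distinct_isoenzymes = "k_L", two_fraction = "k_L",
      multicomponent = "k_1", series_type = "k_1"
    )
    k <- purrr::map_dbl(est, rate_sym)
    per <- tibble::tibble(
      temperature_C = temps, r2 = fits$r2, k = k,
      t_half = half_life(k), D = d_value(k)
    )
    zv <- if (length(unique(temps)) >= 2) z_value(temps, per$D) else NULL
    out <- list(model_id = mid, per_temperature = per, z = zv)
  }
  structure(out, class = "kinetic_summary")
}

#' @export
print.kinetic_summary <- function(x, ...) {
  cat("Kinetic summary (", x$model_id, ")\n", sep = "")
  print(x$per_temperature)
  if (!is.null(x[["z"]])) {
    cat(sprintf("z-value: %.1f degC (log10 D vs T, r2 = %.4f)\n",
                x[["z"]]$z, x[["z"]]$r2))
  }
  if (!is.null(x$z_prime)) {
    cat(sprintf("z'-value: %.1f degC (%s t_R vs T, r2 = %.4f)\n",
                x$z_prime$z_prime, x$z_prime$log_base, x$z_prime$r2))
  }
  if (!is.null(x$log_logistic) && isTRUE(x$log_logistic$converged)) {
    cat(sprintf("log-logistic b(T): k' = %.4f per degC, Tc = %.2f degC (r2 = %.4f)\n",
                x$log_logistic$k_prime, x$log_logistic$T_c, x$log_logistic$r2))
  }
  invisible(x)
}
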