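# Closed-form residual-activity models for enzyme thermal inactivation.
#
# All models return the residual-activity fraction A/A0 with A0 normalized
# to 1, as a function of heating time t (min). Rate constants are in min^-1
# throughout; the Weibull scale b carries units min^-n.

MODEL_IDS <- c(
  "first_order", "weibull", "distinct_isoenzymes", "two_fraction",
  "multicomponent", "series_type", "nth_order", "fractional_conversion"
)

# param_names: ordered symbols; positive: symbols whose negative estimates
# violate the physical admissibility criterion (rates, fractions, shapes).
.model_bank <- list(
  first_order = list(
    label = "First-order",
    param_names = "k",
    positive = "k",
    fun = function(p, t) exp(-p[["k"]] * t)
  ),
  weibull = list(
    label = "Weibull distribution",
    param_names = c("b", "n"),
    positive = c("b", "n"),
    fun = function(p, t) exp(-p[["b"]] * t^p[["n"]])
  ),
  distinct_isoenzymes = list(
    label = "Distinct isoenzymes",
    param_names = c("A_L", "A_S", "k_L", "k_R"),
    positive = c("A_L", "A_S", "k_L", "k_R"),
    fun = function(p, t) {
      p[["A_L"]] * exp(-p[["k_L"]] * t) + p[["A_S"]] * exp(-p[["k_R"]] * t)
    }
  ),
  two_fraction = list(
    label = "Two-fraction",
    param_names = c("a", "k_L", "k_R"),
    positive = c("a", "k_L", "k_R"),
    fun = function(p, t) {
      p[["a"]] * exp(-p[["k_L"]] * t) + (1 - p[["a"]]) * exp(-p[["k_R"]] * t)
    }
  ),
  multicomponent = list(
    label = "Multi-component first-order",
    param_names = c("r", "k_1", "k_2"),
    positive = c("r", "k_1", "k_2"),
    fun = function(p, t) {
      (exp(-p[["k_1"]] * t) + p[["r"]] * exp(-p[["k_2"]] * t)) / (1 + p[["r"]])
    }
  ),
  series_type = list(
    label = "Series-type",
    param_names = c("alpha_1", "k_1", "k_2"),
    positive = c("alpha_1", "k_1", "k_2"),
    fun = function(p, t) {
      a2 <- if ("alpha_2" %in% names(p)) p[["alpha_2"]] else 0
      k1 <- p[["k_1"]]
      k2 <- p[["k_2"]]
      if (isTRUE(all.equal(k1, k2, tolerance = 1e-12))) {
        stop("series_type model is singular when k_1 = k_2", call. = FALSE)
      }
      cc <- p[["alpha_1"]] * k1 / (k2 - k1) - a2 * k2 / (k2 - k1)
      a2 + (1 + cc) * exp(-k1 * t) - cc * exp(-k2 * t)
    }
  ),
  nth_order = list(
    label = "nth-order decay",
    param_names = c("n", "k"),
    positive = c("n", "k"),
    fun = function(p, t) {
      n <- p[["n"]]
      if (isTRUE(all.equal(n, 1, tolerance = 1e-12))) {
        stop("nth_order model requires n != 1 (n = 1 is first-order)", call. = FALSE)
      }
      base <- 1 + (n - 1) * p[["k"]] * t
      if (any(base <= 0)) {
        stop("nth_order model undefined: 1 + (n - 1) k t must stay positive", call. = FALSE)
      }
      base^(1 / (1 - n))
    }
  ),
  fractional_conversion = list(
    label = "Fractional conversion",
    param_names = c("A_r", "k"),
    positive = c("A_r", "k"),
    fun = function(p, t) {
      p[["A_r"]] + (1 - p[["A_r"]]) * exp(-p[["k"]] * t)
    }
  )
)

#' Catalog of thermal-inactivation models
#'
#' The eight kinetic models commonly used to describe the loss of enzyme
#' activity under isothermal heating, in their conventional order:
#' first-order, Weibull distribution, distinct isoenzymes, two-fraction,
#' multi-component first-order, series-type, nth-order decay, and
#' fractional conversion. All are closed-form expressions for the residual
#' activity fraction A/A0 at time t (min), normalized so A/A0 = 1 at t = 0
#' (the series-type model uses the fully-deactivated final state,
#' `alpha_2 = 0`, unless an `alpha_2` parameter is supplied explicitly).
#'
#' @return A tibble with one row per model: `model_id`, `label`,
#'   `n_params`, and a list-column `param_names` of the ordered parameter
#'   symbols.
#' @examples
#' model_catalog()
#' @export
model_catalog <- function() {
  tibble::tibble(
    model_id = names(.model_bank),
    label = purrr::map_chr(.model_bank, "label"),
    n_params = unname(purrr::map_int(.model_bank, ~ length(.x$param_names))),
    param_names = unname(purrr::map(.model_bank, "param_names"))
  )
}

.get_model <- function(model_id) {
  m <- .model_bank[[model_id]]
  if (is.null(m)) {
    stop("unknown model_id: '", model_id, "'. Known models: ",
         paste(MODEL_IDS, collapse = ", "), call. = FALSE)
  }
  m
}

.check_params <- function(model_id, params) {
  m <- .get_model(model_id)
  params <- unlist(params)
  missing <- setdiff(m$param_names, names(params))
  if (length(missing) > 0) {
    stop("model '", model_id, "' is missing parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(params[m$param_names]))) {
    stop("non-finite parameter value for model '", model_id, "'", call. = FALSE)
  }
  params
}

#' Evaluate a residual-activity model
#'
#' Computes the residual-activity fraction A/A0 predicted by one of the
#' eight inactivation models at the given heating times.
#'
#' @param model_id One of the ids in [model_catalog()].
#' @param params Named numeric vector (or list) of model parameters. Rate
#'   constants are in min^-1; the Weibull scale `b` is in min^-n; amplitude
#'   fractions are dimensionless. The series-type model accepts an optional
#'   `alpha_2` (final-state activity fraction), defaulting to 0.
#' @param t Numeric vector of heating times in minutes, t >= 0.
#' @return Numeric vector of predicted A/A0, same length as `t`.
#' @examples
#' evaluate_model("first_order", c(k = 0.0136), t = c(0, 50.97))
#' evaluate_model("weibull", c(b = 4.22e-4, n = 2.869), t = 20.07)
#' @export
evaluate_model <- function(model_id, params, t) {
  m <- .get_model(model_id)
  params <- .check_params(model_id, params)
  stopifnot(is.numeric(t))
  if (any(t < 0, na.rm = TRUE)) {
    stop("heating times must be nonnegative", call. = FALSE)
  }
  m$fun(params, t)
}

#' Convert the Weibull scale b to the time-scale parameter alpha
#'
#' The Weibull model exp(-b t^n) can be reparameterized as
#' exp(-(t/alpha)^n) with b = 1/alpha^n; alpha (min) is the characteristic
#' inactivation time and its inverse serves as an apparent rate for
#' Arrhenius analysis.
#'
#' @param b Weibull scale, min^-n, positive.
#' @param n Weibull shape, positive.
#' @return alpha in minutes, `b^(-1/n)`. Vectorized.
#' @examples
#' weibull_to_alpha(1.97e-7, 4.357)
#' @export
weibull_to_alpha <- function(b, n) {
  if (any(b <= 0) || any(n <= 0)) {
    stop("weibull_to_alpha requires b > 0 and n > 0", call. = FALSE)
  }
  b^(-1 / n)
}
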