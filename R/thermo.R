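# Arrhenius activation energy and Eyring (transition-state) activation
# thermodynamics of enzyme deactivation.

# physical constants (SI)
.KB <- 1.380649e-23   # Boltzmann, J K^-1
.PLANCK <- 6.62607015e-34  # Planck, J s
.RGAS <- 8.314        # gas constant, J mol^-1 K^-1

#' Arrhenius fit of temperature-dependent rates
#'
#' Ordinary least squares of ln(rate) on reciprocal absolute temperature;
#' the activation energy is Ea = -slope * R. Ea is invariant to the rate
#' unit (a unit change shifts only the intercept), so rates may be given
#' in any single consistent unit.
#'
#' @param temperature_K Absolute temperatures in kelvin (>= 2 distinct).
#' @param rate Positive rate constants (one consistent unit).
#' @return A list: `Ea` (kJ mol^-1), `intercept` (ln of the
#'   pre-exponential constant, in the rate's unit), `slope` (K), `r2`.
#' @examples
#' fit_arrhenius(c(40, 50, 60, 70) + 273.15, c(0.0136, 0.0197, 0.0289, 0.0440))
#' @export
fit_arrhenius <- function(temperature_K, rate) {
  stopifnot(length(temperature_K) == length(rate))
  if (length(unique(temperature_K)) < 2) {
    stop("fit_arrhenius needs at least two distinct temperatures", call. = FALSE)
  }
  if (any(rate <= 0)) stop("fit_arrhenius requires positive rates", call. = FALSE)
  if (any(temperature_K <= 0)) stop("temperatures must be in kelvin (> 0)", call. = FALSE)
  invT <- 1 / temperature_K
  fit <- stats::lm(log(rate) ~ invT)
  slope <- stats::coef(fit)[[2]]
  list(
    Ea = -slope * .RGAS / 1000,
    intercept = stats::coef(fit)[[1]],
    slope = slope,
    r2 = suppressWarnings(summary(fit)$r.squared)
  )
}

#' Eyring activation thermodynamics of deactivation
#'
#' Transition-state quantities for an inactivation rate constant at one
#' temperature: dH = Ea - R T; dG = -R T ln(k h / (kB T)) with k in s^-1;
#' dS = (dH - dG)/T; and the entropy/enthalpy balance ratio T dS / dH.
#'
#' Rates are supplied in min^-1 and converted to s^-1 before entering the
#' Eyring expression (`units = "si"`, the default). `units =
#' "paper-compat"` inserts the numeric value in min^-1 without conversion,
#' a convention encountered in parts of the inactivation literature for
#' Weibull-derived apparent rates; it rescales dG by -RT ln(60) and leaves
#' dH untouched.
#'
#' @param k Inactivation rate constant(s), min^-1, positive. Vectorized
#'   together with `temperature_K`.
#' @param temperature_K Absolute temperature(s), kelvin.
#' @param Ea Activation energy in kJ mol^-1 (from [fit_arrhenius()]).
#' @param units `"si"` (convert min^-1 to s^-1; default) or
#'   `"paper-compat"`.
#' @return A tibble: `temperature_K`, `dH` and `dG` (kJ mol^-1), `dS`
#'   (J mol^-1 K^-1), `ratio` (T dS / dH, dimensionless).
#' @examples
#' eyring_thermodynamics(0.0136, 313.15, Ea = 34.80)
#' @export
eyring_thermodynamics <- function(k, temperature_K, Ea,
                                  units = c("si", "paper-compat")) {
  units <- match.arg(units)
  if (any(k <= 0) || any(temperature_K <= 0)) {
    stop("eyring_thermodynamics requires k > 0 and temperature_K > 0", call. = FALSE)
  }
  if (!all(is.finite(Ea))) stop("Ea must be finite", call. = FALSE)
  k_s <- if (units == "si") k / 60 else k
  TK <- temperature_K
  dH <- Ea - .RGAS * TK / 1000
  dG <- -.RGAS * TK * log(k_s * .PLANCK / (.KB * TK)) / 1000
  dS <- (dH - dG) * 1000 / TK
  tibble::tibble(
    temperature_K = TK, dH = dH, dG = dG, dS = dS,
    ratio = TK * dS / (dH * 1000)
  )
}

#' Activation thermodynamic summary across temperatures
#'
#' Runs the Arrhenius regression on per-temperature rates and derives the
#' Eyring quantities at each temperature. For Weibull fits the rate is the
#' apparent rate alpha^-1 (alpha from the scale/shape reparameterization
#' b = 1/alpha^n), expressed in h^-1 for the Arrhenius step as is
#' conventional for that surrogate; the resulting thermodynamic outputs
#' are flagged `apparent`.
#'
#' @param temperature_C Temperatures in degrees Celsius.
#' @param rate Rate constants in min^-1 (first-order k, or alpha^-1 for
#'   Weibull-derived input).
#' @param apparent Flag the outputs as apparent (Weibull-derived) rather
#'   than true first-order quantities.
#' @param arrhenius_rate_unit Unit in which rates enter the Arrhenius
#'   regression: `"per_min"` (default) or `"per_h"` (multiplies by 60;
#'   affects only the intercept, never Ea).
#' @inheritParams eyring_thermodynamics
#' @return A list of class `thermo_summary`: `Ea` (kJ mol^-1),
#'   `arrhenius` (full regression), `per_temperature` (tibble with
#'   `temperature_C` plus the [eyring_thermodynamics()] columns),
#'   `apparent`, `units`.
#' @examples
#' thermo_summary(c(40, 50, 60, 70), c(0.0136, 0.0197, 0.0289, 0.0440))
#' @export
thermo_summary <- function(temperature_C, rate, apparent = FALSE,
                           units = c("si", "paper-compat"),
                           arrhenius_rate_unit = c("per_min", "per_h")) {
  units <- match.arg(units)
  arrhenius_rate_unit <- match.arg(arrhenius_rate_unit)
  TK <- temperature_C + 273.15
  arr_rate <- if (arrhenius_rate_unit == "per_h") rate * 60 else rate
  arr <- fit_arrhenius(TK, arr_rate)
  ey <- eyring_thermodynamics(rate, TK, Ea = arr$Ea, units = units)
  per <- dplyr::mutate(ey, temperature_C = temperature_C, .before = 1)
  structure(
    list(Ea = arr$Ea, arrhenius = arr, per_temperature = per,
         apparent = apparent, units = units),
    class = "thermo_summary"
  )
}

#' @export
print.thermo_summary <- function(x, ...) {
  lab <- if (x$apparent) " (apparent, Weibull-derived)" else ""
  cat(sprintf("Activation thermodynamics%s\n", lab))
  cat(sprintf("Ea = %.2f kJ mol^-1 (Arrhenius r2 = %.4f)\n", x$Ea, x$arrhenius$r2))
  print(x$per_temperature)
  invisible(x)
}
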