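# Shared fixtures: the published kinetic parameters of the two reference
# lipases, and small constructors for test curves.

lipase_ps_k <- c(`40` = 0.0136, `50` = 0.0197, `60` = 0.0289, `70` = 0.0440)

palatase_bn <- tibble::tibble(
  temperature_C = c(40, 50, 60, 70),
  b = c(1.97e-7, 1.54e-5, 9.37e-5, 4.22e-4),
  n = c(4.357, 3.461, 2.981, 2.869)
)

study_temps_C <- c(40, 50, 60, 70)
study_temps_K <- study_temps_C + 273.15

# noiseless single-temperature curve in the long layout
noiseless_curve <- function(model_id, params, times = seq(0, 240, by = 20),
                            temperature_C = 40) {
  tibble::tibble(
    temperature_C = temperature_C,
    time_min = times,
    replicate = 1L,
    activity = evaluate_model(model_id, params, times)
  )
}

# independent OLS slope via the closed-form covariance formula (used as an
# oracle for the regression-based quantities)
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
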