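# thermokin

Kinetics and activation thermodynamics of enzyme thermal inactivation.

When an enzyme solution is held at a fixed temperature, its catalytic
activity decays. Characterizing that decay — which kinetic law it follows,
how fast it is, and what energy barrier separates the native enzyme from its
inactivated state — is a routine but multi-step analysis in biocatalysis and
food-process engineering. `thermokin` implements the whole chain for
isothermal residual-activity data:

1. **Model bank.** Eight closed-form models for the residual-activity
   fraction A/A₀(t): first-order `exp(−kt)`, Weibull `exp(−b·tⁿ)`, distinct
   isoenzymes, two-fraction, multi-component first-order, series-type,
   nth-order decay, and fractional conversion.
2. **Fitting and selection.** Unconstrained multi-start nonlinear least
   squares (Levenberg–Marquardt) of every model at every temperature, then
   an accept/reject decision per model combining a physical criterion
   (no negative rate, fraction, or shape estimates) with statistical ones
   (r², χ² = SSres/(m−p), SEM = SSres/m), with parsimony and a secondary
   temperature-dependence regression separating statistically
   indistinguishable fits.
3. **Derived kinetics.** Half-life t½ = ln 2 / k, decimal reduction time
   D = 2.303/k, and the z-value (−1/slope of log₁₀D vs T) for first-order
   kinetics; reliable life t_R = (2.303/b)^(1/n), the z′-value, the
   log-logistic scale model b(T) = ln(1 + exp[k′(T − T_c)]), and the
   time-scale reparameterization α = b^(−1/n) for Weibull kinetics.
4. **Activation thermodynamics.** Arrhenius activation energy
   Ea = −R·slope of ln k vs 1/T, and transition-state quantities
   ΔH‡ = Ea − RT, ΔG‡ = −RT·ln(k·h/(k_B·T)), ΔS‡ = (ΔH‡ − ΔG‡)/T, plus the
   entropy/enthalpy balance TΔS‡/ΔH‡. Weibull-derived (α⁻¹) results are
   flagged as *apparent*.
5. **Synthetic data.** A seeded generator of replicate decay curves from any
   bank model, including presets reproducing the published inactivation
   parameters of two commercial lipases (Lipase PS from *Burkholderia
   cepacia*, first-order; Palatase from *Rhizomucor miehei*, Weibull).

Everything is tibble-in/tibble-out and pipe-friendly; fitted results come
with `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

Simulate a four-temperature inactivation study of a first-order enzyme
(three replicates, 13 sampling times in 0–240 min, replicate SD 0.02) and
run the full pipeline:

```r
library(thermokin)

dat <- simulate_inactivation(paper_presets("lipase_ps", seed = 1))
report <- run_pipeline(dat, label = "Lipase PS (synthetic)")
report
#> Inactivation analysis: Lipase PS (synthetic)
#> Curves: 4 temperature(s); 40/50/60/70 degC
#> Accepted model: first_order
#>
#> Kinetic summary (first_order)
#> # A tibble: 4 × 5
#>   temperature_C    r2      k t_half     D
#>           <dbl> <dbl>  <dbl>  <dbl> <dbl>
#> 1            40 0.997 0.0135   51.4 171.
#> 2            50 0.997 0.0194   35.7 118.
#> 3            60 0.998 0.0288   24.0  79.8
#> 4            70 0.998 0.0449   15.4  51.3
#> z-value: 57.5 degC (log10 D vs T, r2 = 0.9981)
#>
#> Activation thermodynamics
#> Ea = 35.69 kJ mol^-1 (Arrhenius r2 = 0.9951)
#> # A tibble: 4 × 6
#>   temperature_C temperature_K    dH    dG    dS ratio
#>           <dbl>         <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1            40          313.  33.1  98.7 -209. -1.98
#> 2            50          323.  33.0 101.  -210. -2.06
#> 3            60          333.  32.9 103.  -211. -2.13
#> 4            70          343.  32.8 105.  -210. -2.20
```

The selection table (`report$verdicts`) records why each competing model was
rejected — negative parameter estimates, equal rate constants in the
distinct-isoenzymes model, a Weibull shape statistically indistinguishable
from 1 (i.e. first-order), failure to converge, or simply worse statistics.
The fitted rate constants recover the generating values
(k = 0.0136…0.0440 min⁻¹), the half-life falls from ~51 min at 40 °C to
~15 min at 70 °C, and the activation energy lands near the generating
34.8 kJ mol⁻¹. `glance(report)` condenses the same run to one row;
`tidy(report)` returns the per-parameter fit table;
`autoplot(report, data = dat)` overlays the accepted model on the
observations.

To analyze your own measurements, provide a delimited table with columns
`temperature_C, time_min, replicate, activity` and call
`run_pipeline("my_table.csv")`, or use the shell wrapper in
`inst/scripts/thermokin-cli.R` (`fit` and `simulate` subcommands).

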