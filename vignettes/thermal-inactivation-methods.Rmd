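---
title: "Methods: thermal inactivation kinetics and activation thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal inactivation kinetics and activation thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermokin)
```

## The problem

Heating an enzyme solution at a constant temperature degrades its catalytic
activity. The observable is the residual-activity fraction
$A/A_0(t)$ — activity after $t$ minutes of heating, relative to the
unheated control. A thermostability study measures such decay curves at a
few temperatures (here 40–70 °C is the motivating range, with sampling
times between 2 and 240 min and three replicates per point) and asks three
questions: which kinetic law governs the decay, how fast is inactivation at
each temperature, and what energy barrier controls it.

`thermokin` answers all three for isothermal data. This vignette documents
the model, the estimation and selection procedure, the derived quantities,
the synthetic-data generator used for validation, and the numerical and
design choices a user should know about.

## The model bank

Eight closed-form laws for $A/A_0(t)$ are implemented
(`model_catalog()`), reflecting the mechanisms commonly invoked for enzyme
inactivation:

| model | form | parameters |
|---|---|---|
| first-order | $e^{-kt}$ | $k$ |
| Weibull | $e^{-bt^n}$ | $b$, $n$ |
| distinct isoenzymes | $A_L e^{-k_L t} + A_S e^{-k_R t}$ | $A_L, A_S, k_L, k_R$ |
| two-fraction | $a e^{-k_L t} + (1-a) e^{-k_R t}$ | $a, k_L, k_R$ |
| multi-component | $\{e^{-k_1 t} + r e^{-k_2 t}\}/(1+r)$ | $r, k_1, k_2$ |
| series-type | two sequential first-order steps | $\alpha_1, k_1, k_2$ (+ optional $\alpha_2$) |
| nth-order | $\{1 + (n-1)kt\}^{1/(1-n)}$ | $n, k$ |
| fractional conversion | $A_r + (1-A_r)e^{-kt}$ | $A_r, k$ |

Conventions that matter:

* **Units.** All rate constants are min⁻¹ internally; the Weibull scale $b$
  is min⁻ⁿ. Conversion to s⁻¹ happens only inside the Eyring step, where
  absolute units are physically meaningful.
* **Normalization.** Activities are fractions with $A/A_0(0)=1$. The
  nth-order law therefore fixes $A_0 = 1$, and fractional conversion is
  $A_r + (1-A_r)e^{-kt}$.
* **Series-type.** The general series-type expression starts at
  $1 + \alpha_2$ at $t = 0$, which conflicts with fraction-normalized data
  unless $\alpha_2 = 0$ (a fully deactivated final state). The bank
  therefore fits the $\alpha_2 = 0$ restriction by default; passing an
  explicit `alpha_2` parameter evaluates the general form.
* **Distinct isoenzymes vs two-fraction.** The isoenzyme amplitudes
  $A_L, A_S$ are free (they need not sum to 1); the two-fraction $a$ is a
  single fraction. This is the only reading under which the two models are
  distinct.

Several models nest first-order exactly (Weibull with $n=1$; two-fraction
with $a=1$; fractional conversion with $A_r=0$; multi-component with
$r=0$), which the test suite exploits as algebraic invariants.

## Estimation

`fit_model()` minimizes the unweighted residual sum of squares over all
individual observations (replicates are not averaged by default — averaging
is available via `use_means` but discards within-time information). The
optimizer is Levenberg–Marquardt (`minpack.lm::nls.lm`), run unconstrained:
sign constraints are deliberately *not* imposed, because a negative
estimate is itself diagnostic — it is the physical ground for rejecting a
model, and clamping it away would hide that signal.

Starting values come from model-specific linearizations: $k$ from the
log-linear regression of $\ln(A/A_0)$ on $t$; the Weibull pair from the
double-log regression of $\ln(-\ln A/A_0)$ on $\ln t$, restricted to
activities in (0.02, 0.98) because the double log amplifies noise at both
ends of the curve; two-phase models from splitting the rate estimate into a
faster and a slower component. Each fit then runs 10 additional restarts
jittered around the deterministic starts (multiplicative log-normal jitter
for scale-like parameters, additive for fractions), and the restart with
the lowest SSres wins. The jitter uses an internal fixed seed and the
caller's RNG state is saved and restored, so fitting is reproducible and
never perturbs a user's random stream. Convergence tolerances are
`ftol = ptol = 1e-10` with up to 1000 iterations.

Parameter covariance is $\hat\sigma^2 (J^\top J)^{-1}$ from the
Gauss–Newton approximation at the optimum. A singular covariance — a
symptom of an unidentifiable, overparameterized fit — is treated the same
as optimizer failure: the fit is flagged not converged ("did not generate
parameter answers"), never an exception.

Fit quality is summarized by three statistics: $r^2 = 1 -
\mathrm{SSres}/\mathrm{SStot}$, the reduced chi-square $\chi^2 =
\mathrm{SSres}/(m-p)$, and $\mathrm{SEM} = \mathrm{SSres}/m$, where $m$
counts observations and $p$ parameters. By construction
$\chi^2 (m-p) = \mathrm{SEM}\, m$ exactly.

## Model selection

`select_model()` applies, in order:

1. **Convergence.** Any temperature failing to converge rejects the model.
2. **Physical admissibility.** Any negative estimate of a rate, fraction,
   or shape rejects the model.
3. **Degeneracy.** The distinct-isoenzymes model is rejected when
   $k_L \approx k_R$ (within 1 % relative) at every temperature — two
   indistinguishable rate constants mean there is no second isoenzyme. The
   Weibull model is set aside as "reduces to first-order" when
   $|n - 1| \le \mathrm{SE}(n)$ at every temperature.
4. **Statistics.** Survivors are ranked by mean $r^2$ (with $\chi^2$ and
   SEM as secondary keys). Survivors within 0.01 mean $r^2$ of the best
   are treated as statistically indistinguishable: among them the most
   parsimonious model (fewest parameters) is preferred, and models with
   equally many parameters are separated by the $r^2$ of the secondary
   temperature-dependence regression — Arrhenius for rate-type models,
   log-logistic $b(T)$ for Weibull — or by $\chi^2$ when only one
   temperature is available.

Exactly one surviving model is accepted. The parsimony step deserves a
note, because the design here was genuinely open. Raw $r^2$ can never
prefer a nested model to its superset: a four-parameter biexponential
always fits at least as well as a single exponential, even when the extra
parameters only absorb noise. Ranking on $r^2$ alone therefore
systematically selects overparameterized models on single-temperature
data, where no secondary temperature regression exists to arbitrate. The
indistinguishability band (0.01 on $r^2$) plus parsimony restores the
intended behavior — simulated first-order data select first-order
essentially always — while leaving genuinely better-fitting flexible
models (e.g. Weibull on shoulder-shaped curves, where the $r^2$ gap is
far larger than 0.01) unaffected. The 1 % equal-rate threshold and the
one-SE rule for $n \approx 1$ operationalize qualitative criteria that
are otherwise stated without tolerances.

## Derived kinetic quantities

For an accepted first-order model: half-life $t_{1/2} = \ln 2 / k$,
decimal reduction time $D = 2.303/k$, and the z-value from the OLS
regression of $\log_{10} D$ on temperature ($z = -1/\mathrm{slope}$, the
temperature rise that cuts $D$ tenfold).

For an accepted Weibull model: the reliable life
$t_R = (2.303/b)^{1/n}$ — the 90th percentile of the inactivation-time
distribution, the Weibull analogue of $D$ (residual activity at $t_R$ is
$e^{-2.303} \approx 10\%$, an exact identity the property tests check);
the z′-value from regressing $\log t_R$ on temperature; the time-scale
parameter $\alpha = b^{-1/n}$; and the log-logistic scale model
$b(T) = \ln(1 + \exp[k'(T - T_c)])$, where $T_c$ marks the onset of fast
inactivation and $k'$ its steepness.

Two numerical conventions are worth spelling out:

* **The z′ log base.** The standard z-value convention is base-10. For
  z′, however, part of the inactivation literature regresses $\ln t_R$
  instead, and the two differ by a factor $\ln 10 \approx 2.303$. Both are
  implemented (`log_base = "log10"` default, `"ln"` for compatibility with
  the natural-log convention); every report labels which base produced its
  z′.
* **The log-logistic objective.** Across a 30 °C span the Weibull scale
  $b$ typically grows by three orders of magnitude. Least squares on the
  raw $b$ scale is then dominated entirely by the highest-temperature
  point and yields unstable, weighting-artifact parameters; `thermokin`
  minimizes residuals of $\ln b$ against the log of the model instead
  (equivalently, in the usual regime $k'(T - T_c) \ll 0$, the log-linear
  regression of $\ln b$ on $T$), initialized from that exponential
  regime. `scale = "linear"` exposes the raw-scale objective for
  comparison.

## Activation thermodynamics

The Arrhenius activation energy is $E_a = -R \cdot \mathrm{slope}$ of
$\ln k$ vs $1/T$ (temperatures in kelvin only here). $E_a$ is invariant to
the rate unit; only the intercept shifts.

Transition-state (Eyring) quantities at each temperature:
$\Delta H^\ddagger = E_a - RT$;
$\Delta G^\ddagger = -RT \ln\!\big(k_s h / (k_B T)\big)$ with the rate
$k_s$ in s⁻¹;
$\Delta S^\ddagger = (\Delta H^\ddagger - \Delta G^\ddagger)/T$; and the
balance ratio $T\Delta S^\ddagger / \Delta H^\ddagger$. The identity
$\Delta G^\ddagger = \Delta H^\ddagger - T\Delta S^\ddagger$ holds by
construction.

For Weibull kinetics a true rate constant does not exist; following common
practice the apparent rate $\alpha^{-1}$ (in h⁻¹ for the Arrhenius
regression, which changes only the intercept) stands in, and all resulting
quantities are flagged **apparent** — they characterize the fitted time
scale, not an elementary reaction step.

Because part of the literature inserts the numeric value of a min⁻¹ rate
into the Eyring expression without converting to s⁻¹ (shifting every
$\Delta G^\ddagger$ by $-RT\ln 60 \approx -10.7$ kJ mol⁻¹ at these
temperatures), `eyring_units = "paper-compat"` reproduces that convention
on demand; the default is the proper s⁻¹ conversion, and reports record
which mode was used.

## The synthetic-data generator

`simulate_inactivation()` produces replicate decay curves from any bank
model: the closed-form truth at each (temperature, time) plus independent
additive Gaussian noise per replicate observation. Defaults describe a
realistic bench design: four temperatures (40/50/60/70 °C), $t = 0$ plus
12 log-spaced withdrawal times from 2 to 240 min (log spacing concentrates
points where curvature lives; $t=0$ makes normalization testable), three
replicates, noise SD 0.02 on the activity fraction — within the replicate
SD envelopes reported for the motivating data (< 0.038–0.058). Two presets
(`paper_presets()`) carry the published per-temperature parameters of a
first-order enzyme (Lipase PS, $k$ = 0.0136–0.0440 min⁻¹) and a Weibull
enzyme (Palatase, $b$ = 1.97×10⁻⁷–4.22×10⁻⁴ min⁻ⁿ, $n$ = 4.36–2.87).

Choices, and what they imply about test evidence:

* **Homoscedastic noise.** The motivating data report only a single SD
  envelope per enzyme, so a constant SD is the defensible default. Real
  assay noise is often larger near full activity (pipetting scales with
  signal); passing tests under homoscedastic noise do not certify behavior
  under strong heteroscedasticity.
* **No clipping by default.** Near-zero activities plus noise produce
  occasional small negative observations, as real assays do; the fitting
  layer must cope, and the default exercises that. `clip_to_zero` is
  available.
* **Determinism.** A fixed seed reproduces a dataset bit for bit, and
  generation restores the caller's RNG state.

The generator emulates the *statistical* structure of an inactivation
study, not the assay itself (no absorbance calibration, no substrate
depletion, no temperature ramp-up transients). Validation on synthetic
data demonstrates estimator correctness and selection behavior under the
stated noise model — it cannot rule out model misspecification in real
curves.

## Validation design and problem sizes

The test suite validates each layer against independent oracles: closed
forms at defining points (half-life, $t_R$, reduction cases to 1e−12),
hand-computed fit statistics, OLS slopes recomputed from the covariance
formula, and `stats::nls` standard errors on a seeded fixture. Simulation
checks use 200 seeded single-temperature runs per scenario (first-order:
median $\hat k$ error and selection rate; Weibull: median $\hat n$ and
$\hat t_R$ error) with the default 13 × 3 design — sizes chosen so the
whole suite runs in a few minutes on one CPU while estimating acceptance
rates to a few percent. End-to-end runs of both presets confirm the
pipeline reproduces the expected accepted model, $E_a$, z/z′, and the
thermodynamic blocks from the published parameter sets.

## Known limitations

* Only isothermal curves: no dynamic temperature profiles, no F-value
  process integration.
* Unweighted least squares; no bootstrap or Bayesian uncertainty — standard
  errors are asymptotic Gauss–Newton.
* The series-type and nth-order models are numerically fragile near their
  singular parameterizations ($k_1 = k_2$, $n = 1$); fits that land there
  are reported as non-converged rather than extrapolated.
* Acceptance of a model is relative to the bank: a decay mechanism outside
  the eight laws will be assigned to whichever member fits best.
* The z′ base and Eyring unit ambiguities are surfaced as options rather
  than resolved; reports always record the conventions used.
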