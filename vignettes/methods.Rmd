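---
title: "Methods: from dendrometer signals to a water-potential regulation surface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from dendrometer signals to a water-potential regulation surface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the scientific and numerical choices behind
`stemdelta`: what the model assumes, how the raw-series reduction is
defined at the edges, what the synthetic-data generator does and does not
emulate, and where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The observation unit

Stomata regulate stem water potential against two distinct droughts:
atmospheric (VPD) and edaphic (soil water potential, Ψ_soil). Diurnal ΔΨ
(= Ψ_soil − Ψ_stem) confounds this regulation with tissue capacitance, so
the pipeline reduces each tree-day to a single *steady-state daily
maximum*: the 2-h mean around the most negative daytime Ψ_stem, accepted
only when the window varies by less than 5% over at least one hour.
Definitions pinned down here because the field description leaves them
open:

* the 2-h averaging window is half-open, `[t − 1 h, t + 1 h)`, which
  yields 8 points at 15-min cadence and 4 at 30-min — the expected 4–8
  datapoints;
* "< 5% change" is `(max − min) / |mean|` within that window (the
  denominator is unstated in the field description; the window mean is
  the natural scale);
* ties at the daytime minimum (flat plateaus) make every tied point a
  candidate centre; the qualifying window with the most negative mean
  wins, earliest on equal means. This returns the plateau itself rather
  than a shoulder window that happens to pass the tolerance;
* "daytime" is sunrise–sunset from NOAA solar geometry at the site
  coordinates (default 43.051°S, 147.104°E, UTC+10 civil time, no DST
  arithmetic); all timestamps are site-local civil time.

Ψ_soil is tracked per tree by linear interpolation between *predawn
anchors*: the 2-h mean around the pre-sunrise maximum of Ψ_stem, on
nights whose VPD stays below 0.05 kPa from midnight to sunrise (so
nocturnal transpiration is negligible and the stem equilibrates with the
root zone). Interpolation is refused outside the anchor span, and anchor
gaps above 21 d are flagged — interpolation across such gaps is retained
(there is no better estimator available) but poorly constrained. The
daily covariates are the daytime *maximum* VPD (the window-mean VPD is
kept as an optional column) and the interpolated Ψ_soil at the
steady-state window midpoint. The diurnal exploratory slice defaults to
11:00–15:00 (the alternative 11:00–16:00 reading is configurable).

## The regulation model

$$\Delta\Psi = \theta(\Psi_{soil})\left(1 - e^{-\lambda(\Psi_{soil})\,VPD}\right) + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2)$$

with θ and λ constant (θ₀, λ₀) above a soil threshold Ψ_thr and changing
exponentially below it at rates α and β. The exponential form keeps both
quantities positive for any finite Ψ_soil; α = β = 0 collapses to the
no-threshold limiting case, so the changepoint is a testable hypothesis,
not an assumption. θ₀ and λ₀ carry correlated random effects on the log
scale with one level per plant–year combination — the log scale is chosen
because it preserves positivity and makes the effects multiplicative,
matching the form of the soil terms. A single population-level threshold
and a single residual σ are used (the source analysis reports one of
each; letting σ vary by plant–year is out of scope).

Parameters, units, defaults used by the generator:

| parameter | unit | meaning | generator default |
|---|---|---|---|
| θ₀ | MPa | ΔΨ asymptote, hydrated soil | 1.2 |
| λ₀ | kPa⁻¹ | curvature rate, hydrated soil | 1.5 |
| α | MPa⁻¹ | asymptote decay below threshold | 0.29 |
| β | MPa⁻¹ | curvature decay (negative ⇒ λ rises) | −0.22 |
| Ψ_thr | MPa | soil changepoint | −0.83 |
| σ | MPa | residual SD | 0.08 |
| sd(log θ₀), sd(log λ₀) | — | plant–year scales | 0.10, 0.15 |
| corr | — | random-effect correlation | 0.3 |

α, β and Ψ_thr are the published posterior means for the studied conifer;
θ₀, λ₀ and σ are generator choices (not published values) set so the
curve reaches 95% of its asymptote near 1.94 kPa and ΔΨ spans the
magnitudes visible in the study's figures. The random-effect scales
(10–15% coefficient of variation, mild positive correlation) represent
the modest between-plant-year variation the study reports; they are
stated once here and not tuned.

## Inference

No probabilistic-programming backend is available in this environment,
and the sampler is part of what the package re-implements, so fitting
uses a purpose-built Hamiltonian Monte Carlo engine: analytic gradients
of the log posterior (verified against central differences in the test
suite), dual-averaging step-size adaptation targeting 85% acceptance,
jittered static trajectories (24 ± 50% leapfrog steps), and a diagonal
mass matrix re-estimated twice during warmup. Defaults are four chains of
2000 iterations with the first half discarded as warmup.

Priors are weakly informative and documented rather than inherited:
log θ₀, log λ₀ ~ N(0, 1); α ~ half-N(0, 0.5); β ~ N(0, 0.5) (sign-free —
the data decide whether λ rises or falls); Ψ_thr ~ N(−1, 1) truncated at
0; σ and the random-effect scales ~ half-N(0, 0.5); correlation uniform
on (−1, 1). All are overridable in `fit_config()`. Sensitivity to them is
a user exercise, not an assumption.

**Parameterization.** The conventional advice for hierarchical models is
a non-centred parameterization. Here each plant–year level carries ~85
records, so the level effects are data-rich: the non-centred chains mix
poorly (the population means and the standardized offsets become strongly
coupled), while the centred form — sampling the level-specific log
parameters directly under a bivariate-normal hierarchy prior — reaches
R-hat < 1.01 at the same computational cost. Both are implemented
(`fit_config(parameterization =)`); centred is the default. Constrained
parameters are sampled through log/tanh transforms with their Jacobians;
the threshold uses Ψ_thr = −exp(t), keeping it negative without a hard
boundary.

Diagnostics are implemented from first principles and tested against
oracles: rank-normalized split R-hat (bulk and folded, the maximum is
reported; gate at 1.01); PSIS-LOO with the Zhang–Stephens
generalized-Pareto tail fit (checked against exact leave-one-out in a
conjugate normal model, and against known GPD shapes); Bayesian R² as the
draw-wise variance ratio; LOO R² from PSIS-weighted held-out predictive
means with a Bayesian-bootstrap interval over observations (the interval
construction is a documented choice — it reflects sampling uncertainty of
the variance ratio, which draw-wise quantiles of R² do not); and 95%
posterior-predictive coverage with seeded predictive noise.

## The synthetic world

The generator emulates: seasonal diurnal VPD with daily maxima clipped to
the observed 0.34–4.09 kPa envelope and daytime temperatures within
10–32 °C; per-plant soil drydowns decaying exponentially (rate
0.025 d⁻¹) toward a seasonal floor drawn from −3.6…−1.2 MPa, with
episodic partial recharge (daily rain probability 0.05); humid nights
(VPD < 0.05 kPa) with probability 0.5, always including the night of and
the night before a rain day (synoptic humidity around frontal rain —
this also guarantees that recharge jumps are bracketed by anchors);
asynchronous monitoring (default 3/2/1/1 seasons across four trees,
86 days each, ≈600 tree-days).

Raw-mode rendering is built to be *self-consistent with the extractor's
assumptions*, which is what makes the round trip a meaningful test
rather than a tautology: soil varies continuously (linear between
midnight knots), predawn Ψ_stem equals the knot exactly on every night
(equilibrium), the midday Ψ_stem plateau is a quartic bell whose ±1-h
variation (~1%) sits under the 5% steadiness tolerance, and microclimate
is emitted as temperature/RH pairs that invert through the Buck formula
to the intended VPD exactly. What it does **not** emulate: capacitance
lags and non-steady diurnal dynamics, branch growth trends or thermal
expansion of the dendrometer signal, sensor noise on widths, rhizosphere
conductance loss during drydown, and weather autocorrelation beyond the
seasonal cycle. A green round-trip test therefore establishes the
correctness of the reduction logic, not robustness to those artefacts.

## Numerical details worth knowing

* Buck (1981) over-water saturation pressure,
  `0.61121·exp((18.678 − T/234.5)·T/(257.14 + T))` kPa; supersaturated
  humidity readings are clamped to 100% (preserving humid-night
  detection) rather than dropped; VPD is exactly 0 at RH = 100.
* Calibration is one OLS line per plant over all paired points (the
  study's supplementary calibrations are linear; per-season refits are
  not attempted).
* Ψ_stem > 0 after calibration (sensor drift) is clipped to 0; values at
  the 0 boundary are flagged.
* g_c uses the analytic VPD→0 limit θλ, and the normalization constant
  (hydraulic conductance, held constant over the whole Ψ_soil range)
  cancels; a user-supplied conductance–Ψ_soil hook exists but none
  ships. The surface is reported at posterior-mean parameters by
  default; propagating full draws is available through
  `posterior_params()` on subsets of draws.
* The no-threshold limiting case in the sampler removes α, β, Ψ_thr from
  the parameter vector rather than pinning them, so model comparison by
  LOO is honest about dimensionality. When fitted to data that truly
  lack a changepoint, the threshold drifts to the dry edge of the
  observed soil range and α loses leverage — the identified quantity is
  the *effective* change over the observed range, which the tests check
  concentrates at zero.

## Known limitations

Static-trajectory HMC is less efficient than NUTS on strongly varying
curvature; the R-hat gate and divergence counts are the guard rails. The
changepoint makes the posterior density continuous but only piecewise
smooth in Ψ_thr; in practice divergences stay rare and concentrated in
warmup. Interpolated Ψ_soil overestimates the potential at the root
surface during strong drydown (rhizosphere conductance loss), so ΔΨ
magnitudes below about −1 MPa soil inherit that bias from the method
itself; the pipeline reproduces, rather than corrects, this property of
the measurement approach.
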