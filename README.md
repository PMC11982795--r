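# stemdelta

Tools for characterizing how a tree regulates its stem water potential
(Ψ_stem) against the combined pull of atmospheric drought (vapour pressure
deficit, VPD) and soil drought (soil water potential, Ψ_soil), from
continuous optical-dendrometer monitoring.

The package is aimed at plant ecophysiologists who monitor Ψ_stem at
15–30 min resolution and want a species-level, statistically comparable
description of stomatal regulation across seasons and individuals.

## The model

The unit of observation is one steady-state daily maximum of the
soil-to-stem water potential difference, ΔΨ = Ψ_soil − Ψ_stem ≥ 0, per
tree-day. ΔΨ responds to the day's maximum VPD as a saturating curve whose
shape shifts once the soil dries past a changepoint:

    ΔΨ   = θ(Ψ_soil) · (1 − exp(−λ(Ψ_soil) · VPD)) + ε,   ε ~ N(0, σ²)
    θ    = θ₀                                  Ψ_soil ≥ Ψ_thr
         = θ₀ · exp(−α (Ψ_thr − Ψ_soil))       Ψ_soil < Ψ_thr
    λ    = λ₀                                  Ψ_soil ≥ Ψ_thr
         = λ₀ · exp(−β (Ψ_thr − Ψ_soil))       Ψ_soil < Ψ_thr

θ (MPa) is the asymptote of ΔΨ, λ (kPa⁻¹) the rate of curvature, α and β
(MPa⁻¹) the rates at which they change below the soil threshold Ψ_thr
(MPa). θ₀ and λ₀ carry correlated log-normal random effects with one level
per plant–year. The posterior is sampled with a built-in Hamiltonian Monte
Carlo engine (analytic gradients, adaptive step size and diagonal mass
matrix), and checked with rank-normalized split R-hat, PSIS-LOO
cross-validation, Bayesian R², and posterior-predictive coverage.

Under Darcy's law with constant soil-to-leaf hydraulic conductance,
whole-plant diffusive conductance follows as g_c ∝ ΔΨ/VPD, reported as a
normalized percentage surface over (VPD, Ψ_soil).

## Worked example

Everything below is runnable offline: the synthetic-data generator creates
a study with known parameters (4 trees, 1–3 growing seasons each, ~600
tree-days), renders it down to raw 15-min width/microclimate signals, and
the pipeline re-estimates the truth.

```r
library(stemdelta)

study <- simulate_raw_series(simulation_config(seed = 1))
dir <- tempfile(); write_study(study, dir)

man <- run_pipeline(dir, file.path(dir, "out"),
                    pipeline_config(seed = 2))
fit <- read_records_csv(file.path(dir, "out", "records.csv")) |>
  fit_posterior(fit_config(seed = 2))
summary(fit)
```

With seeds 1/2 this run extracts 583 steady-state tree-days (8 excluded
for missing soil coverage, 11 for no steady state) and prints:

```
       parameter      mean        sd      q2.5    median     q97.5    rhat
1         theta0  1.138626 0.0762560  0.985990  1.137675  1.291339 1.00016
2        lambda0  1.364753 0.1030407  1.172219  1.360674  1.588642 1.00046
3          alpha  0.308575 0.0319335  0.246458  0.308838  0.371562 1.00053
4           beta -0.287921 0.1056438 -0.482762 -0.291708 -0.067636 1.00089
5  psi_threshold -0.834035 0.0490824 -0.931281 -0.834661 -0.745023 1.00027
6          sigma  0.082155 0.0024933  0.077490  0.082073  0.087207 1.00161
```

The generating values were θ₀ = 1.2 MPa, λ₀ = 1.5 kPa⁻¹, α = 0.29 MPa⁻¹,
β = −0.22 MPa⁻¹, Ψ_thr = −0.83 MPa, σ = 0.08 MPa: every 95% credible
interval above covers its truth, and all R-hat pass the 1.01 gate.
`diagnostics_report(fit)` adds LOO/R²/coverage;
`gc_surface(posterior_params(fit))` turns the fit into the conductance
surface.

The same stages are scriptable from the command line
(`inst/cli/stemdelta`): `simulate`, `ingest`, `extract`, `fit`,
`diagnose`, `predict-gc`, `run`.

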