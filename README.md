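# coralmpm

Matrix population modelling for coral size-frequency monitoring data that is
too sparse for classical demographic estimation: irregular survey years,
unequal transect effort, and no repeated measurements of individual
colonies. The package inversely estimates a stage-transition (Leslie) matrix
from annual size-frequency vectors, verifies it by hindcast, and projects
population and percent-cover trajectories a century ahead under density
dependence, stochastic imported recruitment, and random pulse disturbances.
It is aimed at reef ecologists and conservation planners who need trajectory
information from less-than-ideal monitoring series.

## The model

Colonies are grouped into five diameter classes (SC1: 0–5, SC2: 5–10,
SC3: 10–20, SC4: 20–40, SC5: >40 cm). Annual dynamics follow

```
n(t+1) = M n(t) + v(t) e1
```

where `n(t)` is the size-frequency vector, `v(t)` adds recruits to the
smallest class, and `M` is constrained by a life-cycle graph: stasis loops
on the diagonal, growth by one class on the subdiagonal, shrinkage of SC5
to SC4, and fertility from SC4/SC5 into SC1. `M` is estimated by Wood's
method — constrained least squares minimising `Σ_t ‖n(t+1) − M n(t)‖²`
subject to nonnegative entries and per-column survival sums ≤ 1 (a convex
quadratic program solved to its global optimum). Because only the direction
of `n` matters to the estimate, surveys of unequal effort are made
comparable as standardized proportional frequencies (percent contributions
× 100); missing years are filled by per-class linear regression.

For forecasting, `M = S + R` is split into survival and fecundity parts and
growth is capped by a Ricker factor `exp(−b_j n_j)` (default
`b = 0.001` on SC3–SC5), with zero-truncated Gaussian imported recruitment
(mean 25, variance 25 per year) feeding SC1 — an open-population model.
Abundance converts to percent cover by summing circle areas at per-class
representative diameters over a 300 m² reference area. Pulse disturbances
recur at uniform-random 10–20-year intervals and kill a uniform-random
0–100 % of all classes.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
synthetic study system (known ground-truth matrix, 80 % mass mortality in
2010, survey effort and detection mimicking the monitoring record). For
example:

```sh
Rscript analysis/01_simulate_data.R --seed 1   # ground truth + survey
Rscript analysis/02_preprocess.R    --seed 1   # standardize, impute
Rscript analysis/03_solve_matrix.R  --seed 1   # inverse solve
Rscript analysis/04_hindcast.R      --seed 1   # verification
Rscript analysis/05_forecast.R      --seed 1   # 100-year projection
Rscript analysis/06_disturbance.R   --seed 1   # 500-run ensemble
Rscript analysis/07_recruitment_sweep.R --seed 1
```

With seed 1 the run prints, among other things:

```
Identifiability: 15 equations, 12 unknowns -> identifiable
Hindcast fit: pooled R^2 = 0.9906 over 20 cells
Total cover: 2.90% (year 0) -> 8.38% (year 50) -> 8.23% (year 100)
Trajectory settles into a stable regime at about year 26
Dominant class at year 100: SC5
mean cover at horizon: 5.634% (q05 1.267, q95 7.964); persistent: TRUE
line: cover = 3.6486 + 0.1533 * recruits, R^2 = 0.9671
```

Read: four annual vectors overdetermine the 12 free matrix parameters; the
solved matrix hindcasts the held-out series almost perfectly; undisturbed,
cover roughly triples and stabilises within three decades with the largest
colonies dominating; under random pulse disturbances the population keeps a
positive mean cover (persists) at a reduced level; and long-run cover rises
linearly with the imported-recruitment level — the population's fate is
set by connectivity to outside larval sources.

The same stages are available programmatically (`solve_wood()`,
`project_density_dependent()`, `run_ensemble()`, ...) or as one call via
`run_pipeline()`, which writes every intermediate artifact plus a
checksummed manifest.

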