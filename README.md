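# cloneforecast

Spatial simulation of tumour clonal evolution, and the analysis
pipeline for asking **when, why and how clonal diversity forecasts
tumour growth rate and progression-free survival**.

Intratumour heterogeneity is a candidate prognostic biomarker, but the
evolutionary process linking measured diversity to later progression is
subtle: early in growth, high clonal diversity signals driver mutations
that have not yet swept; late in growth, selective sweeps in aggressive
tumours *purge* diversity; and across patients, variation in mutation
rate couples diversity to growth through a shared cause. This package
provides the machinery to generate and dissect those regimes in silico:

* **Simulator** — exact Gillespie dynamics on a 2-D lattice of demes
  (well-mixed subpopulations regulated around carrying capacity `K` by
  a crowding death rate). A newborn tumour cell acquires
  `Poisson(mu)` driver mutations, each multiplying its division rate
  `r` by `1 + X (1 - r/m)` with `X ~ Exp(mean s)` (diminishing
  returns), acquires neutral resistance mutations at `mu/10`, and
  disperses to a neighbouring deme with calibrated probability `d`.
  The core loop is C++ (Rcpp); R owns parameters, trajectories and
  analysis.
* **Sampling** — whole-tumour census, tumour-edge sampling (all demes
  visible from the lattice sides, `round(sqrt(K))` cells each), and
  disc-shaped virtual biopsies on perpendicular transects with
  multinomial subsampling.
* **Statistics** — inverse Simpson clonal diversity `1 / sum(f_i^2)`,
  clonal turnover `mean_t sum_i (f_i(t) - f_i(t - tau))^2` with `tau`
  = 10% of the simulation time, cell-weighted mean division rate, and
  future growth rate `(E - M) / (t_E - t_M)`.
* **Cohorts & forecasting** — reproducible virtual patient cohorts
  (fixed parameters, or per-tumour `mu = 10^-X`, `X ~ U(4,6)`) and
  Spearman/Kendall correlations between predictors measured at a given
  tumour size and subsequent growth rate.
* **Survival** — treatment at the endpoint size eliminates all
  non-resistant cells; progression-free survival is the time to regrow.
  Kaplan-Meier / log-rank on median-split groups and Cox proportional
  hazards with automated martingale-residual transform selection and
  `log10(t + 10)` time-interaction handling (via the `survival`
  package).

## Worked example

Grow one tumour to 30,000 cells, measure diversity three ways, then
treat it and measure time to regrowth:

```r
library(cloneforecast)

d <- calibrate_dispersal(K = 512, endpoint_size = 3e4, seed = 1)
p <- sim_params(K = 512, mu = 5e-5, s = 0.1, d = as.numeric(d),
                endpoint_size = 3e4)
sim <- simulate_tumour(p, record_sizes = c(7500, 15000), seed = 42)
while (sim$extinct) sim <- simulate_tumour(p, record_sizes = c(7500, 15000))
sim
#> tumour_sim: 30000 tumour cells at t = 116.60 generations
#>   50 genotype(s), 13 clone(s), 3654150 events
```

The founder often loses the early within-deme competition against
normal tissue, hence the establishment loop. Thirteen driver clones
coexist; diversity is the effective number of equally abundant clones,
and the invading edge is more diverse than the whole tumour:

```r
inverse_simpson(clone_counts(whole_tumour_sample(sim), sim$genotypes))
#> [1] 1.479407
inverse_simpson(clone_counts(edge_sample(sim), sim$genotypes))
#> [1] 2.33304
mean_division_rate(sim)   # founder divides at rate 1
#> [1] 1.242693
clonal_turnover(frequency_series(sim))
#> [1] 0.039298

set.seed(7)
out <- simulate_pfs(sim)  # treat at 30,000 cells, track regrowth
out[c("pfs_time", "event", "n_survivors")]
#> $pfs_time
#> [1] 1166.003   # no resistant cells: cured, censored at the horizon
#> $event
#> [1] FALSE
#> $n_survivors
#> [1] 0
```

Cohort-level forecasting (5-minute desk scale):

```r
spec <- cohort_spec(n_tumours = 30, K = 512, mu = "random", s = 0.1,
                    endpoint_size = 5e4, treatment = TRUE,
                    master_seed = 11)
res <- run_cohort(spec)
forecast_analysis(res)
```

which prints, per predictor and measurement size, the Spearman
correlation with subsequent growth rate — positive at every size in
diverse-`mu` cohorts (diversity proxies mutation rate), with mean
division rate always the stronger predictor.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/cloneforecast.R simulate --config cfg.yaml --seed 1 --outdir out
Rscript inst/cli/cloneforecast.R cohort   --config cfg.yaml --seed 1 --outdir out
```

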