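---
title: "Forecasting tumour growth and survival from clonal diversity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting tumour growth and survival from clonal diversity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cloneforecast)
```

## The model

`cloneforecast` simulates invasive solid tumour growth on a
two-dimensional square lattice of *demes* — localized, well-mixed
subpopulations of cells, of the size of the glands of acinar tumours
(kidney, lung, breast). Each deme holds normal and tumour cells and is
regulated around a carrying capacity $K$: every cell dies at rate zero
while the deme population is at or below $K$, and at a large rate (100
times the initial tumour division rate) as soon as the population
exceeds it. Growth is therefore invasion: tumour cells displace normal
tissue deme by deme rather than piling up locally.

Initially every deme holds exactly $K$ normal cells and the central
deme additionally holds a single tumour cell. Tumour cells divide at
their genotype's rate $r$ (founder $r = 1$, which defines the time
unit: one *generation* is the founder's expected division time);
normal cells divide at rate $0.9$ and never mutate or disperse. A
newborn tumour cell

* acquires $\mathrm{Poisson}(\mu)$ driver mutations, each multiplying
  its division rate by $1 + X\,(1 - r/m)$ with
  $X \sim \mathrm{Exponential}(\text{mean } s)$ — diminishing returns
  bounded by $m = 10$, approximately multiplicative while $r \ll m$;
* acquires $\mathrm{Poisson}(\mu/10)$ neutral *resistance* mutations,
  heritable flags that let a lineage survive treatment;
* with probability $d$ disperses into a uniformly chosen von Neumann
  neighbour deme.

Every driver mutation founds a new *clone* (infinite-alleles
assumption): a clone is the set of cells identical by descent with
respect to driver mutations. Resistance mutations do not define
clones.

Dynamics are simulated with Gillespie's exact stochastic simulation
algorithm. Events are drawn from (deme, genotype) classes with rate =
cell count × per-cell rate, which preserves the per-cell law exactly;
the test suite verifies distributional equivalence against a literal
one-record-per-cell implementation on toy lattices. Only demes that
have ever contained a tumour cell are simulated stochastically:
untouched all-normal demes sit at exactly $K$ cells and generate no
events, which cannot influence the tumour because normal cells never
disperse. A tumour-free deme whose normal population has returned to
$K$ is likewise frozen again.

### Parameters

| Parameter | Default / range | Meaning |
|---|---|---|
| `K` | 64, 512, 4096 | deme carrying capacity (cells) |
| `mu` | $10^{-6}$–$10^{-4}$ | driver mutation rate per division |
| `s` | 0.05–0.2 | mean driver fitness effect |
| `resistance_rate` | `mu`/10 | resistance mutation rate per division |
| `m` | 10 | upper bound on division rate |
| `r_init` | 1 | founder division rate (time unit) |
| `normal_rate` | 0.9 | normal-cell division rate |
| `death_multiplier` | 100 | per-cell death rate above capacity |
| `d` | calibrated | dispersal probability per division |
| `endpoint_size` | $10^6$ | size terminating growth / triggering treatment |

`d` is not free: [calibrate_dispersal()] adjusts it per $K$ so that
mutation-free tumours reach the endpoint in a prescribed median time —
1,000 generations for the standard endpoint of $10^6$ cells (the
middle of the typical 500–1,500 band, corresponding to several years
of human tumour growth). For smaller endpoints the target rescales as
$1000\sqrt{E/10^6}$, the two-dimensional radial growth law (time
$\propto$ radius $\propto \sqrt{\text{cell number}}$). Calibration
bisects on $\log d$ over five mutation-free pilot runs per candidate
until the median endpoint time is within 20% of the target.

### Numerical and degenerate-case choices

* $X$ is unbounded, so the fitness update can in principle cross $m$;
  rates are capped infinitesimally below $m$ (the event has
  probability $\sim e^{-100}$ at default parameters).
* The founder is seeded into a deme already holding $K$ normal cells,
  so the deme starts above capacity and crowding deaths begin
  immediately. Consequently most founders are lost in the early
  within-deme competition against normal cells (a Moran-type process
  with fitness 1 vs 0.9; establishment probability roughly 10% at
  default parameters). Extinct runs terminate within a few thousand
  events; cohort runners redraw the seed and record the number of
  redraws.
* A tumour cell placed in a boundary deme is a hard error by default
  (`boundary_policy = "error"`); the default lattice side
  $\max(16, \lceil 4\sqrt{E/K}\rceil + 8)$ leaves margin for the
  pioneer cells that run ahead of the compact front. The `"stay"`
  policy (off-lattice dispersal keeps the cell in place) exists for
  deliberately tiny validation lattices.
* `seed_normal_cells = FALSE` provides an empty-tissue configuration;
  with $K$ above the target size it realises a pure-birth (Yule)
  process whose mean time from 1 to $n$ cells is
  $\sum_{k=1}^{n-1} 1/k$, used as an analytic oracle in the tests.
* Clone frequencies are recorded at fixed time intervals and
  resampled by step interpolation onto 101 evenly spaced times
  spanning the full run for the turnover index; $\tau$ is 10 grid
  steps (10% of the total time). Frequency differences are taken over
  the union clone set, clones absent at a time contributing frequency
  zero.

## Measurement pipeline

**Diversity.** The inverse Simpson index $1/\sum_i f_i^2$ over clone
frequencies — the effective number of equally abundant clones.
Computed from whole-tumour censuses or samples.

**Sampling schemes** (all leave the state untouched):

* *whole*: exact global clone counts;
* *edge*: all demes "visible" from one of the four lattice sides
  (first occupied deme per row from the left and right, per column
  from the top and bottom), $\mathrm{round}(\sqrt K)$ cells per deme
  by multinomial subsampling, so deme size does not bias the sample;
* *biopsy*: disc-shaped regions centred a given fraction of the way
  from the tumour edge to the cell-weighted centre of mass, on
  perpendicular axis-aligned transects (up/right/down/left). The disc
  radius is $\max(0.5, \sqrt{C/(\pi K)})$ deme units, sized so the
  expected cell yield at density $K$ is the requested
  `cells_per_biopsy` $C \in [100, 4000]$ (the single-cell-assay
  range); per-deme draws are proportional to disc–deme area overlap
  (estimated on a deterministic 16×16 subgrid). Both the per-biopsy
  mean diversity (the default predictor) and the pooled-count
  diversity are reported.

**Turnover.** $\Theta(t) = \sum_i (f_i(t) - f_i(t-\tau))^2$ averaged
over grid times $t \ge \tau$; near 0 for static clonal compositions,
up to 2 for a complete replacement within one $\tau$.

**Future growth rate.** $(E - M)/(t_E - t_M)$ cells per generation,
between a measurement (size $M$, age $t_M$) and the endpoint.

**Forecast correlations.** Spearman's rank correlation (Kendall's
$\tau$-b as a cross-check; the two agree in sign throughout) between
each predictor at each measurement size and the outcome, with
two-sided p-values (exact permutation below $n = 10$), ties by
mid-ranks, and constant inputs flagged as undefined rather than
reported as zero. Measurement sizes default to fractions 1/8, 1/4,
1/2, 3/4 of the endpoint (the exact sizes used in the original
figures are not printed; these fractions span the early-to-late
range).

## Treatment and survival

Treatment is applied when the tumour reaches the endpoint size and
instantly removes every cell lacking a resistance mutation.
Progression-free survival (PFS) is the time to regrow to the
pre-treatment size; a cured tumour (no resistant cells) is censored
at the observation horizon, by default 10× the pre-treatment endpoint
time (the original analysis states only that cures outlast the
observation period; an explicit finite horizon keeps the data
well-defined).

Survival analysis follows the standard clinical workflow via the
`survival` package: Kaplan–Meier curves and log-rank tests on
median-split groups (ties to "low"; optionally two variables crossed
into four groups), and Cox proportional-hazards models in which each
continuous covariate is first transformed — identity,
$\log_{10}(x + \varepsilon)$ ($\varepsilon = 1$ for quantities
bounded below by 1 such as diversity, $10^{-7}$ for rates) or
mid-ranks — to linearize its relationship with null-model martingale
residuals. The transform minimizing the lack of fit of a straight
line relative to a lowess smoother is selected automatically and
reported, making the (originally manual) choice auditable.
Proportional hazards are checked per covariate through the
correlation of scaled Schoenfeld residuals with $\log_{10}(t + 10)$
($t$ in days; one generation maps to one day by default, and results
are insensitive to the +10 constant); covariates failing at
$\alpha = 0.05$ are refitted with a $\log_{10}(t+10)$ interaction
term.

## What the synthetic cohorts emulate — and what they do not

Virtual cohorts ([cohort_spec()], [run_cohort()]) simulate tumours
that share all parameters (isolating stochastic variability) or draw
per-tumour driver mutation rates as $\mu = 10^{-X}$,
$X \sim U(4, 6)$ (emulating variable genomic instability). Per-tumour
seeds derive deterministically from the master seed, so tables are
reproducible and independent of execution order.

The simulations capture spatially constrained clonal competition,
selective sweeps and clonal interference, sampling error of localized
biopsies, and the resistance-mediated link between pre-treatment
growth and post-treatment regrowth. They do not capture
three-dimensional geometry, deleterious passengers, frequency-
dependent interactions, microenvironmental heterogeneity, metastasis,
or sequencing noise; passing tests therefore support the internal
evolutionary logic of the forecasts, not clinical performance of any
particular assay.

## Problem sizes used in the shipped checks

The original study cohorts (100 tumours grown to $10^6$ cells) are
cluster-scale. The shipped test-suite and acceptance script use
desk-scale versions of the same study conditions, chosen once:
endpoints of $10^5$ cells for the cohort-level correlation and
survival checks (50, 40 and 9×12 tumours for the fixed, diverse-μ and
parameter-grid cohorts), $2\times10^4$ for the dispersal-calibration
band checks, and toy 3×3 lattices with $K = 8$ for the exact
per-cell-oracle comparisons. The calibration target rescales with the
radial growth law as described above. At these sizes all qualitative
patterns of the full-scale analysis are reproduced; the magnitudes of
late-stage negative correlations are attenuated relative to
million-cell tumours because selective sweeps have had less time to
complete, and the low-mutation-rate subset of the survival analysis
retains the expected hazard direction but not statistical
significance at 20 tumours per subset.

## Known limitations

* Establishment conditioning: cohorts condition on non-extinction by
  redrawing seeds, matching how the original cohorts are built, but
  meaning the effective per-seed distribution is conditional.
* The biopsy transect geometry (axis-aligned, four directions) is one
  reasonable reading of "perpendicular transects"; other rotations
  would sample different demes.
* The Cox transform search considers three transform families only;
  covariates that are constant or non-positive fall back to identity
  or ranks.
* Wide cohort CSV export flattens per-size measurements into suffixed
  columns; the long measurement table is the primary interchange
  format.
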