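#' Draw tumour-specific driver mutation rates
#'
#' For cohorts with diverse mutation rates each tumour's `mu` is
#' `10^-X` with `X ~ Uniform(4, 6)`, so `mu` spans `1e-6` to `1e-4`
#' with `log10(mu)` uniformly distributed.
#'
#' @param n Number of draws.
#' @return Numeric vector of mutation rates.
#' @export
sample_mutation_rate <- function(n = 1) {
  10^-stats::runif(n, 4, 6)
}

#' Specify a virtual tumour cohort
#'
#' Defines the parameter plan, measurement plan and seed for a cohort
#' of simulated tumours (see [run_cohort()]).
#'
#' @param n_tumours Number of tumours (>= 3 for any correlation).
#' @param K,s,endpoint_size Shared simulation parameters.
#' @param mu Driver mutation rate: a single value for a
#'   fixed-parameter cohort, or `"random"` to draw each tumour's rate
#'   with [sample_mutation_rate()].
#' @param d Dispersal probability; `NULL` calibrates per `K` with
#'   [calibrate_dispersal()].
#' @param measurement_sizes Tumour sizes at which predictors are
#'   measured; default `endpoint_size * c(1/8, 1/4, 1/2, 3/4)`.
#' @param schemes Sampling schemes evaluated at each measurement size:
#'   subset of `"whole"`, `"edge"`, `"biopsy"`.
#' @param biopsy Settings for the biopsy scheme: list with
#'   `depth_fraction`, `n_biopsies`, `cells_per_biopsy`.
#' @param treatment Simulate treatment at the endpoint and record
#'   progression-free survival (see [simulate_pfs()]).
#' @param horizon_multiplier Observation horizon for cures, as a
#'   multiple of the pre-treatment endpoint time.
#' @param n_time_records Grid points for the turnover index.
#' @param master_seed Master seed; per-tumour seeds are derived
#'   deterministically with [derive_seed()].
#' @param calibration Optional list passed to [calibrate_dispersal()]
#'   (`target_generations`, `replicates`, `tol`, `seed`).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_tumours = 100, K = 512, mu = 1e-5, s = 0.1,
                        endpoint_size = 1e6, d = NULL,
                        measurement_sizes = NULL,
                        schemes = c("whole", "edge"),
                        biopsy = list(depth_fraction = 0.4, n_biopsies = 4,
                                      cells_per_biopsy = 1000),
                        treatment = FALSE, horizon_multiplier = 10,
                        n_time_records = 101, master_seed = 1,
                        calibration = list()) {
  if (n_tumours < 3) stop("n_tumours must be at least 3")
  schemes <- match.arg(schemes, c("whole", "edge", "biopsy"),
                       several.ok = TRUE)
  if (is.null(measurement_sizes)) {
    measurement_sizes <- endpoint_size * c(1 / 8, 1 / 4, 1 / 2, 3 / 4)
  }
  if (any(measurement_sizes >= endpoint_size)) {
    stop("measurement sizes must be below endpoint_size")
  }
  random_mu <- identical(mu, "random")
  if (!random_mu && (!is.numeric(mu) || length(mu) != 1)) {
    stop("mu must be a single rate or \"random\"")
  }
  structure(list(n_tumours = n_tumours, K = K, mu = mu, s = s,
                 endpoint_size = endpoint_size, d = d,
                 measurement_sizes = sort(measurement_sizes),
                 schemes = schemes, biopsy = biopsy,
                 treatment = treatment,
                 horizon_multiplier = horizon_multiplier,
                 n_time_records = n_time_records,
                 master_seed = master_seed, random_mu = random_mu,
                 calibration = calibration),
            class = "cohort_spec")
}

#' Run a virtual tumour cohort
#'
#' Simulates every tumour of a [cohort_spec()] to the endpoint size,
#' measuring the configured predictors (clonal diversity per sampling
#' scheme and mean cell division rate) at each measurement size, the
#' clonal turnover index over the whole trajectory, the future growth
#' rate from each measurement to the endpoint and, optionally,
#' progression-free survival after treatment. Per-tumour seeds are
#' derived from the master seed, so the table does not depend on
#' execution order; the rare tumour that goes extinct before the
#' endpoint is redrawn with a fresh seed (logged in `attr(.,
#' "redraws")`).
#'
#' @param spec A `cohort_spec`.
#' @param progress Print one line per simulated tumour.
#' @return A `cohort_result`: list with `tumours` (one row per tumour),
#'   `measurements` (one row per tumour x measurement size, including
#'   the pre-treatment endpoint measurement) and the `spec`.
#' @export
run_cohort <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  d <- spec$d
  if (is.null(d)) {
    cal <- spec$calibration
    d <- calibrate_dispersal(
      K = spec$K, endpoint_size = spec$endpoint_size,
      target_generations = cal$target_generations,
      replicates = if (is.null(cal$replicates)) 5 else cal$replicates,
      tol = if (is.null(cal$tol)) 0.2 else cal$tol,
      seed = if (is.null(cal$seed)) spec$master_seed else cal$seed)
  }
  set.seed(spec$master_seed)
  mus <- if (spec$random_mu) sample_mutation_rate(spec$n_tumours) else {
    rep(spec$mu, spec$n_tumours)
  }
  tum_rows <- vector("list", spec$n_tumours)
  meas_rows <- vector("list", spec$n_tumours)
  failures <- character(0)
  redraws <- 0L
  for (i in seq_len(spec$n_tumours)) {
    row <- tryCatch(
      run_one_tumour(spec, i, mus[i], d),
      error = function(e) e)
    if (inherits(row, "error")) {
      failures <- c(failures,
                    sprintf("tumour %d: %s", i, conditionMessage(row)))
      if (length(failures) > 0.1 * spec$n_tumours) {
        stop("more than 10% of cohort simulations failed:\n",
             paste(failures, collapse = "\n"))
      }
      next
    }
    redraws <- redraws + row$redraws
    tum_rows[[i]] <- row$tumour
    meas_rows[[i]] <- row$measurements
    if (progress) {
      cat(sprintf("tumour %d/%d: t_end = %.1f, %d clones\n", i,
                  spec$n_tumours, row$tumour$endpoint_time,
                  row$tumour$n_clones))
    }
  }
  out <- structure(
    list(tumours = do.call(rbind, tum_rows),
         measurements = do.call(rbind, meas_rows), spec = spec, d = d),
    class = "cohort_result")
  attr(out, "failures") <- failures
  attr(out, "redraws") <- redraws
  out
}

run_one_tumour <- function(spec, i, mu, d) {
  redraws <- 0L
  sim <- NULL
  for (attempt in 0:199) {
    seed <- derive_seed(spec$master_seed, i + attempt * spec$n_tumours)
    p <- sim_params(K = spec$K, mu = mu, s = spec$s, d = as.numeric(d),
                    endpoint_size = spec$endpoint_size,
                    allow_nonstandard = TRUE)
    sim <- simulate_tumour(p, record_sizes = spec$measurement_sizes,
                           record_grids = TRUE,
                           n_time_records = spec$n_time_records,
                           seed = seed)
    if (!sim$extinct && sim$reached_target) break
    redraws <- redraws + 1L
  }
  if (sim$extinct || !sim$reached_target) {
    stop("tumour failed to reach the endpoint after 200 seed redraws")
  }
  turnover <- clonal_turnover(frequency_series(sim, spec$n_time_records))
  snaps <- sim$size_snapshots
  # pre-treatment (endpoint) measurement appended with the final state
  meas_sizes <- c(snaps$target, spec$endpoint_size)
  m <- vector("list", length(meas_sizes))
  for (k in seq_along(meas_sizes)) {
    at_end <- k > nrow(snaps)
    counts_df <- if (at_end) {
      data.frame(genotype_id = sim$genotypes$id, count = sim$genotypes$count)
    } else snaps$counts[[k]]
    grid <- if (at_end) sim$demes else snaps$grid[[k]]
    counts <- stats::setNames(counts_df$count, counts_df$genotype_id)
    counts <- counts[counts > 0]
    t_k <- if (at_end) sim$time else snaps$time[k]
    row <- data.frame(
      tumour_id = i, measurement_size = meas_sizes[k],
      measurement_time = t_k,
      diversity_whole = NA_real_, diversity_edge = NA_real_,
      diversity_biopsy = NA_real_, diversity_biopsy_pooled = NA_real_,
      mean_division_rate = mean_division_rate(counts, sim$genotypes),
      growth_rate = if (at_end) NA_real_ else {
        future_growth_rate(snaps$size[k], snaps$time[k],
                           sim$tumour_size, sim$time)
      })
    if ("whole" %in% spec$schemes) {
      row$diversity_whole <-
        inverse_simpson(clone_counts(counts, sim$genotypes))
    }
    if ("edge" %in% spec$schemes) {
      es <- edge_sample(grid, K = spec$K)
      row$diversity_edge <-
        inverse_simpson(clone_counts(es, sim$genotypes))
    }
    if ("biopsy" %in% spec$schemes) {
      bs <- tryCatch(
        biopsy_sample(grid, depth_fraction = spec$biopsy$depth_fraction,
                      n_biopsies = spec$biopsy$n_biopsies,
                      cells_per_biopsy = spec$biopsy$cells_per_biopsy,
                      K = spec$K),
        error = function(e) NULL)
      if (!is.null(bs)) {
        divs <- vapply(bs$biopsies, function(b) {
          inverse_simpson(clone_counts(b, sim$genotypes))
        }, numeric(1))
        row$diversity_biopsy <- mean(divs)
        row$diversity_biopsy_pooled <-
          inverse_simpson(clone_counts(bs$pooled, sim$genotypes))
      }
    }
    m[[k]] <- row
  }
  measurements <- do.call(rbind, m)
  tumour <- data.frame(
    tumour_id = i, K = spec$K, mu = mu, s = spec$s, d = as.numeric(d),
    seed = derive_seed(spec$master_seed, i + redraws * spec$n_tumours),
    endpoint_size = sim$tumour_size, endpoint_time = sim$time,
    n_clones = length(unique(sim$genotypes$clone_id[sim$genotypes$count > 0])),
    turnover = turnover, redraws = redraws,
    pfs_time = NA_real_, pfs_event = NA)
  if (spec$treatment) {
    pfs <- simulate_pfs(sim, horizon = spec$horizon_multiplier * sim$time)
    tumour$pfs_time <- pfs$pfs_time
    tumour$pfs_event <- pfs$event
  }
  list(tumour = tumour, measurements = measurements, redraws = redraws)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("cohort_result: %d tumours (K = %g, s = %g, mu = %s)\n",
              nrow(x$tumours), x$spec$K, x$spec$s,
              if (x$spec$random_mu) "random" else format(x$spec$mu)))
  cat(sprintf("  endpoint %g cells; d = %.4g; median endpoint time %.1f\n",
              x$spec$endpoint_size, x$d,
              stats::median(x$tumours$endpoint_time)))
  invisible(x)
}

#' Rank correlation between a predictor and an outcome
#'
#' Spearman's rho (default) or Kendall's tau-b with a two-sided
#' p-value; ties are handled by mid-ranks. For Spearman, the p-value
#' uses the exact permutation distribution below n = 10 and the
#' t-distribution approximation otherwise. A constant predictor or
#' outcome yields a flagged undefined result rather than a silent 0.
#'
#' @param x,y Paired numeric vectors (pairs with missing values are
#'   dropped).
#' @param method `"spearman"` or `"kendall"`.
#' @return A one-row `data.frame`: `method`, `estimate`, `p_value`,
#'   `n`, `defined`.
#' @export
rank_correlation <- function(x, y, method = c("spearman", "kendall")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(method = method, estimate = NA_real_,
                      p_value = NA_real_, n = n, defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(
    x, y, method = method,
    exact = if (method == "spearman") n < 10 else NULL))
  data.frame(method = method, estimate = unname(ct$estimate),
             p_value = ct$p.value, n = n, defined = TRUE)
}

#' Forecast correlations across measurement sizes
#'
#' For every combination of predictor, measurement size and correlation
#' method, computes the rank correlation between the predictor
#' (measured at that tumour size) and the outcome — by default the
#' future growth rate from that measurement to the endpoint.
#' Correlations significantly different from zero are flagged at
#' two-sided p < 0.05 (uncorrected).
#'
#' @param cohort A `cohort_result`, or its `measurements` table
#'   (optionally merged with per-tumour outcomes).
#' @param predictors Column names of predictor variables.
#' @param outcome Column name of the outcome variable.
#' @param methods Correlation methods to apply.
#' @return A `data.frame` with one row per (predictor, measurement
#'   size, method): `estimate`, `p_value`, `n`, `defined`,
#'   `significant`.
#' @export
forecast_analysis <- function(cohort,
                              predictors = c("diversity_whole",
                                             "diversity_edge",
                                             "mean_division_rate"),
                              outcome = "growth_rate",
                              methods = "spearman") {
  meas <- if (inherits(cohort, "cohort_result")) {
    merge(cohort$measurements,
          cohort$tumours[, c("tumour_id", "pfs_time", "pfs_event", "mu",
                             "turnover")],
          by = "tumour_id")
  } else cohort
  predictors <- intersect(predictors, names(meas))
  if (length(predictors) == 0) stop("no requested predictor column present")
  if (!outcome %in% names(meas)) stop("outcome column not present")
  out <- list()
  for (sz in sort(unique(meas$measurement_size))) {
    sub <- meas[meas$measurement_size == sz, ]
    if (all(is.na(sub[[outcome]]))) next
    for (pred in predictors) {
      for (mth in methods) {
        n_ok <- sum(is.finite(sub[[pred]]) & is.finite(sub[[outcome]]))
        rc <- if (n_ok < 3) {
          data.frame(method = mth, estimate = NA_real_,
                     p_value = NA_real_, n = n_ok, defined = FALSE)
        } else {
          rank_correlation(sub[[pred]], sub[[outcome]], method = mth)
        }
        rc$predictor <- pred
        rc$outcome <- outcome
        rc$measurement_size <- sz
        out[[length(out) + 1]] <- rc
      }
    }
  }
  res <- do.call(rbind, out)
  res$significant <- !is.na(res$p_value) & res$p_value < 0.05
  res[, c("predictor", "outcome", "measurement_size", "method",
          "estimate", "p_value", "n", "defined", "significant")]
}
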