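# Shared cohorts for the acceptance checks, built once per test run.
# Problem sizes are desk-scale versions of the study conditions: the
# endpoint is reduced to 1e5 cells (with the growth-time target rescaled
# by the radial growth law inside calibrate_dispersal) and cohort sizes
# trimmed so the whole suite runs on one CPU in minutes.
.acc_cache <- new.env(parent = emptyenv())

acc_get <- function(name, builder) {
  if (is.null(.acc_cache[[name]])) .acc_cache[[name]] <- builder()
  .acc_cache[[name]]
}

# fixed-parameter cohort (K = 512, mu = 1e-5), endpoint 1e5, n = 50
acc_fixed_cohort <- function(s = 0.2) {
  acc_get(paste0("fixed_s", s), function() {
    run_cohort(cohort_spec(
      n_tumours = 50, K = 512, mu = 1e-5, s = s, endpoint_size = 1e5,
      schemes = c("whole", "edge"), master_seed = 202,
      calibration = list(seed = 101)))
  })
}

# diverse-mutation-rate cohort with treatment, endpoint 1e5, n = 40
acc_randmu_cohort <- function() {
  acc_get("randmu", function() {
    run_cohort(cohort_spec(
      n_tumours = 40, K = 512, mu = "random", s = 0.1, endpoint_size = 1e5,
      schemes = c("whole", "edge", "biopsy"),
      biopsy = list(depth_fraction = 0.4, n_biopsies = 4,
                    cells_per_biopsy = 1000),
      treatment = TRUE, master_seed = 303,
      calibration = list(seed = 101)))
  })
}

# mini-cohorts spanning carrying capacity and selection strength at the
# central mutation rate: K in {64, 512, 4096} x s in {0.05, 0.1, 0.15,
# 0.2}, mu = 1e-5, endpoint 1e5, n = 20, diversity measured late
# (3/4 of the endpoint, where the sweep regime is most advanced at this
# scale). The (512, 0.2) cell reuses the fixed-parameter cohort.
acc_turnover_grid <- function() {
  acc_get("grid", function() {
    plan <- expand.grid(K = c(64, 512, 4096), s = c(0.05, 0.1, 0.15, 0.2))
    out <- lapply(seq_len(nrow(plan)), function(i) {
      res <- if (plan$K[i] == 512 && plan$s[i] == 0.2) {
        acc_fixed_cohort(0.2)
      } else {
        run_cohort(cohort_spec(
          n_tumours = 20, K = plan$K[i], mu = 1e-5, s = plan$s[i],
          endpoint_size = 1e5, measurement_sizes = 7.5e4,
          schemes = "whole", master_seed = 400 + i,
          calibration = list(seed = 101)))
      }
      fa <- forecast_analysis(res, predictors = "diversity_whole")
      data.frame(K = plan$K[i], s = plan$s[i],
                 rho = fa$estimate[fa$measurement_size == 7.5e4],
                 turnover = mean(res$tumours$turnover))
    })
    do.call(rbind, out)
  })
}
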