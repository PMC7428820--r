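make_grown_sim <- function(resistance_rate = 0, seed_start = 1,
                           endpoint = 2000) {
  p <- sim_params(K = 64, mu = 1e-4, s = 0.1, d = 0.2,
                  endpoint_size = endpoint,
                  resistance_rate = resistance_rate,
                  allow_nonstandard = TRUE)
  for (seed in seed_start:(seed_start + 60)) {
    sim <- simulate_tumour(p, seed = seed)
    if (!sim$extinct && sim$reached_target) return(sim)
  }
  stop("no established tumour found")
}

test_that("cures are censored at the horizon, resistant tumours progress", {
  sim <- make_grown_sim(resistance_rate = 0)
  out <- simulate_pfs(sim, horizon = 500)
  expect_false(out$event)
  expect_equal(out$pfs_time, 500)
  expect_equal(out$n_survivors, 0)
  # a fully resistant tumour progresses immediately: nothing is removed
  sim2 <- sim
  sim2$genotypes$resistant <- rep(TRUE, nrow(sim2$genotypes))
  set.seed(2)
  out2 <- simulate_pfs(sim2, horizon = 500)
  expect_true(out2$event)
  expect_lt(out2$pfs_time, 1)
  expect_gt(out2$pfs_time, 0)
})

test_that("partially resistant tumours regrow to the pretreatment size", {
  found <- FALSE
  for (seed in c(1, 40, 80, 120)) {
    sim <- make_grown_sim(resistance_rate = 5e-3, seed_start = seed)
    treated <- apply_treatment(sim)
    if (treated$tumour_size > 0 && treated$tumour_size < sim$tumour_size) {
      set.seed(3)
      out <- simulate_pfs(sim, horizon = 10 * sim$time)
      expect_true(out$event)
      expect_gt(out$pfs_time, 0)
      expect_gte(out$regrown$tumour_size, sim$tumour_size)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("log-rank matches the hand-computed hypergeometric statistic", {
  # textbook 6-subject fixture: group A dies at 1,2,3; group B at 4,5,6
  df <- data.frame(pfs_time = 1:6, pfs_event = TRUE,
                   grp = rep(c(0, 1), each = 3))
  res <- km_logrank(df, "grp")
  # independent 2x2-table computation of O - E and its variance
  o_minus_e <- 0; v <- 0
  at_risk_a <- 3; at_risk <- 6
  for (t in 1:3) {  # the three group-A deaths; B deaths contribute 0
    o_minus_e <- o_minus_e + 1 - at_risk_a / at_risk
    v <- v + at_risk_a * (at_risk - at_risk_a) * (at_risk - 1) /
      (at_risk^2 * (at_risk - 1))
    at_risk_a <- at_risk_a - 1; at_risk <- at_risk - 1
  }
  expect_equal(res$test$chisq, o_minus_e^2 / v, tolerance = 1e-6)
  expect_lt(res$p_value, 0.05)
  # KM curves start at 1 and are non-increasing
  expect_true(all(res$fit$surv <= 1))
  expect_true(all(diff(res$fit$surv[seq_len(3)]) <= 0))
})

test_that("log-rank is invariant to time rescaling and near 1 for identical groups", {
  df <- data.frame(pfs_time = c(1, 2, 3, 4, 1, 2, 3, 4),
                   pfs_event = TRUE, x = c(0, 0, 1, 1, 1, 1, 0, 0))
  r1 <- km_logrank(df, "x")
  df2 <- df; df2$pfs_time <- df$pfs_time * 37.5
  r2 <- km_logrank(df2, "x")
  expect_equal(r1$test$chisq, r2$test$chisq)
  expect_gt(r1$p_value, 0.5)
  # median split assigns ties to "low"
  expect_equal(unname(table(median_split(c(1, 1, 2, 3), "v"))[["low"]]), 2)
})

test_that("four-group split crosses two median-split variables", {
  set.seed(8)
  df <- data.frame(pfs_time = rexp(40) + 0.1, pfs_event = TRUE,
                   a = rnorm(40), b = rnorm(40))
  res <- km_logrank(df, "a", second_var = "b")
  expect_equal(nlevels(res$groups), 4)
  expect_equal(length(res$test$n), 4)
})

test_that("Cox p-values are calibrated under the null", {
  set.seed(21)
  n <- 60
  base <- data.frame(pfs_time = rexp(n), pfs_event = TRUE)
  pvals <- replicate(150, {
    base$x <- rnorm(n)
    cox_analysis(base, "x")$terms$p_value[1]
  })
  expect_gt(suppressWarnings(ks.test(pvals, punif))$p.value, 0.01)
  expect_lt(mean(pvals < 0.05), 0.12)
})

test_that("Cox hazard ratio sign matches the Kaplan-Meier ordering", {
  set.seed(5)
  n <- 80
  grp <- rep(c(0, 1), each = n / 2)
  df <- data.frame(pfs_time = rexp(n, rate = ifelse(grp == 1, 3, 1)),
                   pfs_event = TRUE, grp = grp)
  cx <- cox_analysis(df, "grp", continuous = FALSE)
  expect_true(cx$converged)
  expect_gt(cx$terms$hazard_ratio[1], 1)  # group 1 fails faster
  expect_lt(cx$terms$p_value[1], 0.01)
  km <- km_logrank(df, "grp")
  expect_lt(km$p_value, 0.01)
})

test_that("transform selection linearizes a log-scaled covariate", {
  set.seed(31)
  n <- 150
  x <- 10^runif(n, -6, -4)          # spans two decades
  rate <- exp(2 * (log10(x) + 5))   # hazard log-linear in log10(x)
  df <- data.frame(pfs_time = rexp(n, rate), pfs_event = TRUE, x = x)
  cx <- cox_analysis(df, "x")
  expect_true(cx$converged)
  expect_true(cx$terms$transform[1] %in% c("log10", "rank"))
  expect_lt(cx$terms$p_value[1], 1e-4)
})
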