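#' Simulate treatment and progression-free survival
#'
#' Treatment is applied at the endpoint size and instantly eliminates
#' every tumour cell that lacks a resistance mutation
#' ([apply_treatment()]). The surviving population is then simulated
#' until it regrows to the pre-treatment size; progression-free
#' survival (PFS) is the regrowth duration in generations. If no cell
#' is resistant the tumour is cured and PFS is censored at the
#' observation horizon; a tumour that fails to regrow within the
#' horizon is likewise censored.
#'
#' @param sim A `tumour_sim` at the endpoint size.
#' @param horizon Observation horizon in generations after treatment
#'   (default: 10 times the pre-treatment endpoint time).
#' @param target_size Size defining progression (default: the
#'   pre-treatment tumour size).
#' @return A list: `pfs_time` (generations), `event` (`TRUE` =
#'   progressed, `FALSE` = censored), `horizon`, `n_survivors`, and the
#'   regrown state (`NULL` for cures).
#' @export
simulate_pfs <- function(sim, horizon = NULL, target_size = NULL) {
  stopifnot(inherits(sim, "tumour_sim"))
  if (is.null(horizon)) horizon <- 10 * sim$time
  if (is.null(target_size)) target_size <- sim$tumour_size
  treated <- apply_treatment(sim)
  n_surv <- treated$tumour_size
  if (n_surv == 0) {
    return(list(pfs_time = horizon, event = FALSE, horizon = horizon,
                n_survivors = 0, regrown = NULL))
  }
  t0 <- treated$time
  if (n_surv >= target_size) {
    # nothing was removed: record progression at the first event
    regrown <- continue_tumour(treated, target_size = Inf, max_events = 1)
    return(list(pfs_time = regrown$time - t0, event = TRUE,
                horizon = horizon, n_survivors = n_surv, regrown = regrown))
  }
  regrown <- continue_tumour(treated, target_size = target_size,
                             max_time = t0 + horizon)
  if (regrown$reached_target) {
    list(pfs_time = regrown$time - t0, event = TRUE, horizon = horizon,
         n_survivors = n_surv, regrown = regrown)
  } else {
    list(pfs_time = horizon, event = FALSE, horizon = horizon,
         n_survivors = n_surv, regrown = regrown)
  }
}

#' Kaplan-Meier curves and log-rank test by median split
#'
#' Groups tumours into "high" and "low" by the median of a grouping
#' variable (ties assigned to "low"), optionally crossed with a second
#' median-split variable into four groups, then estimates Kaplan-Meier
#' survival curves per group and tests their difference with the
#' log-rank test.
#'
#' @param data A `data.frame` with survival columns and the grouping
#'   variable(s), e.g. the `tumours` table of a treatment cohort.
#' @param group_var Name of the grouping variable.
#' @param second_var Optional second variable for a four-group split.
#' @param time,event Column names of the survival time and event
#'   indicator.
#' @return A list: `fit` (a [survival::survfit] object), `test` (the
#'   [survival::survdiff] object), `p_value`, and the per-tumour
#'   `groups` factor.
#' @export
km_logrank <- function(data, group_var, second_var = NULL,
                       time = "pfs_time", event = "pfs_event") {
  stopifnot(all(c(time, event, group_var) %in% names(data)))
  grp <- median_split(data[[group_var]], group_var)
  if (!is.null(second_var)) {
    grp2 <- median_split(data[[second_var]], second_var)
    grp <- interaction(grp, grp2, sep = " / ")
  }
  grp <- droplevels(grp)
  if (nlevels(grp) < 2) stop("grouping produced fewer than 2 groups")
  tab <- table(grp)
  if (any(tab == 0)) {
    stop("empty group: ", paste(names(tab)[tab == 0], collapse = ", "))
  }
  df <- data.frame(.time = data[[time]], .event = as.integer(data[[event]]),
                   .group = grp)
  fit <- survival::survfit(survival::Surv(.time, .event) ~ .group, data = df)
  test <- survival::survdiff(survival::Surv(.time, .event) ~ .group,
                             data = df)
  p <- stats::pchisq(test$chisq, df = length(test$n) - 1, lower.tail = FALSE)
  list(fit = fit, test = test, p_value = p, groups = grp)
}

median_split <- function(x, name) {
  if (!is.numeric(x)) stop(name, " must be numeric for a median split")
  med <- stats::median(x)
  factor(ifelse(x > med, "high", "low"), levels = c("low", "high"))
}

#' Cox proportional hazards analysis with automated transform selection
#'
#' Fits a Cox model of survival on the given covariates following a
#' three-step procedure. (1) For each continuous covariate a transform
#' is chosen from identity, `log10(x + eps)` and mid-ranks, by
#' minimizing the lack of fit of a straight line relative to a lowess
#' smoother of the null-model martingale residuals against the
#' transformed covariate (`eps` is 1 for quantities bounded below by 1,
#' such as diversity, and 1e-7 otherwise). (2) The Cox model is fitted
#' on the transformed covariates. (3) Proportional hazards are tested
#' per covariate via the correlation of scaled Schoenfeld residuals
#' with `log10(t + 10)` (`t` in days; one generation = `days_per_gen`
#' days); covariates failing at `alpha = 0.05` are refitted with an
#' interaction term between the covariate and `log10(t + 10)`.
#'
#' @param data A `data.frame` with survival columns and covariates.
#' @param covariates Covariate column names.
#' @param continuous Logical vector (recycled): which covariates are
#'   continuous and eligible for transformation.
#' @param time,event Survival column names (time in generations).
#' @param days_per_gen Days per generation for the time-interaction
#'   scale (results are insensitive to the +10 constant).
#' @param zph_alpha Significance level of the proportional-hazards
#'   test.
#' @return A `cox_result`: `terms` table (term, transform, coef,
#'   hazard ratio, se, p), the fitted model, the PH test table,
#'   `converged` flag and notes.
#' @export
cox_analysis <- function(data, covariates, continuous = TRUE,
                         time = "pfs_time", event = "pfs_event",
                         days_per_gen = 1, zph_alpha = 0.05) {
  stopifnot(all(c(time, event) %in% names(data)),
            all(covariates %in% names(data)))
  if (sum(data[[event]]) < 10) {
    stop("need at least 10 progression events for a stable Cox fit")
  }
  continuous <- rep_len(continuous, length(covariates))
  df <- data.frame(.time = data[[time]] * days_per_gen,
                   .event = as.integer(data[[event]]))
  null_fit <- survival::coxph(survival::Surv(.time, .event) ~ 1, data = df)
  mres <- stats::residuals(null_fit, type = "martingale")
  transforms <- character(length(covariates))
  for (j in seq_along(covariates)) {
    x <- data[[covariates[j]]]
    if (!continuous[j]) {
      transforms[j] <- "identity"
      df[[covariates[j]]] <- x
      next
    }
    transforms[j] <- choose_transform(x, mres)
    df[[covariates[j]]] <- apply_transform(x, transforms[j])
  }
  fml <- stats::reformulate(covariates,
                            response = "survival::Surv(.time, .event)")
  notes <- character(0)
  fit <- tryCatch(
    survival::coxph(fml, data = df),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      suppressWarnings(survival::coxph(fml, data = df))
    },
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(terms = NULL, fit = NULL, zph = NULL,
                          converged = FALSE,
                          notes = conditionMessage(fit)),
                     class = "cox_result"))
  }
  zph <- tryCatch(
    survival::cox.zph(fit, transform = function(t) log10(t + 10)),
    error = function(e) NULL)
  tt_vars <- character(0)
  if (!is.null(zph)) {
    ztab <- zph$table
    rn <- rownames(ztab)
    tt_vars <- rn[rn %in% covariates & ztab[, "p"] < zph_alpha]
  }
  if (length(tt_vars) > 0) {
    fml2 <- stats::reformulate(
      c(covariates, paste0("tt(", tt_vars, ")")),
      response = "survival::Surv(.time, .event)")
    fit2 <- tryCatch(
      survival::coxph(fml2, data = df,
                      tt = function(x, t, ...) x * log10(t + 10)),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        suppressWarnings(survival::coxph(
          fml2, data = df, tt = function(x, t, ...) x * log10(t + 10)))
      },
      error = function(e) NULL)
    if (!is.null(fit2)) fit <- fit2
  }
  sm <- summary(fit)$coefficients
  terms <- data.frame(
    term = rownames(sm),
    transform = transforms[match(rownames(sm), covariates)],
    coef = sm[, "coef"], hazard_ratio = sm[, "exp(coef)"],
    se = sm[, "se(coef)"], p_value = sm[, "Pr(>|z|)"],
    row.names = NULL)
  terms$time_interaction <- grepl("^tt\\(", terms$term)
  structure(list(terms = terms, fit = fit, zph = zph,
                 converged = TRUE, notes = notes),
            class = "cox_result")
}

choose_transform <- function(x, mres) {
  cands <- c("identity", "rank")
  # the log candidate only applies to positive-valued covariates
  if (min(x, na.rm = TRUE) > 0 || min(x, na.rm = TRUE) >= 1 - 1e-7) {
    cands <- c("identity", "log10", "rank")
  }
  score <- vapply(cands, function(tr) {
    tx <- apply_transform(x, tr)
    if (!all(is.finite(tx)) || stats::sd(tx) == 0) return(Inf)
    sm <- stats::lowess(tx, mres)
    fit_sm <- stats::approx(sm$x, sm$y, xout = tx, rule = 2,
                            ties = mean)$y
    sse_sm <- sum((mres - fit_sm)^2)
    sse_lin <- sum(stats::residuals(stats::lm(mres ~ tx))^2)
    if (sse_sm <= 0) return(sse_lin)
    (sse_lin - sse_sm) / sse_sm
  }, numeric(1))
  cands[which.min(score)]
}

apply_transform <- function(x, transform) {
  switch(transform,
         identity = x,
         log10 = log10(x + if (min(x, na.rm = TRUE) >= 1) 1 else 1e-7),
         rank = rank(x),
         stop("unknown transform: ", transform))
}

#' @export
print.cox_result <- function(x, ...) {
  if (!x$converged) {
    cat("cox_result: fit did not converge\n  ", x$notes, "\n")
    return(invisible(x))
  }
  cat("Cox proportional hazards fit\n")
  print(x$terms, digits = 4)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
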