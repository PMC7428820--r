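#' Inverse Simpson clonal diversity index
#'
#' One divided by the sum of squared clone frequencies,
#' `1 / sum(f_i^2)`: the effective number of equally abundant clones.
#' A tumour of `n` equally abundant clones has diversity exactly `n`;
#' a monomorphic tumour has diversity 1.
#'
#' @param x A frequency vector (non-negative, summing to 1 within
#'   1e-9), a count vector (normalized after dropping zero counts), or
#'   a `clone_sample`.
#' @return The inverse Simpson index (>= 1).
#' @export
inverse_simpson <- function(x) {
  if (inherits(x, "clone_sample")) x <- x$counts
  x <- as.numeric(x)
  if (length(x) == 0) stop("empty input: no clones to measure")
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("clone frequencies/counts must be finite and non-negative")
  }
  total <- sum(x)
  if (total <= 0) stop("clone counts sum to zero")
  f <- x[x > 0] / total
  1 / sum(f^2)
}

#' Clonal turnover index
#'
#' Quantifies the average rate of change in clone frequencies:
#' `Theta(t) = sum_i (f_i(t) - f_i(t - tau))^2` evaluated at every grid
#' time `t >= tau`, with `tau` equal to 10% of the total simulation
#' time by default; the index is the mean of `Theta(t)` over those
#' times. Frequencies are compared over the union clone set (a clone
#' absent at one of the two times contributes its full squared
#' frequency at the other), so `0 <= Theta(t) <= 2`.
#'
#' @param series A [frequency_series()] object, or a numeric matrix of
#'   frequencies (rows = evenly spaced times, columns = clones).
#' @param tau_fraction `tau` as a fraction of the total time spanned.
#' @param tau_steps Directly specify `tau` in grid steps (overrides
#'   `tau_fraction`).
#' @return The clonal turnover index (mean Theta).
#' @export
clonal_turnover <- function(series, tau_fraction = 0.1, tau_steps = NULL) {
  freqs <- if (inherits(series, "frequency_series")) series$freqs else series
  freqs <- as.matrix(freqs)
  n <- nrow(freqs)
  if (n < 2) stop("need at least 2 time points to measure turnover")
  if (is.null(tau_steps)) {
    tau_steps <- max(1L, as.integer(round(tau_fraction * (n - 1))))
  }
  if (tau_steps < 1 || tau_steps >= n) {
    stop("tau (", tau_steps, " grid steps) not representable on a grid of ",
         n, " points")
  }
  idx <- (tau_steps + 1):n
  theta <- vapply(idx, function(i) {
    sum((freqs[i, ] - freqs[i - tau_steps, ])^2)
  }, numeric(1))
  mean(theta)
}

#' Cell-count-weighted mean division rate
#'
#' The mean division rate `r` over tumour cells of a census or sample,
#' weighting each genotype's rate by its cell count.
#'
#' @param x A `tumour_sim` (census over all tumour cells), a
#'   `clone_sample`, or a named count vector keyed by genotype id.
#' @param genotypes Genotype registry (`data.frame` with `id` and
#'   `division_rate`); taken from `x` when it is a `tumour_sim`.
#' @return Mean division rate per cell.
#' @export
mean_division_rate <- function(x, genotypes = NULL) {
  if (inherits(x, "tumour_sim")) {
    genotypes <- x$genotypes
    counts <- stats::setNames(genotypes$count, genotypes$id)
  } else if (inherits(x, "clone_sample")) {
    counts <- x$counts
  } else {
    counts <- x
  }
  if (is.null(genotypes)) stop("genotype registry required")
  counts <- counts[counts > 0]
  if (length(counts) == 0 || sum(counts) == 0) {
    stop("empty input: no tumour cells")
  }
  r <- genotypes$division_rate[match(as.integer(names(counts)),
                                     genotypes$id)]
  if (any(is.na(r))) stop("sampled genotype missing from the registry")
  sum(r * counts) / sum(counts)
}

#' Future tumour growth rate
#'
#' The average growth rate between a measurement and the endpoint:
#' `(endpoint_size - measurement_size) / (endpoint_time -
#' measurement_time)`, in cells per generation.
#'
#' @param measurement_size,measurement_time Tumour size (cells) and age
#'   (generations) when the predictor variable is measured.
#' @param endpoint_size,endpoint_time Tumour size and age at the
#'   endpoint.
#' @return Growth rate in cells per generation.
#' @export
future_growth_rate <- function(measurement_size, measurement_time,
                               endpoint_size, endpoint_time) {
  if (any(endpoint_time <= measurement_time)) {
    stop("endpoint_time must exceed measurement_time")
  }
  if (any(endpoint_size < measurement_size)) {
    stop("endpoint_size must be >= measurement_size")
  }
  (endpoint_size - measurement_size) / (endpoint_time - measurement_time)
}

#' Aggregate genotype counts into driver clones
#'
#' Clones are sets of cells identical by descent with respect to driver
#' mutations; resistance-only lineages belong to their parent driver
#' clone. This helper collapses genotype-level counts (as produced by
#' the sampling schemes) to clone-level counts for diversity
#' measurement.
#'
#' @param x A `clone_sample` or named count vector keyed by genotype id.
#' @param genotypes Genotype registry with `id` and `clone_id` columns.
#' @return Named count vector keyed by clone id.
#' @export
clone_counts <- function(x, genotypes) {
  counts <- if (inherits(x, "clone_sample")) x$counts else x
  cl <- genotypes$clone_id[match(as.integer(names(counts)), genotypes$id)]
  if (any(is.na(cl))) stop("sampled genotype missing from the registry")
  agg <- tapply(counts, cl, sum)
  stats::setNames(as.numeric(agg), names(agg))
}
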