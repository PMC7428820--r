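#' Per-cell crowding death rate of a deme
#'
#' The death rate is zero while the deme population is at or below the
#' carrying capacity and jumps to `death_multiplier` (by default 100
#' times the initial tumour division rate) once the population exceeds
#' it. The same rate applies to normal and tumour cells, so demes are
#' regulated to fluctuate around `K` cells.
#'
#' @param population Total deme population (normal + tumour cells).
#' @param K Deme carrying capacity.
#' @param death_multiplier Per-cell death rate above capacity.
#' @return Per-cell death rate (vectorized over `population`).
#' @export
deme_death_rate <- function(population, K, death_multiplier = 100) {
  if (any(population < 0)) stop("population must be non-negative")
  ifelse(population > K, death_multiplier, 0)
}

#' Division rate after acquiring a driver mutation
#'
#' A driver with effect `X` multiplies the division rate `r` by
#' `1 + X * (1 - r/m)`: gains diminish as `r` approaches the upper
#' bound `m`, and for `r` well below `m` successive drivers act
#' approximately multiplicatively.
#'
#' @param r Current division rate, `0 < r < m`.
#' @param X Fitness effect draw (non-negative; see
#'   [draw_driver_effect()]).
#' @param m Upper bound on the division rate.
#' @return The new division rate.
#' @export
fitness_after_driver <- function(r, X, m = 10) {
  if (any(r <= 0) || any(r >= m)) stop("r must satisfy 0 < r < m")
  if (any(X < 0)) stop("X must be non-negative")
  r * (1 + X * (1 - r / m))
}

#' Draw driver fitness effects
#'
#' Fitness effects of driver mutations are exponentially distributed
#' with mean `s`.
#'
#' @param n Number of draws.
#' @param s Mean fitness effect (`s > 0`).
#' @return Numeric vector of `n` non-negative draws.
#' @export
draw_driver_effect <- function(n = 1, s = 0.1) {
  if (s <= 0) stop("s must be positive")
  stats::rexp(n, rate = 1 / s)
}
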