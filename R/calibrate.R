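.calibration_cache <- new.env(parent = emptyenv())

#' Calibrate the dispersal probability for a carrying capacity
#'
#' The dispersal probability `d` is adjusted per carrying capacity `K`
#' so that, in the absence of mutation, tumours take a prescribed
#' median number of generations to grow from one cell to the endpoint
#' size. For the standard endpoint of one million cells the target is
#' 1,000 generations (the middle of the typical 500--1,500 range); for
#' smaller endpoints the target is rescaled as
#' `1000 * sqrt(endpoint_size / 1e6)`, following the two-dimensional
#' radial growth law (time proportional to radius, radius proportional
#' to the square root of cell number).
#'
#' Calibration runs `replicates` mutation-free pilot simulations per
#' candidate `d` and bisects on `log10(d)` until the median endpoint
#' time is within `tol` (default 20%) of the target. Results are cached
#' per `(K, endpoint_size, target, seed)`.
#'
#' @param K Deme carrying capacity.
#' @param endpoint_size Endpoint tumour size used for the pilots.
#' @param target_generations Target median time to endpoint; `NULL`
#'   applies the rescaling rule above.
#' @param replicates Number of pilot simulations per candidate `d`.
#' @param tol Relative tolerance on the median endpoint time.
#' @param seed Seed for the pilot schedule (deterministic pipeline).
#' @param cache Reuse / store the result in the in-session cache.
#' @return The calibrated dispersal probability `d`, with attributes
#'   `median_time` and `target`.
#' @export
calibrate_dispersal <- function(K, endpoint_size = 1e6,
                                target_generations = NULL, replicates = 5,
                                tol = 0.2, seed = 1, cache = TRUE) {
  if (is.null(target_generations)) {
    target_generations <- 1000 * sqrt(endpoint_size / 1e6)
  }
  if (target_generations <= 0) stop("target_generations must be positive")
  key <- paste("K", K, "E", endpoint_size, "T", signif(target_generations, 6),
               "R", replicates, "S", seed, sep = "_")
  if (cache && !is.null(.calibration_cache[[key]])) {
    return(.calibration_cache[[key]])
  }
  median_time <- function(d) {
    # high trial values of d sprawl far beyond the compact footprint the
    # default lattice is sized for, so pilots enlarge it on exhaustion
    side <- sim_params(K = K, mu = 0, d = d, endpoint_size = endpoint_size,
                       allow_nonstandard = TRUE)$lattice_side
    times <- vapply(seq_len(replicates), function(j) {
      # founders often die out in the early within-deme competition;
      # extinct pilots are redrawn with fresh seeds (they cost almost
      # nothing, ending after a handful of events)
      for (attempt in 0:199) {
        p <- sim_params(K = K, mu = 0, s = 0.1, d = d,
                        endpoint_size = endpoint_size, lattice_side = side,
                        allow_nonstandard = TRUE)
        sim <- tryCatch(
          simulate_tumour(p, record_grids = FALSE, n_time_records = 0,
                          max_time = 20 * target_generations,
                          seed = derive_seed(seed, j + 1000 * attempt)),
          error = function(e) {
            if (grepl("lattice exhausted", conditionMessage(e))) NULL
            else stop(e)
          })
        if (is.null(sim)) {
          side <<- side * 2L
          next
        }
        if (!sim$extinct) {
          return(if (sim$timed_out) Inf else sim$time)
        }
      }
      NA_real_
    }, numeric(1))
    stats::median(times, na.rm = FALSE)
  }
  within_tol <- function(t) {
    !is.na(t) && abs(t - target_generations) <= tol * target_generations
  }
  done <- function(d, t) {
    d_out <- structure(d, median_time = t, target = target_generations)
    if (cache) .calibration_cache[[key]] <- d_out
    d_out
  }
  # initial guess from the radial growth picture: the colonization wave
  # must cover radius = sqrt(E / (pi K)) demes in `target` generations,
  # and the wave speed grows roughly like sqrt(d)
  v <- sqrt(endpoint_size / (pi * K)) / target_generations
  d0 <- min(1, max(1e-6, 30 * v^2))
  t0 <- median_time(d0)
  if (within_tol(t0)) return(done(d0, t0))
  if (is.na(t0) || t0 > target_generations) {
    # too slow: bracket upward
    d_lo <- d0; t_lo <- t0
    d_hi <- d0
    repeat {
      if (d_hi >= 1) {
        stop("calibration error: even d = 1 gives median time ",
             signif(t_lo, 4), " > target ", signif(target_generations, 4),
             " generations (K = ", K, ", endpoint = ", endpoint_size, ")")
      }
      d_hi <- min(1, d_hi * 4)
      t_hi <- median_time(d_hi)
      if (within_tol(t_hi)) return(done(d_hi, t_hi))
      if (!is.na(t_hi) && t_hi < target_generations) break
      d_lo <- d_hi; t_lo <- t_hi
    }
  } else {
    # too fast: bracket downward
    d_hi <- d0
    d_lo <- d0
    repeat {
      d_lo <- d_lo / 4
      if (d_lo < 1e-8) {
        stop("calibration error: no d in (0, 1] slows growth to the ",
             "target of ", signif(target_generations, 4), " generations ",
             "(K = ", K, ", endpoint = ", endpoint_size, ")")
      }
      t_lo <- median_time(d_lo)
      if (within_tol(t_lo)) return(done(d_lo, t_lo))
      if (is.na(t_lo) || t_lo > target_generations) break
      d_hi <- d_lo
    }
  }
  lo <- log10(d_lo); hi <- log10(d_hi)
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    t_mid <- median_time(10^mid)
    if (within_tol(t_mid)) return(done(10^mid, t_mid))
    if (is.na(t_mid) || t_mid > target_generations) lo <- mid else hi <- mid
  }
  stop("calibration error: bisection on d did not converge for K = ", K,
       ", endpoint = ", endpoint_size, " (target ",
       signif(target_generations, 4), " generations)")
}

#' Deterministic per-replicate seed derivation
#'
#' Derives a stream of reproducible 31-bit seeds from a master seed, so
#' cohort members are independent of execution order.
#'
#' @param master_seed Integer master seed.
#' @param index Positive replicate index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, index) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime; all arithmetic exact in doubles
  x <- (as.numeric(master_seed) %% m)
  for (k in seq_len(2)) {
    x <- (x * 48271 + as.numeric(index) * 16807 + 12345) %% m
  }
  as.integer(x %% (m - 2) + 1)
}
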