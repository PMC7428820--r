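#' Simulation parameters for the deme-lattice tumour model
#'
#' Constructs and validates the parameter set of the spatial tumour
#' simulator. Time is measured in cell generations: the founding tumour
#' cell divides at rate `r_init = 1`, so one generation is its expected
#' division time. Within each deme (lattice site) the population is
#' regulated around the carrying capacity `K` by a crowding death rate
#' that switches from zero to `death_multiplier` per cell as soon as the
#' deme population exceeds `K`.
#'
#' Driver mutations arise in newborn tumour cells at rate `mu` per
#' division and multiply the division rate `r` by `1 + X * (1 - r/m)`
#' with `X ~ Exponential(mean = s)`, so fitness gains diminish as `r`
#' approaches the bound `m`. Resistance mutations (rate
#' `resistance_rate`, by default `mu/10`) are neutral heritable flags
#' that let a lineage survive treatment; they do not define clones.
#'
#' @param K Deme carrying capacity in cells. Standard values are 64, 512
#'   and 4096; other values require `allow_nonstandard = TRUE`.
#' @param mu Driver mutation rate per cell division (standard range
#'   `1e-6`--`1e-4`; `0` gives a neutral, single-clone simulation).
#' @param s Mean driver fitness effect (standard range 0.05--0.2).
#' @param resistance_rate Resistance mutation rate per division;
#'   defaults to `mu / 10`.
#' @param m Upper bound on the cell division rate.
#' @param r_init Initial tumour cell division rate; defines the time
#'   unit and must satisfy `0 < r_init < m`.
#' @param normal_rate Division rate of normal cells (default
#'   `0.9 * r_init`).
#' @param death_multiplier Per-cell death rate applied when a deme
#'   exceeds its carrying capacity (default `100 * r_init`).
#' @param d Dispersal probability per tumour cell division: the newborn
#'   cell moves to a uniformly chosen von Neumann neighbour deme with
#'   this probability. Usually set by [calibrate_dispersal()].
#' @param endpoint_size Tumour cell count at which growth simulations
#'   terminate (and treatment, if any, is applied).
#' @param lattice_side Side length of the square deme lattice; defaults
#'   to `max(16, ceiling(3 * sqrt(endpoint_size / K)))` so a growing
#'   tumour cannot plausibly reach the boundary.
#' @param boundary_policy `"error"` (default) aborts if a tumour cell is
#'   ever placed in a boundary deme; `"stay"` keeps off-lattice
#'   dispersers in their source deme and permits boundary occupancy
#'   (used for small-lattice validation runs).
#' @param seed_normal_cells If `TRUE` (default) every deme initially
#'   holds `K` normal cells. `FALSE` gives an empty-tissue degenerate
#'   configuration in which, with `K >= endpoint_size`, tumour growth is
#'   a pure birth (Yule) process; used for analytic validation.
#' @param seed Optional RNG seed stored with the parameters.
#' @param allow_nonstandard Permit `K` outside the standard set and
#'   `mu`, `s` outside their standard ranges.
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [simulate_tumour()], [calibrate_dispersal()]
#' @export
sim_params <- function(K = 512, mu = 1e-5, s = 0.1,
                       resistance_rate = mu / 10, m = 10, r_init = 1,
                       normal_rate = 0.9 * r_init,
                       death_multiplier = 100 * r_init, d = NULL,
                       endpoint_size = 1e6, lattice_side = NULL,
                       boundary_policy = c("error", "stay"),
                       seed_normal_cells = TRUE, seed = NULL,
                       allow_nonstandard = FALSE) {
  boundary_policy <- match.arg(boundary_policy)
  stopifnot(length(K) == 1, length(mu) == 1, length(s) == 1)
  if (!allow_nonstandard && !K %in% c(64, 512, 4096)) {
    stop("K = ", K, " is not a standard carrying capacity ",
         "(64, 512, 4096); set allow_nonstandard = TRUE to override")
  }
  if (mu < 0 || mu >= 1) stop("mu must lie in [0, 1)")
  if (!allow_nonstandard && mu > 0 && (mu < 1e-6 || mu > 1e-4)) {
    stop("mu = ", mu, " outside the standard range 1e-6..1e-4; ",
         "set allow_nonstandard = TRUE to override")
  }
  if (s <= 0) stop("s must be positive")
  if (!allow_nonstandard && (s < 0.05 || s > 0.2)) {
    stop("s = ", s, " outside the standard range 0.05..0.2; ",
         "set allow_nonstandard = TRUE to override")
  }
  if (!is.null(d) && (d < 0 || d > 1)) stop("d must lie in [0, 1]")
  if (r_init <= 0 || r_init >= m) stop("r_init must satisfy 0 < r_init < m")
  if (resistance_rate < 0) stop("resistance_rate must be non-negative")
  if (endpoint_size < 1) stop("endpoint_size must be >= 1")
  if (is.null(lattice_side)) {
    # margin sized for the occupied footprint (demes holding >= 1 cell),
    # which outruns the filled-deme radius via pioneer dispersers
    lattice_side <- max(16L,
                        as.integer(ceiling(4 * sqrt(endpoint_size / K))) + 8L)
  }
  lattice_side <- as.integer(lattice_side)
  if (lattice_side < 3) stop("lattice_side must be at least 3")
  p <- list(K = K, mu = mu, s = s, resistance_rate = resistance_rate,
            m = m, r_init = r_init, normal_rate = normal_rate,
            death_multiplier = death_multiplier, d = d,
            endpoint_size = endpoint_size, lattice_side = lattice_side,
            boundary_policy = boundary_policy,
            seed_normal_cells = seed_normal_cells, seed = seed)
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Deme-lattice tumour simulation parameters\n")
  cat(sprintf("  K = %g, mu = %g, s = %g, resistance rate = %g\n",
              x$K, x$mu, x$s, x$resistance_rate))
  cat(sprintf("  r_init = %g, m = %g, normal rate = %g, death multiplier = %g\n",
              x$r_init, x$m, x$normal_rate, x$death_multiplier))
  cat(sprintf("  dispersal d = %s, endpoint = %g cells, lattice %d x %d\n",
              ifelse(is.null(x$d), "<uncalibrated>", format(x$d)),
              x$endpoint_size, x$lattice_side, x$lattice_side))
  invisible(x)
}

# internal: flat list handed to the C++ engine
engine_params <- function(params) {
  if (is.null(params$d)) {
    stop("dispersal probability d is not set; call calibrate_dispersal() ",
         "or supply d explicitly")
  }
  list(K = params$K, mu = params$mu, s = params$s,
       resistance_rate = params$resistance_rate, m = params$m,
       r_init = params$r_init, normal_rate = params$normal_rate,
       death_multiplier = params$death_multiplier, d = params$d,
       lattice_side = params$lattice_side,
       boundary_error = identical(params$boundary_policy, "error"),
       seed_normal_cells = isTRUE(params$seed_normal_cells))
}
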