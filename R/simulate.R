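#' Simulate tumour growth to a target size
#'
#' Runs the exact stochastic (Gillespie) simulation from a single
#' founding tumour cell in the central deme until the tumour reaches
#' `target_size` cells, recording size snapshots (with spatial clone
#' grids) at the first crossing of each requested measurement size and
#' global clone counts at fixed time intervals for turnover analysis.
#'
#' @param params A [sim_params()] object with dispersal `d` set.
#' @param target_size Tumour size terminating the run (defaults to
#'   `params$endpoint_size`).
#' @param record_sizes Tumour sizes at which to store measurement
#'   snapshots (times, global clone counts and, if `record_grids`,
#'   per-deme clone counts).
#' @param record_grids Store spatial clone grids with size snapshots.
#' @param n_time_records Approximate number of evenly spaced clone
#'   frequency records kept for the turnover index; `0` disables time
#'   recording.
#' @param max_time Stop (flagged `timed_out`) if simulation time
#'   exceeds this value.
#' @param max_events Stop after this many events (`0` = unlimited).
#' @param seed Optional seed (`set.seed`) applied before the run;
#'   defaults to `params$seed`.
#' @return A `tumour_sim` object: final state (genotype registry,
#'   per-deme clone counts, normal cell counts), trajectory snapshots
#'   and run flags.
#' @export
simulate_tumour <- function(params, target_size = params$endpoint_size,
                            record_sizes = numeric(0), record_grids = TRUE,
                            n_time_records = 101, max_time = Inf,
                            max_events = 0, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  record_dt <- time_record_interval(target_size, n_time_records)
  res <- cpp_run(NULL, engine_params(params), target_size, max_time,
                 as.numeric(record_sizes), record_dt, max_events,
                 record_grids)
  build_sim(res, params, target_size)
}

#' Continue a simulation from a stored state
#'
#' Resumes the Gillespie dynamics from the final state of an existing
#' `tumour_sim` object (for example after [apply_treatment()]) until a
#' new target size, time limit or event cap is reached. The RNG
#' continues from R's current state unless `seed` is given.
#'
#' @param sim A `tumour_sim` object.
#' @inheritParams simulate_tumour
#' @return A new `tumour_sim` object starting from the given state.
#' @export
continue_tumour <- function(sim, target_size, record_sizes = numeric(0),
                            record_grids = FALSE, n_time_records = 0,
                            max_time = Inf, max_events = 0, seed = NULL) {
  stopifnot(inherits(sim, "tumour_sim"))
  if (!is.null(seed)) set.seed(seed)
  state <- list(genotypes = sim$genotypes, demes = sim$demes,
                normals = sim$normals, time = sim$time,
                event_count = sim$event_count)
  record_dt <- if (n_time_records > 0) {
    time_record_interval(target_size, n_time_records)
  } else 0
  res <- cpp_run(state, engine_params(sim$params), target_size, max_time,
                 as.numeric(record_sizes), record_dt, max_events,
                 record_grids)
  build_sim(res, sim$params, target_size)
}

#' Advance a simulation by a fixed number of events
#'
#' Executes exactly `n_events` elementary events (cell division or
#' crowding death), mainly for inspecting the event-level dynamics.
#'
#' @param sim A `tumour_sim` object.
#' @param n_events Number of events to execute.
#' @return A new `tumour_sim` object.
#' @export
advance_events <- function(sim, n_events = 1) {
  continue_tumour(sim, target_size = Inf, max_events = n_events)
}

#' Initialize a simulation state without running any events
#'
#' @param params A [sim_params()] object.
#' @param seed Optional seed applied before initialization.
#' @return A `tumour_sim` object at time 0 with a single founder cell.
#' @export
init_simulation <- function(params, seed = params$seed) {
  simulate_tumour(params, target_size = 1, n_time_records = 0, seed = seed)
}

time_record_interval <- function(target_size, n_time_records) {
  if (n_time_records <= 0) return(0)
  # expected run length from the radial growth law (time ~ sqrt(N)),
  # recorded ~5x more densely than needed; the engine thins on overrun
  guess <- max(10, 1000 * sqrt(target_size / 1e6))
  guess / (5 * max(n_time_records, 2))
}

build_sim <- function(res, params, target_size) {
  size_snapshots <- NULL
  if (length(res$snap_time)) {
    size_snapshots <- data.frame(target = res$snap_target,
                                 time = res$snap_time,
                                 size = res$snap_size)
    size_snapshots$counts <- lapply(res$snap_counts, function(cc) {
      data.frame(genotype_id = cc$genotype_id, count = cc$count)
    })
    if (length(res$snap_grids)) {
      size_snapshots$grid <- res$snap_grids
    }
  }
  time_snapshots <- NULL
  if (length(res$trec_time)) {
    time_snapshots <- list(
      times = res$trec_time,
      counts = lapply(res$trec_counts, function(cc) {
        data.frame(genotype_id = cc$genotype_id, count = cc$count)
      }))
  }
  structure(list(params = params, target_size = target_size,
                 time = res$time, tumour_size = res$tumour_size,
                 event_count = res$event_count, extinct = res$extinct,
                 reached_target = res$reached_target,
                 timed_out = res$timed_out,
                 event_capped = res$event_capped,
                 genotypes = res$genotypes, demes = res$demes,
                 normals = res$normals, size_snapshots = size_snapshots,
                 time_snapshots = time_snapshots),
            class = "tumour_sim")
}

#' @export
print.tumour_sim <- function(x, ...) {
  cat(sprintf("tumour_sim: %g tumour cells at t = %.2f generations\n",
              x$tumour_size, x$time))
  cat(sprintf("  %d genotype(s), %d clone(s), %g events%s%s\n",
              nrow(x$genotypes),
              length(unique(x$genotypes$clone_id[x$genotypes$count > 0])),
              x$event_count,
              if (x$extinct) ", EXTINCT" else "",
              if (x$timed_out) ", timed out" else ""))
  invisible(x)
}

#' Apply treatment: eliminate all non-resistant tumour cells
#'
#' Treatment is applied instantaneously (time does not advance): every
#' tumour cell whose lineage lacks a resistance mutation is removed;
#' normal cells are untouched. The number of surviving cells is
#' available as `tumour_size` of the result (0 means cure).
#'
#' @param sim A `tumour_sim` object, normally at the endpoint size.
#' @return A `tumour_sim` object containing only resistant tumour
#'   cells, with attribute `n_survivors`.
#' @export
apply_treatment <- function(sim) {
  stopifnot(inherits(sim, "tumour_sim"))
  res_ids <- sim$genotypes$id[sim$genotypes$resistant]
  keep <- sim$demes$genotype_id %in% res_ids
  out <- sim
  out$demes <- sim$demes[keep, , drop = FALSE]
  removed <- !sim$genotypes$id %in% res_ids
  out$genotypes$count[removed] <- 0
  out$tumour_size <- sum(out$demes$count)
  out$extinct <- out$tumour_size == 0
  out$size_snapshots <- NULL
  out$time_snapshots <- NULL
  attr(out, "n_survivors") <- out$tumour_size
  out
}

#' Clone frequency series on an even time grid
#'
#' Resamples the fixed-interval clone-count records of a run onto
#' `n_records` evenly spaced times spanning `[0, t_end]` (step
#' interpolation: each grid time takes the latest record not after it).
#' Clones are combinations of driver mutations: genotype counts are
#' aggregated by `clone_id`, so resistance-only lineages are merged
#' with their driver clone.
#'
#' @param sim A `tumour_sim` run with time recording enabled.
#' @param n_records Number of grid points (default 101).
#' @return A `frequency_series` object: `times`, a `freqs` matrix (one
#'   row per time, one column per clone ever observed; rows sum to 1)
#'   and `clone_ids`.
#' @export
frequency_series <- function(sim, n_records = 101) {
  stopifnot(inherits(sim, "tumour_sim"))
  ts <- sim$time_snapshots
  if (is.null(ts) || length(ts$times) < 2) {
    stop("simulation has fewer than 2 time records; ",
         "rerun with n_time_records > 0")
  }
  clone_of <- sim$genotypes$clone_id
  names(clone_of) <- as.character(sim$genotypes$id)
  grid <- seq(0, sim$time, length.out = n_records)
  idx <- findInterval(grid, ts$times)
  idx[idx < 1] <- 1
  clones <- sort(unique(unlist(lapply(ts$counts, function(cc) {
    unique(clone_of[as.character(cc$genotype_id)])
  }))))
  freqs <- matrix(0, nrow = n_records, ncol = length(clones),
                  dimnames = list(NULL, as.character(clones)))
  for (i in seq_len(n_records)) {
    cc <- ts$counts[[idx[i]]]
    cl <- clone_of[as.character(cc$genotype_id)]
    agg <- tapply(cc$count, cl, sum)
    freqs[i, names(agg)] <- agg / sum(cc$count)
  }
  structure(list(times = grid, freqs = freqs, clone_ids = clones),
            class = "frequency_series")
}
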