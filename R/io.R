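#' Load and validate a YAML run configuration
#'
#' A configuration document has up to three sections: `params`
#' (simulation parameters, see [sim_params()]), `cohort` (cohort plan,
#' see [cohort_spec()]) and `calibration` (passed to
#' [calibrate_dispersal()]). Missing fields take the standard defaults
#' (K = 512, m = 10, normal rate 0.9, resistance rate mu/10, ...);
#' unknown keys and out-of-range values are rejected with an error
#' naming the field and its standard range.
#'
#' @param path Path to a YAML file, or a list already parsed.
#' @return A list with validated `params` ([sim_params()]), `cohort`
#'   ([cohort_spec()] or `NULL`) and `calibration` entries, plus the
#'   raw config echo.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else path
  if (is.null(cfg)) cfg <- list()
  known_top <- c("params", "cohort", "calibration")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  pc <- if (is.null(cfg$params)) list() else cfg$params
  known_p <- names(formals(sim_params))
  unknown <- setdiff(names(pc), known_p)
  if (length(unknown)) {
    stop("unknown params field(s): ", paste(unknown, collapse = ", "))
  }
  params <- tryCatch(do.call(sim_params, pc), error = function(e) {
    stop("invalid params: ", conditionMessage(e),
         " [standard ranges: K in {64, 512, 4096}, mu in 1e-6..1e-4, ",
         "s in 0.05..0.2]", call. = FALSE)
  })
  cohort <- NULL
  if (!is.null(cfg$cohort)) {
    cc <- cfg$cohort
    known_c <- names(formals(cohort_spec))
    unknown <- setdiff(names(cc), known_c)
    if (length(unknown)) {
      stop("unknown cohort field(s): ", paste(unknown, collapse = ", "))
    }
    defaults <- list(K = params$K, s = params$s,
                     endpoint_size = params$endpoint_size, d = params$d)
    if (!identical(cc$mu, "random") && is.null(cc$mu)) {
      defaults$mu <- params$mu
    }
    cc <- utils::modifyList(defaults, cc)
    cohort <- do.call(cohort_spec, cc)
  }
  calibration <- if (is.null(cfg$calibration)) list() else cfg$calibration
  list(params = params, cohort = cohort, calibration = calibration,
       raw = cfg)
}

#' Write a configuration back to YAML
#'
#' @param config A list as returned by [load_config()] (the `raw` echo
#'   is written) or any plain configuration list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  raw <- if (!is.null(config$raw)) config$raw else config
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Export a clone table for Muller plot tooling
#'
#' Long-format rows (generation, genotype_id, parent_id, n_drivers,
#' division_rate, resistant, cell_count) from the fixed-interval time
#' records of a run, with full ancestry so downstream tooling can nest
#' descendant clones within their parents.
#'
#' @param sim A `tumour_sim` with time records.
#' @param path Optional CSV output path.
#' @return The table (invisibly if written to `path`).
#' @export
export_muller_table <- function(sim, path = NULL) {
  stopifnot(inherits(sim, "tumour_sim"))
  ts <- sim$time_snapshots
  if (is.null(ts)) stop("simulation has no time records")
  gen <- sim$genotypes
  rows <- lapply(seq_along(ts$times), function(i) {
    cc <- ts$counts[[i]]
    j <- match(cc$genotype_id, gen$id)
    data.frame(generation = ts$times[i], genotype_id = cc$genotype_id,
               parent_id = gen$parent_id[j], n_drivers = gen$n_drivers[j],
               division_rate = gen$division_rate[j],
               resistant = gen$resistant[j], cell_count = cc$count)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Export the spatial snapshot as a modal-genotype matrix
#'
#' A matrix over the deme lattice holding the most abundant genotype id
#' in each tumour-containing deme (0 elsewhere), written as CSV.
#'
#' @param sim A `tumour_sim` object.
#' @param path Optional CSV output path.
#' @return The matrix (invisibly if written).
#' @export
export_spatial_csv <- function(sim, path = NULL) {
  stopifnot(inherits(sim, "tumour_sim"))
  L <- sim$params$lattice_side
  mat <- matrix(0L, L, L)
  g <- sim$demes[sim$demes$count > 0, ]
  for (key in unique(paste(g$row, g$col))) {
    sub <- g[paste(g$row, g$col) == key, ]
    i <- which.max(sub$count)
    mat[sub$row[i], sub$col[i]] <- sub$genotype_id[i]
  }
  if (!is.null(path)) {
    utils::write.table(mat, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    return(invisible(mat))
  }
  mat
}

#' Export cohort tables to CSV
#'
#' Writes the per-tumour table (wide: one row per tumour, with
#' per-measurement-size predictor columns) and the long measurements
#' table.
#'
#' @param cohort A `cohort_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Character vector of the files written.
#' @export
export_cohort_csv <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "cohort_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meas <- cohort$measurements
  wide <- cohort$tumours
  sizes <- sort(unique(meas$measurement_size))
  vars <- c("diversity_whole", "diversity_edge", "diversity_biopsy",
            "mean_division_rate", "growth_rate")
  for (k in seq_along(sizes)) {
    sub <- meas[meas$measurement_size == sizes[k], ]
    for (v in vars) {
      wide[[sprintf("%s_size%d", v, k)]] <-
        sub[[v]][match(wide$tumour_id, sub$tumour_id)]
    }
  }
  f1 <- file.path(dir, paste0(prefix, "_tumours.csv"))
  f2 <- file.path(dir, paste0(prefix, "_measurements.csv"))
  utils::write.csv(wide, f1, row.names = FALSE)
  utils::write.csv(meas, f2, row.names = FALSE)
  c(f1, f2)
}

#' Write a reproducibility manifest
#'
#' Records the configuration snapshot, package version, master seed,
#' per-tumour seeds, timestamp, and the output file inventory with MD5
#' checksums, as JSON.
#'
#' @param path Output JSON path.
#' @param config Configuration echo (any list).
#' @param master_seed Master seed of the run.
#' @param seeds Per-replicate seeds (optional).
#' @param outputs Paths of output files to inventory.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), master_seed = NA,
                           seeds = NULL, outputs = character(0)) {
  inv <- lapply(outputs, function(f) {
    list(file = basename(f),
         md5 = unname(tools::md5sum(f)),
         bytes = file.size(f))
  })
  manifest <- list(
    package = "cloneforecast",
    version = as.character(utils::packageVersion("cloneforecast")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = master_seed,
    seeds = seeds,
    config = config,
    outputs = inv)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
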