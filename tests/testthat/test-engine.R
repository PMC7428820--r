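test_that("initial state seeds one founder among K normal cells", {
  for (K in c(64, 512)) {
    p <- sim_params(K = K, mu = 0, d = 0, endpoint_size = 100)
    sim <- init_simulation(p, seed = 1)
    expect_equal(sim$tumour_size, 1)
    expect_equal(sim$time, 0)
    expect_equal(nrow(sim$genotypes), 1)
    expect_equal(sim$genotypes$n_drivers, 0)
    expect_equal(sim$genotypes$division_rate, 1)
    # central deme holds K normals + the founder
    expect_equal(nrow(sim$demes), 1)
    expect_equal(sim$normals$normal + sim$demes$count, K + 1)
    centre <- p$lattice_side %/% 2 + 1
    expect_equal(unname(c(sim$demes$row, sim$demes$col)), c(centre, centre))
  }
})

test_that("identical seeds give bit-identical runs", {
  p <- sim_params(K = 64, mu = 5e-5, s = 0.1, d = 0.1, endpoint_size = 500)
  s1 <- simulate_tumour(p, record_sizes = 250, seed = 11)
  s2 <- simulate_tumour(p, record_sizes = 250, seed = 11)
  expect_identical(s1, s2)
  s3 <- simulate_tumour(p, record_sizes = 250, seed = 12)
  expect_false(identical(s1$time, s3$time))
})

test_that("deme death rate switches from 0 to the crowding value above K", {
  expect_equal(deme_death_rate(512, 512), 0)
  expect_equal(deme_death_rate(513, 512), 100)
  expect_equal(deme_death_rate(0, 64), 0)
  expect_equal(deme_death_rate(c(10, 65), 64), c(0, 100))
  expect_error(deme_death_rate(-1, 64), "non-negative")
})

test_that("driver fitness update follows the diminishing-returns formula", {
  expect_equal(fitness_after_driver(1, 0.1, 10), 1.09)
  expect_equal(fitness_after_driver(1, 0, 10), 1)
  # vanishing gain as r approaches the bound
  expect_lt(fitness_after_driver(9.999, 1, 10) - 9.999, 0.001)
  expect_error(fitness_after_driver(10, 0.1, 10), "r must satisfy")
  expect_error(fitness_after_driver(1, -0.5, 10), "non-negative")
})

test_that("driver effects are exponential with mean s", {
  set.seed(42)
  x <- draw_driver_effect(1e5, s = 0.1)
  expect_true(all(x >= 0))
  expect_equal(mean(x), 0.1, tolerance = 0.02)
  ks <- suppressWarnings(ks.test(x, pexp, rate = 10))
  expect_gt(ks$p.value, 0.01)
  expect_error(draw_driver_effect(1, s = 0), "positive")
})

test_that("every event conserves counts and changes one deme by one cell", {
  p <- sim_params(K = 64, mu = 1e-3, s = 0.1, d = 0.2, endpoint_size = 1e4,
                  allow_nonstandard = TRUE)
  sim <- simulate_tumour(p, target_size = 30, n_time_records = 0, seed = 5)
  seed <- 5
  while (sim$extinct) {
    seed <- seed + 1
    sim <- simulate_tumour(p, target_size = 30, n_time_records = 0,
                           seed = seed)
  }
  pop_map <- function(s) {
    key <- paste(s$normals$row, s$normals$col)
    pop <- setNames(s$normals$normal, key)
    for (i in seq_len(nrow(s$demes))) {
      k <- paste(s$demes$row[i], s$demes$col[i])
      pop[k] <- pop[k] + s$demes$count[i]
    }
    pop
  }
  prev <- sim
  for (step in 1:150) {
    cur <- advance_events(prev, 1)
    # tumour size equals both the grid-wide and registry-wide sums
    expect_equal(cur$tumour_size, sum(cur$demes$count))
    expect_equal(cur$tumour_size, sum(cur$genotypes$count))
    expect_gte(cur$time, prev$time)
    pm_prev <- pop_map(prev)
    pm_cur <- pop_map(cur)
    keys <- union(names(pm_prev), names(pm_cur))
    a <- ifelse(is.na(pm_prev[keys]), p$K, pm_prev[keys])
    b <- ifelse(is.na(pm_cur[keys]), p$K, pm_cur[keys])
    delta <- b - a
    expect_equal(sum(delta != 0), 1)
    expect_equal(abs(sum(delta)), 1)
    prev <- cur
  }
})

test_that("without mutation exactly one genotype ever exists", {
  p <- sim_params(K = 64, mu = 0, d = 0.2, endpoint_size = 2000)
  sim <- simulate_tumour(p, seed = 31)
  while (sim$extinct) sim <- simulate_tumour(p)
  expect_equal(nrow(sim$genotypes), 1)
  expect_equal(sim$tumour_size, sum(sim$demes$count))
  fs <- frequency_series(sim)
  expect_true(all(fs$freqs == 1))
})

test_that("division rates never reach the upper bound m", {
  p <- sim_params(K = 64, mu = 5e-3, s = 0.2, d = 0.1, endpoint_size = 5000,
                  allow_nonstandard = TRUE)
  sim <- simulate_tumour(p, seed = 8)
  while (sim$extinct) sim <- simulate_tumour(p)
  expect_true(all(sim$genotypes$division_rate < p$m))
  expect_true(all(sim$genotypes$division_rate >= 1))
  # child rates strictly exceed their parents' when a driver is added
  g <- sim$genotypes
  child <- g[!is.na(g$parent_id) & g$n_drivers > 0, ]
  if (nrow(child)) {
    parent_r <- g$division_rate[match(child$parent_id, g$id)]
    added <- child$n_drivers > g$n_drivers[match(child$parent_id, g$id)]
    expect_true(all(child$division_rate[added] > parent_r[added]))
  }
})

test_that("interior demes are regulated to about K cells", {
  p <- sim_params(K = 64, mu = 0, d = 0.1, endpoint_size = 4000)
  sim <- simulate_tumour(p, seed = 21)
  while (sim$extinct) sim <- simulate_tumour(p)
  per_deme <- aggregate(count ~ row + col, data = sim$demes, FUN = sum)
  key <- paste(sim$normals$row, sim$normals$col)
  normals <- setNames(sim$normals$normal, key)
  occ <- paste(per_deme$row, per_deme$col)
  interior <- vapply(seq_len(nrow(per_deme)), function(i) {
    nb <- paste(per_deme$row[i] + c(-1, 1, 0, 0),
                per_deme$col[i] + c(0, 0, -1, 1))
    all(nb %in% occ)
  }, logical(1))
  expect_gt(sum(interior), 4)
  pops <- per_deme$count[interior] +
    ifelse(is.na(normals[occ[interior]]), 0, normals[occ[interior]])
  expect_lt(abs(mean(pops) - p$K), 3 * sqrt(p$K))
})

test_that("boundary occupancy is a hard error by default", {
  p <- sim_params(K = 64, mu = 0, d = 0.5, endpoint_size = 1e6,
                  lattice_side = 5)
  # a tumour established on a 5x5 lattice must hit the boundary well
  # before 2000 cells; extinct founders are redrawn first
  hit <- FALSE
  for (seed in 1:50) {
    out <- tryCatch(simulate_tumour(p, target_size = 2000, seed = seed),
                    error = function(e) e)
    if (inherits(out, "error")) {
      expect_match(conditionMessage(out), "lattice exhausted")
      hit <- TRUE
      break
    }
    expect_true(out$extinct)  # the only non-error outcome at this size
  }
  expect_true(hit)
})

test_that("mutation-free growth without normal cells is a pure birth process", {
  # single deme, K above the target: no crowding, no competition, so the
  # time to grow from 1 to 100 cells is a Yule process with unit rate
  # and mean sum_{k=1}^{99} 1/k
  p <- sim_params(K = 200, mu = 0, d = 0, endpoint_size = 100,
                  seed_normal_cells = FALSE, allow_nonstandard = TRUE)
  set.seed(99)
  times <- replicate(400, {
    sim <- simulate_tumour(p, n_time_records = 0, record_grids = FALSE)
    sim$time
  })
  expect_equal(mean(times), sum(1 / (1:99)), tolerance = 0.05)
})

test_that("treatment removes exactly the non-resistant cells", {
  p <- sim_params(K = 64, mu = 1e-3, s = 0.1, d = 0.2, endpoint_size = 1e4,
                  resistance_rate = 1e-3, allow_nonstandard = TRUE)
  found <- FALSE
  for (seed in 1:40) {
    sim <- simulate_tumour(p, seed = seed)
    if (sim$extinct || !sim$reached_target) next
    res_ids <- sim$genotypes$id[sim$genotypes$resistant]
    n_resistant <- sum(sim$demes$count[sim$demes$genotype_id %in% res_ids])
    treated <- apply_treatment(sim)
    expect_equal(treated$tumour_size, n_resistant)
    expect_identical(treated$normals, sim$normals)
    expect_identical(treated$time, sim$time)
    if (n_resistant > 0) found <- TRUE
    if (found && seed > 10) break
  }
  expect_true(found)  # at this mutation rate some runs carry resistance
})

test_that("run snapshots are taken at the first crossing of each size", {
  p <- sim_params(K = 64, mu = 0, d = 0.2, endpoint_size = 2000)
  sim <- simulate_tumour(p, record_sizes = c(500, 1000), seed = 77)
  while (sim$extinct) sim <- simulate_tumour(p, record_sizes = c(500, 1000))
  sn <- sim$size_snapshots
  expect_equal(sn$target, c(500, 1000))
  expect_true(all(diff(sn$time) >= 0))
  expect_true(all(sn$size >= sn$target))
  expect_lte(sn$time[2], sim$time)
  # frequency vectors in the trajectory sum to one
  fs <- frequency_series(sim)
  expect_true(all(abs(rowSums(fs$freqs) - 1) < 1e-9))
})

test_that("parameter validation enforces the documented ranges", {
  expect_error(sim_params(K = 100), "standard carrying capacity")
  expect_silent(sim_params(K = 100, allow_nonstandard = TRUE))
  expect_error(sim_params(mu = 1.5), "mu")
  expect_error(sim_params(mu = 1e-3), "standard range")
  expect_error(sim_params(d = 1.2), "d must lie")
  expect_error(sim_params(r_init = 11, m = 10), "r_init")
  expect_error(sim_params(endpoint_size = 0), "endpoint_size")
  p <- sim_params(mu = 2e-5)
  expect_equal(p$resistance_rate, 2e-6)  # default mu/10
})
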