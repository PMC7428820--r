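# constructed spatial fixture: a filled 3x3 block of demes centred at
# (8,8) with two genotypes at 7:3 within every deme
block_fixture <- function(n_per_deme = 1000) {
  demes <- expand.grid(row = 7:9, col = 7:9)
  rbind(
    data.frame(row = demes$row, col = demes$col, genotype_id = 1L,
               count = 0.7 * n_per_deme),
    data.frame(row = demes$row, col = demes$col, genotype_id = 2L,
               count = 0.3 * n_per_deme))
}

registry_fixture <- data.frame(
  id = 1:2, parent_id = c(NA, 1L), clone_id = 1:2, n_drivers = 0:1,
  division_rate = c(1, 1.1), resistant = c(FALSE, FALSE),
  origin_time = c(0, 1), count = c(7000, 3000))

test_that("whole-tumour sampling is an exact census", {
  g <- block_fixture()
  ws <- whole_tumour_sample(g)
  expect_equal(ws$n_cells, 9000)
  expect_equal(unname(ws$counts[c("1", "2")]), c(6300, 2700))
  expect_equal(unname(ws$counts / ws$n_cells)[1], 0.7)
  # a monomorphic state yields a single genotype
  g1 <- g[g$genotype_id == 1, ]
  expect_equal(length(whole_tumour_sample(g1)$counts), 1)
})

test_that("edge visibility returns the block perimeter, not the centre", {
  g <- block_fixture()
  ed <- edge_demes(g)
  expect_equal(nrow(ed), 8)
  expect_false(any(ed$row == 8 & ed$col == 8))
  # single occupied deme is visible from all four sides
  single <- data.frame(row = 5, col = 5, genotype_id = 1, count = 10)
  expect_equal(nrow(edge_demes(single)), 1)
  # occupied columns {2, 5, 9} in one row: only 2 and 9 are visible
  row3 <- data.frame(row = 3, col = c(2, 5, 9), genotype_id = 1, count = 1)
  ed3 <- edge_demes(row3)
  # the middle deme is visible from above/below but not from the sides
  expect_true(all(c(2, 9) %in% ed3$col))
})

test_that("edge sampling draws round(sqrt(K)) cells per edge deme", {
  g <- block_fixture()
  set.seed(1)
  es64 <- edge_sample(g, K = 64)
  expect_equal(es64$geometry$cells_per_deme, 8)   # sqrt(64)
  expect_equal(es64$n_cells, 8 * 8)
  es512 <- edge_sample(g, K = 512)
  expect_equal(es512$geometry$cells_per_deme, 23)  # round(22.63)
  expect_equal(es512$n_cells, 8 * 23)
  # a deme holding fewer cells than the quota is taken whole
  tiny <- data.frame(row = 5, col = 5, genotype_id = 1, count = 3)
  expect_equal(edge_sample(tiny, K = 512)$n_cells, 3)
})

test_that("multinomial subsampling preserves composition in expectation", {
  expect_equal(unname(multinomial_subsample(c(A = 10), 3)), 3)
  expect_equal(multinomial_subsample(c(A = 5, B = 5), 20), c(A = 5, B = 5))
  expect_error(multinomial_subsample(c(A = -1), 3), "non-negative")
  set.seed(7)
  fr <- replicate(300, {
    s <- multinomial_subsample(c(A = 8000, B = 2000), 1000)
    s[["A"]] / 1000
  })
  expect_equal(mean(fr), 0.8, tolerance = 0.005)
  expect_lt(sd(fr), 3 * sqrt(0.8 * 0.2 / 1000))
})

test_that("biopsy discs sit on the edge-to-centre segment and fill quota", {
  g <- block_fixture()
  set.seed(3)
  bs <- biopsy_sample(g, depth_fraction = 1, n_biopsies = 4,
                      cells_per_biopsy = 500, K = 512)
  # depth 1: all discs centred at the centre of mass
  for (b in seq_len(4)) {
    expect_equal(unname(bs$geometry$centres[b, ]), c(8, 8))
  }
  expect_equal(bs$pooled$n_cells, 4 * 500)
  expect_equal(length(bs$biopsies), 4)
  b0 <- biopsy_sample(g, depth_fraction = 0, n_biopsies = 1,
                      cells_per_biopsy = 500, K = 512)
  # depth 0: disc centred on the outermost deme of the upward transect
  expect_equal(unname(b0$geometry$centres[1, ]), c(7, 8))
  expect_error(biopsy_sample(g, cells_per_biopsy = 50, K = 512),
               "cells_per_biopsy")
})

test_that("sampling a monomorphic tumour always gives diversity one", {
  g <- block_fixture()[block_fixture()$genotype_id == 1, ]
  reg <- registry_fixture[1, ]
  set.seed(5)
  expect_equal(inverse_simpson(whole_tumour_sample(g)), 1)
  expect_equal(inverse_simpson(edge_sample(g, K = 64)), 1)
  bs <- biopsy_sample(g, cells_per_biopsy = 200, K = 64)
  expect_equal(inverse_simpson(bs$pooled), 1)
})

test_that("sampling never mutates the simulation state", {
  p <- sim_params(K = 64, mu = 1e-4, s = 0.1, d = 0.2, endpoint_size = 3000)
  sim <- simulate_tumour(p, seed = 13)
  while (sim$extinct) sim <- simulate_tumour(p)
  before <- sim
  set.seed(2)
  invisible(whole_tumour_sample(sim))
  invisible(edge_sample(sim))
  invisible(tryCatch(biopsy_sample(sim, cells_per_biopsy = 200),
                     error = function(e) NULL))
  expect_identical(sim, before)
})

test_that("edge demes are a subset of occupied demes, none fully interior", {
  p <- sim_params(K = 64, mu = 0, d = 0.15, endpoint_size = 3000)
  sim <- simulate_tumour(p, seed = 17)
  while (sim$extinct) sim <- simulate_tumour(p)
  ed <- edge_demes(sim)
  occ <- unique(sim$demes[sim$demes$count > 0, c("row", "col")])
  occ_key <- paste(occ$row, occ$col)
  expect_true(all(paste(ed$row, ed$col) %in% occ_key))
  surrounded <- vapply(seq_len(nrow(ed)), function(i) {
    all(paste(ed$row[i] + c(-1, 1, 0, 0),
              ed$col[i] + c(0, 0, -1, 1)) %in% occ_key)
  }, logical(1))
  expect_false(any(surrounded))
})
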