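# Literal one-record-per-cell Gillespie simulator, independent of the
# package's class-aggregated engine. Every cell is a row; per-cell rates
# are recomputed from scratch each event. Usable only at toy scale.
#
# Model: tumour cells divide at their genotype rate; normal cells divide
# at normal_rate; every cell dies at death_rate while its deme exceeds
# K. Newborn tumour cells draw Poisson(mu) driver mutations (each a new
# genotype with effect X ~ Exp(s) applied as r * (1 + X(1 - r/m))) and
# disperse to a uniform von Neumann neighbour with probability d
# (off-lattice moves stay put).
oracle_simulate <- function(K, mu, s, d, L, target_size,
                            r_init = 1, m = 10, normal_rate = 0.9,
                            death_rate = 100, max_events = 1e6) {
  centre <- floor(L / 2) + 1
  deme_of <- function(row, col) (row - 1) * L + col
  # per-cell records
  cell_deme <- integer(0)
  cell_gen <- integer(0)      # 0 = normal cell
  gen_r <- c(r_init)          # genotype registry: division rates
  gen_parent <- c(NA_integer_)
  for (row in seq_len(L)) {
    for (col in seq_len(L)) {
      cell_deme <- c(cell_deme, rep(deme_of(row, col), K))
      cell_gen <- c(cell_gen, rep(0L, K))
    }
  }
  cell_deme <- c(cell_deme, deme_of(centre, centre))
  cell_gen <- c(cell_gen, 1L)
  time <- 0
  events <- 0
  repeat {
    n_tum <- sum(cell_gen > 0)
    if (n_tum == 0) {
      return(list(extinct = TRUE, time = time,
                  n_clones = 0L, tumour_size = 0L))
    }
    if (n_tum >= target_size) {
      return(list(extinct = FALSE, time = time,
                  n_clones = length(unique(cell_gen[cell_gen > 0])),
                  tumour_size = n_tum))
    }
    if (events >= max_events) stop("oracle exceeded event cap")
    pop <- tabulate(cell_deme, nbins = L * L)
    over <- pop[cell_deme] > K
    div_rate <- ifelse(cell_gen > 0, gen_r[pmax(cell_gen, 1)], normal_rate)
    death <- ifelse(over, death_rate, 0)
    rates <- div_rate + death
    total <- sum(rates)
    time <- time + stats::rexp(1, total)
    i <- sample.int(length(rates), 1, prob = rates)
    events <- events + 1
    if (stats::runif(1) < div_rate[i] / rates[i]) {
      # division
      if (cell_gen[i] == 0L) {
        cell_deme <- c(cell_deme, cell_deme[i])
        cell_gen <- c(cell_gen, 0L)
      } else {
        g <- cell_gen[i]
        nmut <- stats::rpois(1, mu)
        for (k in seq_len(nmut)) {
          X <- stats::rexp(1, 1 / s)
          gen_r <- c(gen_r, gen_r[g] * (1 + X * (1 - gen_r[g] / m)))
          gen_parent <- c(gen_parent, g)
          g <- length(gen_r)
        }
        dest <- cell_deme[i]
        if (d > 0 && stats::runif(1) < d) {
          row <- (dest - 1) %/% L + 1
          col <- (dest - 1) %% L + 1
          dir <- sample(4, 1)
          row2 <- row + c(-1, 1, 0, 0)[dir]
          col2 <- col + c(0, 0, -1, 1)[dir]
          if (row2 >= 1 && row2 <= L && col2 >= 1 && col2 <= L) {
            dest <- deme_of(row2, col2)
          }
        }
        cell_deme <- c(cell_deme, dest)
        cell_gen <- c(cell_gen, g)
      }
    } else {
      cell_deme <- cell_deme[-i]
      cell_gen <- cell_gen[-i]
    }
  }
}
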