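#' Extract the tumour clone-count grid from a simulation or snapshot
#'
#' Sampling schemes operate on a spatial grid of per-deme tumour clone
#' counts. This helper accepts either a `tumour_sim` object (final
#' state) or a size-snapshot grid (`data.frame` with columns `row`,
#' `col`, `genotype_id`, `count`).
#'
#' @param x A `tumour_sim` or a snapshot grid `data.frame`.
#' @return A `data.frame` with columns `row`, `col`, `genotype_id`,
#'   `count` (positive counts only).
#' @keywords internal
tumour_grid <- function(x) {
  g <- if (inherits(x, "tumour_sim")) x$demes else x
  stopifnot(is.data.frame(g),
            all(c("row", "col", "genotype_id", "count") %in% names(g)))
  g <- g[g$count > 0, , drop = FALSE]
  if (nrow(g) == 0) stop("tumour is empty: nothing to sample")
  g
}

new_clone_sample <- function(counts, scheme, geometry = NULL) {
  counts <- counts[counts > 0]
  structure(list(counts = counts, n_cells = sum(counts),
                 scheme = scheme, geometry = geometry),
            class = "clone_sample")
}

#' @export
print.clone_sample <- function(x, ...) {
  cat(sprintf("clone_sample (%s): %g cells, %d genotype(s)\n",
              x$scheme, x$n_cells, length(x$counts)))
  invisible(x)
}

#' Whole-tumour census sample
#'
#' Exact global genotype counts over every tumour cell.
#'
#' @param x A `tumour_sim` or snapshot grid (see [tumour_grid()]).
#' @return A `clone_sample` with the full census.
#' @export
whole_tumour_sample <- function(x) {
  g <- tumour_grid(x)
  counts <- tapply(g$count, g$genotype_id, sum)
  new_clone_sample(stats::setNames(as.numeric(counts), names(counts)),
                   "whole")
}

#' Demes visible from the sides of the lattice
#'
#' Implements the edge-visibility rule: for every lattice row, the
#' first tumour-containing deme scanning from the left and from the
#' right; for every column, the first scanning from the top and from
#' the bottom; duplicates removed.
#'
#' @inheritParams whole_tumour_sample
#' @return A `data.frame` of `row`, `col` coordinates of edge demes.
#' @export
edge_demes <- function(x) {
  g <- tumour_grid(x)
  occ <- unique(g[, c("row", "col")])
  picks <- rbind(
    do.call(rbind, lapply(split(occ, occ$row), function(z) {
      z[c(which.min(z$col), which.max(z$col)), ]
    })),
    do.call(rbind, lapply(split(occ, occ$col), function(z) {
      z[c(which.min(z$row), which.max(z$row)), ]
    })))
  out <- unique(picks)
  rownames(out) <- NULL
  out[order(out$row, out$col), ]
}

#' Edge sample: sqrt(K) cells from each visible edge deme
#'
#' From each deme returned by [edge_demes()], `round(sqrt(K))` cells
#' are drawn by multinomial subsampling of that deme's clone counts
#' (all cells if the deme holds fewer), and the draws are pooled. The
#' per-deme quota makes the total sample size insensitive to deme size.
#'
#' @inheritParams whole_tumour_sample
#' @param K Deme carrying capacity; taken from `x$params` when `x` is a
#'   `tumour_sim`.
#' @return A pooled `clone_sample` (geometry lists the edge demes).
#' @export
edge_sample <- function(x, K = NULL) {
  if (is.null(K)) {
    if (!inherits(x, "tumour_sim")) {
      stop("K must be supplied when sampling from a snapshot grid")
    }
    K <- x$params$K
  }
  g <- tumour_grid(x)
  ed <- edge_demes(g)
  n_per <- round(sqrt(K))
  pooled <- numeric(0)
  for (i in seq_len(nrow(ed))) {
    dd <- g[g$row == ed$row[i] & g$col == ed$col[i], , drop = FALSE]
    counts <- stats::setNames(dd$count, dd$genotype_id)
    take <- multinomial_subsample(counts, n_per)
    pooled <- merge_counts(pooled, take)
  }
  new_clone_sample(pooled, "edge", geometry = list(edge_demes = ed,
                                                   cells_per_deme = n_per))
}

merge_counts <- function(a, b) {
  ids <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(ids)), ids)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

#' Multinomial subsampling of clone counts
#'
#' Draws `n` cells without regard to order from a clone-count vector:
#' if `n` is at least the population size the counts are returned
#' unchanged, otherwise a multinomial draw of size `n` with
#' probabilities proportional to the counts.
#'
#' @param counts Named non-negative count vector.
#' @param n Sample size.
#' @return Named count vector of the sample.
#' @export
multinomial_subsample <- function(counts, n) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (n < 0) stop("n must be non-negative")
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (n >= total) return(counts)
  if (n == 0) return(counts[0])
  draw <- stats::rmultinom(1, size = n, prob = counts)[, 1]
  stats::setNames(as.numeric(draw), names(counts))
}

#' Disc-shaped biopsy samples
#'
#' Biopsies are discs centred at a fixed proportion of the distance
#' from the tumour edge to its cell-weighted centre of mass, located on
#' perpendicular axis-aligned transects through the centre of mass.
#' For each transect the edge point is the outermost tumour-containing
#' deme along it. The disc radius is sized so that the expected number
#' of cells under the disc at density `K` per deme is
#' `cells_per_biopsy` (with a floor of half a deme width); the number
#' of cells drawn from each deme is proportional to the disc--deme area
#' overlap (estimated on a 16x16 subgrid), renormalized to
#' `cells_per_biopsy`, and drawn by [multinomial_subsample()].
#'
#' @inheritParams edge_sample
#' @param depth_fraction Position of the disc centre: 0 = at the edge
#'   deme, 1 = at the centre of mass.
#' @param n_biopsies Number of biopsies (1, 2 or 4), taken on the up,
#'   right, down, left transects in that order.
#' @param cells_per_biopsy Cells drawn per biopsy (100--4,000 is the
#'   range practical for single-cell assays; values outside it error).
#' @return A `biopsy_set`: list with per-biopsy `clone_sample`s
#'   (`$biopsies`), the pooled sample (`$pooled`) and geometry.
#' @export
biopsy_sample <- function(x, depth_fraction = 0.4, n_biopsies = 4,
                          cells_per_biopsy = 1000, K = NULL) {
  if (is.null(K)) {
    if (!inherits(x, "tumour_sim")) {
      stop("K must be supplied when sampling from a snapshot grid")
    }
    K <- x$params$K
  }
  if (!n_biopsies %in% c(1, 2, 4)) stop("n_biopsies must be 1, 2 or 4")
  if (depth_fraction < 0 || depth_fraction > 1) {
    stop("depth_fraction must lie in [0, 1]")
  }
  if (cells_per_biopsy < 100 || cells_per_biopsy > 4000) {
    stop("cells_per_biopsy must lie in [100, 4000]")
  }
  g <- tumour_grid(x)
  per_deme <- stats::aggregate(count ~ row + col, data = g, FUN = sum)
  com <- c(row = sum(per_deme$row * per_deme$count) / sum(per_deme$count),
           col = sum(per_deme$col * per_deme$count) / sum(per_deme$count))
  dirs <- list(up = c(-1, 0), right = c(0, 1), down = c(1, 0),
               left = c(0, -1))[seq_len(n_biopsies)]
  rho <- max(0.5, sqrt(cells_per_biopsy / (pi * K)))
  biopsies <- list()
  centres <- matrix(NA_real_, n_biopsies, 2,
                    dimnames = list(names(dirs), c("row", "col")))
  for (b in seq_along(dirs)) {
    edge <- transect_edge(per_deme, com, dirs[[b]])
    centre <- edge + depth_fraction * (com - edge)
    centres[b, ] <- centre
    w <- disc_overlap_weights(per_deme, centre, rho)
    covered <- which(w > 0)
    avail <- per_deme$count[covered]
    if (length(covered) == 0 || sum(avail) == 0) {
      stop("biopsy ", names(dirs)[b], " covers zero tumour cells ",
           "(disc centre ", paste(round(centre, 2), collapse = ","),
           ", radius ", round(rho, 2), ")")
    }
    alloc <- allocate_proportional(w[covered], avail, cells_per_biopsy)
    pooled <- numeric(0)
    for (j in seq_along(covered)) {
      if (alloc[j] == 0) next
      dd <- g[g$row == per_deme$row[covered[j]] &
                g$col == per_deme$col[covered[j]], , drop = FALSE]
      counts <- stats::setNames(dd$count, dd$genotype_id)
      pooled <- merge_counts(pooled, multinomial_subsample(counts, alloc[j]))
    }
    biopsies[[names(dirs)[b]]] <-
      new_clone_sample(pooled, "biopsy",
                       geometry = list(centre = centre, radius = rho,
                                       transect = names(dirs)[b]))
  }
  pooled_all <- Reduce(merge_counts, lapply(biopsies, `[[`, "counts"),
                       accumulate = FALSE)
  structure(list(biopsies = biopsies,
                 pooled = new_clone_sample(pooled_all, "biopsy_pooled"),
                 geometry = list(centre_of_mass = com, centres = centres,
                                 radius = rho,
                                 depth_fraction = depth_fraction,
                                 cells_per_biopsy = cells_per_biopsy)),
            class = "biopsy_set")
}

# outermost occupied deme along an axis-aligned transect through com;
# the perpendicular tolerance widens until the ray hits occupied demes
transect_edge <- function(per_deme, com, dir) {
  axis <- if (dir[1] != 0) "row" else "col"
  perp <- if (dir[1] != 0) "col" else "row"
  sgn <- sum(dir)
  for (tol in c(0.51, 1.01, 2.01, Inf)) {
    cand <- per_deme[abs(per_deme[[perp]] - com[perp]) <= tol, , drop = FALSE]
    cand <- cand[sign(cand[[axis]] - com[axis]) * sgn >= 0 |
                   cand[[axis]] == round(com[axis]), , drop = FALSE]
    if (nrow(cand) == 0) next
    i <- if (sgn < 0) which.min(cand[[axis]]) else which.max(cand[[axis]])
    out <- c(cand$row[i], cand$col[i])
    names(out) <- c("row", "col")
    return(out)
  }
  stop("internal error: no occupied deme found on transect")
}

# fraction of each deme's unit cell covered by the disc (16x16 subgrid)
disc_overlap_weights <- function(per_deme, centre, rho) {
  ss <- (seq_len(16) - 0.5) / 16 - 0.5
  sub <- expand.grid(dr = ss, dc = ss)
  vapply(seq_len(nrow(per_deme)), function(i) {
    pr <- per_deme$row[i] + sub$dr
    pc <- per_deme$col[i] + sub$dc
    mean((pr - centre["row"])^2 + (pc - centre["col"])^2 <= rho^2)
  }, numeric(1))
}

# integer allocation proportional to weights, capped by availability
allocate_proportional <- function(w, avail, n_target) {
  n_target <- min(n_target, sum(avail))
  alloc <- pmin(avail, floor(w / sum(w) * n_target))
  # distribute the remainder by largest fractional part, respecting caps
  while (sum(alloc) < n_target) {
    room <- avail - alloc
    frac <- w / sum(w) * n_target - alloc
    frac[room <= 0] <- -Inf
    j <- which.max(frac)
    if (!is.finite(frac[j])) break
    alloc[j] <- alloc[j] + 1
  }
  alloc
}
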