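# Exact two-lineage Monte-Carlo simulation and grid demography generation.
# The Gillespie scheme draws the next migration/coalescence event within the
# current epoch; draws past an epoch boundary advance to the boundary and
# refresh the rates, which is exact for piecewise-constant intensities.

#' Simulate pairwise branch lengths
#'
#' Draws `n` independent realizations of the pairwise branch length
#' `B = 2 T_coal - x - y` for one lineage sampled in deme `i` at backward time
#' `x` and one in deme `j` at time `y >= x`. Backward from `x` only the first
#' lineage migrates until `y`; from `y` both lineages migrate independently
#' and coalesce at rate `gamma_k` while co-located in deme `k`.
#'
#' @param model a valid [demographic_model()].
#' @param i,j sampling demes (1-based).
#' @param x,y sampling times (swapped, with demes, if `x > y`).
#' @param n number of replicates.
#' @param seed optional integer seed (R RNG).
#' @return Data frame with columns `deme_i`, `x`, `deme_j`, `y`,
#'   `branch_length`.
#' @export
simulate_pair <- function(model, i, x, j, y, n, seed = NULL) {
  viol <- validate_model(model)
  if (length(viol) > 0) stop(paste(viol, collapse = "; "))
  if (x > y) {
    tmp <- x; x <- y; y <- tmp
    tmp <- i; i <- j; j <- tmp
  }
  if (x < model$epochs[[1]]$t_start) {
    stop("sampling time precedes the first epoch")
  }
  if (!is.null(seed)) set.seed(seed)
  b <- simulate_pairs_cpp(model, as.integer(i), x, as.integer(j), y,
                          as.integer(n))
  data.frame(deme_i = i, x = x, deme_j = j, y = y, branch_length = b)
}

#' Attach simulated LPSC segment lengths to pairwise samples
#'
#' Given branch length `b`, a random shared-segment length is exponential
#' with rate `r * b` (so that `P(length > mu) = exp(-r b mu)`).
#'
#' @param samples data frame from [simulate_pair()].
#' @param r recombination rate per unit length per generation (`> 0`).
#' @param seed optional integer seed.
#' @return `samples` with an added `lpsc_length` column.
#' @export
attach_lpsc_lengths <- function(samples, r, seed = NULL) {
  if (r <= 0) stop("r must be positive")
  if (!is.null(seed)) set.seed(seed)
  samples$lpsc_length <- stats::rexp(nrow(samples),
                                     rate = r * samples$branch_length)
  samples
}

#' Empirical expected pairwise branch-length matrix
#'
#' Sample mean and standard error per ordered deme pair from tabulated
#' pairwise samples. Cells with no samples are `NA` and listed in the
#' `missing` attribute (the vacant-deme situation); cells with one sample get
#' an `NA` standard error.
#'
#' @param samples data frame with `deme_i`, `deme_j`, `branch_length`.
#' @param d deme count.
#' @return List with `mean`, `se`, `n` (all d x d) and `missing`, a two-column
#'   matrix of empty cells.
#' @export
empirical_B <- function(samples, d) {
  mean_m <- matrix(NA_real_, d, d)
  se_m <- matrix(NA_real_, d, d)
  n_m <- matrix(0L, d, d)
  agg_n <- tapply(samples$branch_length,
                  list(factor(samples$deme_i, levels = 1:d),
                       factor(samples$deme_j, levels = 1:d)), length)
  agg_mean <- tapply(samples$branch_length,
                     list(factor(samples$deme_i, levels = 1:d),
                          factor(samples$deme_j, levels = 1:d)), mean)
  agg_sd <- tapply(samples$branch_length,
                   list(factor(samples$deme_i, levels = 1:d),
                        factor(samples$deme_j, levels = 1:d)), stats::sd)
  has <- !is.na(agg_n)
  n_m[has] <- agg_n[has]
  mean_m[has] <- agg_mean[has]
  se_m[has] <- agg_sd[has] / sqrt(agg_n[has])
  missing <- which(n_m == 0L, arr.ind = TRUE)
  colnames(missing) <- c("deme_i", "deme_j")
  list(mean = mean_m, se = se_m, n = n_m, missing = missing)
}

#' Simulated expected branch-length matrix for a sampling-time pair
#'
#' Runs the two-lineage simulator for every ordered deme pair (`i` at `x`,
#' `j` at `y`) and returns the per-cell sample mean and standard error. For
#' `x == y` unordered cells are simulated once and mirrored.
#'
#' @param model a valid [demographic_model()].
#' @param x,y sampling times, `x <= y`.
#' @param n_per_cell replicates per cell.
#' @param seed optional integer seed.
#' @return List with `mean`, `se` (d x d) and `n`.
#' @export
simulate_B_matrix <- function(model, x, y, n_per_cell, seed = NULL) {
  viol <- validate_model(model)
  if (length(viol) > 0) stop(paste(viol, collapse = "; "))
  if (x > y) stop("x must not exceed y")
  if (!is.null(seed)) set.seed(seed)
  out <- empirical_B_cpp(model, x, y, as.integer(n_per_cell))
  attr(out$mean, "x") <- x
  attr(out$mean, "y") <- y
  out
}

grid_coords <- function(rows, cols) {
  cbind(col = rep(1:cols, times = rows), row = rep(1:rows, each = cols))
}

#' Rook-adjacency edge set of a grid demography
#'
#' Directed edges between horizontally and vertically adjacent cells of a
#' `rows x cols` grid (deme index `(row - 1) * cols + col`), plus the
#' same-orientation spatial adjacency between edges used by the smoothness
#' penalty of the inference module.
#'
#' @param rows,cols grid dimensions.
#' @return List with `edges` (two-column matrix `from`, `to`), `coords`
#'   (deme coordinates), and `penalty_pairs` (two-column matrix of edge-index
#'   pairs that are spatially adjacent and share orientation).
#' @export
grid_edge_set <- function(rows, cols) {
  coords <- grid_coords(rows, cols)
  id <- function(r, c) (r - 1) * cols + c
  edges <- NULL
  for (r in 1:rows) for (c in 1:cols) {
    if (c < cols) edges <- rbind(edges, c(id(r, c), id(r, c + 1)),
                                 c(id(r, c + 1), id(r, c)))
    if (r < rows) edges <- rbind(edges, c(id(r, c), id(r + 1, c)),
                                 c(id(r + 1, c), id(r, c)))
  }
  colnames(edges) <- c("from", "to")
  # orientation vector of each directed edge
  disp <- coords[edges[, 2], , drop = FALSE] - coords[edges[, 1], , drop = FALSE]
  n_e <- nrow(edges)
  pairs <- NULL
  for (a in seq_len(n_e - 1)) {
    for (b in (a + 1):n_e) {
      if (all(disp[a, ] == disp[b, ])) {
        dd <- abs(coords[edges[a, 1], ] - coords[edges[b, 1], ])
        if (sum(dd) == 1) pairs <- rbind(pairs, c(a, b))
      }
    }
  }
  list(edges = edges, coords = coords, penalty_pairs = pairs)
}

#' Grid stepping-stone demography with a prescribed migration topology
#'
#' Builds one epoch of a `rows x cols` rook-adjacency grid demography with a
#' large-scale backward-migration topology: `"directional"` elevates all
#' west-to-east edges (lineages trace back from the left boundary to the
#' right), `"converging"` elevates every edge pointing toward the grid
#' center, and `"mixed"` scatters seeded local source/sink/corridor motifs.
#' All remaining edges carry `base_rate`; per-deme coalescence rates are
#' drawn from `gamma_spec` (a range for uniform draws, or a fixed vector).
#'
#' @param rows,cols grid dimensions (`>= 2`).
#' @param topology one of `"directional"`, `"converging"`, `"mixed"`.
#' @param base_rate,feature_rate background and elevated backward migration
#'   rates per generation.
#' @param gamma_spec length-2 range for uniform per-deme coalescence rates,
#'   or a length-d vector of fixed rates.
#' @param seed integer seed controlling the gamma draw and mixed motifs.
#' @param t_start,t_end epoch boundaries.
#' @return An [epoch_params()] with attributes `coords`, `topology`, and
#'   `edges`.
#' @export
make_grid_demography <- function(rows, cols, topology = c("directional",
                                                          "converging",
                                                          "mixed"),
                                 base_rate = 0.1, feature_rate = 1.0,
                                 gamma_spec = c(0.5, 2), seed = 1,
                                 t_start = 0, t_end = Inf) {
  topology <- match.arg(topology)
  if (rows < 2 || cols < 2) stop("rows and cols must be at least 2")
  d <- rows * cols
  coords <- grid_coords(rows, cols)
  es <- grid_edge_set(rows, cols)
  edges <- es$edges
  set.seed(seed)
  w <- rep(base_rate, nrow(edges))
  center <- c((cols + 1) / 2, (rows + 1) / 2)
  dist2 <- function(v) sum((v - center)^2)
  if (topology == "directional") {
    east <- coords[edges[, 2], 1] - coords[edges[, 1], 1] == 1 &
      coords[edges[, 2], 2] == coords[edges[, 1], 2]
    w[east] <- feature_rate
  } else if (topology == "converging") {
    toward <- vapply(seq_len(nrow(edges)), function(e) {
      dist2(coords[edges[e, 2], ]) < dist2(coords[edges[e, 1], ])
    }, logical(1))
    w[toward] <- feature_rate
  } else {
    n_motifs <- max(2L, round(d / 8))
    for (m in seq_len(n_motifs)) {
      cell <- sample.int(d, 1)
      kind <- sample(c("sink", "source", "corridor"), 1)
      if (kind == "sink") {
        w[edges[, 2] == cell] <- feature_rate
      } else if (kind == "source") {
        w[edges[, 1] == cell] <- feature_rate
      } else {
        horiz <- sample(c(TRUE, FALSE), 1)
        run <- if (horiz) {
          r0 <- coords[cell, 2]
          which(coords[edges[, 1], 2] == r0 &
                  coords[edges[, 2], 1] - coords[edges[, 1], 1] == 1)
        } else {
          c0 <- coords[cell, 1]
          which(coords[edges[, 1], 1] == c0 &
                  coords[edges[, 2], 2] - coords[edges[, 1], 2] == 1)
        }
        w[run] <- feature_rate
      }
    }
  }
  M <- matrix(0, d, d)
  M[edges] <- w
  gamma <- if (length(gamma_spec) == 2 && d != 2) {
    stats::runif(d, gamma_spec[1], gamma_spec[2])
  } else if (length(gamma_spec) == d) {
    as.numeric(gamma_spec)
  } else {
    stats::runif(d, gamma_spec[1], gamma_spec[2])
  }
  ep <- epoch_params(t_start, t_end, M = M, gamma = gamma)
  attr(ep, "coords") <- coords
  attr(ep, "topology") <- topology
  attr(ep, "edges") <- edges
  ep
}
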