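# Shared fixtures: random models and independent numerical oracles.

random_adjacency <- function(d, lo = 0.1, hi = 2) {
  M <- matrix(stats::runif(d * d, lo, hi), d, d)
  diag(M) <- 0
  M
}

random_epoch <- function(d, t_start = 0, t_end = Inf, gamma_lo = 0.3,
                         gamma_hi = 2, m_lo = 0.1, m_hi = 2) {
  epoch_params(t_start, t_end, M = random_adjacency(d, m_lo, m_hi),
               gamma = stats::runif(d, gamma_lo, gamma_hi))
}

random_model <- function(d, boundaries = c(0, 1)) {
  K <- length(boundaries)
  eps <- vector("list", K)
  for (k in seq_len(K)) {
    eps[[k]] <- random_epoch(d, boundaries[k],
                             if (k < K) boundaries[k + 1] else Inf)
  }
  demographic_model(eps)
}

full_edge_set <- function(d) {
  idx <- which(diag(d) == 0, arr.ind = TRUE)
  cbind(from = idx[, 1], to = idx[, 2])
}

# First-order upwind method-of-characteristics solver for the contemporaneous
# PDE: with s = elapsed backward time, the vectorized density g(s, b) obeys
#   dg/ds = -2 dg/db - S g,   g(s, 0) = vec(diag(gamma) / 2),
# discretized as g_k^{n+1} = (I - ds S) g_{k-1}^n with ds = db / 2 (unit
# Courant number: the advection shift along each characteristic is exact and
# the reaction is integrated by forward Euler at the upstream point, for a
# global error of O(ds)). Completely independent of the matrix-exponential
# propagators.
upwind_diagonal_oracle <- function(epoch, f0_vals, tau, db, b_max) {
  ops <- build_operators(epoch)
  d2 <- epoch$d^2
  bgrid <- seq(0, b_max, by = db)
  K <- length(bgrid)
  stopifnot(ncol(f0_vals) == K)
  boundary <- numeric(d2)
  eps_idx <- (seq_len(epoch$d) - 1L) * epoch$d + seq_len(epoch$d)
  boundary[eps_idx] <- epoch$gamma / 2
  g <- f0_vals
  ds <- db / 2
  nsteps <- round(tau / ds)
  stopifnot(abs(nsteps * ds - tau) < 1e-9)
  for (n in seq_len(nsteps)) {
    shifted <- cbind(boundary, g[, -K, drop = FALSE])
    g <- shifted - ds * (ops$S %*% shifted)
  }
  list(b = bgrid, values = g)
}

# evaluate a branch_pdf as a d^2 x K matrix of vec'd densities
pdf_vec_grid <- function(f, b) {
  vals <- pdf_evaluate(f, b)
  matrix(vals, f$d^2, length(b))
}
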