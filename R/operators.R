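# Linear operators of the two-lineage process.
#
# vec(.) is column-stacking, so vec(A X t(B)) = (B %x% A) vec(X) and the
# Kronecker-sum operator S = L (x) I + I (x) L + sum_i gamma_i e_i e_i^T
# represents the map X -> L X + X t(L) + diag(gamma) diag{X}.

dense_expm <- function(A) {
  as.matrix(Matrix::expm(Matrix::Matrix(A)))
}

#' Backward-time transition matrix of the migration process
#'
#' Computes `exp(-L * tau)`, the probability that a lineage in deme i at some
#' time is found in deme j a duration `tau` further into the past.
#'
#' @param L migration Laplacian.
#' @param tau nonnegative duration (generations).
#' @return A stochastic d x d matrix (rows sum to 1).
#' @export
transition_matrix <- function(L, tau) {
  if (tau < 0) stop("tau must be nonnegative: propagators are defined backward in time")
  L <- as.matrix(L)
  if (tau == 0) return(diag(nrow(L)))
  P <- dense_expm(-L * tau)
  if (any(P < -1e-12)) {
    warning("transition matrix entries below -1e-12 clipped to 0")
    P[P < 0] <- 0
  }
  P
}

#' Kronecker-sum operators of the joint two-lineage process
#'
#' For an epoch with Laplacian `L` and coalescence rates `gamma`, builds
#' `S = L (x) I + I (x) L + sum_i gamma_i e_i e_i^T` (with `e_i = vec(E_i)`,
#' `E_i` the matrix with a single 1 at `(i, i)`) and `G = sum_i gamma_i e_i`.
#' `S` generates the evolution of vectorized d x d pairwise quantities when
#' both lineages move; `G` injects freshly coalescing mass. The structural
#' identity `S %*% vec(1) = G` (a consequence of the zero row sums of `L`)
#' underlies mass conservation in all downstream propagators.
#'
#' @param epoch an [epoch_params()] object.
#' @return List with `S` (d^2 x d^2), `G` (length d^2), `d`, and `eps_idx`,
#'   the positions of the vec'd diagonal, i.e. `e_i` is the unit vector at
#'   `eps_idx[i]`.
#' @export
build_operators <- function(epoch) {
  L <- epoch$L
  d <- epoch$d
  Id <- diag(d)
  S <- kronecker(Id, L) + kronecker(L, Id)
  eps_idx <- (seq_len(d) - 1L) * d + seq_len(d)
  diag(S)[eps_idx] <- diag(S)[eps_idx] + epoch$gamma
  G <- numeric(d * d)
  G[eps_idx] <- epoch$gamma
  list(S = S, G = G, d = d, eps_idx = eps_idx)
}

#' Equilibrium expected pairwise branch-length matrix
#'
#' Solves `diag(gamma) diag{B*} + L B* + B* t(L) = 2 * 1_{dxd}`, i.e.
#' `vec(B*) = 2 * solve(S, vec(1))`. `B*` is the stationary matrix of expected
#' pairwise branch lengths (twice the expected pairwise coalescence times)
#' under constant rates.
#'
#' @param epoch an [epoch_params()] object.
#' @return d x d matrix `B*`.
#' @export
equilibrium_mean <- function(epoch) {
  ops <- build_operators(epoch)
  d <- ops$d
  Bstar <- try(solve(ops$S, rep(2, d * d)), silent = TRUE)
  if (inherits(Bstar, "try-error") || any(!is.finite(Bstar))) {
    stop("no unique equilibrium (disconnected graph or zero coalescence)")
  }
  matrix(Bstar, d, d)
}

#' Action of a matrix exponential on vectors
#'
#' Computes `exp(-S * tau) %*% V` without forming `exp(-S * tau)` when `S` is
#' large, by scaling and truncated Taylor summation on the vectors (the
#' standard action-based alternative to dense Pade exponentiation). Below
#' `dense_cutoff` rows the dense exponential is used directly.
#'
#' @param S square matrix (typically the d^2 x d^2 Kronecker-sum operator).
#' @param tau nonnegative duration.
#' @param V vector or matrix of column vectors.
#' @param dense_cutoff dimension below which the dense path is taken.
#' @return `exp(-S * tau) %*% V`, same shape as `V`.
#' @export
expm_action <- function(S, tau, V, dense_cutoff = 400) {
  if (tau < 0) stop("tau must be nonnegative")
  v_is_vec <- is.null(dim(V))
  V <- as.matrix(V)
  if (nrow(V) != nrow(S)) stop("shape mismatch between S and V")
  if (tau == 0) return(if (v_is_vec) drop(V) else V)
  if (nrow(S) <= dense_cutoff) {
    out <- dense_expm(-S * tau) %*% V
    return(if (v_is_vec) drop(out) else out)
  }
  A <- -S * tau
  nrmA <- max(colSums(abs(A)))
  s <- max(1L, ceiling(nrmA))
  A <- A / s
  out <- V
  for (step in seq_len(s)) {
    term <- out
    acc <- out
    for (k in 1:60) {
      term <- (A %*% term) / k
      acc <- acc + term
      if (max(abs(term)) <= 1e-16 * max(abs(acc))) break
    }
    out <- acc
  }
  if (v_is_vec) drop(out) else out
}

# exp(-S tau) as a dense matrix (helper shared by propagators)
expm_S <- function(S, tau) {
  if (tau == 0) return(diag(nrow(S)))
  dense_expm(-S * tau)
}
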