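# Survival functions of LPSC (long pairwise shared coalescent / IBD) segment
# lengths. Given pairwise branch length b and per-generation, per-unit-length
# recombination rate r, a random shared segment exceeds length mu with
# probability exp(-r b mu); the survival matrix is therefore the elementwise
# Laplace transform of the branch-length pdf at theta = r * mu. r and mu only
# enter through their product.

# int_0^tau expm(-A s) G ds, robust to singular A (block augmentation)
phi1_integral <- function(A, G, tau) {
  n <- nrow(A)
  Aug <- rbind(cbind(-A * tau, G * tau), matrix(0, 1, n + 1))
  drop(dense_expm(Aug)[1:n, n + 1])
}

#' Survival matrix of LPSC segment lengths from a branch-length pdf
#'
#' `rho^{x,y}(mu) = int exp(-r b mu) f^{x,y}(b) db`, computed exactly from the
#' matrix-exponential segments of `f`.
#'
#' @param f a `"branch_pdf"` with unit per-entry mass.
#' @param r recombination rate per unit length per generation.
#' @param mu segment-length threshold (same length units as `1/r`).
#' @return d x d matrix of survival probabilities with attributes `r`, `mu`,
#'   `x`, `y`; entries in `[0, 1]`, equal to 1 at `mu = 0`.
#' @export
survival_from_pdf <- function(f, r, mu) {
  if (r < 0 || mu < 0) stop("r and mu must be nonnegative")
  rho <- pdf_laplace(f, r * mu)
  structure(rho, r = r, mu = mu, x = f$x, y = f$y)
}

#' Vertical propagation of an LPSC survival matrix
#'
#' `rho^{x - tau, y} = expm(-(L + r mu I) tau) rho^{x, y}`: the shifted
#' Laplacian absorbs the factor `exp(-r mu tau)` induced by the support shift
#' of the underlying pdf.
#'
#' @param rho d x d survival matrix at `(x, y)`.
#' @param L migration Laplacian of the epoch covering the step.
#' @param r,mu recombination rate and length threshold.
#' @param tau nonnegative duration within one epoch.
#' @return Propagated survival matrix.
#' @export
survival_vertical <- function(rho, L, r, mu, tau) {
  if (tau < 0) stop("tau must be nonnegative")
  if (r < 0 || mu < 0) stop("r and mu must be nonnegative")
  out <- exp(-r * mu * tau) * (transition_matrix(L, tau) %*% as.matrix(rho))
  structure(out, r = r, mu = mu)
}

#' Diagonal propagation of an LPSC survival matrix
#'
#' For contemporaneous pairs, with `S_mu = S + 2 r mu I`,
#' `vec(rho_out) = [I - expm(-S_mu tau)] S_mu^{-1} G + expm(-S_mu tau)
#' vec(rho_old)`. The first term is the transform of freshly coalescing pairs
#' (coefficient 1 under the normalized fresh-branch density; the printed
#' coefficient 2 is available via `paper_literal`). At `mu = 0` the identity
#' `S vec(1) = G` makes unit survival an exact fixed point.
#'
#' @param rho_old d x d survival matrix at `(x, x)`.
#' @param epoch the [epoch_params()] covering the step.
#' @param r,mu recombination rate and length threshold.
#' @param tau nonnegative duration within the epoch.
#' @param paper_literal if TRUE use the printed coefficient 2 on the fresh
#'   term.
#' @return Propagated survival matrix.
#' @export
survival_diagonal <- function(rho_old, epoch, r, mu, tau,
                              paper_literal = FALSE) {
  if (tau < 0) stop("tau must be nonnegative")
  if (r < 0 || mu < 0) stop("r and mu must be nonnegative")
  ops <- build_operators(epoch)
  Smu <- ops$S + 2 * r * mu * diag(epoch$d^2)
  coef <- if (paper_literal) 2 else 1
  fresh <- coef * phi1_integral(Smu, ops$G, tau)
  out <- fresh + expm_S(Smu, tau) %*% as.vector(as.matrix(rho_old))
  structure(matrix(out, epoch$d, epoch$d), r = r, mu = mu)
}

#' Stationary LPSC survival matrix
#'
#' Limit of the diagonal propagation, `vec(rho*) = S_mu^{-1} G`; for a single
#' deme this is the classical `gamma / (gamma + 2 r mu)`.
#'
#' @param epoch an [epoch_params()] object.
#' @param r,mu recombination rate and length threshold.
#' @return d x d stationary survival matrix.
#' @export
survival_stationary <- function(epoch, r, mu) {
  ops <- build_operators(epoch)
  Smu <- ops$S + 2 * r * mu * diag(epoch$d^2)
  structure(matrix(solve(Smu, ops$G), epoch$d, epoch$d), r = r, mu = mu)
}

#' LPSC survival matrix for an arbitrary sampling-time pair
#'
#' Chains stationary start, diagonal and vertical survival propagation across
#' epochs, mirroring [branch_mean_xy()].
#'
#' @param model a valid [demographic_model()].
#' @param x,y sampling times, `x <= y`.
#' @param r,mu recombination rate and length threshold.
#' @return d x d survival matrix with attributes `r`, `mu`, `x`, `y`.
#' @export
branch_survival_xy <- function(model, x, y, r, mu) {
  if (x > y) stop("x must not exceed y")
  K <- length(model$epochs)
  term <- model$epochs[[K]]
  top <- max(y, term$t_start)
  rho <- survival_stationary(term, r, mu)
  for (st in chain_schedule(model, top, y)) {
    rho <- survival_diagonal(rho, model$epochs[[st$epoch]], r, mu, st$tau)
  }
  for (st in chain_schedule(model, y, x)) {
    rho <- survival_vertical(rho, model$epochs[[st$epoch]]$L, r, mu, st$tau)
  }
  structure(rho, r = r, mu = mu, x = x, y = y)
}

#' Consistency check of the composed (horizontal) survival relations
#'
#' Evaluates the three identities obtained by composing the vertical and
#' diagonal survival propagators for a three-epoch model.
#'
#' @param model a three-epoch [demographic_model()].
#' @param r,mu recombination rate and length threshold.
#' @param rho optional named list overriding computed matrices (`r00`, `r01`,
#'   `r11`, `r12`, `r02`) for sensitivity checks.
#' @param paper_literal use the printed coefficient 2 on the fresh terms.
#' @return List with per-identity max-abs residuals and their maximum.
#' @export
survival_horizontal_check <- function(model, r, mu, rho = NULL,
                                      paper_literal = FALSE) {
  if (length(model$epochs) != 3) stop("three-epoch model required")
  t0 <- model$epochs[[1]]$t_start
  t1 <- model$epochs[[2]]$t_start
  t2 <- model$epochs[[3]]$t_start
  tau0 <- t1 - t0
  tau1 <- t2 - t1
  e0 <- model$epochs[[1]]
  e1 <- model$epochs[[2]]
  need <- list(r00 = c(t0, t0), r01 = c(t0, t1), r11 = c(t1, t1),
               r12 = c(t1, t2), r02 = c(t0, t2))
  RR <- lapply(names(need), function(nm) {
    if (!is.null(rho[[nm]])) as.matrix(rho[[nm]]) else {
      unname(as.matrix(branch_survival_xy(model, need[[nm]][1],
                                          need[[nm]][2], r, mu)))
    }
  })
  names(RR) <- names(need)
  ops0 <- build_operators(e0)
  ops1 <- build_operators(e1)
  d2 <- model$d^2
  Smu0 <- ops0$S + 2 * r * mu * diag(d2)
  Smu1 <- ops1$S + 2 * r * mu * diag(d2)
  coef <- if (paper_literal) 2 else 1
  fresh0 <- coef * phi1_integral(Smu0, ops0$G, tau0)
  fresh1 <- coef * phi1_integral(Smu1, ops1$G, tau1)
  E0 <- expm_S(Smu0, tau0)
  E1 <- expm_S(Smu1, tau1)
  # expm(+L_mu tau) = inverse of the vertical survival propagator
  Pm0inv <- solve(exp(-r * mu * tau0) * transition_matrix(e0$L, tau0))
  Pm1inv <- solve(exp(-r * mu * tau1) * transition_matrix(e1$L, tau1))

  lhs_a <- as.vector(RR$r00)
  rhs_a <- fresh0 + drop(E0 %*% as.vector(Pm0inv %*% RR$r01))
  lhs_b <- as.vector(RR$r11)
  rhs_b <- fresh1 + drop(E1 %*% as.vector(Pm1inv %*% RR$r12))
  lhs_c <- as.vector(Pm0inv %*% RR$r01)
  rhs_c <- fresh1 + drop(E1 %*% as.vector(Pm1inv %*% Pm0inv %*% RR$r02))
  res <- c(a = max(abs(lhs_a - rhs_a)),
           b = max(abs(lhs_b - rhs_b)),
           c = max(abs(lhs_c - rhs_c)))
  list(residuals = res, max = max(res))
}
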