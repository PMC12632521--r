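# Expected pairwise branch-length matrices.
#
# Orientation convention: rows index the deme of the more recently sampled
# lineage (time x), columns the deme of the older lineage (time y >= x).
# Vertical propagation acts on the left (row/lineage-1 side) only.

#' Vertical propagation of an expected branch-length matrix
#'
#' `B^{x - tau, y} = expm(-L tau) B^{x, y} + tau * 1_{dxd}`: while only the
#' more recent lineage moves back in time no coalescence can occur, so the
#' expectation is mixed by the migration transition matrix and grows by the
#' elapsed duration.
#'
#' @param B d x d matrix of expected pairwise branch lengths at `(x, y)`.
#' @param L migration Laplacian of the epoch covering `[x - tau, x]`.
#' @param tau nonnegative duration within one epoch.
#' @return The propagated d x d matrix at `(x - tau, y)`.
#' @export
mean_vertical <- function(B, L, tau) {
  if (tau < 0) stop("tau must be nonnegative")
  transition_matrix(L, tau) %*% as.matrix(B) + tau
}

#' Diagonal propagation of an expected branch-length matrix
#'
#' For contemporaneous pairs, `vec(B^{x - tau} - B*) = expm(-S tau)
#' vec(B^{x} - B*)` with `B*` the epoch's equilibrium matrix
#' ([equilibrium_mean()]): deviations from equilibrium decay under the
#' two-lineage Kronecker-sum generator.
#'
#' @param B_old d x d matrix at `(x, x)`.
#' @param epoch the [epoch_params()] covering `[x - tau, x]`.
#' @param tau nonnegative duration within the epoch.
#' @return The propagated d x d matrix at `(x - tau, x - tau)`.
#' @export
mean_diagonal <- function(B_old, epoch, tau) {
  if (tau < 0) stop("tau must be nonnegative")
  if (tau == 0) return(as.matrix(B_old))
  ops <- build_operators(epoch)
  Bstar <- equilibrium_mean(epoch)
  dev <- expm_S(ops$S, tau) %*% as.vector(as.matrix(B_old) - Bstar)
  Bstar + matrix(dev, epoch$d, epoch$d)
}

#' Expected pairwise branch-length matrix for a sampling-time pair
#'
#' Chains diagonal then vertical propagation from the terminal epoch's
#' equilibrium down to the requested sampling times, decomposing the move
#' per epoch.
#'
#' @param model a valid [demographic_model()].
#' @param x,y sampling times, `x <= y`, backward from the present.
#' @return d x d matrix with attributes `x` and `y`.
#' @export
branch_mean_xy <- function(model, x, y) {
  if (x > y) stop("x must not exceed y")
  K <- length(model$epochs)
  term <- model$epochs[[K]]
  top <- max(y, term$t_start)
  B <- equilibrium_mean(term)
  for (st in chain_schedule(model, top, y)) {
    B <- mean_diagonal(B, model$epochs[[st$epoch]], st$tau)
  }
  for (st in chain_schedule(model, y, x)) {
    B <- mean_vertical(B, model$epochs[[st$epoch]]$L, st$tau)
  }
  attr(B, "x") <- x
  attr(B, "y") <- y
  B
}

#' Consistency check of the composed (horizontal) mean relations
#'
#' Evaluates the three identities obtained by composing the vertical and
#' diagonal mean propagators for a three-epoch model (the relations in which
#' the older sampling time moves). The second identity is implemented in the
#' form implied by that composition, which links `B^{t1,t1}` to `B^{t1,t2}`;
#' see the methods vignette for the rationale.
#'
#' @param model a three-epoch [demographic_model()].
#' @param B optional named list overriding computed matrices (`B00`, `B01`,
#'   `B11`, `B12`, `B02`) for sensitivity checks.
#' @return List with per-identity max-abs residuals and their maximum.
#' @export
mean_horizontal_check <- function(model, B = NULL) {
  if (length(model$epochs) != 3) stop("three-epoch model required")
  t0 <- model$epochs[[1]]$t_start
  t1 <- model$epochs[[2]]$t_start
  t2 <- model$epochs[[3]]$t_start
  tau0 <- t1 - t0
  tau1 <- t2 - t1
  e0 <- model$epochs[[1]]
  e1 <- model$epochs[[2]]
  need <- list(B00 = c(t0, t0), B01 = c(t0, t1), B11 = c(t1, t1),
               B12 = c(t1, t2), B02 = c(t0, t2))
  BB <- lapply(names(need), function(nm) {
    if (!is.null(B[[nm]])) as.matrix(B[[nm]]) else {
      unname(branch_mean_xy(model, need[[nm]][1], need[[nm]][2]))
    }
  })
  names(BB) <- names(need)
  P0inv <- solve(transition_matrix(e0$L, tau0))
  P1inv <- solve(transition_matrix(e1$L, tau1))
  ops0 <- build_operators(e0)
  ops1 <- build_operators(e1)
  B0s <- equilibrium_mean(e0)
  B1s <- equilibrium_mean(e1)
  E0 <- expm_S(ops0$S, tau0)
  E1 <- expm_S(ops1$S, tau1)

  lhs_a <- as.vector(BB$B00 - B0s)
  rhs_a <- drop(E0 %*% as.vector(P0inv %*% BB$B01 - tau0 - B0s))
  lhs_b <- as.vector(BB$B11 - B1s)
  rhs_b <- drop(E1 %*% as.vector(P1inv %*% BB$B12 - tau1 - B1s))
  lhs_c <- as.vector(P0inv %*% BB$B01 - tau0 - B1s)
  rhs_c <- drop(E1 %*% as.vector(P1inv %*% P0inv %*% BB$B02 -
                                   (t2 - t0) - B1s))
  res <- c(a = max(abs(lhs_a - rhs_a)),
           b = max(abs(lhs_b - rhs_b)),
           c = max(abs(lhs_c - rhs_c)))
  list(residuals = res, max = max(res))
}
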