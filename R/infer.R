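# Sequential inference of per-epoch backward migration rates (and optionally
# coalescence rates) from estimated expected pairwise branch-length matrices.
#
# The vertical relation B_young = expm(-L tau) B_old + tau * 1 depends only on
# the migration Laplacian, so each epoch's edge weights are fit by nonlinear
# least squares on the relative-error matrix, with an optional smoothness
# penalty on spatially adjacent same-orientation edges and nonnegativity
# enforced through a log parameterization. Jacobians use the Frechet
# derivative of the matrix exponential (block-matrix identity).

# L(w) on a declared directed edge set
laplacian_from_weights <- function(w, edge_set, d) {
  L <- matrix(0, d, d)
  for (e in seq_len(nrow(edge_set))) {
    i <- edge_set[e, 1]; j <- edge_set[e, 2]
    L[i, i] <- L[i, i] + w[e]
    L[i, j] <- L[i, j] - w[e]
  }
  L
}

# Frechet derivative of expm at A in direction E (top-right block trick)
expm_frechet <- function(A, E) {
  d <- nrow(A)
  blk <- rbind(cbind(A, E), cbind(matrix(0, d, d), A))
  dense_expm(blk)[seq_len(d), d + seq_len(d), drop = FALSE]
}

# residuals and Jacobian for a set of vertical relations sharing one L.
# relations: list of list(B_older, B_hat, cells (logical matrix))
vertical_residuals <- function(theta, relations, tau, edge_set, d,
                               lambda, penalty_pairs, jacobian = FALSE) {
  # clamp to keep expm well-posed during unbounded LM steps
  w <- exp(pmin(pmax(theta, log(1e-10)), log(1e4)))
  L <- laplacian_from_weights(w, edge_set, d)
  A <- -tau * L
  P <- dense_expm(A)
  res <- NULL
  rows_per_rel <- list()
  for (rel in relations) {
    pred <- P %*% rel$B_older + tau
    r <- (pred - rel$B_hat) / rel$B_hat
    res <- c(res, r[rel$cells])
  }
  n_pen <- if (lambda > 0 && !is.null(penalty_pairs)) nrow(penalty_pairs) else 0
  if (n_pen > 0) {
    res <- c(res, sqrt(lambda) *
               (w[penalty_pairs[, 1]] - w[penalty_pairs[, 2]]))
  }
  if (!jacobian) return(res)
  n_e <- nrow(edge_set)
  J <- matrix(0, length(res), n_e)
  for (e in seq_len(n_e)) {
    i <- edge_set[e, 1]; j <- edge_set[e, 2]
    D <- matrix(0, d, d)
    D[i, i] <- 1; D[i, j] <- -1
    dP <- expm_frechet(A, -tau * D)
    row0 <- 0
    for (rel in relations) {
      dr <- (dP %*% rel$B_older) / rel$B_hat
      vals <- dr[rel$cells]
      J[row0 + seq_along(vals), e] <- vals
      row0 <- row0 + length(vals)
    }
    if (n_pen > 0) {
      pe <- sqrt(lambda) * ((penalty_pairs[, 1] == e) -
                              (penalty_pairs[, 2] == e))
      J[row0 + seq_len(n_pen), e] <- pe
    }
    J[, e] <- J[, e] * w[e]   # chain rule for theta = log w
  }
  J
}

fit_L_vertical <- function(relations, tau, edge_set, d, lambda = 0,
                           penalty_pairs = NULL, w_init = 0.5,
                           control = list()) {
  for (rel in relations) {
    if (any(rel$B_hat[rel$cells] <= 0)) {
      stop("nonpositive entries in the observed mean matrix: relative error undefined")
    }
  }
  n_e <- nrow(edge_set)
  w0 <- rep_len(w_init, n_e)
  ctrl <- utils::modifyList(list(maxiter = 200, ftol = 1e-15,
                                 ptol = 1e-15, gtol = 0), control)
  fn <- function(theta) vertical_residuals(theta, relations, tau, edge_set,
                                           d, lambda, penalty_pairs)
  jac <- function(theta) vertical_residuals(theta, relations, tau, edge_set,
                                            d, lambda, penalty_pairs,
                                            jacobian = TRUE)
  # on noisy data LM may exhaust maxiter; the best iterate is kept and the
  # converged flag reports it, so the iteration-count warning is muffled
  fit <- withCallingHandlers(
    minpack.lm::nls.lm(par = log(w0), fn = fn, jac = jac,
                       control = do.call(minpack.lm::nls.lm.control, ctrl)),
    warning = function(w) {
      if (grepl("maxiter", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  w <- exp(pmin(pmax(fit$par, log(1e-10)), log(1e4)))
  L_hat <- laplacian_from_weights(w, edge_set, d)
  data_res <- vertical_residuals(fit$par, relations, tau, edge_set, d,
                                 0, NULL)
  list(w = w, L = L_hat, M = adjacency_from_laplacian(L_hat),
       edge_set = edge_set, lambda = lambda,
       objective = sum(fn(fit$par)^2), data_sse = sum(data_res^2),
       converged = fit$info %in% 1:4, info = fit$info,
       message = fit$message, niter = fit$niter)
}

#' Infer an epoch's migration Laplacian from a vertical relation
#'
#' Fits nonnegative backward-migration edge weights `w` on a declared edge
#' set by minimizing the summed squared relative error between the vertical
#' prediction `expm(-L(w) tau) B_older + tau * 1` and the observed matrix
#' `B_hat_younger`, plus `lambda` times a smoothness penalty
#' `sum (w_e - w_e')^2` over the supplied edge pairs. Because the vertical
#' relation involves no coalescence rates, the fit is decoupled from local
#' effective population sizes and recovers rates on an absolute scale.
#'
#' @param B_older d x d expected branch-length matrix at the older sampling
#'   pair (complete; impute first if needed).
#' @param B_hat_younger d x d observed matrix at the younger pair (entries
#'   must be positive where used).
#' @param tau epoch duration separating the two sampling pairs (`> 0`).
#' @param edge_set two-column matrix of directed edges `(from, to)` allowed
#'   to carry migration.
#' @param lambda smoothness-penalty weight.
#' @param penalty_pairs two-column matrix of edge-index pairs entering the
#'   penalty (e.g. from [grid_edge_set()]).
#' @param cells optional logical matrix restricting which entries enter the
#'   loss (used by cross-validation).
#' @param w_init uniform deterministic initialization of the edge weights.
#' @param control list passed to [minpack.lm::nls.lm.control()].
#' @return List with the fitted `w`, `L`, `M`, objective values and
#'   convergence diagnostics.
#' @export
infer_L_vertical <- function(B_older, B_hat_younger, tau, edge_set,
                             lambda = 0, penalty_pairs = NULL, cells = NULL,
                             w_init = 0.5, control = list()) {
  if (tau <= 0) stop("tau must be positive")
  B_older <- as.matrix(B_older)
  B_hat_younger <- as.matrix(B_hat_younger)
  d <- nrow(B_older)
  if (is.null(cells)) cells <- matrix(TRUE, d, d)
  cells <- cells & is.finite(B_hat_younger)
  rel <- list(list(B_older = B_older, B_hat = B_hat_younger, cells = cells))
  fit_L_vertical(rel, tau, edge_set, d, lambda, penalty_pairs, w_init,
                 control)
}

#' Refine a mean-matrix estimate through a fitted vertical relation
#'
#' Projects the (possibly noisy) direct estimate onto the fitted model:
#' `B_refined = expm(-L_hat tau) B_older + tau * 1`, the form consistent with
#' the vertical propagator. The refined matrix feeds the next, older step of
#' the sequential protocol.
#'
#' @param B_older complete matrix at the older sampling pair.
#' @param L_hat fitted Laplacian.
#' @param tau epoch duration.
#' @return Refined d x d matrix at the younger pair.
#' @export
refine_B <- function(B_older, L_hat, tau) {
  mean_vertical(as.matrix(B_older), L_hat, tau)
}

#' Cross-validate the smoothness-penalty weight
#'
#' Randomly partitions the observed matrix cells into folds; for each
#' candidate `lambda`, fits the vertical relation on the training cells and
#' scores the held-out mean squared relative error. Deterministic given
#' `seed`.
#'
#' @param relations list of relations, each `list(B_older, B_hat, cells)`.
#' @param tau epoch duration.
#' @param edge_set,penalty_pairs as in [infer_L_vertical()].
#' @param lambda_grid candidate penalty weights.
#' @param folds number of folds (`>= 2` unless the grid has one value).
#' @param seed integer seed for the fold assignment.
#' @param one_se if TRUE pick the largest lambda within one standard error of
#'   the minimum.
#' @param w_init,control as in [infer_L_vertical()].
#' @return List with `lambda` (the choice) and `table` (lambda, mean and SE
#'   of held-out error).
#' @export
cross_validate_lambda <- function(relations, tau, edge_set, lambda_grid,
                                  penalty_pairs = NULL, folds = 5, seed = 1,
                                  one_se = FALSE, w_init = 0.5,
                                  control = list()) {
  lambda_grid <- sort(unique(lambda_grid))
  if (length(lambda_grid) == 1) {
    return(list(lambda = lambda_grid,
                table = data.frame(lambda = lambda_grid, cv_error = NA,
                                   cv_se = NA)))
  }
  if (folds < 2) stop("at least 2 folds required")
  d <- nrow(relations[[1]]$B_older)
  set.seed(seed)
  fold_of <- lapply(relations, function(rel) {
    idx <- which(rel$cells)
    f <- rep_len(seq_len(folds), length(idx))
    out <- matrix(NA_integer_, d, d)
    out[idx] <- sample(f)
    out
  })
  err <- matrix(NA_real_, length(lambda_grid), folds)
  for (li in seq_along(lambda_grid)) {
    for (fo in seq_len(folds)) {
      train <- lapply(seq_along(relations), function(ri) {
        rel <- relations[[ri]]
        rel$cells <- rel$cells & !is.na(fold_of[[ri]]) &
          fold_of[[ri]] != fo
        rel
      })
      if (any(vapply(train, function(r) sum(r$cells) == 0, logical(1)))) {
        stop("cross-validation fold with empty training set")
      }
      fit <- fit_L_vertical(train, tau, edge_set, d, lambda_grid[li],
                            penalty_pairs, w_init, control)
      P <- dense_expm(-tau * fit$L)
      held <- unlist(lapply(seq_along(relations), function(ri) {
        rel <- relations[[ri]]
        test_cells <- rel$cells & !is.na(fold_of[[ri]]) &
          fold_of[[ri]] == fo
        pred <- P %*% rel$B_older + tau
        ((pred - rel$B_hat) / rel$B_hat)[test_cells]
      }))
      err[li, fo] <- mean(held^2)
    }
  }
  cv_mean <- rowMeans(err)
  cv_se <- apply(err, 1, stats::sd) / sqrt(folds)
  # ties at numerical zero resolve toward less regularization
  best <- which(cv_mean <= min(cv_mean) + 1e-12)[1]
  pick <- if (one_se) {
    max(which(cv_mean <= cv_mean[best] + cv_se[best]))
  } else best
  list(lambda = lambda_grid[pick],
       table = data.frame(lambda = lambda_grid, cv_error = cv_mean,
                          cv_se = cv_se))
}

#' Impute a mean matrix under the equilibrium assumption
#'
#' For the oldest sampling slice the protocol assumes lineages older than the
#' slice evolved at migration-drift equilibrium: the complete matrix is the
#' equilibrium solution `diag(gamma) diag{B} + L B + B t(L) = 2 * 1`. Missing
#' cells are filled by fitting equilibrium rates `(L_inf, gamma_inf)` to the
#' observed cells by squared relative error.
#'
#' @param B_partial d x d matrix with `NA` in unobserved cells.
#' @param edge_set directed edges allowed to carry migration.
#' @param lambda,penalty_pairs optional smoothness penalty on edge weights.
#' @param w_init,gamma_init deterministic initializations.
#' @param control list passed to [minpack.lm::nls.lm.control()].
#' @return List with `B` (completed matrix; observed cells kept), `L_inf`,
#'   `gamma_inf`, `w`, `fitted` (FALSE when nothing was missing).
#' @export
impute_B_equilibrium <- function(B_partial, edge_set, lambda = 0,
                                 penalty_pairs = NULL, w_init = 0.5,
                                 gamma_init = 1, control = list()) {
  B_partial <- as.matrix(B_partial)
  d <- nrow(B_partial)
  obs <- is.finite(B_partial)
  if (all(obs)) {
    return(list(B = B_partial, fitted = FALSE))
  }
  if (!any(obs)) stop("no observed cells to constrain the equilibrium fit")
  if (sum(obs) < d) {
    warning("fewer observed cells than demes: equilibrium fit may be underdetermined")
  }
  n_e <- nrow(edge_set)
  eps_idx <- (seq_len(d) - 1L) * d + seq_len(d)
  theta0 <- c(rep(log(w_init), n_e), rep(log(gamma_init), d))
  resid_fn <- function(theta, jacobian = FALSE) {
    theta <- pmin(pmax(theta, log(1e-8)), log(1e4))
    w <- exp(theta[seq_len(n_e)])
    gam <- exp(theta[n_e + seq_len(d)])
    L <- laplacian_from_weights(w, edge_set, d)
    ep <- epoch_params(0, Inf, L = L, gamma = gam)
    ops <- build_operators(ep)
    vB <- solve(ops$S, rep(2, d * d))
    Bstar <- matrix(vB, d, d)
    res <- ((Bstar - B_partial) / B_partial)[obs]
    n_pen <- if (lambda > 0 && !is.null(penalty_pairs)) {
      nrow(penalty_pairs)
    } else 0
    if (n_pen > 0) {
      res <- c(res, sqrt(lambda) *
                 (w[penalty_pairs[, 1]] - w[penalty_pairs[, 2]]))
    }
    if (!jacobian) return(res)
    # dvec(B*) = -S^{-1} dS vec(B*); one multi-RHS solve per iteration
    RHS <- matrix(0, d * d, n_e + d)
    for (e in seq_len(n_e)) {
      i <- edge_set[e, 1]; j <- edge_set[e, 2]
      Dm <- matrix(0, d, d)
      Dm[i, ] <- Bstar[i, ] - Bstar[j, ]
      Dm2 <- matrix(0, d, d)
      Dm2[, i] <- Bstar[, i] - Bstar[, j]
      RHS[, e] <- as.vector(Dm + Dm2)
    }
    for (i in seq_len(d)) {
      RHS[eps_idx[i], n_e + i] <- Bstar[i, i]
    }
    dB <- -solve(ops$S, RHS)
    J <- matrix(0, length(res), n_e + d)
    obs_scale <- 1 / B_partial[obs]
    J[seq_len(sum(obs)), ] <- dB[as.vector(obs), , drop = FALSE] * obs_scale
    if (n_pen > 0) {
      for (e in seq_len(n_e)) {
        J[sum(obs) + seq_len(n_pen), e] <- sqrt(lambda) *
          ((penalty_pairs[, 1] == e) - (penalty_pairs[, 2] == e))
      }
    }
    sweep(J, 2, exp(theta), `*`)
  }
  n_par <- n_e + d
  ridge <- 0
  if (sum(obs) + (if (lambda > 0 && !is.null(penalty_pairs)) {
    nrow(penalty_pairs)
  } else 0) < n_par) {
    warning("underdetermined equilibrium fit: returning an init-anchored regularized solution")
    ridge <- 1e-4
  }
  fn_full <- function(theta) {
    res <- resid_fn(theta)
    if (ridge > 0) res <- c(res, ridge * (theta - theta0))
    res
  }
  jac_full <- function(theta) {
    J <- resid_fn(theta, jacobian = TRUE)
    if (ridge > 0) J <- rbind(J, ridge * diag(n_par))
    J
  }
  ctrl <- utils::modifyList(list(maxiter = 300, ftol = 1e-14, ptol = 1e-14),
                            control)
  fit <- minpack.lm::nls.lm(par = theta0, fn = fn_full, jac = jac_full,
                            control = do.call(minpack.lm::nls.lm.control,
                                              ctrl))
  par <- pmin(pmax(fit$par, log(1e-8)), log(1e4))
  w <- exp(par[seq_len(n_e)])
  gam <- exp(par[n_e + seq_len(d)])
  L_inf <- laplacian_from_weights(w, edge_set, d)
  Bfit <- equilibrium_mean(epoch_params(0, Inf, L = L_inf, gamma = gam))
  B_out <- B_partial
  B_out[!obs] <- Bfit[!obs]
  list(B = B_out, L_inf = L_inf, gamma_inf = gam, w = w, fitted = TRUE,
       converged = fit$info %in% 1:4)
}

#' Infer coalescence rates from a diagonal relation
#'
#' With the epoch's Laplacian fixed at `L_hat`, fits per-deme coalescence
#' rates `gamma` by squared relative error between the observed
#' contemporaneous matrix and the diagonal prediction
#' `B*(gamma) + reshape(expm(-S(gamma) tau) vec(B_older - B*(gamma)))`.
#' Demes appearing in no observed cell are unidentifiable and returned as
#' `NA`.
#'
#' @param B_hat_t1t1 observed d x d matrix at the younger contemporaneous
#'   pair (NA allowed).
#' @param B_t2t2 complete matrix at the older contemporaneous pair.
#' @param L_hat fixed epoch Laplacian (from the migration step).
#' @param tau epoch duration (`> 0`).
#' @param gamma_init deterministic initialization.
#' @param control list passed to [minpack.lm::nls.lm.control()].
#' @return List with `gamma` (NA for unidentifiable demes), fit diagnostics.
#' @export
infer_gamma_diagonal <- function(B_hat_t1t1, B_t2t2, L_hat, tau,
                                 gamma_init = 1, control = list()) {
  if (tau <= 0) stop("tau must be positive")
  B_hat_t1t1 <- as.matrix(B_hat_t1t1)
  B_t2t2 <- as.matrix(B_t2t2)
  d <- nrow(B_t2t2)
  obs <- is.finite(B_hat_t1t1)
  identifiable <- vapply(seq_len(d), function(i) {
    any(obs[i, ]) || any(obs[, i])
  }, logical(1))
  if (!any(identifiable)) stop("no deme is identifiable from the data")
  resid_fn <- function(theta) {
    gam <- rep(1, d)
    gam[identifiable] <- exp(pmin(pmax(theta, log(1e-8)), log(1e4)))
    ep <- epoch_params(0, Inf, L = L_hat, gamma = gam)
    pred <- mean_diagonal(B_t2t2, ep, tau)
    ((pred - B_hat_t1t1) / B_hat_t1t1)[obs]
  }
  ctrl <- utils::modifyList(list(maxiter = 200, ftol = 1e-14, ptol = 1e-14),
                            control)
  fit <- minpack.lm::nls.lm(par = rep(log(gamma_init), sum(identifiable)),
                            fn = resid_fn,
                            control = do.call(minpack.lm::nls.lm.control,
                                              ctrl))
  gamma <- rep(NA_real_, d)
  gamma[identifiable] <- exp(fit$par)
  list(gamma = gamma, identifiable = identifiable,
       objective = sum(fit$fvec^2), converged = fit$info %in% 1:4)
}

#' Sequential migration-rate inference across epochs
#'
#' Implements the time-stratified protocol: starting from the oldest sampling
#' slice (imputed under the equilibrium assumption if cells are missing),
#' each epoch's Laplacian is fit from the vertical relation(s) linking the
#' previous step's refined matrix to the observed matrices of the next
#' younger slice, and the estimates are refined through the fitted relation
#' before the next step. When several vertical relations constrain the same
#' epoch (e.g. matrices observed against more than one older slice) they are
#' fit jointly by stacked least squares with equal weight.
#'
#' @param B_hat named list of observed matrices; each element needs
#'   attributes `x` and `y` giving its sampling-time pair (see
#'   [simulate_B_matrix()]), e.g. the pairs `(t2, t2)`, `(t1, t2)`,
#'   `(t0, t2)` for a three-slice design.
#' @param times sorted sampling times `t0 < t1 < ... < tK` aligned with the
#'   epoch boundaries of the model scaffold.
#' @param edge_set directed edges allowed to carry migration.
#' @param lambda single penalty weight, or a grid to be selected per epoch by
#'   cross-validation.
#' @param penalty_pairs edge-index pairs for the smoothness penalty.
#' @param impute if TRUE, complete the oldest slice with
#'   [impute_B_equilibrium()]; otherwise missing cells are an error.
#' @param cv_folds,seed cross-validation controls.
#' @param w_init,control optimizer controls, as in [infer_L_vertical()].
#' @return An object of class `"serial_mig_fit"`; see [coef.serial_mig_fit()]
#'   and the print/summary/plot methods.
#' @export
sequential_migration_inference <- function(B_hat, times, edge_set,
                                           lambda = 0, penalty_pairs = NULL,
                                           impute = FALSE, cv_folds = 5,
                                           seed = 1, w_init = 0.5,
                                           control = list()) {
  times <- sort(times)
  K <- length(times)
  get_B <- function(x, y) {
    for (B in B_hat) {
      ax <- attr(B, "x"); ay <- attr(B, "y")
      if (!is.null(ax) && !is.null(ay) &&
          isTRUE(all.equal(c(ax, ay), c(x, y)))) {
        return(as.matrix(B))
      }
    }
    NULL
  }
  tK <- times[K]
  B_top <- get_B(tK, tK)
  if (is.null(B_top)) stop("observed matrix at the oldest slice is required")
  if (any(!is.finite(B_top))) {
    if (!impute) {
      vac <- which(!apply(is.finite(B_top), 1, any))
      stop(paste("missing cells at the oldest slice; vacant demes:",
                 paste(vac, collapse = ", "), "- set impute = TRUE"))
    }
    imp <- impute_B_equilibrium(B_top, edge_set, lambda = max(lambda[1], 0),
                                penalty_pairs = penalty_pairs,
                                w_init = w_init)
    B_top <- imp$B
  } else imp <- NULL
  d <- nrow(B_top)
  B_ref <- list()
  B_ref[[key_xy(tK, tK)]] <- B_top
  steps <- list()
  if (K == 1) {
    out <- structure(list(L_hat = list(), w = NULL, edge_set = edge_set,
                          times = times, B_refined = B_ref, steps = steps,
                          imputation = imp, d = d),
                     class = "serial_mig_fit")
    return(out)
  }
  for (k in (K - 1):1) {
    tau <- times[k + 1] - times[k]
    relations <- list()
    for (yc in times[seq(k + 1, K)]) {
      Bo <- B_ref[[key_xy(times[k + 1], yc)]]
      Bh <- get_B(times[k], yc)
      if (!is.null(Bo) && !is.null(Bh)) {
        cells <- is.finite(Bh)
        relations[[length(relations) + 1]] <-
          list(B_older = Bo, B_hat = Bh, cells = cells, y = yc)
      }
    }
    if (length(relations) == 0) {
      stop(sprintf("no observed matrix constrains epoch [%g, %g)",
                   times[k], times[k + 1]))
    }
    cv <- NULL
    lam <- lambda
    if (length(lambda) > 1) {
      cv <- cross_validate_lambda(relations, tau, edge_set, lambda,
                                  penalty_pairs, folds = cv_folds,
                                  seed = seed, w_init = w_init,
                                  control = control)
      lam <- cv$lambda
    }
    fit <- fit_L_vertical(relations, tau, edge_set, d, lam, penalty_pairs,
                          w_init, control)
    for (rel in relations) {
      B_ref[[key_xy(times[k], rel$y)]] <- refine_B(rel$B_older, fit$L, tau)
    }
    steps[[length(steps) + 1]] <- list(epoch = k, t_start = times[k],
                                       t_end = times[k + 1], fit = fit,
                                       cv = cv, lambda = lam,
                                       n_relations = length(relations))
  }
  steps <- rev(steps)   # oldest-first fitting, report youngest-first
  L_hat <- lapply(steps, function(s) s$fit$L)
  names(L_hat) <- vapply(steps, function(s) {
    sprintf("epoch_%g_%g", s$t_start, s$t_end)
  }, character(1))
  w <- vapply(steps, function(s) s$fit$w, numeric(nrow(edge_set)))
  colnames(w) <- names(L_hat)
  structure(list(L_hat = L_hat, w = w, edge_set = edge_set, times = times,
                 B_refined = B_ref, steps = steps, imputation = imp, d = d),
            class = "serial_mig_fit")
}

key_xy <- function(x, y) sprintf("%.10g|%.10g", x, y)

#' @exportS3Method print serial_mig_fit
print.serial_mig_fit <- function(x, ...) {
  cat(sprintf("Sequential migration-rate fit: %d demes, %d slice(s), %d fitted epoch(s)\n",
              x$d, length(x$times), length(x$L_hat)))
  for (s in x$steps) {
    cat(sprintf("  epoch [%g, %g): lambda = %g, SSE = %.4g, %s\n",
                s$t_start, s$t_end, s$lambda, s$fit$data_sse,
                if (s$fit$converged) "converged" else
                  paste("NOT converged:", s$fit$message)))
  }
  invisible(x)
}

#' @exportS3Method summary serial_mig_fit
summary.serial_mig_fit <- function(object, ...) {
  w <- object$w
  cat(sprintf("Edge-weight estimates on %d directed edges\n", nrow(w)))
  print(apply(w, 2, summary))
  if (!is.null(object$imputation) && isTRUE(object$imputation$fitted)) {
    cat("Oldest slice completed by equilibrium imputation\n")
  }
  invisible(object)
}

#' Extract fitted edge weights
#'
#' @param object a `"serial_mig_fit"`.
#' @param ... unused.
#' @return Matrix of fitted backward migration rates, one row per directed
#'   edge of the edge set, one column per fitted epoch (youngest first).
#' @export
coef.serial_mig_fit <- function(object, ...) {
  object$w
}

#' Plot fitted edge weights
#'
#' With `truth` supplied, draws inferred-versus-true scatter plots per epoch
#' on the identity line; otherwise histograms of the fitted weights.
#'
#' @param x a `"serial_mig_fit"`.
#' @param truth optional matrix of true edge weights (edges x epochs).
#' @param ... passed to the base plotting calls.
#' @export
plot.serial_mig_fit <- function(x, truth = NULL, ...) {
  w <- x$w
  ncols <- ncol(w)
  op <- graphics::par(mfrow = c(1, ncols))
  on.exit(graphics::par(op))
  for (k in seq_len(ncols)) {
    if (!is.null(truth)) {
      graphics::plot(truth[, k], w[, k], xlab = "true edge weight",
                     ylab = "inferred edge weight",
                     main = colnames(w)[k], ...)
      graphics::abline(0, 1, lty = 2)
    } else {
      graphics::hist(w[, k], xlab = "edge weight", main = colnames(w)[k],
                     ...)
    }
  }
  invisible(x)
}

#' Per-deme net migration flux vectors
#'
#' For each deme, sums `w_e` times the unit displacement of each outgoing
#' edge: the resulting vector field summarizes the large-scale backward
#' migration pattern (eastward for a directional topology, center-pointing
#' for a converging one).
#'
#' @param w edge weights on `edge_set`.
#' @param edge_set two-column matrix of directed edges.
#' @param coords deme coordinates (d x 2).
#' @return d x 2 matrix of flux vectors.
#' @export
net_flux <- function(w, edge_set, coords) {
  d <- nrow(coords)
  out <- matrix(0, d, 2)
  for (e in seq_len(nrow(edge_set))) {
    i <- edge_set[e, 1]; j <- edge_set[e, 2]
    disp <- coords[j, ] - coords[i, ]
    disp <- disp / sqrt(sum(disp^2))
    out[i, ] <- out[i, ] + w[e] * disp
  }
  out
}

#' Agreement of net-flux sign structure with a reference
#'
#' A deme matches when every flux component that is decisively nonzero in the
#' reference (|component| above `tol`) has the same sign in the candidate.
#'
#' @param w_hat,w_true candidate and reference edge weights.
#' @param edge_set,coords as in [net_flux()].
#' @param tol threshold below which a reference component is ignored.
#' @return Fraction of demes (with any decisive component) that match.
#' @export
flux_sign_agreement <- function(w_hat, w_true, edge_set, coords,
                                tol = 1e-6) {
  Fh <- net_flux(w_hat, edge_set, coords)
  Ft <- net_flux(w_true, edge_set, coords)
  ok <- 0L; tot <- 0L
  for (i in seq_len(nrow(coords))) {
    decisive <- abs(Ft[i, ]) > tol
    if (!any(decisive)) next
    tot <- tot + 1L
    if (all(sign(Fh[i, decisive]) == sign(Ft[i, decisive]))) ok <- ok + 1L
  }
  if (tot == 0L) return(NA_real_)
  ok / tot
}
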