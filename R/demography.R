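#' Build a migration Laplacian from a backward-migration adjacency matrix
#'
#' The backward migration process of a single lineage is a continuous-time jump
#' process on the deme graph with generator `Q`; its Laplacian is `L = -Q`.
#' Given the weighted adjacency matrix `M` of backward migration rates
#' (`M[i, j]` = rate at which a lineage in deme `i` traces its ancestry to deme
#' `j`), the Laplacian is `L = diag(rowSums(M)) - M`, so that `exp(-L * tau)`
#' is the backward-time transition matrix over a duration `tau`.
#'
#' @param M square nonnegative matrix of backward migration rates with zero
#'   diagonal. Nonzero diagonal entries are ignored with a warning.
#' @return A d x d Laplacian matrix with zero row sums and non-positive
#'   off-diagonal entries equal to `-M[i, j]`.
#' @export
laplacian_from_adjacency <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("adjacency matrix must be square")
  neg <- which(M < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative migration rate on edge %d -> %d",
                 neg[1, 1], neg[1, 2]))
  }
  if (any(diag(M) != 0)) {
    warning("nonzero diagonal entries in adjacency matrix ignored")
    diag(M) <- 0
  }
  diag(rowSums(M), nrow = nrow(M)) - M
}

#' Recover the adjacency matrix from a Laplacian
#'
#' Inverse of [laplacian_from_adjacency()]: the backward migration rates are
#' the negated off-diagonal entries of `L`.
#'
#' @param L a valid migration Laplacian.
#' @return The nonnegative adjacency matrix `M` with zero diagonal.
#' @export
adjacency_from_laplacian <- function(L) {
  M <- -as.matrix(L)
  diag(M) <- 0
  M
}

#' Define one epoch of a piecewise-constant demographic model
#'
#' An epoch is a half-open backward-time interval `[t_start, t_end)` over which
#' the backward migration rates and per-deme pairwise coalescence rates are
#' constant. Exactly one of `M` (adjacency) or `L` (Laplacian) must be given.
#'
#' @param t_start,t_end backward times in generations (0 = present, increasing
#'   into the past); `t_end` may be `Inf`.
#' @param M d x d nonnegative backward-migration adjacency matrix.
#' @param L d x d migration Laplacian (zero row sums).
#' @param gamma length-d nonnegative vector of per-deme pairwise coalescence
#'   rates per generation (for diploids with local effective size N_i,
#'   `gamma_i = 1 / (2 * N_i)`; no ploidy scaling is applied internally).
#' @return An object of class `"epoch_params"` with elements `t_start`,
#'   `t_end`, `L`, `M`, `gamma`, `d`.
#' @export
epoch_params <- function(t_start, t_end, M = NULL, L = NULL, gamma) {
  if (is.null(M) == is.null(L)) {
    stop("exactly one of M (adjacency) or L (laplacian) must be supplied")
  }
  if (is.null(L)) {
    L <- laplacian_from_adjacency(M)
    M <- adjacency_from_laplacian(L)
  } else {
    L <- as.matrix(L)
    M <- adjacency_from_laplacian(L)
    if (any(M < 0)) stop("positive off-diagonal entry in Laplacian")
  }
  gamma <- as.numeric(gamma)
  d <- nrow(L)
  if (length(gamma) == 1 && d > 1) gamma <- rep(gamma, d)
  if (length(gamma) != d) stop("gamma must have one entry per deme")
  structure(list(t_start = t_start, t_end = t_end, L = L, M = M,
                 gamma = gamma, d = d),
            class = "epoch_params")
}

#' Define a piecewise-constant structured serial coalescent model
#'
#' A demographic model is an ordered list of epochs tiling `[t_0, Inf)` on a
#' fixed set of d demes. Time is measured backward from the present.
#'
#' @param epochs list of [epoch_params()] objects ordered by `t_start`.
#' @param deme_labels optional character vector of deme names.
#' @return An object of class `"demographic_model"`.
#' @export
demographic_model <- function(epochs, deme_labels = NULL) {
  if (inherits(epochs, "epoch_params")) epochs <- list(epochs)
  ord <- order(vapply(epochs, function(e) e$t_start, numeric(1)))
  epochs <- epochs[ord]
  model <- structure(list(d = epochs[[1]]$d, epochs = epochs,
                          deme_labels = deme_labels),
                     class = "demographic_model")
  viol <- validate_model(model)
  if (length(viol) > 0) {
    warning(paste("invalid demographic model:", paste(viol, collapse = "; ")))
  }
  model
}

#' Validate a demographic model
#'
#' Checks the structural invariants: epochs tile `[t_0, Inf)` without gaps or
#' overlaps, every Laplacian has zero row sums and non-positive off-diagonals,
#' coalescence rates are nonnegative, all epochs share one deme count, and the
#' terminal epoch has at least one deme with positive coalescence rate
#' (otherwise coalescence is not certain and the branch-length distributions
#' are defective).
#'
#' @param model a [demographic_model()].
#' @return Character vector of violations; empty if the model is valid.
#' @export
validate_model <- function(model) {
  viol <- character(0)
  eps <- model$epochs
  K <- length(eps)
  d <- model$d
  for (k in seq_len(K)) {
    e <- eps[[k]]
    if (e$d != d) viol <- c(viol, sprintf("epoch %d: deme count differs", k))
    if (!(e$t_start < e$t_end)) {
      viol <- c(viol, sprintf("epoch %d: t_start >= t_end", k))
    }
    if (max(abs(rowSums(e$L))) > 1e-10) {
      viol <- c(viol, sprintf("epoch %d: Laplacian row sums nonzero", k))
    }
    offd <- e$L - diag(diag(e$L), nrow = nrow(e$L))
    if (any(offd > 1e-12)) {
      viol <- c(viol, sprintf("epoch %d: positive off-diagonal in Laplacian", k))
    }
    if (any(e$gamma < 0)) {
      viol <- c(viol, sprintf("epoch %d: negative coalescence rate", k))
    }
    if (k < K && !isTRUE(all.equal(e$t_end, eps[[k + 1]]$t_start))) {
      if (e$t_end < eps[[k + 1]]$t_start) {
        viol <- c(viol, sprintf("epoch gap between epochs %d and %d", k, k + 1))
      } else {
        viol <- c(viol, sprintf("epoch overlap between epochs %d and %d", k, k + 1))
      }
    }
  }
  if (is.finite(eps[[K]]$t_end)) {
    viol <- c(viol, "terminal epoch must have t_end = Inf")
  }
  if (all(eps[[K]]$gamma <= 0)) {
    viol <- c(viol, "defective terminal epoch: no deme with positive coalescence rate")
  }
  viol
}

#' @exportS3Method print demographic_model
print.demographic_model <- function(x, ...) {
  cat(sprintf("Structured serial coalescent model: %d demes, %d epoch(s)\n",
              x$d, length(x$epochs)))
  for (k in seq_along(x$epochs)) {
    e <- x$epochs[[k]]
    cat(sprintf("  epoch %d: [%g, %g)  max m_ij = %g  gamma in [%g, %g]\n",
                k - 1, e$t_start, e$t_end, max(e$M),
                min(e$gamma), max(e$gamma)))
  }
  invisible(x)
}

#' @exportS3Method print epoch_params
print.epoch_params <- function(x, ...) {
  cat(sprintf("Epoch [%g, %g): %d demes\n", x$t_start, x$t_end, x$d))
  invisible(x)
}

# epoch (1-based index) containing backward time t; boundary t belongs to the
# epoch starting at t (epochs are half-open [t_start, t_end))
epoch_at <- function(model, t) {
  for (k in seq_along(model$epochs)) {
    e <- model$epochs[[k]]
    if (t >= e$t_start && t < e$t_end) return(k)
  }
  if (t < model$epochs[[1]]$t_start) {
    stop("time precedes the first epoch of the model")
  }
  length(model$epochs)
}
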