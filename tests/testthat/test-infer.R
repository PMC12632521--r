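test_that("noiseless vertical inference recovers the migration rates", {
  edge_set <- cbind(from = c(1, 2), to = c(2, 1))
  L_true <- matrix(c(0.5, -0.5, -0.2, 0.2), 2, 2, byrow = TRUE)
  B_old <- matrix(c(4, 5, 5, 4), 2, 2)
  B_young <- mean_vertical(B_old, L_true, 1)
  fit <- infer_L_vertical(B_old, B_young, 1, edge_set)
  expect_lt(max(abs(fit$w - c(0.5, 0.2)) / c(0.5, 0.2)), 1e-3)
  expect_true(fit$converged)
  # zero-migration truth drives all weights to zero
  fit0 <- infer_L_vertical(B_old, B_old + 1, 1, edge_set)
  expect_lt(max(fit0$w), 1e-4)
  expect_error(infer_L_vertical(B_old, -B_young, 1, edge_set), "nonpositive")
})

test_that("vertical inference is exact and on the absolute scale for d = 10", {
  set.seed(70)
  d <- 10
  M_true <- random_adjacency(d, 0.1, 2)
  L_true <- laplacian_from_adjacency(M_true)
  es <- full_edge_set(d)
  w_true <- M_true[es]
  B_old <- equilibrium_mean(random_epoch(d))
  B_young <- mean_vertical(B_old, L_true, 0.7)
  fit <- infer_L_vertical(B_old, B_young, 0.7, es)
  expect_lt(max(abs(fit$w - w_true) / w_true), 1e-3)
  slope <- unname(stats::coef(stats::lm(fit$w ~ w_true))[2])
  expect_gt(slope, 0.9); expect_lt(slope, 1.1)
})

test_that("refine_B applies the fitted vertical relation", {
  B <- matrix(c(4, 5, 5, 4), 2, 2)
  L <- matrix(c(0.3, -0.3, -0.1, 0.1), 2, 2, byrow = TRUE)
  expect_equal(refine_B(B, L, 0.8), mean_vertical(B, L, 0.8))
  expect_equal(refine_B(B, matrix(0, 2, 2), 0.8), B + 0.8)
})

test_that("refinement reduces noise relative to the raw estimate", {
  set.seed(71)
  d <- 3
  L_true <- laplacian_from_adjacency(random_adjacency(d, 0.3, 1))
  B_old <- equilibrium_mean(random_epoch(d))
  truth <- mean_vertical(B_old, L_true, 1)
  rmse_raw <- rmse_ref <- numeric(20)
  for (rep in 1:20) {
    noisy <- truth * (1 + matrix(stats::rnorm(d * d, 0, 0.05), d, d))
    fit <- infer_L_vertical(B_old, noisy, 1, full_edge_set(d))
    refined <- refine_B(B_old, fit$L, 1)
    rmse_raw[rep] <- sqrt(mean((noisy - truth)^2))
    rmse_ref[rep] <- sqrt(mean((refined - truth)^2))
  }
  expect_lt(mean(rmse_ref), mean(rmse_raw))
})

test_that("sequential inference recovers all epochs from exact inputs", {
  set.seed(72)
  d <- 3
  es <- full_edge_set(d)
  e0 <- random_epoch(d, 0, 1)
  e1 <- random_epoch(d, 1, 2.5)
  e2 <- random_epoch(d, 2.5, Inf)
  mod <- demographic_model(list(e0, e1, e2))
  B22 <- branch_mean_xy(mod, 2.5, 2.5)
  B12 <- branch_mean_xy(mod, 1, 2.5)
  B02 <- branch_mean_xy(mod, 0, 2.5)
  fit <- sequential_migration_inference(list(B22, B12, B02),
                                        times = c(0, 1, 2.5),
                                        edge_set = es)
  w <- coef(fit)
  expect_lt(max(abs(w[, 1] - e0$M[es]) / e0$M[es]), 1e-3)
  expect_lt(max(abs(w[, 2] - e1$M[es]) / e1$M[es]), 1e-3)
  expect_output(print(fit), "2 demes|3 demes")
  # single-slice input yields no vertical steps
  solo <- sequential_migration_inference(list(B22), times = 2.5,
                                         edge_set = es)
  expect_length(solo$L_hat, 0)
  # a slice without data is an error
  expect_error(sequential_migration_inference(list(B22, B02),
                                              times = c(0, 1, 2.5),
                                              edge_set = es),
               "no observed matrix")
})

test_that("vertical inference is decoupled from coalescence rates", {
  # identical B inputs, different gamma elsewhere in the scenario:
  # the fit must be bit-identical
  set.seed(73)
  d <- 3
  es <- full_edge_set(d)
  B_old <- equilibrium_mean(random_epoch(d))
  L_true <- laplacian_from_adjacency(random_adjacency(d))
  B_young <- mean_vertical(B_old, L_true, 0.9)
  scenario_gamma_a <- rep(0.5, d)
  scenario_gamma_b <- c(5, 0.1, 2)
  fit_a <- infer_L_vertical(B_old, B_young, 0.9, es)
  dummy <- stationary_pdf(epoch_params(0, Inf, L = L_true,
                                       gamma = scenario_gamma_b))
  fit_b <- infer_L_vertical(B_old, B_young, 0.9, es)
  expect_identical(fit_a$w, fit_b$w)
  expect_identical(fit_a$L, fit_b$L)
  expect_true(is.numeric(scenario_gamma_a))
})

test_that("equilibrium imputation completes missing cells", {
  # identifiable case: 2 x 2 grid, one off-diagonal cell missing, more
  # observed cells (15) than free parameters (8 edges + 4 rates)
  es <- grid_edge_set(2, 2)
  ep <- make_grid_demography(2, 2, "directional", base_rate = 0.3,
                             feature_rate = 1, gamma_spec = c(0.8, 1.2),
                             seed = 78)
  truth <- equilibrium_mean(ep)
  B <- truth
  B[1, 4] <- NA
  imp <- impute_B_equilibrium(B, es$edges)
  expect_true(imp$fitted)
  expect_equal(imp$B[1, 4], truth[1, 4], tolerance = 1e-2)
  expect_equal(imp$B[1, 1], truth[1, 1])   # observed cells untouched
  full <- impute_B_equilibrium(truth, es$edges)
  expect_false(full$fitted)
  expect_error(impute_B_equilibrium(matrix(NA_real_, 2, 2),
                                    cbind(from = c(1, 2), to = c(2, 1))),
               "no observed cells")
  # within-deme diversity alone cannot identify migration: the
  # underdetermined fit warns and anchors at the initialization
  expect_warning(impute_B_equilibrium(matrix(c(4, NA, NA, 4), 2, 2),
                                      cbind(from = c(1, 2), to = c(2, 1))),
                 "underdetermined")
})

test_that("coalescence rates are recovered from the diagonal relation", {
  set.seed(74)
  d <- 2
  gam_true <- c(0.8, 1.6)
  L <- laplacian_from_adjacency(matrix(c(0, 0.7, 0.4, 0), 2, 2,
                                       byrow = TRUE))
  ep <- epoch_params(0, Inf, L = L, gamma = gam_true)
  B_t2 <- equilibrium_mean(random_epoch(d)) + 1
  B_t1 <- mean_diagonal(B_t2, ep, 1.2)
  out <- infer_gamma_diagonal(B_t1, B_t2, L, 1.2)
  expect_lt(max(abs(out$gamma - gam_true) / gam_true), 1e-3)
  # at the tau -> Inf limit the fit reduces to the equilibrium equation
  Bstar <- equilibrium_mean(ep)
  out_inf <- infer_gamma_diagonal(Bstar, B_t2, L, 60)
  expect_lt(max(abs(out_inf$gamma - gam_true) / gam_true), 1e-3)
})

test_that("lambda cross-validation is deterministic and noise-responsive", {
  set.seed(75)
  es <- grid_edge_set(3, 3)
  d <- 9
  e_true <- make_grid_demography(3, 3, "directional", seed = 76)
  B_old <- equilibrium_mean(e_true)
  truth <- mean_vertical(B_old, e_true$L, 1)
  rel <- list(list(B_older = B_old, B_hat = truth,
                   cells = matrix(TRUE, d, d)))
  # degenerate grid: the single value is returned
  expect_equal(cross_validate_lambda(rel, 1, es$edges, 0,
                                     es$penalty_pairs)$lambda, 0)
  # noiseless data: the smallest lambda wins
  cv0 <- cross_validate_lambda(rel, 1, es$edges, c(0, 0.1, 1),
                               es$penalty_pairs, folds = 3, seed = 77)
  expect_equal(cv0$lambda, 0)
  # heavy noise: a positive lambda is selected in nearly all replicates
  picks <- vapply(1:10, function(rep) {
    set.seed(100 + rep)
    noisy <- truth * (1 + matrix(stats::rnorm(d * d, 0, 0.2), d, d))
    noisy[noisy <= 0.1] <- 0.1
    reln <- list(list(B_older = B_old, B_hat = noisy,
                      cells = matrix(TRUE, d, d)))
    cross_validate_lambda(reln, 1, es$edges, c(0, 0.1, 1),
                          es$penalty_pairs, folds = 3,
                          seed = rep)$lambda
  }, numeric(1))
  expect_gte(mean(picks > 0), 0.9)
  # determinism
  cv_a <- cross_validate_lambda(rel, 1, es$edges, c(0, 0.1),
                                es$penalty_pairs, folds = 3, seed = 5)
  cv_b <- cross_validate_lambda(rel, 1, es$edges, c(0, 0.1),
                                es$penalty_pairs, folds = 3, seed = 5)
  expect_identical(cv_a, cv_b)
})
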