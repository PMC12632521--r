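test_that("stationary pdf has the closed single-deme form", {
  e1 <- epoch_params(0, Inf, M = matrix(0, 1, 1), gamma = 1)
  f <- stationary_pdf(e1)
  b <- c(0, 0.5, 1, 2, 5)
  expect_equal(drop(pdf_evaluate(f, b)), 0.5 * exp(-b / 2),
               tolerance = 1e-12)
  expect_equal(pdf_mass(f), matrix(1, 1, 1), tolerance = 1e-12)
  expect_equal(pdf_mean(f), matrix(2, 1, 1), tolerance = 1e-12)
})

test_that("stationary pdf boundary value is diag(gamma) / 2", {
  set.seed(20)
  ep <- random_epoch(3)
  f <- stationary_pdf(ep)
  f0 <- pdf_evaluate(f, 0)[, , 1]
  expect_equal(diag(f0), ep$gamma / 2, tolerance = 1e-12)
  expect_equal(f0 - diag(diag(f0)), matrix(0, 3, 3))
  # the printed (paper-literal) convention doubles the mass
  f_lit <- stationary_pdf(ep, paper_literal = TRUE)
  expect_equal(pdf_mass(f_lit), matrix(2, 3, 3), tolerance = 1e-10)
})

test_that("stationary mean equals the equilibrium mean matrix", {
  e2 <- epoch_params(0, Inf, M = matrix(c(0, 1, 1, 0), 2, 2),
                     gamma = c(1, 1))
  expect_equal(pdf_mean(stationary_pdf(e2)), matrix(c(4, 5, 5, 4), 2, 2),
               tolerance = 1e-10)
  set.seed(21)
  ep <- random_epoch(3)
  expect_equal(pdf_mean(stationary_pdf(ep)), equilibrium_mean(ep),
               tolerance = 1e-10)
})

test_that("vertical propagation shifts, mixes, and conserves mass", {
  e1 <- epoch_params(-10, Inf, M = matrix(0, 1, 1), gamma = 1)
  f <- stationary_pdf(e1, at = 0)
  expect_identical(propagate_vertical(f, e1$L, 0), f)
  fv <- propagate_vertical(f, e1$L, 3)
  expect_equal(fv$x, -3)
  expect_equal(drop(pdf_evaluate(fv, c(1, 2.9))), c(0, 0))   # below support
  expect_equal(drop(pdf_evaluate(fv, 3 + c(0, 1))),
               0.5 * exp(-c(0, 1) / 2), tolerance = 1e-12)

  # two demes: output is the transition-matrix mixture of shifted inputs
  e2 <- epoch_params(-10, Inf, M = matrix(c(0, 1, 1, 0), 2, 2),
                     gamma = c(1, 2))
  f2 <- stationary_pdf(e2, at = 0)
  tau <- 0.5 * log(2)
  fv2 <- propagate_vertical(f2, e2$L, tau)
  b <- c(0.3, 1.7, 4)
  vin <- pdf_evaluate(f2, b)
  vout <- pdf_evaluate(fv2, b + tau)
  for (m in seq_along(b)) {
    expect_equal(vout[, , m],
                 matrix(c(0.75, 0.25, 0.25, 0.75), 2, 2) %*% vin[, , m],
                 tolerance = 1e-10)
  }
  expect_equal(pdf_mass(fv2), matrix(1, 2, 2), tolerance = 1e-10)
})

test_that("diagonal propagation is exact against the upwind PDE oracle", {
  set.seed(22)
  gam <- c(0.8, 1.3)
  # same gamma in both epochs keeps the density continuous at b = 2 tau
  e_start <- epoch_params(0.4, Inf, M = random_adjacency(2, 0.3, 1.2),
                          gamma = gam)
  e_prop <- epoch_params(0, 0.4, M = random_adjacency(2, 0.3, 1.2),
                         gamma = gam)
  f_old <- stationary_pdf(e_start, at = 0.4)
  db <- 5e-3
  bgrid <- seq(0, 4, by = db)
  oracle <- upwind_diagonal_oracle(e_prop, pdf_vec_grid(f_old, bgrid),
                                   0.4, db, 4)
  f_new <- propagate_diagonal(f_old, e_prop, 0.4)
  err1 <- max(abs(oracle$values - pdf_vec_grid(f_new, bgrid)))
  expect_lt(err1, 1.5 * db)  # first-order in the step size
  # first-order convergence: halving the grid halves the error
  db2 <- db / 2
  bgrid2 <- seq(0, 4, by = db2)
  oracle2 <- upwind_diagonal_oracle(e_prop, pdf_vec_grid(f_old, bgrid2),
                                    0.4, db2, 4)
  err2 <- max(abs(oracle2$values - pdf_vec_grid(f_new, bgrid2)))
  expect_lt(err2 / err1, 0.65)
})

test_that("diagonal propagation keeps the stationary pdf fixed", {
  set.seed(23)
  ep <- random_epoch(2, t_start = 0)
  f <- stationary_pdf(ep, at = 2)
  expect_identical(propagate_diagonal(f, ep, 0), f)
  f2 <- propagate_diagonal(f, ep, 1.3)
  b <- seq(0, 8, length.out = 30)
  expect_equal(pdf_vec_grid(f2, b), pdf_vec_grid(f, b), tolerance = 1e-10)
  expect_error(propagate_diagonal(branch_pdf_xy(demographic_model(list(ep)),
                                                0.5, 1), ep, 0.2),
               "contemporaneous")
})

test_that("mass is conserved through arbitrary propagation chains", {
  set.seed(24)
  for (rep in 1:5) {
    d <- sample(2:3, 1)
    mod <- random_model(d, boundaries = c(0, 0.7, 1.5))
    x <- stats::runif(1, 0, 0.7)
    y <- stats::runif(1, x, 2.2)
    f <- branch_pdf_xy(mod, x, y)
    expect_equal(pdf_mass(f), matrix(1, d, d), tolerance = 1e-10)
    expect_equal(pdf_laplace(f, 0), matrix(1, d, d), tolerance = 1e-10)
  }
})

test_that("diagonal propagation converges ergodically to the stationary pdf", {
  set.seed(25)
  start_ep <- random_epoch(2)
  target_ep <- epoch_params(-20, Inf, M = random_adjacency(2, 0.5, 1.5),
                            gamma = c(1, 0.6))
  f0 <- stationary_pdf(start_ep, at = 0)
  fstar <- stationary_pdf(target_ep)
  b <- seq(0, 30, by = 0.05)
  tv <- vapply(c(0.5, 2, 4, 8), function(tau) {
    fs <- propagate_diagonal(f0, target_ep, tau)
    sum(abs(pdf_vec_grid(fs, b) - pdf_vec_grid(fstar, b))) * 0.05
  }, numeric(1))
  expect_true(all(diff(tv) < 0))
  expect_lt(tv[4], 1e-2)
})

test_that("composed horizontal pdf relations hold and detect perturbations", {
  set.seed(26)
  mod <- random_model(2, boundaries = c(0, 0.8, 1.7))
  chk <- horizontal_pdf_check(mod)
  expect_lt(chk$max, 1e-8)
  # perturb one density component
  f01 <- branch_pdf_xy(mod, 0, 0.8)
  f01$segments[[1]]$v[1] <- f01$segments[[1]]$v[1] + 0.02
  chk_p <- horizontal_pdf_check(mod, f = list(f01 = f01))
  expect_gt(chk_p$max, 1e-3)
})

test_that("contemporaneous branch lengths are twice structured coalescence times", {
  # single deme: B / 2 ~ Exp(gamma), checked against the simulator
  e1 <- epoch_params(0, Inf, M = matrix(0, 1, 1), gamma = 0.7)
  mod <- demographic_model(list(e1))
  s <- simulate_pair(mod, 1, 0, 1, 0, 2e4, seed = 27)
  ks <- suppressWarnings(stats::ks.test(s$branch_length / 2, "pexp", 0.7))
  expect_gt(ks$p.value, 1e-4)
})

test_that("pdf cdf grid matches direct mass integrals", {
  set.seed(28)
  mod <- random_model(2, boundaries = c(0, 1))
  f <- branch_pdf_xy(mod, 0.2, 1.4)
  b <- seq(1.2, 60, length.out = 40)
  cdf <- pdf_cdf(f, b)
  expect_true(all(diff(matrix(cdf, 4, 40)[1, ]) >= 0))
  expect_equal(cdf[, , 40], pdf_mass(f), tolerance = 1e-3)  # tiny tail beyond grid
  # cdf at a point equals mass below it (independent check via laplace at 0
  # of the truncated complement is unavailable; use numeric integration)
  dense_b <- seq(1.2, b[10], length.out = 4000)
  dens <- pdf_vec_grid(f, dense_b)
  num <- matrix(rowSums(dens[, -1] + dens[, -4000]) / 2 *
                  (dense_b[2] - dense_b[1]), 2, 2)
  expect_equal(cdf[, , 10], num, tolerance = 1e-4)
})
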