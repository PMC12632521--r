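test_that("single-deme simulations match the exponential closed form", {
  e1 <- epoch_params(0, Inf, M = matrix(0, 1, 1), gamma = 1)
  mod <- demographic_model(list(e1))
  s <- simulate_pair(mod, 1, 0, 1, 0, 2e4, seed = 50)
  n <- nrow(s)
  expect_lt(abs(mean(s$branch_length) - 2), 3 * 2 / sqrt(n))
  expect_lt(abs(stats::var(s$branch_length) - 4), 3 * 4 * sqrt(20 / n))
  # serial sampling: B = (y - x) + fresh exponential
  s2 <- simulate_pair(mod, 1, 0, 1, 1, 2e4, seed = 51)
  expect_gte(min(s2$branch_length), 1)
  expect_lt(abs(mean(s2$branch_length) - 3), 3 * 2 / sqrt(n))
})

test_that("two-deme simulations match the equilibrium mean matrix", {
  e2 <- epoch_params(0, Inf, M = matrix(c(0, 1, 1, 0), 2, 2),
                     gamma = c(1, 1))
  mod <- demographic_model(list(e2))
  out <- simulate_B_matrix(mod, 0, 0, 5e3, seed = 52)
  expect_lt(max(abs(out$mean - matrix(c(4, 5, 5, 4), 2, 2)) / out$se), 3.5)
  expect_equal(out$mean[1, 2], out$mean[2, 1])   # mirrored contemporaneous
})

test_that("simulation streams are reproducible given a seed", {
  mod <- demographic_model(list(epoch_params(0, Inf,
                                             M = matrix(c(0, 1, 1, 0), 2, 2),
                                             gamma = c(1, 2))))
  a <- simulate_pair(mod, 1, 0, 2, 0.5, 200, seed = 53)
  b <- simulate_pair(mod, 1, 0, 2, 0.5, 200, seed = 53)
  expect_identical(a, b)
  c <- simulate_pair(mod, 1, 0, 2, 0.5, 200, seed = 54)
  expect_false(identical(a, c))
})

test_that("splitting an epoch in two leaves the simulated law unchanged", {
  M <- matrix(c(0, 0.6, 0.9, 0), 2, 2, byrow = TRUE)
  gam <- c(1, 0.5)
  one <- demographic_model(list(epoch_params(0, Inf, M = M, gamma = gam)))
  two <- demographic_model(list(epoch_params(0, 2, M = M, gamma = gam),
                                epoch_params(2, Inf, M = M, gamma = gam)))
  s <- simulate_pair(two, 1, 0, 2, 0, 2e4, seed = 55)
  # exact analytic cdf of the unsplit model as the reference
  f <- branch_pdf_xy(one, 0, 0)
  bgrid <- seq(0, stats::quantile(s$branch_length, 0.999), length.out = 400)
  Fan <- pdf_cdf(f, bgrid)[1, 2, ] / pdf_mass(f)[1, 2]
  Femp <- stats::ecdf(s$branch_length)(bgrid)
  expect_lt(max(abs(Femp - Fan)), 1.63 / sqrt(nrow(s)) * 1.5)
})

test_that("lpsc lengths are exponential given the branch length", {
  s <- data.frame(branch_length = rep(2, 2e4))
  s <- attach_lpsc_lengths(s, r = 1, seed = 56)
  emp <- mean(s$lpsc_length > 1)
  expect_lt(abs(emp - exp(-2)), 3 * sqrt(exp(-2) * (1 - exp(-2)) / 2e4))
  expect_equal(mean(s$lpsc_length > 0), 1)
  expect_error(attach_lpsc_lengths(s, r = 0), "positive")
})

test_that("grid demographies realize the prescribed topologies", {
  es <- grid_edge_set(3, 3)
  expect_equal(nrow(es$edges), 2 * (2 * 9 - 3 - 3))
  dir3 <- make_grid_demography(3, 3, "directional", base_rate = 0.1,
                               feature_rate = 1, seed = 60)
  coords <- attr(dir3, "coords")
  for (e in seq_len(nrow(es$edges))) {
    i <- es$edges[e, 1]; j <- es$edges[e, 2]
    east <- coords[j, 1] - coords[i, 1] == 1 & coords[j, 2] == coords[i, 2]
    expect_equal(dir3$M[i, j], if (east) 1 else 0.1)
  }
  conv3 <- make_grid_demography(3, 3, "converging", base_rate = 0.1,
                                feature_rate = 1, seed = 60)
  center <- 5   # cell (2, 2) of the 3 x 3 grid
  expect_true(all(conv3$M[conv3$M[, center] > 0, center] == 1))
  mixed_a <- make_grid_demography(3, 3, "mixed", seed = 61)
  mixed_b <- make_grid_demography(3, 3, "mixed", seed = 61)
  expect_identical(mixed_a$M, mixed_b$M)
  expect_identical(mixed_a$gamma, mixed_b$gamma)
  expect_error(make_grid_demography(3, 3, "spiral"), "arg")
  expect_error(make_grid_demography(1, 3, "directional"), "at least 2")
})

test_that("empirical_B aggregates cells and flags vacancies", {
  s <- data.frame(deme_i = c(1, 1, 2), deme_j = c(1, 1, 2),
                  branch_length = c(2, 4, 5))
  out <- empirical_B(s, d = 2)
  expect_equal(out$mean[1, 1], 3)
  expect_equal(out$mean[2, 2], 5)
  expect_true(is.na(out$se[2, 2]))       # single observation
  expect_true(is.na(out$mean[1, 2]))     # vacant cell
  expect_true(any(out$missing[, 1] == 1 & out$missing[, 2] == 2))
})

test_that("samples round-trip through empirical_B consistently", {
  e2 <- epoch_params(0, Inf, M = matrix(c(0, 2, 2, 0), 2, 2),
                     gamma = c(1, 1))
  mod <- demographic_model(list(e2))
  s <- rbind(simulate_pair(mod, 1, 0, 1, 0, 5e3, seed = 62),
             simulate_pair(mod, 1, 0, 2, 0, 5e3, seed = 63))
  out <- empirical_B(s, d = 2)
  Bstar <- equilibrium_mean(e2)
  expect_lt(abs(out$mean[1, 1] - Bstar[1, 1]), 3 * out$se[1, 1])
  expect_lt(abs(out$mean[1, 2] - Bstar[1, 2]), 3 * out$se[1, 2])
})
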