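test_that("transit-time-constrained maxent system hits its constraint", {
  # d = 1: the exponential with mean ET
  one <- maxent_system_transit(1, transit_time = 4, d = 1)
  expect_equal(as.numeric(one$B), -1 / 4, tolerance = 1e-12)

  # d = 3, ET = 2: lambda = d - 1 + 1/ET
  sys <- maxent_system_transit(c(1, 1, 1), transit_time = 2)
  expect_equal(unname(diag(sys$B)), rep(-2.5, 3), tolerance = 1e-12)
  expect_true(all(sys$B[row(sys$B) != col(sys$B)] == 1))
  expect_equal(system_diagnostics(sys)$ET, 2, tolerance = 1e-10)

  expect_error(maxent_system_transit(1, transit_time = 0), "positive")
})

test_that("transit-time maxent dominates rejection-sampled feasible competitors", {
  u <- c(1, 1)
  ET <- 1
  star <- maxent_system_transit(u, transit_time = ET)
  H_star <- path_entropy(star)$H_path
  set.seed(31)
  for (k in 1:200) {
    cand <- random_system(2, connectivity = sample(c(0.5, 1), 1))
    # rescale rates so the transit time matches exactly, keep u fixed
    scale <- system_diagnostics(compartmental_system(u, cand$B))$ET / ET
    comp <- compartmental_system(u, cand$B * scale)
    expect_lte(path_entropy(comp)$H_path, H_star + 1e-9)
  }
})

test_that("steady-state-constrained maxent reproduces the prescribed stocks", {
  # formula check, identical to plugging into the closed form
  sys <- maxent_system_steady_state(c(1, 1), u = c(1, 0), check = FALSE)
  expect_equal(unname(sys$B), rbind(c(-2, 1), c(1, -2)), tolerance = 1e-12)

  # compatible input: the constructed system equilibrates at x*
  xs <- c(1.4, 0.6)
  sys <- maxent_system_steady_state(xs)
  expect_equal(unname(steady_state(sys)), xs, tolerance = 1e-10)
  expect_equal(unname(exit_rate <- -colSums(sys$B)), 1 / xs, tolerance = 1e-12)

  # incompatible input is rejected a posteriori
  expect_error(maxent_system_steady_state(c(1.4, 0.6), u = c(2, 0)),
               "incompatible")
  expect_error(maxent_system_steady_state(c(1, -1)), "positive")
})

test_that("fixing the steady state can only lower the maximum entropy", {
  xs <- c(1.4, 0.6)
  m2 <- maxent_system_steady_state(xs)
  ET <- sum(xs) / sum(m2$u)
  m1 <- maxent_system_transit(m2$u, transit_time = ET)
  expect_lte(path_entropy(m2)$H_path, path_entropy(m1)$H_path + 1e-12)

  # with a symmetric steady state the two constructions coincide
  msym <- maxent_system_steady_state(c(2, 2))
  m1sym <- maxent_system_transit(msym$u, transit_time = 2)
  expect_equal(msym$B, m1sym$B, tolerance = 1e-12)
})

test_that("gamma map is the stated polynomial and round-trips", {
  expect_equal(unname(gammas_from_parameters(c(1.821, 1.098, 0.902, 1.179))),
               c(3, 5, 4), tolerance = 1e-3)
  # decoupled pools factorize the quadratic
  a <- 0.8; b <- 1.7
  expect_equal(unname(gammas_from_parameters(c(0, 0, a, b))),
               c(b, a + b, a * b), tolerance = 1e-12)
  set.seed(13)
  for (k in 1:20) {
    p <- runif(4, 0, 3)
    g <- gammas_from_parameters(p)
    expect_equal(unname(g),
                 c(p[1] + p[4], sum(p), p[3] * p[1] + p[3] * p[4] + p[2] * p[4]),
                 tolerance = 1e-12)
  }
})

test_that("identification finds the known optimum from a coarse grid", {
  fit <- identify_max_theta(c(3, 5, 4), mesh = 2.5)
  expect_true(fit$feasible)
  expect_equal(fit$best_theta, 1.916, tolerance = 1e-3)
  expect_equal(unname(fit$best_parameters),
               c(1.8213, 1.0981, 0.9019, 1.1787), tolerance = 1e-3)
  # every reported local maximum satisfies the constraints
  expect_true(all(fit$local_maxima$residual <= 1e-8))
  expect_true(all(as.matrix(fit$local_maxima[, 1:4]) >= -1e-12))
  # the selected system reproduces the measured coefficients
  expect_equal(unname(gammas_from_parameters(unname(fit$best_parameters))),
               c(3, 5, 4), tolerance = 1e-7)
})

test_that("identification dominates planted feasible systems", {
  set.seed(17)
  for (k in 1:8) {
    p <- runif(4, 0.2, 2.5)
    g <- gammas_from_parameters(p)
    planted_theta <- path_entropy(
      compartmental_system(c(1, 0),
                           rbind(c(-(p[3] + p[2]), p[1]),
                                 c(p[2], -(p[4] + p[1])))))
    planted_theta <- planted_theta$theta_time
    fit <- identify_max_theta(unname(g), mesh = 2.5)
    expect_true(fit$feasible)
    expect_gte(fit$best_theta, planted_theta - 1e-6)
  }
})

test_that("refining the start grid never lowers the best theta", {
  coarse <- identify_max_theta(c(3, 5, 4), mesh = 5)
  fine <- identify_max_theta(c(3, 5, 4), mesh = 2.5)
  expect_gte(fine$best_theta, coarse$best_theta - 1e-9)
})

test_that("the theta-optimal model does not maximize the path entropy", {
  fit <- identify_max_theta(c(3, 5, 4), mesh = 2.5)
  H_best <- path_entropy(fit$best_system)$H_path
  others <- fit$local_maxima
  H_others <- vapply(seq_len(nrow(others)), function(i) {
    sys <- pathentropy:::system_from_parameters(as.numeric(others[i, 1:4]))
    if (is.null(sys)) return(NA_real_)
    path_entropy(sys)$H_path
  }, numeric(1))
  expect_true(any(H_others > H_best + 1e-6, na.rm = TRUE))
})

test_that("infeasible constraints give an explicit infeasible result", {
  # gamma3 far beyond what gamma1, gamma2 admit: no nonnegative solution
  fit <- identify_max_theta(c(0.1, 0.2, 50), mesh = 5)
  expect_false(fit$feasible)
  expect_true(is.na(fit$best_theta))
})
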