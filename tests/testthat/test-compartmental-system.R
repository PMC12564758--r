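test_that("constructor accepts valid systems and rejects invariant violations", {
  sys <- compartmental_system(c(1, 0), rbind(c(-1, 0), c(1, -1)))
  expect_s3_class(sys, "compartmental_system")
  expect_identical(sys$d, 2L)

  # closed one-pool system: no outflow anywhere
  expect_error(compartmental_system(1, matrix(0, 1, 1)))
  # negative off-diagonal rate
  expect_error(compartmental_system(c(1, 0), rbind(c(-1, -0.5), c(1, -1))),
               "off-diagonal")
  # dimension mismatch
  expect_error(compartmental_system(c(1, 0, 0), rbind(c(-1, 0), c(1, -1))),
               "dimension")
  # mass-creating column
  expect_error(compartmental_system(c(1, 0), rbind(c(-1, 0), c(2, -1))),
               "positive sum")
  # no input at all
  expect_error(compartmental_system(c(0, 0), rbind(c(-1, 0), c(1, -1))),
               "positive entry")
  # closed two-pool loop (singular B): all mass recirculates
  expect_error(compartmental_system(c(1, 0), rbind(c(-1, 1), c(1, -1))))
})

test_that("tiny positive column sums from float entry are clamped to zero", {
  B <- rbind(c(-1, 0), c(1 + 1e-12, -1))
  sys <- compartmental_system(c(1, 0), B)
  expect_equal(exit_rates <- -colSums(sys$B), c(0, 1), tolerance = 1e-9)
})

test_that("steady state solves B x + u = 0 with nonnegative stocks", {
  # hand-solved 2x2 feedback system
  sys <- compartmental_system(c(1, 0), rbind(c(-1, 0.5), c(1, -1)))
  expect_equal(unname(steady_state(sys)), c(2, 2), tolerance = 1e-12)

  # one-pool closed form x* = u / lambda
  one <- compartmental_system(1, matrix(-2.5, 1, 1))
  expect_equal(unname(steady_state(one)), 1 / 2.5, tolerance = 1e-12)

  for (sys in random_fixtures(30)) {
    xs <- steady_state(sys)
    expect_true(all(xs >= 0))
    expect_lt(max(abs(sys$B %*% xs + sys$u)), 1e-10 * sum(sys$u))
  }
})

test_that("diagnostics reproduce serial and feedback reference values", {
  dg <- system_diagnostics(reference_system(2))
  expect_equal(dg$ET, 2, tolerance = 1e-12)
  expect_equal(dg$EN, 3, tolerance = 1e-12)

  dg <- system_diagnostics(reference_system(4))
  expect_equal(dg$ET, 4, tolerance = 1e-12)
  expect_equal(dg$EN, 5, tolerance = 1e-12)
})

test_that("diagnostics satisfy conservation and consistency identities", {
  for (sys in c(reference_fixtures(), random_fixtures(30))) {
    dg <- system_diagnostics(sys)
    expect_equal(sum(dg$beta), 1, tolerance = 1e-12)
    expect_equal(unname(colSums(dg$jump_matrix)), rep(1, sys$d),
                 tolerance = 1e-12)
    expect_equal(sum(dg$EO), dg$ET, tolerance = 1e-10)
    expect_equal(sum(dg$r), sum(sys$u), tolerance = 1e-10 * sum(sys$u))
    # fundamental-matrix route equals the stock route to expected visits
    expect_equal(unname(as.numeric(dg$fundamental %*% dg$beta)),
                 unname(dg$EN_per_pool),
                 tolerance = 1e-10)
  }
})

test_that("relabeling pools permutes per-pool quantities, leaves ET and EN alone", {
  set.seed(7)
  sys <- random_system(4, connectivity = 0.8)
  perm <- sample(4)
  per <- compartmental_system(sys$u[perm], sys$B[perm, perm])
  dg <- system_diagnostics(sys)
  dgp <- system_diagnostics(per)
  expect_equal(unname(dgp$x_star), unname(dg$x_star[perm]), tolerance = 1e-10)
  expect_equal(unname(dgp$EN_per_pool), unname(dg$EN_per_pool[perm]),
               tolerance = 1e-10)
  expect_equal(unname(dgp$EO), unname(dg$EO[perm]), tolerance = 1e-10)
  expect_equal(dgp$ET, dg$ET, tolerance = 1e-12)
  expect_equal(dgp$EN, dg$EN, tolerance = 1e-12)
})

test_that("rescaling B by c scales transit time by 1/c, leaves jump structure alone", {
  set.seed(11)
  sys <- random_system(3, connectivity = 1)
  for (c0 in c(0.25, 4)) {
    fast <- compartmental_system(sys$u, c0 * sys$B)
    expect_equal(system_diagnostics(fast)$ET, system_diagnostics(sys)$ET / c0,
                 tolerance = 1e-10)
    expect_equal(system_diagnostics(fast)$EN, system_diagnostics(sys)$EN,
                 tolerance = 1e-10)
    expect_equal(system_diagnostics(fast)$jump_matrix,
                 system_diagnostics(sys)$jump_matrix, tolerance = 1e-12)
  }
})

test_that("transit-time density is the phase-type density", {
  # one pool: exponential
  one <- compartmental_system(1, matrix(-2, 1, 1))
  tt <- c(0, 0.3, 1, 2.5)
  expect_equal(transit_time_density(one, tt), dexp(tt, 2), tolerance = 1e-10)
  expect_error(transit_time_density(one, -1), "nonnegative")

  # any system: integrates to one with the diagnosed mean (quadrature oracle)
  for (sys in list(reference_system(2), reference_system(5))) {
    total <- stats::integrate(function(t) transit_time_density(sys, t),
                              0, Inf, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
    expect_equal(quadrature_mean_transit(sys), system_diagnostics(sys)$ET,
                 tolerance = 1e-6)
  }
})

test_that("transfer function matches the scalar resolvent and its Laplace route", {
  one <- compartmental_system(1, matrix(-1.5, 1, 1))
  expect_equal(as.numeric(transfer_function(one, s = 2)), 1 / (2 + 1.5),
               tolerance = 1e-12)

  # 2-pool observed through C = (1, 0): rational (s + g1)/(s^2 + g2 s + g3)
  p <- c(B12 = 0.7, B21 = 0.4, z1 = 0.6, z2 = 0.9)
  B <- rbind(c(-(p[3] + p[2]), p[1]), c(p[2], -(p[4] + p[1])))
  sys <- compartmental_system(c(1, 0), B)
  g <- gammas_from_parameters(p)
  for (s in c(0, 0.5, 2)) {
    expect_equal(as.numeric(transfer_function(sys, C = rbind(c(1, 0)), s = s))[1],
                 (s + g[[1]]) / (s^2 + g[[2]] * s + g[[3]]), tolerance = 1e-10)
  }

  # transfer function equals the numerically Laplace-transformed impulse
  # response at s = 1 for a seeded 3-pool fixture
  set.seed(5)
  sys3 <- random_system(3, connectivity = 1)
  C <- rbind(c(1, 0, 0), c(0, 1, 1))
  direct <- transfer_function(sys3, C = C, s = 1)
  quad <- matrix(0, 2, 3)
  for (i in 1:2) for (j in 1:3) {
    quad[i, j] <- stats::integrate(function(t) {
      vapply(t, function(tt) impulse_response(sys3, C = C, t = tt)[i, j] *
               exp(-tt), numeric(1))
    }, 0, Inf, rel.tol = 1e-9)$value
  }
  expect_equal(direct, quad, tolerance = 1e-6, ignore_attr = TRUE)
})
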