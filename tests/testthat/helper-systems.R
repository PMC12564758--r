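# Shared fixtures: the seven simple reference systems plus seeded random
# systems of mixed dimension and connectivity.

reference_fixtures <- function() {
  lapply(1:7, reference_system)
}

# deterministic batch of random open systems for property-style tests
random_fixtures <- function(n, dims = 2:5, connectivity = c(0.4, 0.7, 1),
                            seed = 20251) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    random_system(d = sample(dims, 1L),
                  connectivity = sample(connectivity, 1L))
  })
}

# numeric-quadrature mean of the transit-time density (independent oracle)
quadrature_mean_transit <- function(sys, upper = Inf) {
  stats::integrate(function(t) t * transit_time_density(sys, t),
                   0, upper, rel.tol = 1e-9)$value
}

# 4-standard-error agreement; the SE is floored at the sampler's resolution
# 1/n so that events unseen in n draws (empirical SE exactly 0) are compared
# against the granularity of the estimator rather than a zero-width band
expect_within_se <- function(est, se, truth, n, k = 4) {
  expect_lt(abs(est - truth), k * max(se, 1 / n))
}
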