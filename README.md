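# pathentropy

Information-theoretic analysis of open compartmental systems in
equilibrium, for modellers of carbon cycling, tracer kinetics and other
mass-balanced box models who want to quantify how *predictable* a model's
internal pathways are — and to pick among structurally different models
that fit the same data equally well (equifinality) by the maximum-entropy
principle.

## The idea

A compartmental system `dx/dt = B x + u` in equilibrium is, seen through a
single particle, an absorbing continuous-time Markov chain: the particle
enters pool *j* with probability `β_j = u_j/‖u‖`, waits an exponential
sojourn with rate `λ_j = -B_jj`, jumps to pool *i* with probability
`B_ij/λ_j` or out with probability `z_j/λ_j` (`z = -colSums(B)`), and is
eventually absorbed.  The Shannon entropy of the particle's whole path —
visited pools *and* sojourn times — has the closed form

    H(P) = H(β) + Σ_j (x*_j/‖u‖) [ Σ_{i≠j} B_ij (1 − log B_ij) + z_j (1 − log z_j) ]

with `x* = −B⁻¹u` the equilibrium stocks.  From it derive the entropy rate
per unit time `θ = H(P)/E[T]`, the entropy rate per jump `θ_J = H(P)/E[N]`,
and the macroscopic system entropy `H(M) = ‖u‖·H(P) = ‖x*‖·θ`.  The
package computes these with their jump/sojourn decomposition, samples
particle paths as an exact Monte-Carlo cross-check, constructs closed-form
maximum-entropy systems under transit-time and steady-state constraints,
and identifies the maximum-`θ` system consistent with measured
transfer-function coefficients by multi-start constrained optimization.

## Worked example

A two-pool system with a feedback loop: pool 1 feeds pool 2, half of pool
2's outflow is recycled back into pool 1.

```r
library(pathentropy)

sys <- compartmental_system(c(1, 0), rbind(c(-1, 0.5), c(1, -1)),
                            pool_names = c("fast", "slow"),
                            time_unit = "yr", mass_unit = "gC")
path_entropy(sys)
#> Path entropy report (nats)
#>   H(path)        = 5.386  (jump part 1.386 + sojourn part 4)
#>   H(entry)       = 0
#>   theta per time = 1.347   theta per jump = 1.077
#>   system entropy = 5.386
#>   E[T] = 4   E[N] = 5
```

Reading this: a particle needs 4 years and 5 jumps through the system on
average; the full path carries 5.39 nats of uncertainty, of which 1.39
nats come from *where* the particle jumps (the recycling choice) and 4.00
nats from *when* (the exponential sojourns); the entry pool is certain
(`H(entry) = 0` since all input enters pool 1).  The simulator confirms
the closed forms from 20,000 sampled paths:

```r
mc_estimates(sys, n_paths = 20000, seed = 1)
#> Monte-Carlo estimates from 20000 particle paths
#>   H(path)      = 5.398 (se 0.031)
#>   transit time = 4.007 (se 0.025)
#>   jumps        = 5.012 (se 0.02)
```

Structural identification from tracer data: among all two-pool systems
whose transfer function is `(s + 3)/(s² + 5s + 4)`, the most unbiased
(maximum entropy rate) one is

```r
fit <- identify_max_theta(c(3, 5, 4), mesh = 1)
fit$best_theta           # 1.9164 nats/yr
round(fit$best_system$B, 3)
#>        [,1]   [,2]
#> [1,] -2.000  1.821
#> [2,]  1.098 -3.000
```

Model builders `emanuel_system(xi)` (five-pool global carbon cycle),
`wang_system(epsilon)` (two-pool microbial soil carbon),
`one_pool_equivalent()`, `reference_system()`/`reference_entropy_table()`
(seven benchmark structures) and `parameter_sweep()` cover the worked
systems; `read_system()`/`write_system()` handle JSON and CSV specs.  The
methods vignette (`vignettes/path-entropy-methods.Rmd`) documents the
formulas, numerical conventions and design choices.

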