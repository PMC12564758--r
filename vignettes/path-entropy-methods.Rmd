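---
title: "Path entropy of compartmental systems: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path entropy of compartmental systems: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathentropy)
```

## The model

An open compartmental system in equilibrium is the linear mass balance

$$\frac{dx}{dt} = Bx + u,$$

with nonnegative external inputs $u \in \mathbb{R}_+^d$ (mass/time) and a
compartmental matrix $B$ whose off-diagonal entries $B_{ij} \ge 0$ are flux
rates from pool $j$ to pool $i$ (1/time), whose diagonal entries are
negative, and whose column sums are nonpositive; the column deficit
$z_j = -\sum_i B_{ij}$ is the rate at which pool $j$ releases material to
the environment.  Invertibility of $B$ makes the system *open*: every
particle eventually leaves, and the equilibrium stocks are
$x^* = -B^{-1}u$.

The same system, watched through a single particle, is an absorbing
continuous-time Markov chain on the pools plus an absorbing environment
state.  The particle enters through pool $j$ with probability
$\beta_j = u_j / \|u\|$, stays in pool $j$ an $\mathrm{Exp}(\lambda_j)$
time with $\lambda_j = -B_{jj}$, and then jumps to pool $i$ with
probability $B_{ij}/\lambda_j$ or out with probability $z_j/\lambda_j$.
`system_diagnostics()` exposes this chain completely: the jump matrix, the
fundamental matrix of expected visit counts, expected visits
$E[N_j] = \lambda_j x^*_j / \|u\|$, the mean number of jumps
$E[N] = 1 + \sum_j E[N_j]$ (the final exit counts as a jump), the mean
transit time $E[T] = \|x^*\|/\|u\|$ (total stocks over total fluxes), and
mean occupation times $E[O_j] = x^*_j/\|u\|$.

## The entropy calculus

The path of the particle — the sequence of visited pools with their sojourn
times — has density
$f(p) = \beta_{x_1} \prod_k q_k e^{-\lambda_{x_k} t_k}$ with respect to the
natural product measure on the path space, where $q_k$ is the rate of the
$k$-th jump ($B_{ij}$ internally, $z_j$ for the exit).  Its Shannon
entropy, the **path entropy**, has the closed form implemented in
`path_entropy()`:

$$H(P) = H(\beta) + \sum_{j=1}^{d} \frac{x^*_j}{\|u\|}
  \Big[\sum_{i \neq j} B_{ij}\,(1 - \log B_{ij}) + z_j\,(1 - \log z_j)\Big].$$

Two algebraically equivalent representations are computed alongside and
cross-checked on every call: occupation times weighting Poisson
entropy rates $\theta(\mathrm{Poi}(\lambda)) = \lambda(1-\log\lambda)$ of
each outgoing jump stream, and visit counts weighting the per-pool sum of
the exponential sojourn entropy $1-\log\lambda_j$ and the categorical
entropy of the jump destination.  The latter splits $H(P)$ into a discrete
*jump part* (which includes the entry entropy $H(\beta)$, mirroring the
natural grouping of the visit-count form) and a continuous *sojourn part*;
only their sum is comparable across systems, since the sojourn part is a
differential entropy and can be negative.  Derived measures are the entropy
rate per unit time $\theta = H(P)/E[T]$, the entropy rate per jump
$\theta_J = H(P)/E[N]$, and the macroscopic system entropy
$H(M) = \|u\| H(P) = \|x^*\|\theta$.

Numerical conventions: every zero rate or probability contributes exactly
zero to an entropy sum ($0\log 0 := 0$ and $0(1-\log 0) := 0$), which keeps
the closed form well-defined for sparse $B$ and matches the limit; the
default logarithm base is $e$ (nats) and a single `base` argument rescales
every entropy by $1/\log b$; matrix exponentials (transit-time density,
impulse response) use a dense Padé scaling-and-squaring method and assume
nothing about diagonalizability of $B$; pools with $\lambda_j = 0$ are
rejected at validation (they imply a singular $B$), and a positive column
sum below $10^{-9}$ times the largest rate magnitude is clamped to zero to
absorb float-entered matrices.  The absorbing state is the last row of the
jump matrix internally and never appears among user-facing pool labels.

## The particle simulator as an oracle

`sample_path()` draws paths exactly from the generative model (entry from
$\beta$, exponential sojourns, jump-chain transitions), and
`path_log_density()` evaluates the path density above, so the sample mean
of the negative log-density is a consistent estimator of $H(P)$ with a
valid standard error.  `mc_estimates()` packages this together with
estimators of $E[T]$, $E[N]$, $E[O_j]$ and $E[N_j]$.  The test suite
demands 4-standard-error agreement between every closed form and its
Monte-Carlo estimate.  Because the estimators are exact (no discretization
of time), a disagreement can only mean an error in a closed form or in the
sampler — this dual route is the package's main correctness argument.  The
empirical standard error of a count-type statistic is floored at the
sampler's resolution $1/n$ when an event was not observed at all, so the
comparison band is never zero-width.

`mc_estimates()` advances all particles in
a vectorized batch (grouped by current pool) and is distributionally
identical to repeated `sample_path()` calls, which keeps 20,000 paths per
system cheap; the suite checks the seven reference systems and a batch of
200 randomly generated systems (2–4 pools, mixed connectivity, fixed seed)
at that sample size.  The random-system generator draws uniform rates and
inputs and rejects draws that fail validation; it emulates dense and sparse
jump structures but not the extreme stiffness (rate ratios of $10^4$ or
more) or the near-closed recycling of some real biogeochemical models, so
passing tests bound correctness, not numerical robustness at arbitrary
condition numbers.

## Maximum-entropy constructions

Two constraint classes admit closed-form maximum-entropy systems, provided
by `maxent_system_transit()` (given $u$ and $E[T]$: all internal rates 1,
diagonal $-(d - 1 + 1/E[T])$, so every pool exits at rate $1/E[T]$) and
`maxent_system_steady_state()` (given $x^*$: $B_{ij} = x^*_i/x^*_j$,
exit rates $1/x^*_j$).  The steady-state construction depends on $x^*$
alone; its equilibrium equals $x^*$ only for the compatible input
$u_j = \|x^*\| + 1 - d\,x^*_j$.  The constructor therefore verifies
$-B^{-1}u = x^*$ a posteriori and refuses incompatible inputs rather than
silently returning a system that equilibrates elsewhere; `u = NULL`
derives the compatible input, and `check = FALSE` exposes the bare formula.
Fixing the steady state breaks symmetry, so the steady-state optimum never
exceeds the transit-time optimum at matched $(u, E[T])$ — a property the
suite checks directly, along with dominance of the transit-time optimum
over hundreds of rejection-sampled feasible competitors.

## Structural identification

A tracer experiment on the two-pool system observed through $C = (1, 0)$
identifies the three coefficients of the rational transfer function
$\hat\Psi(s) = (s + \gamma_1)/(s^2 + \gamma_2 s + \gamma_3)$, but the
system has four free parameters $p = (B_{12}, B_{21}, z_1, z_2)$ — an
equifinality problem.  `identify_max_theta()` resolves it by selecting,
among all nonnegative $p$ reproducing $(\gamma_1, \gamma_2, \gamma_3)$,
the system maximizing the entropy rate per unit time $\theta$ (the path
entropy itself is unbounded over the constraint set: slowing the system
down inflates it indefinitely).

Design choices, where the design was genuinely open:

* **Constraint handling.** The three coefficient equations are kept as
  explicit equality constraints (residual form) rather than eliminated
  analytically; elimination branches on sign cases while the residual form
  is uniform in $(\gamma_1, \gamma_2, \gamma_3)$.  The local solver is an
  augmented-Lagrangian loop around box-constrained L-BFGS-B: multipliers
  and a growing quadratic penalty drive the residuals below $10^{-9}$,
  and only results with residuals below $10^{-8}$ are admitted as feasible
  local maxima.
* **Multi-start.** The constraint set is not convex, so local
  maximizations start from every node of a regular grid on $[0, 5]^4$.
  The default spacing of 1.0 (1,296 starts, about two minutes) attains the
  same optimum as spacing 0.5 (14,641 starts) on the reference problem;
  the spacing and box are arguments.  Refining the grid can only add
  starts, so the best feasible $\theta$ is non-decreasing under mesh
  halving — a monotonicity the suite asserts.
* **Tie-breaking.** Maxima within $10^{-9}$ of the best $\theta$ are
  resolved deterministically by the smallest parameter $\ell_1$-norm.
* **Infeasibility.** If no start converges to a feasible point the result
  is an explicit infeasible fit object, not an exception.

For $\gamma = (3, 5, 4)$ the procedure finds
$\theta_{\max} \approx 1.916$ at
$p \approx (1.821, 1.098, 0.902, 1.179)$, i.e.
$B \approx \begin{pmatrix}-2.0 & 1.821\\ 1.098 & -3.0\end{pmatrix}$,
and the $\theta$-optimal model is *not* the path-entropy-optimal one among
the feasible local maxima — maximizing a rate and maximizing a total are
different selections.

## The carbon-cycle model library

`emanuel_system(xi)` builds the classic five-pool terrestrial carbon model
(inputs $(77, 0, 36, 0, 0)$ PgC/yr) with rate coefficients stored as exact
rationals of the original fluxes over stocks, so that `xi = 1` reproduces
the stocks $(37, 452, 69, 81, 1121)$ PgC to machine precision rather than
to the rounding of re-derived decimals.  The modifier `xi` scales all
rates: stocks and transit time scale by $1/\xi$, the jump structure — and
with it $E[N]$ and the whole discrete jump part of the entropy — is
untouched, and the path entropy obeys the exact rescaling law
$H(\xi) = H(1) - (E[N] - 1)\log\xi$, which the suite verifies to $10^{-9}$
as an independent analytic oracle.

`wang_system(epsilon)` builds the two-pool microbial soil model (substrate
and microbial biomass) frozen at its equilibrium: assimilation
$\lambda^* = C_b^* V_s/(C_s^* + K_s)$, efficiency $\varepsilon$ into
biomass, respiration $1 - \varepsilon$ out, microbial turnover $\mu_b$
back to substrate.  Feasibility requires
$\mu_b/V_s < \varepsilon < 1$; the builder rejects the boundary where
$C_s^*$ diverges.  The default $V_s = 59.13$/yr reflects the calibration
of the source model to its reported stocks ($C_s^*$ computes to about
12,650.8 gC m$^{-2}$, matching the reported 12,650.00 approximately, and
$C_b^* = 50.36$ exactly to two decimals).

`one_pool_equivalent()` collapses any system to the single pool with the
same total input and mean transit time (path entropy $1 + \log E[T]$),
separating uncertainty due to structure from uncertainty due to speed.
`parameter_sweep()` tabulates all diagnostics over a parameter grid
(defaults: 200 log-spaced $\xi \in [0.5, 10]$; 200 linear $\varepsilon$
just inside feasibility), recording builder failures as `NA` rows.

One reproducibility caveat is worth stating plainly.  The five-pool model's
entropy break-even with its one-pool equivalent — the $\xi$ where the
detailed model's path becomes *easier* to predict than a bare exit time —
solves $H(1) - (E[N]-1)\log\xi = 1 + \log(E[T]_1/\xi)$ and computes to
$\xi = 4.49$ here, both by root-finding on the closed forms and from the
analytic solution $\exp\{(H(1) - 1 - \log E[T]_1)/(E[N]-2)\}$; the value
4.31 has also been reported for this crossing, which is not consistent
with the closed forms above given that the same inputs reproduce the
model's published stocks exactly and place the $\theta$ peak at
$\xi \approx 5.8$, consistent with its published location near 6.

## Limitations

Only autonomous systems in equilibrium are covered: no time-varying rates,
no transient solutions, and the nonlinear soil model enters only through
its frozen equilibrium linearization.  Global optimality of the identified
maximum-$\theta$ model is not provable (the constraint set is non-convex);
the multi-start grid provides a strong candidate, not a certificate.
Model dimension is assumed known — selecting $d$ from impulse-response
data is out of scope.  Entropies mix discrete and differential parts;
individual parts should never be compared across systems, only the
composite measures $H(P)$, $\theta$, $\theta_J$ and $H(M)$.
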