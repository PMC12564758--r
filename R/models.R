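# Carbon-cycle model builders and fixtures ----------------------------------

#' Five-pool global carbon-cycle system
#'
#' The classic five-pool terrestrial carbon model (non-woody tree parts,
#' woody tree parts, ground vegetation, detritus/decomposers, active soil
#' carbon) with inputs `u = (77, 0, 36, 0, 0)` PgC/yr and a lower-triangular
#' (feedback-free) rate matrix stored as exact rationals of the original
#' fluxes over stocks, e.g. `B[2, 1] = 31/37` and `B[5, 5] = -11/1121`.  An
#' environmental rate modifier `xi` scales all rates: `xi > 1` cycles carbon
#' faster, emulating warming, and leaves the jump structure (and so the mean
#' number of jumps) unchanged.  At `xi = 1` the equilibrium stocks are the
#' original `(37, 452, 69, 81, 1121)` PgC.
#'
#' @param xi positive environmental rate modifier.
#' @return a [compartmental_system()] (units PgC, yr).
#' @examples
#' round(steady_state(emanuel_system(1)))
#' @export
emanuel_system <- function(xi = 1) {
  if (xi <= 0) stop("'xi' must be positive")
  B <- matrix(0, 5L, 5L)
  B[1L, 1L] <- -77 / 37
  B[2L, 1L] <- 31 / 37
  B[4L, 1L] <- 21 / 37
  B[2L, 2L] <- -31 / 452
  B[4L, 2L] <- 15 / 452
  B[5L, 2L] <- 2 / 452
  B[3L, 3L] <- -36 / 69
  B[4L, 3L] <- 12 / 69
  B[5L, 3L] <- 6 / 69
  B[4L, 4L] <- -48 / 81
  B[5L, 4L] <- 3 / 81
  B[5L, 5L] <- -11 / 1121
  compartmental_system(
    u = c(77, 0, 36, 0, 0), B = xi * B,
    pool_names = c("nonwoody_tree", "woody_tree", "ground_vegetation",
                   "detritus", "active_soil"),
    time_unit = "yr", mass_unit = "PgC")
}

#' Two-pool microbial soil-carbon system
#'
#' The two-pool soil model of substrate organic carbon `Cs` and microbial
#' biomass carbon `Cb`: microbes assimilate substrate at the
#' Michaelis-Menten rate `lambda(x) = Cb * Vs / (Cs + Ks)`, a fraction
#' `epsilon` (carbon use efficiency) builds biomass while `1 - epsilon` is
#' respired, and dead microbes (turnover `mu_b`) return to the substrate --
#' a feedback loop.  In equilibrium
#' `Cs* = Ks / (Vs * epsilon / mu_b - 1)` and
#' `Cb* = F_NPP / (mu_b * (1/epsilon - 1))`, and the frozen linear system is
#' `B = rbind(c(-lambda*, mu_b), c(epsilon * lambda*, -mu_b))` with
#' `u = (F_NPP, 0)`.  Feasibility requires `mu_b / V_s < epsilon < 1`
#' (otherwise `Cs*` diverges or is negative).
#'
#' Defaults are the published parameter set; `V_s` was calibrated by the
#' original study to approximately meet the reported equilibrium contents
#' (`Cs*` computes to about 12650.8, not 12650.00 exactly).
#'
#' @param epsilon carbon use efficiency, in `(mu_b / V_s, 1)`.
#' @param mu_b microbial turnover rate (1/yr).
#' @param F_NPP carbon influx (gC m^-2 yr^-1).
#' @param K_s half-saturation constant (gC m^-2).
#' @param V_s maximum assimilation rate (1/yr).
#' @return a [compartmental_system()] (units gC m^-2, yr) whose steady
#'   state equals `(Cs*, Cb*)`.
#' @examples
#' round(steady_state(wang_system(0.39)), 2)
#' @export
wang_system <- function(epsilon = 0.39, mu_b = 4.38, F_NPP = 345.00,
                        K_s = 53954.83, V_s = 59.13) {
  if (any(c(mu_b, F_NPP, K_s, V_s) <= 0)) {
    stop("'mu_b', 'F_NPP', 'K_s', 'V_s' must be positive")
  }
  if (epsilon <= mu_b / V_s || epsilon >= 1) {
    stop(sprintf("'epsilon' must lie in (mu_b/V_s, 1) = (%.4f, 1)", mu_b / V_s))
  }
  Cs <- K_s / (V_s * epsilon / mu_b - 1)
  Cb <- F_NPP / (mu_b * (1 / epsilon - 1))
  lam_star <- Cb * V_s / (Cs + K_s)
  B <- matrix(c(-lam_star, epsilon * lam_star, mu_b, -mu_b), 2L, 2L)
  compartmental_system(u = c(F_NPP, 0), B = B,
                       pool_names = c("substrate", "microbial_biomass"),
                       time_unit = "yr", mass_unit = "gC m-2")
}

#' One-pool system with matched mean transit time
#'
#' Collapses a system to the single pool `M(||u||, -1/ET)` with the same
#' total input and the same mean transit time.  Its path entropy is
#' `1 + log(ET)`: the only remaining uncertainty is the exponentially
#' distributed exit time.  Comparing a multi-pool system against its
#' one-pool equivalent separates the uncertainty due to structure from the
#' uncertainty due to speed.
#'
#' @param sys a [compartmental_system()].
#' @return a one-pool [compartmental_system()]; idempotent on one-pool
#'   systems.
#' @examples
#' one_pool_equivalent(emanuel_system(1))$B  # -(1 / 15.575)
#' @export
one_pool_equivalent <- function(sys) {
  stopifnot(is.compartmental_system(sys))
  ET <- mean_transit_time(sys)
  compartmental_system(u = sum(sys$u), B = matrix(-1 / ET, 1L, 1L),
                       time_unit = sys$time_unit, mass_unit = sys$mass_unit)
}

#' Random open compartmental system
#'
#' Fixture generator: draws off-diagonal rates `~ Unif(0.1, 2)` with edge
#' probability `connectivity`, exit rates `~ Unif(0.1, 2)` for a random
#' nonempty subset of pools, and inputs `~ Unif(0, 1)` with at least one
#' positive entry; draws are rejected until the system passes validation
#' (openness can fail when no exit is reachable).
#'
#' @param d number of pools.
#' @param connectivity probability of each internal edge, in `(0, 1]`.
#' @param max_tries rejection-loop bound.
#' @return a validated [compartmental_system()].
#' @examples
#' set.seed(1)
#' random_system(3)
#' @export
random_system <- function(d, connectivity = 0.5, max_tries = 1000L) {
  stopifnot(d >= 1, connectivity > 0, connectivity <= 1)
  for (k in seq_len(max_tries)) {
    R <- matrix(stats::runif(d * d, 0.1, 2), d, d) *
      matrix(stats::runif(d * d) < connectivity, d, d)
    diag(R) <- 0
    nexit <- sample.int(d, 1L)
    z <- numeric(d)
    z[sample.int(d, nexit)] <- stats::runif(nexit, 0.1, 2)
    B <- R
    diag(B) <- -(colSums(R) + z)
    u <- stats::runif(d)
    u[sample.int(d, 1L)] <- stats::runif(1L, 0.5, 1)
    sys <- tryCatch(compartmental_system(u, B), error = function(e) NULL)
    if (!is.null(sys)) return(sys)
  }
  stop("failed to draw a valid open system; increase 'connectivity'")
}

#' Parameter sweep of entropy diagnostics
#'
#' Evaluates all equilibrium and entropy quantities over a grid of the
#' builder's parameter (the rate modifier `xi` for
#' [emanuel_system()], the carbon use efficiency `epsilon` for
#' [wang_system()], or any user function returning a system), together with
#' the matched one-pool equivalent's path entropy and rates.  Builder
#' failures (e.g. infeasible `epsilon`) are recorded as `NA` rows, not
#' errors.
#'
#' @param builder `"emanuel"`, `"wang"`, or a function of one parameter
#'   returning a [compartmental_system()].
#' @param values numeric vector of parameter values; defaults to 200
#'   log-spaced points on `[0.5, 10]` for `"emanuel"` and 200 linear points
#'   just inside the feasible `epsilon` interval for `"wang"`.
#' @param base logarithm base for the entropies.
#' @return data frame with one row per parameter value: `value`, `ET`,
#'   `EN`, `H_path`, `H_jump_part`, `H_sojourn_part`, `theta_time`,
#'   `theta_jump`, `x_star` (list column of stocks), and the matched
#'   one-pool `H_path_1pool`, `theta_time_1pool`, `theta_jump_1pool`.
#' @examples
#' sw <- parameter_sweep("emanuel", values = c(0.5, 1, 2))
#' sw$EN  # constant: the rate modifier does not change the jump structure
#' @export
parameter_sweep <- function(builder, values = NULL, base = exp(1)) {
  if (is.character(builder)) {
    builder <- match.arg(builder, c("emanuel", "wang"))
    fn <- switch(builder,
                 emanuel = emanuel_system,
                 wang = function(v) wang_system(epsilon = v))
    if (is.null(values)) {
      values <- switch(builder,
                       emanuel = exp(seq(log(0.5), log(10), length.out = 200L)),
                       wang = seq(0.08, 0.99, length.out = 200L))
    }
  } else {
    fn <- builder
    if (is.null(values)) stop("'values' must be given for a custom builder")
  }
  rows <- lapply(values, function(v) {
    sys <- tryCatch(fn(v), error = function(e) NULL)
    if (is.null(sys)) {
      return(data.frame(value = v, ET = NA_real_, EN = NA_real_,
                        H_path = NA_real_, H_jump_part = NA_real_,
                        H_sojourn_part = NA_real_, theta_time = NA_real_,
                        theta_jump = NA_real_, H_path_1pool = NA_real_,
                        theta_time_1pool = NA_real_,
                        theta_jump_1pool = NA_real_))
    }
    ent <- path_entropy(sys, base = base)
    one <- path_entropy(one_pool_equivalent(sys), base = base)
    out <- data.frame(value = v, ET = ent$ET, EN = ent$EN,
                      H_path = ent$H_path, H_jump_part = ent$H_jump_part,
                      H_sojourn_part = ent$H_sojourn_part,
                      theta_time = ent$theta_time,
                      theta_jump = ent$theta_jump,
                      H_path_1pool = one$H_path,
                      theta_time_1pool = one$theta_time,
                      theta_jump_1pool = one$theta_jump)
    out$x_star <- list(steady_state(sys))
    out
  })
  has_xs <- vapply(rows, function(r) "x_star" %in% names(r), logical(1))
  if (any(has_xs) && !all(has_xs)) {
    rows <- lapply(rows, function(r) {
      if (!"x_star" %in% names(r)) r$x_star <- list(NULL)
      r
    })
  }
  do.call(rbind, rows)
}

#' Reference systems with simple structure
#'
#' The seven benchmark systems used to illustrate the entropy measures: a
#' generic one-pool system, two-pool serial and parallel chains, a two-pool
#' feedback loop, a symmetric two-pool exchange, a three-pool serial
#' cascade, and three parallel pools.  `reference_system(row)` returns one
#' of them; `reference_entropy_table()` evaluates `theta_jump`, `EN`,
#' `theta_time`, `ET` and `H_path` for all seven.
#'
#' @param row integer 1-7.
#' @param lambda rate for the generic one-pool row (row 1).
#' @param base logarithm base for the entropies.
#' @return `reference_system()`: a [compartmental_system()];
#'   `reference_entropy_table()`: a data frame with columns `row`,
#'   `structure`, `theta_jump`, `EN`, `theta_time`, `ET`, `H_path`.
#' @examples
#' round(reference_entropy_table()[, -2], 2)
#' @export
reference_system <- function(row, lambda = 1) {
  switch(as.integer(row),
    compartmental_system(1, matrix(-lambda, 1L, 1L)),                        # 1
    compartmental_system(c(1, 0), rbind(c(-1, 0), c(1, -1))),                # 2
    compartmental_system(c(1, 1), rbind(c(-1, 0), c(0, -1))),                # 3
    compartmental_system(c(1, 0), rbind(c(-1, 0.5), c(1, -1))),              # 4
    compartmental_system(c(1, 1), rbind(c(-1, 0.5), c(0.5, -1))),            # 5
    compartmental_system(c(1, 0, 0),
                         rbind(c(-1, 0, 0), c(1, -1, 0), c(0, 1, -1))),      # 6
    compartmental_system(c(1, 1, 1), diag(-1, 3L)),                          # 7
    stop("'row' must be an integer between 1 and 7")
  )
}

#' @rdname reference_system
#' @export
reference_entropy_table <- function(lambda = 1, base = exp(1)) {
  structures <- c("one pool (rate lambda)", "two-pool serial",
                  "two-pool parallel", "two-pool feedback",
                  "two-pool symmetric exchange", "three-pool serial",
                  "three-pool parallel")
  rows <- lapply(1:7, function(i) {
    ent <- path_entropy(reference_system(i, lambda = lambda), base = base)
    data.frame(row = i, structure = structures[i],
               theta_jump = ent$theta_jump, EN = ent$EN,
               theta_time = ent$theta_time, ET = ent$ET,
               H_path = ent$H_path)
  })
  do.call(rbind, rows)
}
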