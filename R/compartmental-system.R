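#' Define an open compartmental system in equilibrium
#'
#' Constructs and validates a linear autonomous compartmental system
#' \deqn{dx/dt = B x + u,}
#' where `u` is the vector of nonnegative external input fluxes (mass/time)
#' and `B` is the d x d compartmental matrix of rate coefficients (1/time).
#' Off-diagonal entries `B[i, j] >= 0` are flux rates from pool `j` to pool
#' `i`; `-B[j, j]` is the total rate of fluxes out of pool `j`; the
#' nonpositive column sum `-sum(B[, j])` is the rate `z[j]` of the flux from
#' pool `j` out of the system.  The system must be *open*: `B` invertible,
#' equivalently every particle eventually leaves.  The object represents the
#' system at its unique equilibrium `x* = -B^{-1} u`.
#'
#' Validation enforces: nonnegative off-diagonals, strictly negative
#' diagonal, nonpositive column sums (a tiny positive column sum, below
#' `1e-9` times the largest rate magnitude, is clamped to zero to absorb
#' float-entered matrices), invertible `B` with nonnegative equilibrium
#' stocks, and a nonzero nonnegative `u`.
#'
#' @param u numeric vector of external input fluxes, length `d`.
#' @param B numeric `d` x `d` compartmental matrix.
#' @param pool_names optional character vector of `d` pool labels.
#' @param time_unit,mass_unit free-text unit tags (metadata only).
#'
#' @return An object of class `"compartmental_system"`: a list with elements
#'   `u`, `B`, `d`, `pool_names`, `time_unit`, `mass_unit`.
#'
#' @examples
#' # two-pool serial chain: pool 1 -> pool 2 -> out
#' sys <- compartmental_system(u = c(1, 0), B = rbind(c(-1, 0), c(1, -1)))
#' steady_state(sys)
#'
#' @seealso [system_diagnostics()], [path_entropy()], [steady_state()]
#' @export
compartmental_system <- function(u, B, pool_names = NULL,
                                 time_unit = "time", mass_unit = "mass") {
  u <- as.numeric(u)
  if (is.data.frame(B)) B <- as.matrix(B)
  if (!is.matrix(B)) B <- matrix(as.numeric(B), nrow = length(u))
  storage.mode(B) <- "double"
  d <- length(u)
  if (d < 1L) stop("'u' must have length >= 1")
  if (!all(dim(B) == c(d, d))) {
    stop(sprintf("dimension mismatch: length(u) = %d but dim(B) = %d x %d",
                 d, nrow(B), ncol(B)))
  }
  if (anyNA(u) || anyNA(B)) stop("'u' and 'B' must not contain NA")
  if (any(u < 0)) stop("'u' must be nonnegative componentwise")
  if (sum(u) == 0) stop("'u' must have at least one positive entry")

  offdiag <- B; diag(offdiag) <- 0
  if (any(offdiag < 0)) {
    bad <- which(offdiag < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative off-diagonal rate B[%d, %d]", bad[1L], bad[2L]))
  }
  if (any(diag(B) >= 0)) {
    stop(sprintf("diagonal entry B[%d, %d] must be negative (pool with no outflow)",
                 which(diag(B) >= 0)[1L], which(diag(B) >= 0)[1L]))
  }

  # clamp float dust in column sums: z_j = 0 is allowed, z_j < 0 is not
  cs <- colSums(B)
  tol <- 1e-9 * max(abs(B))
  fix <- cs > 0 & cs <= tol
  if (any(fix)) {
    for (j in which(fix)) B[j, j] <- B[j, j] - cs[j]
    cs[fix] <- 0
  }
  if (any(cs > 0)) {
    stop(sprintf("column %d of B has positive sum %.3g: pool creates mass",
                 which(cs > 0)[1L], max(cs)))
  }

  xs <- tryCatch(solve(B, -u), error = function(e) NULL)
  if (is.null(xs) || rcond(B) < .Machine$double.eps * 1e2) {
    stop("B is singular or numerically singular: the system is closed, not open")
  }
  if (any(xs < -1e-10 * max(abs(xs), 1))) {
    stop("equilibrium stocks -B^{-1} u have negative components; B is not a valid open compartmental matrix")
  }

  if (!is.null(pool_names)) {
    pool_names <- as.character(pool_names)
    if (length(pool_names) != d) stop("'pool_names' must have length d")
  }

  structure(
    list(u = u, B = B, d = d, pool_names = pool_names,
         time_unit = time_unit, mass_unit = mass_unit),
    class = "compartmental_system"
  )
}

#' Test for a compartmental system object
#' @param x object to test.
#' @return `TRUE` for objects created by [compartmental_system()].
#' @export
is.compartmental_system <- function(x) inherits(x, "compartmental_system")

#' @export
print.compartmental_system <- function(x, digits = 4L, ...) {
  cat(sprintf("Open compartmental system in equilibrium (%d pool%s)\n",
              x$d, if (x$d == 1L) "" else "s"))
  nm <- if (is.null(x$pool_names)) paste0("pool", seq_len(x$d)) else x$pool_names
  cat(sprintf("  units: %s / %s\n", x$mass_unit, x$time_unit))
  cat("  input fluxes u:\n")
  uu <- x$u; names(uu) <- nm
  print(signif(uu, digits))
  cat("  rate matrix B:\n")
  BB <- x$B; dimnames(BB) <- list(nm, nm)
  print(signif(BB, digits))
  cat(sprintf("  mean transit time: %s %s;  mean jumps: %s\n",
              format(signif(mean_transit_time(x), digits)), x$time_unit,
              format(signif(expected_jumps(x), digits))))
  invisible(x)
}

#' Equilibrium stocks of a compartmental system
#'
#' Solves `B x* + u = 0` for the unique steady-state compartment vector
#' `x* = -B^{-1} u`.
#'
#' @param sys a [compartmental_system()].
#' @return numeric vector of equilibrium stocks (mass), length `d`.
#' @examples
#' steady_state(compartmental_system(c(1, 0), rbind(c(-1, 0.5), c(1, -1))))
#' @export
steady_state <- function(sys) {
  stopifnot(is.compartmental_system(sys))
  xs <- solve(sys$B, -sys$u)
  names(xs) <- sys$pool_names
  pmax(xs, 0)
}

# internal shortcuts used throughout ---------------------------------------

# dense matrix exponential (Pade with scaling/squaring; no diagonalizability
# assumption on B)
mexp <- function(A) as.matrix(Matrix::expm(A))

exit_rates <- function(sys) pmax(-colSums(sys$B), 0)       # z_j, 1/time
total_rates <- function(sys) -diag(sys$B)                  # lambda_j, 1/time
entry_distribution <- function(sys) sys$u / sum(sys$u)     # beta

mean_transit_time <- function(sys) sum(steady_state(sys)) / sum(sys$u)

expected_jumps <- function(sys) {
  xs <- steady_state(sys)
  1 + sum(total_rates(sys) * xs) / sum(sys$u)
}

#' Markov-chain diagnostics of a compartmental system
#'
#' Derives every quantity of the one-particle absorbing continuous-time
#' Markov chain that the entropy formulas consume: the entry distribution
#' `beta = u/||u||`, exit rates `z = -colSums(B)`, total exit rates
#' `lambda_j = -B[j, j]`, the column-stochastic one-step jump matrix of the
#' embedded jump chain (with the absorbing environment as an extra final
#' row), the fundamental matrix `M = (I - P|S)^{-1}` of expected visit
#' counts, expected visits per pool `EN_j = lambda_j x*_j / ||u||`, the
#' total expected number of jumps `EN = sum(EN_j) + 1` (the last jump leaves
#' the system), the mean transit time `ET = ||x*|| / ||u||` (total stocks
#' over total fluxes), and expected occupation times `EO_j = x*_j / ||u||`.
#'
#' @param sys a [compartmental_system()].
#' @return An object of class `"equilibrium_diagnostics"`: a list with
#'   elements `x_star`, `beta`, `z`, `lam`, `jump_matrix` ((d+1) x d,
#'   columns sum to one), `fundamental`, `r` (external output fluxes
#'   `z * x*`), `ET`, `EN_per_pool`, `EN`, `EO`.
#' @examples
#' dg <- system_diagnostics(
#'   compartmental_system(c(1, 0), rbind(c(-1, 0.5), c(1, -1))))
#' dg$ET  # 4: mean transit time of the feedback system
#' dg$EN  # 5: mean number of jumps including the final exit
#' @export
system_diagnostics <- function(sys) {
  stopifnot(is.compartmental_system(sys))
  d <- sys$d
  xs <- steady_state(sys)
  z <- exit_rates(sys)
  lam <- total_rates(sys)
  if (any(lam <= 0)) stop("every pool must have a positive total exit rate")
  beta <- entry_distribution(sys)

  P <- sweep(sys$B, 2L, lam, "/")
  diag(P) <- 0
  jump <- rbind(P, z / lam)                       # (d+1) x d, column-stochastic
  M <- solve(diag(d) - P)                         # fundamental matrix

  normu <- sum(sys$u)
  EN_per_pool <- lam * xs / normu
  nm <- sys$pool_names
  if (!is.null(nm)) {
    names(z) <- names(lam) <- names(beta) <- names(EN_per_pool) <- nm
    dimnames(M) <- list(nm, nm)
    dimnames(jump) <- list(c(nm, "out"), nm)
  }

  structure(
    list(x_star = xs, beta = beta, z = z, lam = lam,
         jump_matrix = jump, fundamental = M,
         r = z * xs,
         ET = sum(xs) / normu,
         EN_per_pool = EN_per_pool,
         EN = 1 + sum(EN_per_pool),
         EO = xs / normu),
    class = "equilibrium_diagnostics"
  )
}

#' @export
print.equilibrium_diagnostics <- function(x, digits = 4L, ...) {
  cat("Equilibrium one-particle diagnostics\n")
  cat("  steady-state stocks x*: ", paste(signif(x$x_star, digits), collapse = ", "), "\n")
  cat("  entry distribution beta:", paste(signif(x$beta, digits), collapse = ", "), "\n")
  cat("  exit rates z:           ", paste(signif(x$z, digits), collapse = ", "), "\n")
  cat(sprintf("  mean transit time E[T] = %s\n", format(signif(x$ET, digits))))
  cat(sprintf("  mean number of jumps E[N] = %s\n", format(signif(x$EN, digits))))
  invisible(x)
}

#' Transit-time density of a compartmental system
#'
#' The time from a particle's entry to its exit is phase-type distributed
#' with density `f_T(t) = z' expm(t B) beta`.  Its mean is the turnover time
#' `||x*|| / ||u||`.
#'
#' @param sys a [compartmental_system()].
#' @param t numeric vector of nonnegative times.
#' @return numeric vector of density values.
#' @examples
#' sys <- compartmental_system(1, matrix(-2, 1, 1))
#' transit_time_density(sys, 0.5)  # dexp(0.5, rate = 2)
#' @export
transit_time_density <- function(sys, t) {
  stopifnot(is.compartmental_system(sys))
  if (any(t < 0)) stop("'t' must be nonnegative")
  z <- exit_rates(sys)
  beta <- entry_distribution(sys)
  vapply(t, function(tt) {
    as.numeric(z %*% mexp(tt * sys$B) %*% beta)
  }, numeric(1))
}

#' Transfer function and impulse response
#'
#' For an experiment that injects an impulse through the input-distribution
#' matrix `A` (d x m) and observes pools through the output-connection
#' matrix `C` (k x d), the impulse response is `Psi(t) = C expm(t B) A` and
#' its Laplace transform, the transfer function, is
#' `Psi_hat(s) = C (s I - B)^{-1} A`.  Tracer experiments identify the
#' coefficients of `Psi_hat`, which is the entry point of structural model
#' identification.
#'
#' @param sys a [compartmental_system()].
#' @param A input-distribution matrix (d x m); defaults to the identity.
#' @param C output-connection matrix (k x d); defaults to the identity.
#' @param s nonnegative Laplace variable (scalar).
#' @param t nonnegative time (scalar).
#' @return a k x m numeric matrix.
#' @examples
#' sys <- compartmental_system(1, matrix(-2, 1, 1))
#' transfer_function(sys, s = 1)  # 1 / (1 + 2)
#' @export
transfer_function <- function(sys, A = diag(sys$d), C = diag(sys$d), s) {
  stopifnot(is.compartmental_system(sys), length(s) == 1L, s >= 0)
  A <- as.matrix(A); C <- as.matrix(C)
  if (nrow(A) != sys$d || ncol(C) != sys$d) {
    stop("'A' must be d x m and 'C' must be k x d")
  }
  C %*% solve(s * diag(sys$d) - sys$B, A)
}

#' @rdname transfer_function
#' @export
impulse_response <- function(sys, A = diag(sys$d), C = diag(sys$d), t) {
  stopifnot(is.compartmental_system(sys), length(t) == 1L, t >= 0)
  A <- as.matrix(A); C <- as.matrix(C)
  if (nrow(A) != sys$d || ncol(C) != sys$d) {
    stop("'A' must be d x m and 'C' must be k x d")
  }
  C %*% mexp(t * sys$B) %*% A
}

#' @export
summary.compartmental_system <- function(object, base = exp(1), ...) {
  out <- list(system = object,
              diagnostics = system_diagnostics(object),
              entropy = path_entropy(object, base = base))
  class(out) <- "summary.compartmental_system"
  out
}

#' @export
print.summary.compartmental_system <- function(x, digits = 4L, ...) {
  print(x$system, digits = digits)
  cat("\n")
  print(x$diagnostics, digits = digits)
  cat("\n")
  print(x$entropy, digits = digits)
  invisible(x)
}

#' @export
plot.compartmental_system <- function(x, t_max = NULL, n = 200L, ...) {
  if (is.null(t_max)) t_max <- 5 * mean_transit_time(x)
  tt <- seq(0, t_max, length.out = n)
  plot(tt, transit_time_density(x, tt), type = "l",
       xlab = sprintf("transit time [%s]", x$time_unit),
       ylab = "density", main = "Transit-time distribution", ...)
  invisible(x)
}
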