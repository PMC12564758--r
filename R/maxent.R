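# Maximum-entropy constructors ----------------------------------------------

#' Maximum-entropy system given input and mean transit time
#'
#' Among all `d`-pool open compartmental systems with a prescribed input
#' vector `u` and mean transit time `E[T]` (steady state free), the path
#' entropy -- equivalently the entropy rate per unit time -- is maximized by
#' the fully symmetric system with every internal rate equal to one and
#' diagonal `-lambda`, where `lambda = d - 1 + 1/ET`.  Every pool then
#' leaves the system at rate `1/ET`.  For `d = 1` this reduces to
#' `B = -1/ET`: the exponential distribution is the maximum-entropy
#' nonnegative distribution with fixed mean.
#'
#' @param u nonnegative nonzero input vector (defines `d` unless `d` given).
#' @param transit_time prescribed mean transit time (> 0).
#' @param d number of pools; defaults to `length(u)`.
#' @return a [compartmental_system()] whose diagnosed mean transit time
#'   equals `transit_time`.
#' @examples
#' sys <- maxent_system_transit(c(1, 1, 1), transit_time = 2)
#' system_diagnostics(sys)$ET  # 2
#' @export
maxent_system_transit <- function(u, transit_time, d = length(u)) {
  if (transit_time <= 0) stop("'transit_time' must be positive")
  if (length(u) != d) stop("'u' must have length d")
  lam <- d - 1 + 1 / transit_time
  B <- matrix(1, d, d)
  diag(B) <- -lam
  compartmental_system(u, B)
}

#' Maximum-entropy system given input and steady state
#'
#' Among systems with prescribed input `u` and steady-state stocks `x*`,
#' the path entropy is maximized by
#' `B[i, j] = x*_i / x*_j` off the diagonal and
#' `B[j, j] = -sum_{k != j} x*_k / x*_j - 1 / x*_j`, so each pool's exit
#' rate to the environment is `1 / x*_j`.  This matrix depends on `x*`
#' alone; it has equilibrium exactly `x*` only for the compatible input
#' `u_j = ||x*|| + 1 - d * x*_j`.  With `check = TRUE` (default) the
#' constructor verifies `-B^{-1} u = x*` and errors if `u` and `x*` are
#' incompatible; `u = NULL` derives the compatible input automatically.
#'
#' @param x_star strictly positive steady-state vector.
#' @param u input vector, or `NULL` to use the compatible input.
#' @param check verify a posteriori that the constructed system's steady
#'   state equals `x_star`.
#' @return a [compartmental_system()].
#' @examples
#' sys <- maxent_system_steady_state(c(1, 1))
#' sys$B  # rbind(c(-2, 1), c(1, -2))
#' @export
maxent_system_steady_state <- function(x_star, u = NULL, check = TRUE) {
  if (any(x_star <= 0)) stop("'x_star' must be positive componentwise")
  d <- length(x_star)
  B <- outer(x_star, 1 / x_star)
  diag(B) <- -vapply(seq_len(d), function(j) {
    sum(x_star[-j]) / x_star[j] + 1 / x_star[j]
  }, numeric(1))
  if (is.null(u)) u <- sum(x_star) + 1 - d * x_star
  if (any(u < -1e-12)) {
    stop("no nonnegative input is compatible with this steady state")
  }
  sys <- compartmental_system(pmax(u, 0), B)
  if (check) {
    xs <- steady_state(sys)
    if (max(abs(xs - x_star)) > 1e-8 * max(x_star)) {
      stop("input 'u' is incompatible with 'x_star': the constructed system equilibrates elsewhere")
    }
  }
  sys
}

# Structural identification --------------------------------------------------

#' Transfer-function coefficients of the two-pool identification problem
#'
#' For the two-pool system observed through `C = (1, 0)` with `A = I`, the
#' transfer function is the rational `(s + gamma1) / (s^2 + gamma2 s +
#' gamma3)` with
#' `gamma1 = B12 + z2`, `gamma2 = B21 + z1 + B12 + z2`,
#' `gamma3 = z1 B12 + z1 z2 + B21 z2`,
#' in the free parameters `p = (B12, B21, z1, z2)` (internal rates and
#' environment exit rates; `B11 = -(z1 + B21)`, `B22 = -(z2 + B12)`).
#'
#' @param p numeric vector `(B12, B21, z1, z2)`, all `>= 0`.
#' @return named numeric vector `c(gamma1, gamma2, gamma3)`.
#' @examples
#' gammas_from_parameters(c(1.821, 1.098, 0.902, 1.179))  # ~ (3, 5, 4)
#' @export
gammas_from_parameters <- function(p) {
  stopifnot(length(p) == 4L)
  B12 <- p[1L]; B21 <- p[2L]; z1 <- p[3L]; z2 <- p[4L]
  c(gamma1 = B12 + z2,
    gamma2 = B21 + z1 + B12 + z2,
    gamma3 = z1 * B12 + z1 * z2 + B21 * z2)
}

# build the two-pool system from the identification parameters; NULL if the
# parameters do not give a valid open system with positive stocks
system_from_parameters <- function(p, u = c(1, 0)) {
  B12 <- p[1L]; B21 <- p[2L]; z1 <- p[3L]; z2 <- p[4L]
  lam1 <- z1 + B21; lam2 <- z2 + B12
  if (lam1 <= 0 || lam2 <= 0) return(NULL)
  B <- matrix(c(-lam1, B21, B12, -lam2), 2L, 2L)
  xs <- tryCatch(solve(B, -u), error = function(e) NULL)
  if (is.null(xs) || any(!is.finite(xs)) || any(xs <= 0)) return(NULL)
  tryCatch(compartmental_system(u, B), error = function(e) NULL)
}

# fast inline theta(P) for the two-pool parameterization (identical to
# path_entropy()$theta_time; kept branch-free for the optimizer's inner loop)
theta_from_parameters <- function(p, u = c(1, 0)) {
  B12 <- p[1L]; B21 <- p[2L]; z1 <- p[3L]; z2 <- p[4L]
  lam1 <- z1 + B21; lam2 <- z2 + B12
  if (lam1 <= 0 || lam2 <= 0) return(NA_real_)
  B <- matrix(c(-lam1, B21, B12, -lam2), 2L, 2L)
  xs <- tryCatch(solve(B, -u), error = function(e) NULL)
  if (is.null(xs) || any(!is.finite(xs)) || any(xs <= 0)) return(NA_real_)
  beta <- u / sum(u)
  H <- -sum(xlogx(beta)) +
    (xs[1L] * (xlog1x(B21) + xlog1x(z1)) +
     xs[2L] * (xlog1x(B12) + xlog1x(z2))) / sum(u)
  H / (sum(xs) / sum(u))
}

# Augmented-Lagrangian minimizer with nonlinear equality constraints and box
# bounds: outer multiplier updates around stats::optim L-BFGS-B inner solves.
auglag_minimize <- function(x0, fn, heq, lower, upper,
                            feas_tol = 1e-9, outer_max = 40L,
                            inner_maxit = 200L) {
  mult <- rep(0, length(heq(x0)))
  rho <- 10
  x <- x0
  for (it in seq_len(outer_max)) {
    lagrangian <- function(p) {
      f <- fn(p)
      if (!is.finite(f)) return(1e8)
      cc <- heq(p)
      f + sum(mult * cc) + 0.5 * rho * sum(cc^2)
    }
    r <- tryCatch(
      stats::optim(x, lagrangian, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = inner_maxit, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(r)) return(NULL)
    x <- r$par
    cc <- heq(x)
    if (max(abs(cc)) < feas_tol) break
    mult <- mult + rho * cc
    rho <- min(rho * 4, 1e10)
  }
  list(par = x, value = fn(x), residual = max(abs(heq(x))))
}

#' Identify the maximum-entropy-rate system from transfer-function data
#'
#' Solves the structural identification problem for the two-pool system
#' observed through `C = (1, 0)`: among all nonnegative parameter vectors
#' `p = (B12, B21, z1, z2)` reproducing the measured transfer-function
#' coefficients `(gamma1, gamma2, gamma3)` (three equations, four
#' unknowns -- the system is non-identifiable), select the one maximizing
#' the entropy rate per unit time `theta(P)`.  The constraint set is not
#' convex, so local constrained maximizations (augmented-Lagrangian with the
#' three coefficient residuals as equality constraints) are started from
#' every node of a regular grid over `[0, box]^4` and the best feasible
#' local maximum is returned.  Note that `theta`, not the path entropy, is
#' maximized: path entropy is unbounded over the constraint set (slowing a
#' system down inflates it indefinitely).
#'
#' @param gamma numeric vector `(gamma1, gamma2, gamma3)`, all positive.
#' @param u input vector; the built-in constraint map assumes the two-pool
#'   problem with `u = c(1, 0)`.
#' @param mesh grid spacing of the multi-start grid (default 1, i.e. 1296
#'   starts over `[0, 5]^4`).
#' @param box upper edge of the start grid cube.
#' @param feas_tol feasibility tolerance on the coefficient residuals.
#' @param verbose print progress every few hundred starts.
#' @return An object of class `"maxent_ident"`: list with `best_system`,
#'   `best_theta`, `best_parameters`, `local_maxima` (data frame of
#'   converged feasible maxima: parameters, theta, residual), `n_starts`,
#'   `feasible` (`FALSE` if no start converged to a feasible point), and
#'   `settings`.
#' @examples
#' \donttest{
#' fit <- identify_max_theta(c(3, 5, 4), mesh = 2.5)
#' fit$best_theta  # ~ 1.916
#' }
#' @export
identify_max_theta <- function(gamma, u = c(1, 0), mesh = 1, box = 5,
                               feas_tol = 1e-9, verbose = FALSE) {
  stopifnot(length(gamma) == 3L, all(gamma > 0), mesh > 0, box > 0)
  heq <- function(p) gammas_from_parameters(p) - gamma
  negobj <- function(p) {
    v <- theta_from_parameters(p, u = u)
    if (is.na(v)) 1e8 else -v
  }
  axis <- seq(0, box, by = mesh)
  starts <- as.matrix(expand.grid(axis, axis, axis, axis,
                                  KEEP.OUT.ATTRS = FALSE))
  ub <- rep(max(4 * box, 2 * max(gamma)), 4L)

  rows <- vector("list", nrow(starts))
  for (k in seq_len(nrow(starts))) {
    if (verbose && k %% 500L == 0L) {
      message(sprintf("start %d / %d", k, nrow(starts)))
    }
    r <- auglag_minimize(starts[k, ], negobj, heq,
                         lower = rep(0, 4L), upper = ub,
                         feas_tol = feas_tol)
    if (is.null(r)) next
    th <- theta_from_parameters(r$par, u = u)
    if (!is.finite(th) || r$residual > 1e-8 || any(r$par < -1e-12)) next
    rows[[k]] <- c(r$par, th, r$residual)
  }
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])

  settings <- list(mesh = mesh, box = box, feas_tol = feas_tol,
                   optimizer = "augmented Lagrangian / L-BFGS-B")
  if (is.null(rows) || nrow(rows) == 0L) {
    return(structure(list(best_system = NULL, best_theta = NA_real_,
                          best_parameters = NULL,
                          local_maxima = NULL, n_starts = nrow(starts),
                          feasible = FALSE, gamma = gamma, u = u,
                          settings = settings),
                     class = "maxent_ident"))
  }
  maxima <- data.frame(B12 = rows[, 1L], B21 = rows[, 2L],
                       z1 = rows[, 3L], z2 = rows[, 4L],
                       theta = rows[, 5L], residual = rows[, 6L])

  # best theta; ties (within 1e-9) broken deterministically by smallest
  # parameter l1-norm
  top <- maxima[maxima$theta >= max(maxima$theta) - 1e-9, , drop = FALSE]
  l1 <- rowSums(abs(top[, 1:4, drop = FALSE]))
  best <- top[which.min(l1), ]
  best_p <- as.numeric(best[1L, 1:4])

  structure(
    list(best_system = system_from_parameters(best_p, u = u),
         best_theta = best$theta,
         best_parameters = c(B12 = best_p[1L], B21 = best_p[2L],
                             z1 = best_p[3L], z2 = best_p[4L]),
         local_maxima = maxima,
         n_starts = nrow(starts),
         feasible = TRUE,
         gamma = gamma, u = u,
         settings = settings),
    class = "maxent_ident"
  )
}

#' @export
print.maxent_ident <- function(x, digits = 4L, ...) {
  cat("Maximum-entropy-rate structural identification (two-pool)\n")
  cat(sprintf("  constraints gamma = (%s)\n",
              paste(format(x$gamma), collapse = ", ")))
  if (!x$feasible) {
    cat("  no feasible point found from any start: infeasible constraints\n")
    return(invisible(x))
  }
  cat(sprintf("  %d grid starts (mesh %g over [0, %g]^4), %d feasible local maxima\n",
              x$n_starts, x$settings$mesh, x$settings$box,
              nrow(x$local_maxima)))
  cat(sprintf("  best theta = %s per %s\n",
              format(signif(x$best_theta, digits)), "unit time"))
  cat("  best parameters (B12, B21, z1, z2):",
      paste(signif(x$best_parameters, digits), collapse = ", "), "\n")
  cat("  best compartmental matrix:\n")
  print(signif(x$best_system$B, digits))
  invisible(x)
}

#' @export
summary.maxent_ident <- function(object, ...) {
  if (object$feasible) {
    ord <- order(-object$local_maxima$theta)
    object$local_maxima <- object$local_maxima[ord, ]
  }
  object
}

#' @export
coef.maxent_ident <- function(object, ...) object$best_parameters
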