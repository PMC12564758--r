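# Single-particle path simulation -------------------------------------------
#
# The simulator is the independent Monte-Carlo cross-check for every closed
# form in the package: sojourn times are exponential with the pool's total
# exit rate, destinations are drawn from the embedded jump chain, and the
# journey ends with the jump into the absorbing environment.

#' Sample one particle path
#'
#' Draws the entry pool from the entry distribution `beta = u/||u||`, then
#' alternates exponential sojourns (rate `lambda_j = -B[j, j]`) with jumps
#' drawn from column `j` of the one-step jump matrix until the particle
#' leaves the system.  Absorption happens with probability one for an open
#' system; a safety cap of `1e7` jumps raises an error rather than silently
#' truncating.
#'
#' @param sys a [compartmental_system()].
#' @param max_jumps safety cap on the number of jumps.
#' @return An object of class `"particle_path"`: a list with `pools`
#'   (visited pool indices, consecutive entries always differ), `sojourns`
#'   (matching positive durations), and `absorbed = TRUE`.
#' @examples
#' sys <- compartmental_system(c(1, 0), rbind(c(-1, 0), c(1, -1)))
#' set.seed(1)
#' sample_path(sys)$pools  # always c(1, 2) for the serial chain
#' @export
sample_path <- function(sys, max_jumps = 1e7) {
  stopifnot(is.compartmental_system(sys))
  d <- sys$d
  lam <- total_rates(sys)
  beta <- entry_distribution(sys)
  jump <- rbind({
    P <- sweep(sys$B, 2L, lam, "/"); diag(P) <- 0; P
  }, exit_rates(sys) / lam)

  pools <- integer(0)
  sojourns <- numeric(0)
  j <- sample.int(d, 1L, prob = beta)
  n <- 0L
  repeat {
    n <- n + 1L
    if (n > max_jumps) {
      stop("particle exceeded the jump safety cap; B may be nearly singular")
    }
    pools[n] <- j
    sojourns[n] <- stats::rexp(1L, rate = lam[j])
    nxt <- sample.int(d + 1L, 1L, prob = jump[, j])
    if (nxt == d + 1L) break
    j <- nxt
  }
  structure(list(pools = pools, sojourns = sojourns, absorbed = TRUE),
            class = "particle_path")
}

#' @export
print.particle_path <- function(x, ...) {
  cat(sprintf("Particle path: %d sojourn%s, transit time %.4g\n",
              length(x$pools), if (length(x$pools) == 1L) "" else "s",
              sum(x$sojourns)))
  cat("  pools:   ", paste(x$pools, collapse = " -> "), " -> out\n")
  invisible(x)
}

#' Simulate particle paths
#'
#' `simulate()` method drawing `nsim` independent particle paths.  The
#' `seed` argument mirrors [stats::simulate()]: if non-`NULL` the global
#' random state is saved, the seed applied, and the previous state restored
#' on exit, so the call is reproducible and side-effect free.
#'
#' @param object a [compartmental_system()].
#' @param nsim number of paths.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of [sample_path()] objects.
#' @export
simulate.compartmental_system <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  replicate(nsim, sample_path(object), simplify = FALSE)
}

#' Summarize a path into transition counts and occupation times
#'
#' @param path a [sample_path()] object.
#' @param d number of pools of the generating system.
#' @return list with `n_transitions` ((d+1) x d matrix of one-step
#'   transition counts, the final row counting the exit jump),
#'   `occupation` (total time per pool), `n_jumps` (including the exit) and
#'   `transit_time`.
#' @export
path_statistics <- function(path, d) {
  stopifnot(inherits(path, "particle_path"))
  n <- length(path$pools)
  trans <- matrix(0L, d + 1L, d)
  if (n > 1L) {
    for (k in seq_len(n - 1L)) {
      trans[path$pools[k + 1L], path$pools[k]] <-
        trans[path$pools[k + 1L], path$pools[k]] + 1L
    }
  }
  trans[d + 1L, path$pools[n]] <- trans[d + 1L, path$pools[n]] + 1L
  occ <- vapply(seq_len(d), function(j) sum(path$sojourns[path$pools == j]),
                numeric(1))
  list(n_transitions = trans, occupation = occ,
       n_jumps = n + 1L, transit_time = sum(path$sojourns))
}

#' Log-density of a particle path
#'
#' Evaluates the exact path density of the absorbing chain:
#' `log f(p) = log beta_{x1} + sum_k log(rate of jump k) - sum_k
#' lambda_{x_k} t_k`, where the rate of an internal jump from `j` to `i` is
#' `B[i, j]` and the rate of the final exit jump from `j` is `z[j]`.  The
#' average of `-path_log_density()` over sampled paths is a consistent
#' estimator of the path entropy.
#'
#' @param sys a [compartmental_system()].
#' @param path a [sample_path()] object.
#' @return log-density in nats; `-Inf` with a warning if the path contains
#'   a transition of rate zero under `sys`.
#' @examples
#' sys <- compartmental_system(1, matrix(-2, 1, 1))
#' p <- structure(list(pools = 1L, sojourns = 0.3, absorbed = TRUE),
#'                class = "particle_path")
#' path_log_density(sys, p)  # log(2) - 2 * 0.3
#' @export
path_log_density <- function(sys, path) {
  stopifnot(is.compartmental_system(sys), inherits(path, "particle_path"))
  lam <- total_rates(sys)
  z <- exit_rates(sys)
  beta <- entry_distribution(sys)
  pools <- path$pools
  n <- length(pools)

  rates <- numeric(n)
  if (n > 1L) {
    rates[seq_len(n - 1L)] <- sys$B[cbind(pools[-1L], pools[-n])]
  }
  rates[n] <- z[pools[n]]
  first <- beta[pools[1L]]
  if (first == 0 || any(rates == 0)) {
    warning("path contains a transition that has probability zero under this system")
    return(-Inf)
  }
  log(first) + sum(log(rates)) - sum(lam[pools] * path$sojourns)
}

#' Monte-Carlo estimates of path functionals
#'
#' Samples `n_paths` particle paths and returns sample means with standard
#' errors for the path entropy (mean of the negative path log-density), the
#' transit time, the jump count, and the per-pool occupation times and
#' visit counts.  Each estimate is directly comparable to its closed form
#' from [path_entropy()] and [system_diagnostics()].
#'
#' @param sys a [compartmental_system()].
#' @param n_paths number of paths (>= 2).
#' @param seed optional integer seed (see [simulate.compartmental_system()]).
#' @return An object of class `"mc_estimates"`: list of `(estimate, se)`
#'   pairs for `H_path`, `transit_time`, `n_jumps`, plus vectors
#'   `occupation` / `occupation_se` and `visits` / `visits_se`, and `n`.
#' @examples
#' sys <- compartmental_system(c(1, 0), rbind(c(-1, 0), c(1, -1)))
#' est <- mc_estimates(sys, n_paths = 2000, seed = 1)
#' est$H_path$estimate  # near 2
#' @export
mc_estimates <- function(sys, n_paths, seed = NULL) {
  stopifnot(is.compartmental_system(sys), n_paths >= 2)
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }

  # batch engine: all particles advance one sojourn per sweep, grouped by
  # current pool so draws vectorize; distributionally identical to
  # repeated sample_path() calls
  d <- sys$d
  lam <- total_rates(sys)
  z <- exit_rates(sys)
  beta <- entry_distribution(sys)
  jump <- rbind({
    P <- sweep(sys$B, 2L, lam, "/"); diag(P) <- 0; P
  }, z / lam)

  pos <- sample.int(d, n_paths, replace = TRUE, prob = beta)
  neg_ll <- -log(beta[pos])
  occ <- matrix(0, n_paths, d)
  vis <- matrix(0, n_paths, d)
  tt <- numeric(n_paths)
  nj <- numeric(n_paths)
  active <- seq_len(n_paths)
  sweeps <- 0L
  while (length(active)) {
    sweeps <- sweeps + 1L
    if (sweeps > 1e7) {
      stop("particles exceeded the jump safety cap; B may be nearly singular")
    }
    posa <- pos[active]
    for (j in unique(posa)) {
      idx <- active[posa == j]
      m <- length(idx)
      s <- stats::rexp(m, rate = lam[j])
      occ[cbind(idx, j)] <- occ[cbind(idx, j)] + s
      vis[cbind(idx, j)] <- vis[cbind(idx, j)] + 1
      tt[idx] <- tt[idx] + s
      nj[idx] <- nj[idx] + 1
      dest <- sample.int(d + 1L, m, replace = TRUE, prob = jump[, j])
      rate <- ifelse(dest <= d, sys$B[cbind(pmin(dest, d), j)], z[j])
      neg_ll[idx] <- neg_ll[idx] + lam[j] * s - log(rate)
      pos[idx] <- dest
    }
    active <- active[pos[active] != d + 1L]
  }
  nj <- nj + 1  # the final exit counts as a jump

  mse <- function(v) list(estimate = mean(v),
                          se = stats::sd(v) / sqrt(length(v)))
  structure(
    list(H_path = mse(neg_ll),
         transit_time = mse(tt),
         n_jumps = mse(nj),
         occupation = colMeans(occ),
         occupation_se = apply(occ, 2L, stats::sd) / sqrt(n_paths),
         visits = colMeans(vis),
         visits_se = apply(vis, 2L, stats::sd) / sqrt(n_paths),
         n = n_paths),
    class = "mc_estimates"
  )
}

#' @export
print.mc_estimates <- function(x, digits = 4L, ...) {
  cat(sprintf("Monte-Carlo estimates from %d particle paths\n", x$n))
  cat(sprintf("  H(path)      = %s (se %s)\n",
              format(signif(x$H_path$estimate, digits)),
              format(signif(x$H_path$se, 2))))
  cat(sprintf("  transit time = %s (se %s)\n",
              format(signif(x$transit_time$estimate, digits)),
              format(signif(x$transit_time$se, 2))))
  cat(sprintf("  jumps        = %s (se %s)\n",
              format(signif(x$n_jumps$estimate, digits)),
              format(signif(x$n_jumps$se, 2))))
  invisible(x)
}

#' Export paths as a tidy data frame
#'
#' @param paths list of [sample_path()] objects.
#' @return data frame with columns `path_id`, `step`, `pool`, `sojourn`.
#' @export
paths_to_data_frame <- function(paths) {
  if (inherits(paths, "particle_path")) paths <- list(paths)
  do.call(rbind, lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    data.frame(path_id = i, step = seq_along(p$pools),
               pool = p$pools, sojourn = p$sojourns)
  }))
}
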