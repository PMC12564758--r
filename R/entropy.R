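# Elementary entropies ------------------------------------------------------
#
# All entropies default to natural logarithms (nats); `base = 2` gives bits.
# Differential and discrete entropies rescale the same way: value in base b
# equals value in nats divided by log(b).

# x * log(x) with the measure-zero convention 0 * log 0 = 0
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

# Poisson entropy-rate kernel x * (1 - log x), with 0 * (1 - log 0) = 0
xlog1x <- function(x) ifelse(x > 0, x * (1 - log(x)), 0)

#' Entropy of a categorical distribution
#'
#' Shannon entropy `-sum(p * log(p))` with the convention `0 * log 0 = 0`.
#'
#' @param p probability vector (nonnegative, summing to one within `1e-9`).
#' @param base logarithm base; `exp(1)` for nats (default), `2` for bits.
#' @return entropy (scalar).
#' @examples
#' categorical_entropy(c(0.5, 0.5), base = 2)  # 1 bit
#' categorical_entropy(rep(1 / 3, 3))          # log(3) nats
#' @export
categorical_entropy <- function(p, base = exp(1)) {
  if (any(p < 0)) stop("'p' must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("'p' must sum to 1 (got %.12g)", sum(p)))
  }
  -sum(xlogx(p)) / log(base)
}

#' Differential entropy of an exponential distribution
#'
#' For a sojourn time with rate `lam`, the differential entropy is
#' `1 - log(lam)` nats.  It is negative for `lam > e`.
#'
#' @param lam positive rate parameter (1/time).
#' @inheritParams categorical_entropy
#' @return differential entropy (scalar).
#' @examples
#' exponential_entropy(1)  # 1
#' exponential_entropy(exp(1))  # 0
#' @export
exponential_entropy <- function(lam, base = exp(1)) {
  if (any(lam <= 0)) stop("'lam' must be positive")
  (1 - log(lam)) / log(base)
}

#' Entropy rate of a Poisson process
#'
#' `lam * (1 - log(lam))` nats per unit time, the instantaneous uncertainty
#' of a Poisson stream of events with intensity `lam`.  It is maximal (= 1)
#' at `lam = 1` and vanishes at `lam = 0` (limit convention) and `lam = e`.
#'
#' @param lam nonnegative intensity rate (1/time).
#' @inheritParams categorical_entropy
#' @return entropy rate (scalar).
#' @examples
#' poisson_entropy_rate(1)  # 1, the maximum
#' @export
poisson_entropy_rate <- function(lam, base = exp(1)) {
  if (any(lam < 0)) stop("'lam' must be nonnegative")
  xlog1x(lam) / log(base)
}

# Path entropy ---------------------------------------------------------------

#' Path entropy of a compartmental system
#'
#' The Shannon entropy of the full path of a single particle through the
#' system -- the sequence of visited pools together with the sojourn time in
#' each -- under the absorbing continuous-time Markov chain induced by
#' `(u, B)`.  In nats,
#' \deqn{H(P) = H(\beta) + \sum_j \frac{x^*_j}{\|u\|}
#'   \Big[\sum_{i \ne j} B_{ij}(1 - \log B_{ij}) + z_j(1 - \log z_j)\Big],}
#' where \eqn{H(\beta)} is the entropy of the entry distribution.  Terms
#' with zero rate contribute exactly zero.  Because sojourn times enter
#' through differential entropies, `H(P)` can be negative.
#'
#' The same number has two equivalent and interpretable decompositions,
#' both computed and cross-checked internally:
#' an occupation-time form (expected occupation times weighting Poisson
#' entropy rates of all outgoing jump streams) and a visit-count form
#' (expected visit counts weighting the exponential sojourn entropy plus the
#' jump-destination entropy of each pool).  The visit-count form splits the
#' path entropy into a discrete *jump part* (entry entropy plus
#' destination-choice entropies) and a continuous *sojourn part*
#' (sojourn-time entropies), returned as `H_jump_part` and `H_sojourn_part`.
#'
#' @param sys a [compartmental_system()].
#' @param base logarithm base; `exp(1)` for nats (default), `2` for bits.
#' @return An object of class `"entropy_report"`: a list with fields
#'   `H_path`, `H_beta`, `H_jump_part`, `H_sojourn_part`, `theta_time`
#'   (entropy rate per unit time, `H_path / ET`), `theta_jump` (entropy rate
#'   per jump, `H_path / EN`), `H_system` (macroscopic system entropy
#'   `||u|| * H_path`), `ET`, `EN`, and `log_base`.
#' @examples
#' serial <- compartmental_system(c(1, 0), rbind(c(-1, 0), c(1, -1)))
#' path_entropy(serial)$H_path  # 2 nats
#' @seealso [entropy_rates()], [system_entropy()], [mc_estimates()]
#' @export
path_entropy <- function(sys, base = exp(1)) {
  stopifnot(is.compartmental_system(sys))
  dg <- system_diagnostics(sys)
  d <- sys$d
  H_beta <- -sum(xlogx(dg$beta))

  # direct closed form: stocks weighting rate kernels
  xs <- solve(sys$B, -sys$u)
  normu <- sum(sys$u)
  per_pool_rates <- vapply(seq_len(d), function(j) {
    sum(xlog1x(sys$B[-j, j])) + xlog1x(dg$z[j])
  }, numeric(1))
  H_direct <- H_beta + sum(xs / normu * per_pool_rates)

  # occupation-time form: EO_j weighting Poisson entropy rates of every
  # outgoing jump stream (internal rates and the exit rate)
  H_occupation <- H_beta + sum(dg$EO * vapply(seq_len(d), function(j) {
    rates <- c(sys$B[-j, j], dg$z[j])
    sum(vapply(rates, poisson_entropy_rate, numeric(1)))
  }, numeric(1)))

  # visit-count form: EN_j weighting sojourn + jump-destination entropies
  jump_dest_H <- vapply(seq_len(d), function(j) {
    -sum(xlogx(dg$jump_matrix[-j, j]))
  }, numeric(1))
  H_jump_part <- H_beta + sum(dg$EN_per_pool * jump_dest_H)
  H_sojourn_part <- sum(dg$EN_per_pool * (1 - log(dg$lam)))
  H_visits <- H_jump_part + H_sojourn_part

  scale <- max(abs(H_direct), 1)
  if (abs(H_direct - H_visits) > 1e-8 * scale ||
      abs(H_direct - H_occupation) > 1e-8 * scale) {
    warning("internal representations of the path entropy disagree beyond tolerance")
  }

  lb <- log(base)
  structure(
    list(H_path = H_direct / lb,
         H_beta = H_beta / lb,
         H_jump_part = H_jump_part / lb,
         H_sojourn_part = H_sojourn_part / lb,
         theta_time = H_direct / dg$ET / lb,
         theta_jump = H_direct / dg$EN / lb,
         H_system = sum(sys$u) * H_direct / lb,
         ET = dg$ET, EN = dg$EN,
         log_base = base),
    class = "entropy_report"
  )
}

#' Entropy rates of a compartmental system
#'
#' The entropy rate per unit time `theta = H(P) / E[T]` (average
#' instantaneous uncertainty while the particle is in the system) and the
#' entropy rate per jump `theta_J = H(P) / E[N]` (average uncertainty per
#' transition, including the final exit).  The two are linked by
#' `theta = (E[N] / E[T]) * theta_J`.
#'
#' @inheritParams path_entropy
#' @return named numeric vector `c(theta_time, theta_jump)`.
#' @examples
#' entropy_rates(compartmental_system(c(1, 0), rbind(c(-1, 0), c(1, -1))))
#' @export
entropy_rates <- function(sys, base = exp(1)) {
  rep <- path_entropy(sys, base = base)
  c(theta_time = rep$theta_time, theta_jump = rep$theta_jump)
}

#' Macroscopic system entropy
#'
#' Upscales the single-particle path entropy to the whole system:
#' `H(M) = ||x*|| * theta = ||u|| * H(P)`.  It can be read as the cumulated
#' mean instantaneous uncertainty of all particles currently in the system,
#' or as the cumulated path uncertainty of all particles entering per unit
#' time.  Both routes are computed and must agree.
#'
#' @inheritParams path_entropy
#' @return system entropy (scalar, mass x entropy-rate scale).
#' @export
system_entropy <- function(sys, base = exp(1)) {
  rep <- path_entropy(sys, base = base)
  via_stocks <- sum(steady_state(sys)) * rep$theta_time
  via_input <- sum(sys$u) * rep$H_path
  if (abs(via_stocks - via_input) > 1e-8 * max(abs(via_input), 1)) {
    warning("system-entropy routes disagree beyond tolerance")
  }
  via_input
}

#' @export
print.entropy_report <- function(x, digits = 4L, ...) {
  unit <- if (abs(x$log_base - 2) < 1e-12) "bits"
          else if (abs(x$log_base - exp(1)) < 1e-12) "nats"
          else sprintf("log-base-%g units", x$log_base)
  cat(sprintf("Path entropy report (%s)\n", unit))
  cat(sprintf("  H(path)        = %s  (jump part %s + sojourn part %s)\n",
              format(signif(x$H_path, digits)),
              format(signif(x$H_jump_part, digits)),
              format(signif(x$H_sojourn_part, digits))))
  cat(sprintf("  H(entry)       = %s\n", format(signif(x$H_beta, digits))))
  cat(sprintf("  theta per time = %s   theta per jump = %s\n",
              format(signif(x$theta_time, digits)),
              format(signif(x$theta_jump, digits))))
  cat(sprintf("  system entropy = %s\n", format(signif(x$H_system, digits))))
  cat(sprintf("  E[T] = %s   E[N] = %s\n",
              format(signif(x$ET, digits)), format(signif(x$EN, digits))))
  invisible(x)
}

#' @export
as.data.frame.entropy_report <- function(x, ...) {
  data.frame(H_path = x$H_path, H_beta = x$H_beta,
             H_jump_part = x$H_jump_part, H_sojourn_part = x$H_sojourn_part,
             theta_time = x$theta_time, theta_jump = x$theta_jump,
             H_system = x$H_system, ET = x$ET, EN = x$EN,
             log_base = x$log_base)
}
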