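#' Bundle one strain's fluctuation assay
#'
#' A fluctuation experiment is a set of replica cultures grown from small
#' inocula, each plated on selective medium; the per-culture mutant colony
#' counts, the plating efficiency and the mean number of colony-forming
#' units (CFU) per culture together determine the per-division mutation
#' rate.
#'
#' @param strain Strain label (character scalar).
#' @param counts Non-negative integer vector of mutant colonies per replica
#'   culture (at least 2 cultures).
#' @param epsilon Plating efficiency in (0, 1].
#' @param n_t Mean colony-forming units per culture (> 0); used as the
#'   number of cell divisions when converting m to a per-division rate.
#' @return An object of class `fluctuation_experiment`.
#' @export
fluctuation_experiment <- function(strain, counts, epsilon = 1, n_t) {
  check_counts(counts)
  if (length(counts) < 2L) {
    stop("a fluctuation experiment needs at least 2 cultures", call. = FALSE)
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0 ||
      epsilon > 1) {
    stop("'epsilon' must be a single value in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(n_t) || length(n_t) != 1L || is.na(n_t) || n_t <= 0) {
    stop("'n_t' must be a single value > 0", call. = FALSE)
  }
  if (n_t <= max(counts) / epsilon) {
    warning("mean CFU n_t is not larger than max(counts)/epsilon; ",
            "check the culture size", call. = FALSE)
  }
  structure(list(strain = as.character(strain)[1],
                 counts = as.integer(counts),
                 epsilon = epsilon, n_t = n_t),
            class = "fluctuation_experiment")
}

#' @export
print.fluctuation_experiment <- function(x, ...) {
  cat("Fluctuation experiment: ", x$strain, "\n", sep = "")
  cat("  ", length(x$counts), " cultures, epsilon = ", x$epsilon,
      ", mean CFU = ", format(x$n_t, digits = 4), "\n", sep = "")
  cat("  counts:", paste(x$counts, collapse = " "), "\n")
  invisible(x)
}

# Evaluate loglik and derivatives at m for fixed counts / clone dist.
loglik_profile_fns <- function(counts, clone) {
  n_max <- max(counts)
  idx <- counts + 1L
  list(
    ll = function(m) {
      if (m == 0) return(if (all(counts == 0)) 0 else -Inf)
      tab <- ld_pmf_derivs(m, clone, n_max, 0L)
      sum(log(tab[idx, 1]))
    },
    score = function(m) {
      tab <- ld_pmf_derivs(m, clone, n_max, 1L)
      p <- tab[idx, 1]; d <- tab[idx, 2]
      list(ll = sum(log(p)), score = sum(d / p))
    },
    full = function(m) {
      tab <- ld_pmf_derivs(m, clone, n_max, 2L)
      p <- tab[idx, 1]; d <- tab[idx, 2]; h <- tab[idx, 3]
      list(ll = sum(log(p)), score = sum(d / p),
           hess = sum((h * p - d * d) / (p * p)))
    }
  )
}

#' Maximum-likelihood estimate of mutational events per culture
#'
#' Maximizes the Lea-Coulson log-likelihood over m >= 0 by safeguarded
#' Newton iteration on the score function, with a bisection fallback inside
#' a bracket on which the score changes sign. Convergence is declared when
#' the relative step |dm| / max(m, 1) falls below `tol`. If every count is
#' zero the MLE is the boundary value m = 0.
#'
#' @param experiment A [fluctuation_experiment()].
#' @param tol Relative convergence tolerance on m.
#' @param max_iter Iteration cap; exceeding it is an error with a trace.
#' @return List with elements `m_hat`, `loglik`, `iterations`, `clone`
#'   (the clone-size distribution reused by downstream steps).
#' @examples
#' e <- fluctuation_experiment("wt", c(0, 1, 0, 2, 0, 0), 1, 1e7)
#' estimate_m(e)$m_hat
#' @export
estimate_m <- function(experiment, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(experiment, "fluctuation_experiment"))
  counts <- experiment$counts
  eps <- experiment$epsilon
  clone <- clone_size_pmf(eps, max(max(counts), 1L))

  if (all(counts == 0)) {
    return(list(m_hat = 0, loglik = 0, iterations = 0L, clone = clone))
  }

  fns <- loglik_profile_fns(counts, clone)
  q0 <- clone$q[1]

  # Initial guess from the fraction of zero-count cultures where available:
  # P(count = 0) = exp(-m (1 - q0)).
  z <- mean(counts == 0)
  m0 <- if (z > 0) -log(z) / (1 - q0) else max(1, mean(counts) / 4)

  # Bracket the score's sign change: score > 0 at lo, < 0 at hi. A
  # non-finite score (pmf underflow far from the optimum) is treated as
  # negative so the bracket contracts back toward representable m.
  score_at <- function(m) {
    s <- fns$score(m)$score
    if (is.finite(s)) s else -1
  }
  lo <- 1e-10
  hi <- max(m0, 1e-6)
  it <- 0L
  while (score_at(hi) > 0) {
    hi <- hi * 4
    it <- it + 1L
    if (it > 60L) stop("failed to bracket the MLE of m (hi = ", hi, ")",
                       call. = FALSE)
  }

  m <- min(max(m0, lo * 2), hi)
  trace <- numeric(0)
  for (i in seq_len(max_iter)) {
    ev <- fns$full(m)
    if (!is.finite(ev$score)) ev$score <- -1  # underflow: contract downward
    if (ev$score > 0) lo <- m else hi <- m
    step_ok <- is.finite(ev$hess) && ev$hess < 0
    m_new <- if (step_ok) m - ev$score / ev$hess else (lo + hi) / 2
    if (!is.finite(m_new) || m_new <= lo || m_new >= hi) {
      m_new <- (lo + hi) / 2
    }
    trace <- c(trace, m_new)
    if (abs(m_new - m) / max(m, 1) < tol) {
      m <- m_new
      return(list(m_hat = m, loglik = fns$ll(m), iterations = i,
                  clone = clone))
    }
    m <- m_new
  }
  stop("Newton iteration for m did not converge after ", max_iter,
       " iterations; trace tail: ",
       paste(format(utils::tail(trace, 5), digits = 8), collapse = ", "),
       call. = FALSE)
}

#' Profile-likelihood confidence interval for m
#'
#' Endpoints are the two solutions of
#' \eqn{2[\ell(\hat m) - \ell(m)] = \chi^2_{1,level}} (3.841 at the default
#' 0.95 level), located by bisection (via [stats::uniroot()]) to a relative
#' tolerance of about 1e-6. When every count is zero the interval is
#' one-sided: the lower endpoint is clamped to 0 and the upper endpoint
#' solves \eqn{2 n_{cultures} m (1-q_0) = \chi^2_{1,level}}.
#'
#' @param experiment A [fluctuation_experiment()].
#' @param level Confidence level in (0, 1).
#' @param fit Optional result of [estimate_m()] for this experiment.
#' @return Numeric vector `c(ci_low, ci_high)` on the m scale.
#' @export
profile_ci <- function(experiment, level = 0.95, fit = NULL) {
  stopifnot(inherits(experiment, "fluctuation_experiment"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("'level' must be in (0, 1)", call. = FALSE)
  }
  if (is.null(fit)) fit <- estimate_m(experiment)
  counts <- experiment$counts
  clone <- fit$clone
  thr <- qchisq(level, df = 1)

  if (fit$m_hat == 0) {
    # all-zero counts: loglik(m) = -n m (1 - q0), deviance = 2 n m (1 - q0)
    upper <- thr / (2 * length(counts) * (1 - clone$q[1]))
    return(c(0, upper))
  }

  fns <- loglik_profile_fns(counts, clone)
  dev <- function(m) 2 * (fit$loglik - fns$ll(m)) - thr

  # upper endpoint
  hi <- fit$m_hat * 2 + 1e-8
  while (dev(hi) < 0) hi <- hi * 2
  up <- uniroot(dev, c(fit$m_hat, hi),
                tol = 1e-8 + 1e-6 * fit$m_hat)$root

  # lower endpoint: deviance -> +Inf as m -> 0 when any count is positive
  lo <- fit$m_hat / 2
  while (dev(lo) < 0 && lo > 1e-14) lo <- lo / 4
  low <- if (dev(lo) < 0) 0 else {
    uniroot(dev, c(lo, fit$m_hat), tol = 1e-10 + 1e-6 * fit$m_hat)$root
  }
  c(low, up)
}

#' Convert m and its confidence interval to a per-division mutation rate
#'
#' The number of cell divisions in a culture grown from a small inoculum is
#' approximately its final number of colony-forming units, so the
#' per-division rate is `m_hat / n_t`; confidence-interval endpoints are
#' divided identically.
#'
#' @param m_hat MLE of mutational events per culture.
#' @param ci Numeric vector `c(ci_low, ci_high)` on the m scale.
#' @param n_t Mean colony-forming units per culture (> 0).
#' @param level Confidence level attached to `ci`.
#' @param loglik Optional log-likelihood at the MLE.
#' @return Object of class `rate_estimate` with fields `m_hat`, `rate`,
#'   `ci_low`, `ci_high`, `level`, `loglik_at_mle`.
#' @examples
#' to_rate(4.4, c(2.6, 6.8), n_t = 2e7)$rate  # 2.2e-7
#' @export
to_rate <- function(m_hat, ci, n_t, level = 0.95, loglik = NA_real_) {
  if (!is.numeric(n_t) || length(n_t) != 1L || is.na(n_t) || n_t <= 0) {
    stop("'n_t' must be > 0", call. = FALSE)
  }
  stopifnot(length(ci) == 2L, m_hat >= 0)
  structure(list(m_hat = m_hat, rate = m_hat / n_t,
                 ci_low = ci[1] / n_t, ci_high = ci[2] / n_t,
                 level = level, loglik_at_mle = loglik),
            class = "rate_estimate")
}

#' Estimate a per-division mutation rate from a fluctuation experiment
#'
#' Convenience pipeline: [estimate_m()], then [profile_ci()], then
#' [to_rate()].
#'
#' @inheritParams profile_ci
#' @return A `rate_estimate` object (see [to_rate()]).
#' @export
estimate_rate <- function(experiment, level = 0.95) {
  fit <- estimate_m(experiment)
  ci <- profile_ci(experiment, level = level, fit = fit)
  out <- to_rate(fit$m_hat, ci, experiment$n_t, level = level,
                 loglik = fit$loglik)
  out$strain <- experiment$strain
  out$n_cultures <- length(experiment$counts)
  out
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("Per-division mutation rate",
      if (!is.null(x$strain)) paste0(" (", x$strain, ")"), ":\n", sep = "")
  cat("  rate = ", format(x$rate, digits = 3), "  ",
      100 * x$level, "% CI [", format(x$ci_low, digits = 3), ", ",
      format(x$ci_high, digits = 3), "]\n", sep = "")
  cat("  m_hat = ", format(x$m_hat, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio comparison of two fluctuation experiments
#'
#' Tests whether two strains share a per-division mutation rate. Under the
#' null a single rate mu generates both experiments with
#' \eqn{m_a = \mu N_{t,a}}, \eqn{m_b = \mu N_{t,b}} (one free parameter,
#' maximized numerically); under the alternative each experiment has its own
#' m. The statistic \eqn{2(\ell_{alt} - \ell_{null})} is referred to the
#' upper tail of \eqn{\chi^2_1}.
#'
#' @param exp_a Test-strain [fluctuation_experiment()].
#' @param exp_b Control-strain [fluctuation_experiment()].
#' @return Object of class `rate_comparison`: `lrt_stat`, `df`, `p_raw`,
#'   `fold` (per-division rate ratio test/control), plus the two fitted
#'   rates. `p_adj` is filled in by [bonferroni()] at the family level.
#' @export
lrt_compare <- function(exp_a, exp_b) {
  stopifnot(inherits(exp_a, "fluctuation_experiment"),
            inherits(exp_b, "fluctuation_experiment"))
  fit_a <- estimate_m(exp_a)
  fit_b <- estimate_m(exp_b)
  ll_alt <- fit_a$loglik + fit_b$loglik
  rate_a <- fit_a$m_hat / exp_a$n_t
  rate_b <- fit_b$m_hat / exp_b$n_t

  degenerate <- fit_a$m_hat == 0 && fit_b$m_hat == 0
  if (degenerate) {
    out <- list(lrt_stat = 0, df = 1L, p_raw = 1, p_adj = NA_real_,
                fold = NA_real_, rate_a = 0, rate_b = 0,
                strain_a = exp_a$strain, strain_b = exp_b$strain)
    class(out) <- "rate_comparison"
    return(out)
  }

  fns_a <- loglik_profile_fns(exp_a$counts, fit_a$clone)
  fns_b <- loglik_profile_fns(exp_b$counts, fit_b$clone)
  g <- function(mu) fns_a$ll(mu * exp_a$n_t) + fns_b$ll(mu * exp_b$n_t)
  gprime <- function(mu) {
    exp_a$n_t * fns_a$score(mu * exp_a$n_t)$score +
      exp_b$n_t * fns_b$score(mu * exp_b$n_t)$score
  }

  # The null optimum lies between the two per-experiment rate MLEs (the
  # combined score is positive below both and negative above both).
  lo <- min(rate_a, rate_b)
  hi <- max(rate_a, rate_b)
  cand <- c(rate_a, rate_b)
  cand <- cand[cand > 0]
  if (lo < hi) {
    if (lo == 0) {
      lo <- hi * 1e-9
      while (gprime(lo) < 0 && lo > hi * 1e-15) lo <- lo / 10
    }
    if (gprime(lo) > 0 && gprime(hi) < 0) {
      root <- uniroot(gprime, c(lo, hi), tol = hi * 1e-9)$root
      cand <- c(cand, root)
    }
  }
  ll_null <- max(vapply(cand, g, numeric(1)))
  stat <- max(0, 2 * (ll_alt - ll_null))

  out <- list(lrt_stat = stat, df = 1L,
              p_raw = pchisq(stat, df = 1, lower.tail = FALSE),
              p_adj = NA_real_,
              fold = if (rate_b > 0) rate_a / rate_b else Inf,
              rate_a = rate_a, rate_b = rate_b,
              strain_a = exp_a$strain, strain_b = exp_b$strain)
  class(out) <- "rate_comparison"
  out
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat("Rate comparison: ", x$strain_a, " vs ", x$strain_b, "\n", sep = "")
  cat("  LRT stat = ", format(x$lrt_stat, digits = 4),
      " (df = 1), p = ", format(x$p_raw, digits = 3), "\n", sep = "")
  cat("  fold (test/control) = ", format(x$fold, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Bonferroni correction for a family of p-values
#'
#' Multiplies each p-value by the family size and caps at 1, via
#' [stats::p.adjust()]. The family is exactly the set of p-values passed in
#' one call.
#'
#' @param p_values Numeric vector of p-values between 0 and 1.
#' @return Adjusted p-values in the input order.
#' @examples
#' bonferroni(c(0.01, 0.02, 0.4))  # 0.03 0.06 1.00
#' @export
bonferroni <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "bonferroni")
}

#' Antimutator (eex) fold effect
#'
#' The fold effect of an antimutator allele is the ratio of the mutation
#' rate of the eex-carrying strain to that of its control background. A
#' value below 1 means the allele lowers the mutation rate.
#'
#' @param rate_eex Per-division mutation rate of the eex strain.
#' @param rate_control Per-division mutation rate of the control (> 0).
#' @return List with `fold` (full precision) and `rounded` (2 decimals, the
#'   display convention for effects below 1).
#' @examples
#' eex_effect(6.8, 180)$rounded  # 0.04
#' @export
eex_effect <- function(rate_eex, rate_control) {
  if (!is.numeric(rate_control) || length(rate_control) != 1L ||
      is.na(rate_control) || rate_control <= 0) {
    stop("'rate_control' must be > 0", call. = FALSE)
  }
  if (!is.numeric(rate_eex) || length(rate_eex) != 1L || is.na(rate_eex) ||
      rate_eex < 0) {
    stop("'rate_eex' must be >= 0", call. = FALSE)
  }
  fold <- rate_eex / rate_control
  list(fold = fold, rounded = round(fold, 2))
}
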