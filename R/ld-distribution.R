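#' Clone-size distribution of a single mutational event under partial plating
#'
#' In the Lea-Coulson model a mutation arising during exponential growth
#' founds a clone whose final size follows the law \eqn{P(S = s) = 1/(s(s+1))}
#' for \eqn{s \ge 1}. When only a fraction \eqn{\epsilon} of the culture is
#' plated (or survives selection plating), each clone is thinned binomially,
#' so the number of mutant colonies contributed by one mutational event is
#' \deqn{q_j = \sum_{s \ge \max(j,1)} \frac{1}{s(s+1)}
#'       \binom{s}{j} \epsilon^j (1-\epsilon)^{s-j}.}
#' At \eqn{\epsilon = 1} this reduces to \eqn{q_0 = 0},
#' \eqn{q_j = 1/(j(j+1))}.
#'
#' The infinite sum over clone sizes is truncated adaptively so that the
#' neglected tail of every coefficient is below `tail_tol`; `q_0` is also
#' cross-checked against its closed form
#' \eqn{q_0 = 1 + \epsilon \log(\epsilon) / (1-\epsilon)}.
#'
#' The distribution is truncated at `j_max` colonies. The probability mass
#' beyond `j_max` is recorded as `mass_deficit`; it is bounded by
#' \eqn{1/(j_{max}+1)} (the clone-size tail) plus the numerical truncation
#' error, because the plated count never exceeds the clone size. Truncation
#' at `j_max` does not bias the mutant-count pmf up to `j_max`: the
#' compound-Poisson recursion for \eqn{p_n} only consumes \eqn{q_0 \dots q_n}.
#'
#' @param epsilon Plating efficiency, the fraction of the culture assayed on
#'   the selective plate (0 < epsilon <= 1).
#' @param j_max Largest number of plated colonies tabulated (integer >= 0).
#' @param tail_tol Numerical tolerance for the truncated clone-size sum
#'   (> 0); each returned coefficient is accurate to about this value.
#' @return An object of class `clone_size_dist`: a list with elements `q`
#'   (numeric vector of q_0..q_J), `J`, `mass_deficit`, `epsilon`,
#'   `tail_tol`.
#' @examples
#' cs <- clone_size_pmf(1, 5)
#' cs$q[2]  # q_1 = 1/2
#' @export
clone_size_pmf <- function(epsilon, j_max, tail_tol = 1e-9) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon <= 0 || epsilon > 1) {
    stop("'epsilon' must be a single value in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(j_max) || length(j_max) != 1L || is.na(j_max) ||
      j_max < 0 || j_max != floor(j_max)) {
    stop("'j_max' must be a single integer >= 0", call. = FALSE)
  }
  if (!is.numeric(tail_tol) || length(tail_tol) != 1L || tail_tol <= 0) {
    stop("'tail_tol' must be a single value > 0", call. = FALSE)
  }

  j <- 0:j_max
  if (epsilon == 1) {
    jj <- as.numeric(seq_len(j_max))
    q <- c(0, 1 / (jj * (jj + 1)))
    deficit <- if (j_max >= 1) 1 / (j_max + 1) else 1
  } else {
    q <- numeric(j_max + 1)
    omx <- 1 - epsilon
    # Sum clone sizes s in chunks; stop once a geometric tail bound on every
    # coefficient drops below tail_tol. For s > j_max the term ratio
    # t_{s+1}/t_s is at most (1-eps)*(s+1)/(s+1-j_max) < 1 eventually.
    s_hi <- 0L
    chunk <- 2048L
    s_cap <- 5e7
    repeat {
      s_lo <- s_hi + 1L
      s_hi <- s_hi + chunk
      for (s in s_lo:s_hi) {
        q <- q + dbinom(j, s, epsilon) / (s * (s + 1))
      }
      r <- omx * (s_hi + 1) / (s_hi + 1 - j_max)
      if (s_hi > 2 * j_max && r < 1) {
        t_next <- dbinom(j, s_hi + 1L, epsilon) / ((s_hi + 1) * (s_hi + 2))
        if (max(t_next) / (1 - r) < tail_tol) break
      }
      if (s_hi >= s_cap) {
        stop("clone-size sum did not converge within the iteration cap (",
             "epsilon = ", epsilon, ", j_max = ", j_max, ")", call. = FALSE)
      }
    }
    q0_closed <- 1 + epsilon * log(epsilon) / (1 - epsilon)
    if (abs(q[1] - q0_closed) > 1e-6) {
      stop("clone-size q_0 disagrees with its closed form; ",
           "numerical failure at epsilon = ", epsilon, call. = FALSE)
    }
    q[1] <- q0_closed
    deficit <- max(0, 1 - sum(q))
  }

  structure(
    list(q = q, J = j_max, mass_deficit = deficit,
         epsilon = epsilon, tail_tol = tail_tol),
    class = "clone_size_dist"
  )
}

#' Parameter bundle for the mutant-count distribution
#'
#' Validates the parameters of the Lea-Coulson mutant-count distribution
#' with partial plating.
#'
#' @param m Expected number of mutational events per culture (>= 0).
#' @param epsilon Plating efficiency in (0, 1].
#' @param n_max Largest mutant count tabulated (integer >= 0).
#' @param tail_tol Truncation tolerance for infinite sums (> 0).
#' @return An object of class `ld_params`.
#' @export
ld_params <- function(m, epsilon = 1, n_max = 100L, tail_tol = 1e-9) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0) {
    stop("'m' must be a single value >= 0", call. = FALSE)
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon <= 0 || epsilon > 1) {
    stop("'epsilon' must be a single value in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(n_max) || length(n_max) != 1L || is.na(n_max) ||
      n_max < 0 || n_max != floor(n_max)) {
    stop("'n_max' must be a single integer >= 0", call. = FALSE)
  }
  if (!is.numeric(tail_tol) || length(tail_tol) != 1L || tail_tol <= 0) {
    stop("'tail_tol' must be a single value > 0", call. = FALSE)
  }
  structure(list(m = m, epsilon = epsilon, n_max = as.integer(n_max),
                 tail_tol = tail_tol),
            class = "ld_params")
}

#' Mutant-count probability mass function (Lea-Coulson with plating)
#'
#' Computes \eqn{p_0 \dots p_{n_{max}}}, the probability of observing n
#' mutant colonies in one culture, as the compound-Poisson composition of the
#' clone-size law: the number of mutational events is Poisson(m) and each
#' event contributes colonies according to [clone_size_pmf()]. The
#' probabilities satisfy the Panjer-type recursion
#' \deqn{p_0 = e^{-m(1-q_0)}, \qquad
#'       p_n = \frac{m}{n} \sum_{j=1}^{n} j\, q_j\, p_{n-j}.}
#' At \eqn{\epsilon = 1} this is exactly the Ma-Sandri-Sarkar recursion.
#'
#' @param params An [ld_params()] object, or a numeric `m` (with `epsilon`,
#'   `n_max`, `tail_tol` supplied as additional arguments).
#' @param epsilon,n_max,tail_tol Used only when `params` is a bare number.
#' @param clone Optional pre-computed [clone_size_pmf()] object (must match
#'   `epsilon` and extend to at least `n_max`); avoids recomputation when
#'   evaluating many values of m.
#' @return Numeric vector `p[1..n_max+1]` with `p[n+1]` = P(count = n).
#' @examples
#' p <- ld_pmf(ld_params(m = 1, epsilon = 1, n_max = 5))
#' p[1]  # exp(-1)
#' @export
ld_pmf <- function(params, epsilon = 1, n_max = 100L, tail_tol = 1e-9,
                   clone = NULL) {
  if (!inherits(params, "ld_params")) {
    params <- ld_params(params, epsilon, n_max, tail_tol)
  }
  if (is.null(clone)) {
    clone <- clone_size_pmf(params$epsilon, max(params$n_max, 1L),
                            params$tail_tol)
  } else {
    stopifnot(inherits(clone, "clone_size_dist"))
    if (clone$epsilon != params$epsilon || clone$J < params$n_max) {
      stop("'clone' does not match epsilon or does not extend to n_max",
           call. = FALSE)
    }
  }
  drop(ld_panjer_cpp(params$m, clone$q, params$n_max, 0L)[, 1])
}

# pmf plus derivatives in m; internal workhorse for Newton iterations.
ld_pmf_derivs <- function(m, clone, n_max, order = 2L) {
  ld_panjer_cpp(m, clone$q, n_max, order)
}

#' Log-likelihood of replica-culture mutant counts
#'
#' Sum of log Lea-Coulson probabilities over the observed mutant colony
#' counts. For `m = 0` the log-likelihood is 0 when every count is zero and
#' `-Inf` otherwise.
#'
#' @param counts Non-negative integer vector of mutant colonies per culture.
#' @param m Expected mutational events per culture (>= 0).
#' @param epsilon Plating efficiency in (0, 1].
#' @param tail_tol Truncation tolerance passed to [clone_size_pmf()].
#' @param clone Optional pre-computed [clone_size_pmf()] object.
#' @return Scalar log-likelihood.
#' @examples
#' ld_loglik(c(0, 0), m = 1, epsilon = 1)  # -2
#' @export
ld_loglik <- function(counts, m, epsilon = 1, tail_tol = 1e-9, clone = NULL) {
  check_counts(counts)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0) {
    stop("'m' must be a single value >= 0", call. = FALSE)
  }
  if (m == 0) {
    return(if (all(counts == 0)) 0 else -Inf)
  }
  n_max <- max(counts)
  p <- ld_pmf(ld_params(m, epsilon, n_max, tail_tol), clone = clone)
  sum(log(p[counts + 1L]))
}

check_counts <- function(counts) {
  if (length(counts) == 0) stop("'counts' must be non-empty", call. = FALSE)
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop("'counts' must be non-negative integers", call. = FALSE)
  }
  invisible(counts)
}

#' @export
print.clone_size_dist <- function(x, ...) {
  cat("Clone-size distribution (Lea-Coulson, plating efficiency ",
      x$epsilon, ")\n", sep = "")
  cat("  tabulated to J =", x$J, "; mass deficit",
      format(x$mass_deficit, digits = 4), "\n")
  invisible(x)
}
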