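# Try-until-success expected cost and Amdahl accounting.
#
# Running an optimizer repeatedly until one run succeeds has expected cost
# x = C/P when each independent run costs C and succeeds with probability P.
# With M observed successes and N failures, P carries a Beta(M+1, N+1)
# posterior, and integrating C/P over it gives the closed form
# E[x] = C (M + N + 2) / (M + 1).

#' Expected cost of running until the first success
#'
#' Closed-form Beta-posterior expectation `C (M + N + 2) / (M + 1)` of the
#' try-until-success cost, given `successes` successful and `failures` failed
#' independent runs of unit cost `cost`.
#'
#' @param successes Number of successful runs `M >= 1`.
#' @param failures Number of failed runs `N >= 0`.
#' @param cost Cost `C` of one run (default 1).
#' @return Scalar expected cost (same units as `cost`).
#' @export
#' @examples
#' expected_cost(12, 8) # 22/13, about 1.69
expected_cost <- function(successes, failures, cost = 1) {
  check_counts(successes, failures, cost)
  cost * (successes + failures + 2) / (successes + 1)
}

check_counts <- function(successes, failures, cost) {
  if (failures < 0 || cost <= 0 ||
      successes != round(successes) || failures != round(failures)) {
    abort("need integer counts with failures >= 0 and cost > 0",
          class = "igapso_argument_error")
  }
  if (successes < 1) {
    abort("the estimator is undefined without at least one success",
          class = "igapso_undefined_estimate")
  }
}

#' Posterior density of the per-run success probability
#'
#' `f(P) = P^M (1-P)^N / B(M+1, N+1)` -- the Beta(M+1, N+1) density arising
#' from a uniform prior and M successes / N failures.
#'
#' @param p Success probability in `[0, 1]` (vectorized).
#' @param successes,failures Observed counts `M`, `N`.
#' @return Density values.
#' @export
success_posterior_density <- function(p, successes, failures) {
  if (any(p < 0 | p > 1)) {
    abort("p must lie in [0, 1]", class = "igapso_argument_error")
  }
  p^successes * (1 - p)^failures / exp(lbeta(successes + 1, failures + 1))
}

#' Expected cost by integrating the posterior directly
#'
#' Evaluates `E[C/P]` by adaptive quadrature (default) or Monte-Carlo
#' sampling -- a brute-force check of the closed form in [expected_cost()].
#'
#' The integration is against the `Beta(M+2, N+1)` density: a
#' try-until-success sequence terminates with one further successful run, so
#' the evidence entering the expectation is `M+1` successes and `N` failures.
#' This is the posterior under which the closed form
#' `C (M + N + 2) / (M + 1)` is exact. (Under the `Beta(M+1, N+1)` posterior
#' of [success_posterior_density()] alone, `E[C/P]` would instead be
#' `C (M + N + 1) / M`.)
#'
#' @inheritParams expected_cost
#' @param method `"quadrature"` (default) or `"mc"`.
#' @param n_samples Monte-Carlo sample count.
#' @param seed Optional seed for the Monte-Carlo draw.
#' @return Scalar estimate of the expected cost.
#' @export
expected_cost_mc <- function(successes, failures, cost = 1,
                             method = c("quadrature", "mc"),
                             n_samples = 10000, seed = NULL) {
  check_counts(successes, failures, cost)
  method <- match.arg(method)
  if (method == "quadrature") {
    val <- integrate(function(p) {
      (cost / p) * stats::dbeta(p, successes + 2, failures + 1)
    }, 0, 1, rel.tol = 1e-10)$value
    return(val)
  }
  draw <- function() mean(cost / rbeta(n_samples, successes + 2, failures + 1))
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Summarize try-until-success runs from a result table
#'
#' Counts successes (final fitness strictly below `threshold`) in a table of
#' run results and applies [expected_cost()].
#'
#' @param runs Data frame with a `final_fitness` column (one row per
#'   independent run).
#' @param threshold Fitness below which a run counts as successful.
#' @param cost Cost of one run.
#' @return One-row tibble with `successes`, `failures`, `threshold`, and
#'   `expected_cost` (`NA` with a warning if no run succeeded).
#' @export
cost_analysis <- function(runs, threshold, cost = 1) {
  if (!is.data.frame(runs) || !"final_fitness" %in% names(runs)) {
    abort("runs must be a data frame with a final_fitness column",
          class = "igapso_argument_error")
  }
  m <- sum(runs$final_fitness < threshold)
  n <- nrow(runs) - m
  ec <- if (m >= 1) expected_cost(m, n, cost) else {
    warn("no successful run; expected cost is undefined")
    NA_real_
  }
  tibble::tibble(successes = m, failures = n, threshold = threshold,
                 cost = cost, expected_cost = ec)
}

#' Amdahl speed-up bound
#'
#' `1 / ((1 - f) + f / S)` for parallel fraction `f` on `S` processors;
#' `S = Inf` gives the limiting bound `1 / (1 - f)`.
#'
#' @param f Parallelizable fraction of the task in `[0, 1]` (vectorized).
#' @param s Processor count `>= 1`; may be `Inf`.
#' @return Speed-up factor(s); `Inf` when `f = 1` and `s = Inf`.
#' @export
#' @examples
#' amdahl_speedup(0.95, Inf) # 20
amdahl_speedup <- function(f, s = Inf) {
  if (any(f < 0 | f > 1)) abort("f must lie in [0, 1]", class = "igapso_argument_error")
  if (any(s < 1)) abort("s must be >= 1", class = "igapso_argument_error")
  serial <- 1 - f
  par <- ifelse(is.infinite(s), 0, f / s)
  ifelse(serial + par == 0, Inf, 1 / (serial + par))
}

#' Parallelized fraction from wall-clock times
#'
#' `1 - parallel_time / sequential_time`: the share of a task eliminated by
#' parallel execution.
#'
#' @param sequential_time,parallel_time Positive wall-clock times in the same
#'   unit.
#' @return Fraction in `[0, 1]`; 0 with a warning when the parallel run was
#'   slower.
#' @export
#' @examples
#' parallel_fraction(16323, 1792) # about 0.89
parallel_fraction <- function(sequential_time, parallel_time) {
  if (sequential_time <= 0 || parallel_time <= 0) {
    abort("times must be positive", class = "igapso_argument_error")
  }
  if (parallel_time > sequential_time) {
    warn("parallel run slower than sequential; no speed-up")
    return(0)
  }
  1 - parallel_time / sequential_time
}
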