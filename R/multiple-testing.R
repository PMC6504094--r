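#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: sort p ascending, take `p_(i) * m / i`, enforce
#' monotonicity from the largest down, cap at 1, return in input order.
#' Thin validated wrapper around [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  .check_p(p)
  stats::p.adjust(p, method = "BH")
}

.check_p <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1] with no missing values")
  invisible(p)
}

#' Estimate the true-null proportion pi0 (Storey)
#'
#' `pi0_hat(lambda) = #\{p > lambda\} / (m * (1 - lambda))` is evaluated on
#' a lambda grid and smoothed with a cubic smoothing spline (df = 3); the
#' estimate is the smoothed value at the largest lambda, clamped to
#' `(0, 1]`. With fewer than 20 p-values the spline is unstable, so the
#' estimator conservatively falls back to `pi0 = 1` with a warning.
#'
#' @param p numeric vector of p-values.
#' @param lambda grid in (0, 1); default `seq(0.05, 0.95, by = 0.05)`.
#' @return `pi0` estimate in `(0, 1]`, with the grid and raw
#'   `pi0_hat(lambda)` attached as attributes.
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  .check_p(p)
  stopifnot(all(lambda > 0 & lambda < 1), length(lambda) >= 4L)
  lambda <- sort(lambda)
  m <- length(p)
  if (m < 20L) {
    warning("fewer than 20 p-values; falling back to pi0 = 1")
    return(structure(1, lambda = lambda, pi0_lambda = rep(NA_real_, length(lambda))))
  }
  pi0_lambda <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), 0)
  fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  pi0 <- min(max(pi0, 1e-8), 1)
  structure(pi0, lambda = lambda, pi0_lambda = pi0_lambda)
}

#' Storey q-values
#'
#' `q_i = min_{t >= p_i} pi0 * m * t / #\{p <= t\}`, minimized over the
#' observed p-values by the standard sorted sweep. With `pi0 = 1` this is
#' exactly the Benjamini-Hochberg adjustment. The q-value of a test is the
#' smallest estimated FDR at which it would be called significant.
#'
#' @param p numeric vector of p-values.
#' @param pi0 true-null proportion in `(0, 1]`; default estimates it with
#'   [estimate_pi0()].
#' @return q-values in the input order.
#' @export
storey_q <- function(p, pi0 = NULL) {
  .check_p(p)
  if (is.null(pi0)) pi0 <- as.numeric(suppressWarnings(estimate_pi0(p)))
  stopifnot(length(pi0) == 1L, pi0 > 0, pi0 <= 1)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)
  q[order(o)]
}

#' Attach per-branch q-values to an association table
#'
#' q-values are computed within each analysis branch's pooled p-value set —
#' all drugs on that branch together — never across branches, so that the
#' multiplicity each test faces matches the family it was actually part of.
#' On the two-step branch only *screened* pairs carry a confirmed p-value
#' and only those enter the pool. A pair is flagged significant when its
#' q-value is at or below `q_threshold` (default 0.3).
#'
#' @param results data.frame from [associate_all()].
#' @param q_threshold significance cut on the q-value (default 0.3).
#' @return `results` with `q_value` filled in and a logical `significant`
#'   column appended.
#' @export
attach_q_by_branch <- function(results, q_threshold = 0.3) {
  stopifnot(is.data.frame(results),
            all(c("branch", "p_value") %in% colnames(results)))
  results$q_value <- NA_real_
  for (br in unique(results$branch)) {
    pool <- which(results$branch == br & !is.na(results$p_value) &
                    (br != "two_step" | results$screened %in% TRUE))
    if (length(pool) == 0L) next
    results$q_value[pool] <- storey_q(results$p_value[pool])
  }
  results$significant <- !is.na(results$q_value) & results$q_value <= q_threshold
  results
}
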