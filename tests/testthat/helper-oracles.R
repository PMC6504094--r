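# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: enumeration, double loops and the
# normal equations, at tiny n.

# Exact two-sided Mann-Whitney p by full enumeration of all group labelings.
oracle_mw_enum_p <- function(values, is_resistant) {
  n <- length(values)
  n1 <- sum(is_resistant)
  r <- rank(values)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(which(is_resistant))
  us <- apply(utils::combn(n, n1), 2L, u_of)
  min(1, 2 * min(mean(us >= u_obs), mean(us <= u_obs)))
}

# Storey q-values by the O(m^2) double-loop min formula.
oracle_storey_q <- function(p, pi0) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(vapply(ts, function(t) pi0 * m * t / sum(p <= t), 0), 1)
  }, 0)
}

# OLS by the explicit normal equations.
oracle_ols <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - ncol(X))
  se <- sqrt(diag(solve(XtX)) * s2)
  list(beta = as.numeric(beta), se = as.numeric(se), sigma2 = s2)
}

# Global test Q as a dense quadratic form.
oracle_global_q <- function(X, y) {
  Xc <- X - rowMeans(X)
  yc <- y - mean(y)
  s2 <- sum(yc^2) / length(y)
  as.numeric(crossprod(yc, crossprod(Xc) %*% yc)) / (nrow(X) * s2)
}

# Exact permutation distribution of Q by enumerating every labeling with
# the observed group sizes.
oracle_q_enum <- function(X, y) {
  n <- length(y)
  n1 <- sum(y == max(y))
  apply(utils::combn(n, n1), 2L, function(idx) {
    yy <- rep(0, n); yy[idx] <- 1
    oracle_global_q(X, yy)
  })
}

# Small named helpers for fixtures.
named_vec <- function(x, prefix = "s") stats::setNames(x, sprintf("%s%02d", prefix, seq_along(x)))

toy_expr <- function(values, scale = "log10") {
  expression_matrix(values, scale = scale)
}

# A drug profile with a prescribed number of censored samples.
censored_profile <- function(neglog, n_at_max, drug = "d", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(neglog))) neglog <- named_vec(neglog)
  ic50 <- 10^(-neglog)
  if (n_at_max > 0) {
    thr <- sort(ic50, decreasing = TRUE)[n_at_max]
    ic50 <- pmin(ic50, thr)
    max_conc <- thr
  } else max_conc <- max(ic50) * 1.05
  drug_response(drug, ic50, max_conc)
}
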