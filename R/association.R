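#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks on ties); the
#' two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' with `|rho| = 1` mapped to `p = 0`. Pairs with a missing value in either
#' vector are dropped.
#'
#' @param x,y numeric vectors of equal length (>= 4 complete pairs).
#' @return List with `rho`, `p_value`, `n` (complete pairs used).
#' @examples
#' spearman_assoc(1:5, c(2, 4, 6, 8, 10))  # rho = 1, p = 0
#' @export
spearman_assoc <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need >= 4 complete pairs for Spearman correlation, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  list(rho = rho, p_value = .spearman_t_p(rho, n), n = n)
}

# two-sided p from the t approximation; vectorized over rho
.spearman_t_p <- function(rho, n) {
  p <- numeric(length(rho))
  exact1 <- abs(rho) >= 1 - 1e-15
  p[exact1] <- 0
  r <- rho[!exact1]
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p[!exact1] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p
}

# Spearman of every row of X (features x samples) against y, in one pass.
# Rows with zero rank variance get NA rho/p. Returns list(rho, p, n).
.spearman_rows <- function(X, y) {
  n <- length(y)
  stopifnot(ncol(X) == n, n >= 4L)
  rX <- t(apply(X, 1L, rank))
  if (nrow(X) == 1L) rX <- matrix(rank(X[1L, ]), 1L, n, dimnames = dimnames(X))
  ry <- rank(y)
  const <- apply(rX, 1L, stats::sd) == 0 | stats::sd(ry) == 0
  rho <- rep(NA_real_, nrow(X))
  if (any(!const))
    rho[!const] <- as.numeric(stats::cor(t(rX[!const, , drop = FALSE]), ry))
  p <- rep(NA_real_, nrow(X))
  p[!const] <- .spearman_t_p(rho[!const], n)
  list(rho = rho, p_value = p, n = n)
}

#' Mann-Whitney U test between resistant and sensitive samples
#'
#' U is reported for the resistant group. The two-sided p-value is exact
#' (from the null U distribution) when `n1 + n2 <= 20` and there are no
#' ties, otherwise a normal approximation with tie correction and
#' continuity correction is used — mirroring standard rank-sum practice.
#' The direction is `"resistance"` iff the median rank of the resistant
#' group exceeds that of the sensitive group (higher expression among
#' resistant lines), else `"sensitivity"`.
#'
#' @param values numeric vector (e.g. a miRNA's log10 expression).
#' @param is_resistant logical vector: group membership per value.
#' @return List with `U`, `p_value`, `direction`, `n_resistant`,
#'   `n_sensitive`.
#' @examples
#' mann_whitney_assoc(c(4, 5, 6, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
mann_whitney_assoc <- function(values, is_resistant) {
  stopifnot(length(values) == length(is_resistant), is.logical(is_resistant))
  ok <- !is.na(values) & !is.na(is_resistant)
  values <- values[ok]; is_resistant <- is_resistant[ok]
  n1 <- sum(is_resistant); n2 <- sum(!is_resistant)
  if (n1 == 0L || n2 == 0L)
    stop("both groups must be non-empty (resistant n=", n1, ", sensitive n=", n2, ")")
  r <- rank(values)
  U <- sum(r[is_resistant]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(values))
  n <- n1 + n2
  if (!ties && n <= 20L) {
    p <- if (U > n1 * n2 / 2)
      stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    else
      stats::pwilcox(U, n1, n2)
    p <- min(2 * p, 1)
  } else {
    z <- U - n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)), 1)
    }
  }
  direction <- if (stats::median(r[is_resistant]) > stats::median(r[!is_resistant]))
    "resistance" else "sensitivity"
  list(U = U, p_value = p, direction = direction,
       n_resistant = n1, n_sensitive = n2)
}

#' Two-step association for moderately censored IC50 profiles
#'
#' Step 1 rank-correlates the miRNA with the *variable* (uncensored)
#' `-log10` IC50 values; pairs passing the screen (`p < screen_alpha`) are
#' confirmed in step 2 by a Mann-Whitney test of the miRNA between the
#' at-maximum samples (classified resistant) and the variable samples
#' (classified sensitive). The confirmed (step-2) p-value is the pair's
#' final p-value; the direction call comes from the step-1 rho sign.
#'
#' @param p a [drug_response()] whose [classify_profile()] branch is
#'   `"two_step"`.
#' @param mirna_row named numeric vector of the miRNA's log10 expression
#'   (names = sample ids; must cover the profile's samples).
#' @param screen_alpha step-1 screening threshold (default 0.05).
#' @return List of class `two_step_result`: `step1` (rho, p_value, n),
#'   `screened`, `step2` (U, p_value, direction; `NULL` unless screened),
#'   `final_p` (`NA` unless screened), `screenable` (`FALSE` when step 1 is
#'   degenerate, e.g. all variable IC50s identical).
#' @export
two_step_assoc <- function(p, mirna_row, screen_alpha = 0.05) {
  cls <- classify_profile(p)
  if (cls$branch != "two_step")
    stop("profile of drug ", p$drug_name, " is on branch '", cls$branch,
         "', not 'two_step'")
  stopifnot(!is.null(names(mirna_row)))
  common <- intersect(names(p$ic50)[!is.na(p$ic50)], names(mirna_row))
  am <- at_max(p)[common]
  y <- neglog10_ic50(p)[common]
  x <- mirna_row[common]
  res <- list(step1 = NULL, screened = FALSE, step2 = NULL,
              final_p = NA_real_, screenable = TRUE)
  step1 <- tryCatch(spearman_assoc(x[!am], y[!am]), error = function(e) e)
  if (inherits(step1, "error")) {
    res$screenable <- FALSE
    res$note <- conditionMessage(step1)
    class(res) <- "two_step_result"
    return(res)
  }
  res$step1 <- step1
  if (step1$p_value < screen_alpha) {
    res$screened <- TRUE
    res$step2 <- mann_whitney_assoc(x, am)
    res$final_p <- res$step2$p_value
  }
  class(res) <- "two_step_result"
  res
}

#' Associate every miRNA with every drug, branch-aware
#'
#' For each drug the profile is classified once ([classify_profile()]) and
#' every miRNA is tested on that branch:
#'
#' * `spearman`: rank correlation of log10 miRNA with `-log10(IC50)` over
#'   all non-missing samples;
#' * `two_step`: [two_step_assoc()] (only screened pairs carry a final p);
#' * `mann_whitney`: miRNA compared between at-max (resistant) and variable
#'   (sensitive) samples.
#'
#' Direction is `"sensitivity"` when higher miRNA expression goes with
#' higher `-log10(IC50)` (lower IC50), i.e. positive rho; `"resistance"`
#' for negative rho; Mann-Whitney pairs use the test's own direction call.
#' Degenerate pairs (constant miRNA over the used samples) yield `NA`
#' statistics and are counted in `attr(, "n_degenerate")`.
#'
#' q-values are left `NA` here; fill them per branch with
#' [attach_q_by_branch()].
#'
#' @param mirna an `expr_matrix` of miRNA expression on the `"log10"` scale.
#' @param drugs list of [drug_response()] profiles.
#' @param screen_alpha step-1 screening alpha for the two-step branch.
#' @return A data.frame with one row per (drug, miRNA) pair: `drug`,
#'   `mirna`, `branch`, `n_at_max`, `n_variable`, `statistic` (rho or U),
#'   `step1_rho`, `step1_p`, `screened`, `p_value`, `q_value` (NA),
#'   `direction`, `n_used`.
#' @export
associate_all <- function(mirna, drugs, screen_alpha = 0.05) {
  stopifnot(inherits(mirna, "expr_matrix"))
  if (mirna$scale != "log10")
    stop("miRNA matrix must be log10-scaled before association (see log10_transform)")
  stopifnot(length(drugs) >= 1L, all(vapply(drugs, inherits, TRUE, "drug_response")))
  out <- vector("list", length(drugs))
  n_degenerate <- 0L
  for (di in seq_along(drugs)) {
    p <- drugs[[di]]
    common <- intersect(sample_ids(mirna), names(p$ic50)[!is.na(p$ic50)])
    if (length(common) == 0L)
      stop("no shared samples between miRNA matrix and drug ", p$drug_name)
    cls <- classify_profile(
      drug_response(p$drug_name, p$ic50[common], p$max_conc))
    X <- mirna$values[, common, drop = FALSE]
    y <- neglog10_ic50(p)[common]
    am <- at_max(p)[common]
    mir_ids <- feature_ids(mirna)
    base <- data.frame(
      drug = p$drug_name, mirna = mir_ids, branch = cls$branch,
      n_at_max = cls$n_at_max, n_variable = cls$n_variable,
      statistic = NA_real_, step1_rho = NA_real_, step1_p = NA_real_,
      screened = NA, p_value = NA_real_, q_value = NA_real_,
      direction = NA_character_, n_used = length(common),
      stringsAsFactors = FALSE)
    if (cls$branch == "spearman") {
      sp <- .spearman_rows(X, y)
      base$statistic <- sp$rho
      base$p_value <- sp$p_value
      base$direction <- ifelse(sp$rho >= 0, "sensitivity", "resistance")
      n_degenerate <- n_degenerate + sum(is.na(sp$rho))
    } else if (cls$branch == "mann_whitney") {
      for (mi in seq_along(mir_ids)) {
        mw <- tryCatch(mann_whitney_assoc(X[mi, ], am), error = function(e) NULL)
        if (is.null(mw)) { n_degenerate <- n_degenerate + 1L; next }
        base$statistic[mi] <- mw$U
        base$p_value[mi] <- mw$p_value
        base$direction[mi] <- mw$direction
      }
    } else { # two_step
      sp1 <- if (sum(!am) >= 4L && stats::sd(y[!am]) > 0)
        .spearman_rows(X[, !am, drop = FALSE], y[!am])
      else list(rho = rep(NA_real_, nrow(X)), p_value = rep(NA_real_, nrow(X)))
      base$step1_rho <- sp1$rho
      base$step1_p <- sp1$p_value
      base$screened <- !is.na(sp1$p_value) & sp1$p_value < screen_alpha
      n_degenerate <- n_degenerate + sum(is.na(sp1$rho))
      for (mi in which(base$screened)) {
        mw <- tryCatch(mann_whitney_assoc(X[mi, ], am), error = function(e) NULL)
        if (is.null(mw)) { base$screened[mi] <- FALSE; next }
        base$statistic[mi] <- mw$U
        base$p_value[mi] <- mw$p_value
        base$direction[mi] <- if (sp1$rho[mi] >= 0) "sensitivity" else "resistance"
      }
    }
    out[[di]] <- base
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_degenerate") <- n_degenerate
  res
}
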