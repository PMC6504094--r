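#' Choose the association analysis for a drug's IC50 profile
#'
#' IC50 profiles differ sharply in how many cell lines are right-censored at
#' the maximum tested concentration, so a single association test cannot fit
#' all drugs. Each profile is routed by two counts over its non-missing
#' samples — `n_at_max` (IC50 at the maximum tested dose) and `n_variable`
#' (below it):
#'
#' * fewer than 10 variable values -> `"mann_whitney"` (the profile is
#'   essentially binary: resistant at-max vs the few responders);
#' * otherwise, at most 5 at-max values -> `"spearman"` (an essentially
#'   "linear" profile, rank correlation applies);
#' * otherwise (more than 5 at max *and* at least 10 variable) ->
#'   `"two_step"` (rank correlation on the variable part, confirmed by a
#'   Mann-Whitney test of at-max vs variable).
#'
#' The three published rules are non-overlapping on a complete panel; the
#' precedence order above only resolves degenerate inputs (heavy
#' missingness, tiny n) deterministically, censoring first.
#'
#' @param p a [drug_response()] profile with at least one non-missing IC50.
#' @return Object of class `analysis_branch`: list with `branch` (one of
#'   `"spearman"`, `"two_step"`, `"mann_whitney"`), `n_at_max`,
#'   `n_variable`, `n_missing`.
#' @examples
#' ic <- c(stats::runif(33, 1e-8, 9e-6), rep(1e-5, 3))
#' names(ic) <- sprintf("s%02d", 1:36)
#' classify_profile(drug_response("d", ic, 1e-5))$branch  # "spearman"
#' @export
classify_profile <- function(p) {
  stopifnot(inherits(p, "drug_response"))
  am <- at_max(p)
  n_missing <- sum(is.na(am))
  am <- am[!is.na(am)]
  if (length(am) == 0L)
    stop("all IC50 values missing for drug ", p$drug_name)
  n_at_max <- sum(am)
  n_variable <- sum(!am)
  branch <-
    if (n_variable < 10L) "mann_whitney"
    else if (n_at_max <= 5L) "spearman"
    else "two_step"
  structure(list(branch = branch, n_at_max = n_at_max,
                 n_variable = n_variable, n_missing = n_missing),
            class = "analysis_branch")
}

#' @export
print.analysis_branch <- function(x, ...) {
  cat(sprintf("<analysis_branch> %s (%d at max, %d variable, %d missing)\n",
              x$branch, x$n_at_max, x$n_variable, x$n_missing))
  invisible(x)
}
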