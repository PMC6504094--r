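#' Ordinary least squares fit with classical inference
#'
#' Fits `y = X beta + e` by least squares and reports, per column of the
#' design, the coefficient, its classical standard error, t statistic and
#' two-sided p-value on `n - p` degrees of freedom. The design must include
#' its own intercept column and be full rank; a rank-deficient design is an
#' error naming the collinear column(s) (e.g. a subtype indicator that is
#' constant over the fitted samples).
#'
#' @param y numeric response vector.
#' @param X numeric design matrix with named columns, including the
#'   intercept.
#' @return Object of class `ols_fit`: list with `coefficients` (a
#'   data.frame: estimate, se, t, p per predictor), `sigma2` (residual
#'   variance), `df_residual`, `n`.
#' @export
ols_fit <- function(y, X) {
  stopifnot(is.numeric(y), is.matrix(X), nrow(X) == length(y),
            !is.null(colnames(X)))
  if (anyNA(y) || anyNA(X)) stop("missing values in regression inputs")
  n <- length(y); p <- ncol(X)
  if (n < p + 2L) stop("need n >= p + 2 observations (n=", n, ", p=", p, ")")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(y ~ 0 + X)
  sm <- summary(fit)
  co <- sm$coefficients
  rownames(co) <- sub("^X", "", rownames(co))
  coefficients <- data.frame(
    term = rownames(co), estimate = co[, 1L], se = co[, 2L],
    t = co[, 3L], p_value = co[, 4L], row.names = NULL,
    stringsAsFactors = FALSE)
  structure(list(coefficients = coefficients, sigma2 = sm$sigma^2,
                 df_residual = fit$df.residual, n = n),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> n = %d, residual df = %d, sigma2 = %.4g\n",
              x$n, x$df_residual, x$sigma2))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Test a miRNA-drug association for molecular-subtype confounding
#'
#' A significant univariate association may merely reflect that both the
#' miRNA and the drug response track molecular subtype. For each binary
#' subtype contrast (basal vs rest, luminal vs rest, normal-like vs rest) a
#' linear model `-log10(IC50) ~ miRNA + subtype indicator` is fitted. A
#' subtype is declared confounding when, in its model, the subtype
#' coefficient is significant (`p < alpha`) while the miRNA coefficient is
#' not (`p >= alpha`); the association is *retained* iff no contrast
#' confounds it. This is a deterministic, auditable rule for "subtype
#' associated more strongly than the miRNA"; alpha is configurable.
#'
#' @param mirna_row named numeric vector of the miRNA's log10 expression.
#' @param drug_values named numeric vector of the drug's `-log10(IC50)`
#'   values (missing allowed; dropped).
#' @param subtypes a [subtype_labels()] object covering the samples.
#' @param alpha per-coefficient significance level (default 0.05).
#' @param drug,mirna identifiers carried through to the result.
#' @return Object of class `confounding_result`: list with `table` (one row
#'   per contrast: coefficient estimates and p-values for miRNA and
#'   subtype, plus a `confounds` flag; contrasts whose indicator is
#'   constant are reported with `NA` and noted), `confounded_by` (character
#'   vector), `retained` (logical), `drug`, `mirna`.
#' @export
confounding_check <- function(mirna_row, drug_values, subtypes, alpha = 0.05,
                              drug = "", mirna = "") {
  stopifnot(inherits(subtypes, "subtype_labels"),
            !is.null(names(mirna_row)), !is.null(names(drug_values)))
  common <- Reduce(intersect, list(names(mirna_row),
                                   names(drug_values)[!is.na(drug_values)],
                                   names(subtypes)))
  if (length(common) < 5L)
    stop("too few shared samples (", length(common), ") for the multivariate model")
  x <- mirna_row[common]
  y <- drug_values[common]
  st <- as.character(subtypes[common])
  contrasts <- c("basal", "luminal", "normal-like")
  rows <- lapply(contrasts, function(lv) {
    ind <- as.numeric(st == lv)
    out <- data.frame(contrast = lv, mirna_estimate = NA_real_,
                      mirna_p = NA_real_, subtype_estimate = NA_real_,
                      subtype_p = NA_real_, confounds = NA,
                      note = "", stringsAsFactors = FALSE)
    X <- cbind(intercept = 1, mirna = x, subtype = ind)
    fit <- tryCatch(ols_fit(y, X), error = function(e) e)
    if (inherits(fit, "error")) {
      out$note <- conditionMessage(fit)
      return(out)
    }
    co <- fit$coefficients
    out$mirna_estimate <- co$estimate[co$term == "mirna"]
    out$mirna_p <- co$p_value[co$term == "mirna"]
    out$subtype_estimate <- co$estimate[co$term == "subtype"]
    out$subtype_p <- co$p_value[co$term == "subtype"]
    out$confounds <- out$subtype_p < alpha && out$mirna_p >= alpha
    out
  })
  tab <- do.call(rbind, rows)
  confounded_by <- tab$contrast[tab$confounds %in% TRUE]
  structure(list(table = tab, confounded_by = confounded_by,
                 retained = length(confounded_by) == 0L,
                 drug = drug, mirna = mirna),
            class = "confounding_result")
}

#' @export
print.confounding_result <- function(x, ...) {
  cat(sprintf("<confounding_result> %s ~ %s: %s\n",
              x$drug, x$mirna,
              if (x$retained) "retained (no subtype confounding)"
              else paste0("confounded by ", paste(x$confounded_by, collapse = ", "))))
  invisible(x)
}

#' Run the confounding check over significant associations
#'
#' Applies [confounding_check()] to each significant row of an association
#' table (the drugs with essentially linear IC50 profiles, i.e. the
#' Spearman branch, are the ones that reach significance and are modelled
#' linearly).
#'
#' @param results association data.frame with `significant` filled in (see
#'   [attach_q_by_branch()]).
#' @param mirna log10-scale `expr_matrix`.
#' @param drugs named list of [drug_response()] profiles.
#' @param subtypes a [subtype_labels()] object.
#' @param alpha per-coefficient alpha (default 0.05).
#' @param branches branches whose hits are checked (default `"spearman"`).
#' @return A data.frame with one row per (association, contrast) plus
#'   summary columns `confounded_by` and `retained` repeated per
#'   association; empty with the right columns when nothing is significant.
#' @export
confounding_screen <- function(results, mirna, drugs, subtypes, alpha = 0.05,
                               branches = "spearman") {
  stopifnot(is.data.frame(results), inherits(mirna, "expr_matrix"))
  hits <- results[results$significant %in% TRUE & results$branch %in% branches, ,
                  drop = FALSE]
  empty <- data.frame(drug = character(), mirna = character(),
                      contrast = character(), mirna_estimate = numeric(),
                      mirna_p = numeric(), subtype_estimate = numeric(),
                      subtype_p = numeric(), confounds = logical(),
                      note = character(), confounded_by = character(),
                      retained = logical(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  out <- lapply(seq_len(nrow(hits)), function(i) {
    d <- drugs[[hits$drug[i]]]
    cc <- confounding_check(mirna$values[hits$mirna[i], ],
                            neglog10_ic50(d), subtypes, alpha = alpha,
                            drug = hits$drug[i], mirna = hits$mirna[i])
    cbind(drug = hits$drug[i], mirna = hits$mirna[i], cc$table,
          confounded_by = paste(cc$confounded_by, collapse = ","),
          retained = cc$retained, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
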