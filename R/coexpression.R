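#' Co-expression among miRNAs associated with the same drug
#'
#' When several miRNAs associate with one drug, their expression patterns
#' may themselves be correlated — pointing at co-regulation rather than
#' independent signals. This computes all pairwise Spearman correlations
#' among the given miRNAs across samples, with the t-approximation p-value
#' of [spearman_assoc()], and flags pairs significant at unadjusted
#' `p < alpha` (the matrices are reported raw; no multiplicity correction).
#'
#' @param mirna an `expr_matrix` (any scale; rank correlation is invariant
#'   to monotone transforms).
#' @param ids miRNA identifiers to correlate (must exist in the matrix).
#' @param alpha significance threshold on the unadjusted p (default 0.05).
#' @return Object of class `coexpression_matrix`: list with `ids`, `rho`
#'   (symmetric, unit diagonal), `p` (symmetric, `NA` diagonal),
#'   `significant` (logical mask, `p < alpha` off-diagonal), `alpha`, `n`.
#' @export
coexpression <- function(mirna, ids, alpha = 0.05) {
  stopifnot(inherits(mirna, "expr_matrix"), length(ids) >= 2L)
  unknown <- setdiff(ids, feature_ids(mirna))
  if (length(unknown))
    stop("unknown miRNA id(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(ids)) stop("duplicated miRNA id(s) requested")
  n <- ncol(mirna$values)
  if (n < 4L) stop("need >= 4 samples for co-expression analysis")
  k <- length(ids)
  rho <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(rho) <- dimnames(p) <- list(ids, ids)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    sp <- spearman_assoc(mirna$values[ids[i], ], mirna$values[ids[j], ])
    rho[i, j] <- rho[j, i] <- sp$rho
    p[i, j] <- p[j, i] <- sp$p_value
  }
  significant <- !is.na(p) & p < alpha
  structure(list(ids = ids, rho = rho, p = p, significant = significant,
                 alpha = alpha, n = n),
            class = "coexpression_matrix")
}

#' @export
print.coexpression_matrix <- function(x, ...) {
  cat(sprintf("<coexpression_matrix> %d miRNAs over %d samples (alpha = %g)\n",
              length(x$ids), x$n, x$alpha))
  print(round(x$rho, 2))
  invisible(x)
}

#' @rdname coexpression
#' @param cx a `coexpression_matrix`.
#' @param path output TSV path; rho and p matrices are stacked with a
#'   `matrix` column distinguishing them.
#' @export
write_coexpression <- function(cx, path) {
  stopifnot(inherits(cx, "coexpression_matrix"))
  block <- function(m, what) {
    df <- data.frame(matrix = what, mirna = rownames(m), m,
                     check.names = FALSE, stringsAsFactors = FALSE)
    df
  }
  utils::write.table(rbind(block(cx$rho, "rho"), block(cx$p, "p")),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
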