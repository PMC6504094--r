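#' Top / bottom expression quartile groups for one miRNA
#'
#' Samples are sorted by the miRNA's expression; the lowest
#' `floor(fraction * n)` form the bottom group and the highest the top
#' group (with 36 samples and the default fraction 0.25, 9 per group).
#' Ties are broken deterministically by sample id, so the grouping is
#' reproducible across runs and platforms.
#'
#' @param mirna_row named numeric vector of one miRNA's expression.
#' @param fraction fraction of samples per group, in `(0, 0.5]`
#'   (default 0.25).
#' @return Object of class `quartile_groups`: list with `top_ids`,
#'   `bottom_ids`, `group_size`.
#' @examples
#' x <- stats::setNames(1:12, sprintf("s%02d", 1:12))
#' quartile_groups(x)$bottom_ids  # s01 s02 s03
#' @export
quartile_groups <- function(mirna_row, fraction = 0.25) {
  stopifnot(is.numeric(mirna_row), !is.null(names(mirna_row)),
            !anyDuplicated(names(mirna_row)))
  if (!(fraction > 0 && fraction <= 0.5))
    stop("`fraction` must lie in (0, 0.5]")
  mirna_row <- mirna_row[!is.na(mirna_row)]
  n <- length(mirna_row)
  g <- as.integer(floor(fraction * n))
  if (g < 1L) stop("group size is 0 with ", n, " samples and fraction ", fraction)
  ord <- order(mirna_row, names(mirna_row))
  structure(list(bottom_ids = names(mirna_row)[ord[seq_len(g)]],
                 top_ids = names(mirna_row)[ord[seq.int(n - g + 1L, n)]],
                 group_size = g),
            class = "quartile_groups")
}

#' @export
print.quartile_groups <- function(x, ...) {
  cat(sprintf("<quartile_groups> %d per group\n top: %s\n bottom: %s\n",
              x$group_size, paste(x$top_ids, collapse = ", "),
              paste(x$bottom_ids, collapse = ", ")))
  invisible(x)
}

# Quadratic-form kernel of the global test: A = Xc' Xc / (m * s2), an
# n x n matrix with zero row sums (genes are centered across the included
# samples; s2 = sum(yc^2)/n is the null variance of the centered labels).
# Q = yc' A yc, and because A 1 = 0 this equals the sum of the A-submatrix
# over the samples of one group.
.gt_kernel <- function(X, y) {
  stopifnot(is.matrix(X), is.numeric(y), ncol(X) == length(y))
  if (nrow(X) < 1L) stop("no genes available for the global test")
  if (length(unique(y)) < 2L) stop("both groups must be non-empty")
  Xc <- X - rowMeans(X)
  yc <- y - mean(y)
  s2 <- sum(yc^2) / length(y)
  list(A = crossprod(Xc) / (nrow(X) * s2), yc = yc, m = nrow(X))
}

#' Global test statistic Q for one gene set
#'
#' Tests whether the joint expression of a set of genes differs between two
#' sample groups. With genes centered across the included samples and
#' group labels centered, `Q = (1/m) * sum_j (x_j . y_c)^2 / s2` where `m`
#' is the number of genes and `s2 = (y_c . y_c)/n` — a quadratic form in
#' the labels that grows when many genes co-vary with the grouping. Genes
#' are centered but not variance-standardized (set `standardize = TRUE` to
#' put genes on equal footing regardless of variance).
#'
#' @param X numeric gene-by-sample matrix, already restricted to the
#'   samples being compared (e.g. top union bottom quartile groups).
#' @param y binary (0/1 or logical) group label per sample.
#' @param standardize scale each gene to unit variance before testing
#'   (genes with zero variance are left centered only).
#' @return Nonnegative scalar Q.
#' @export
global_test_q <- function(X, y, standardize = FALSE) {
  y <- as.numeric(y)
  if (standardize) X <- .gt_standardize(X)
  k <- .gt_kernel(X, y)
  as.numeric(crossprod(k$yc, k$A %*% k$yc))
}

.gt_standardize <- function(X) {
  s <- apply(X, 1L, stats::sd)
  s[s == 0] <- 1
  (X - rowMeans(X)) / s
}

# Exact mean and variance of Q over the label-permutation distribution.
# Q equals sum(A[S, S]) over the random size-k subset S of group-1 labels;
# with A's row sums zero the moments reduce to trace identities in
# tr(A) and the entrywise sums of A^2. Falls back to full subset
# enumeration (exact by construction) when the subset count is small.
.gt_perm_moments <- function(A, k, enum_limit = 20000) {
  n <- nrow(A)
  stopifnot(k >= 1L, k <= n - 1L)
  if (choose(n, k) <= enum_limit) {
    qs <- .gt_enumerate_q(A, k)
    return(list(mean = mean(qs), var = stats::var(qs) * (length(qs) - 1) / length(qs),
                exact_q = qs))
  }
  d <- diag(A)
  D <- sum(d)            # tr(A)
  S2d <- sum(d^2)
  S2off <- sum(A^2) - S2d
  F <- -D                # off-diagonal total (row sums are zero)
  p1 <- k / n
  p2 <- p1 * (k - 1) / (n - 1)
  p3 <- if (n >= 3) p2 * (k - 2) / (n - 2) else 0
  p4 <- if (n >= 4) p3 * (k - 3) / (n - 3) else 0
  mu <- p1 * D + p2 * F
  m2 <- p1 * S2d + p2 * (D^2 - S2d) +
    2 * (-2 * p2 * S2d + p3 * (D * F + 2 * S2d)) +
    2 * p2 * S2off + 4 * p3 * (S2d - S2off) +
    p4 * (F^2 + 2 * S2off - 4 * S2d)
  list(mean = mu, var = max(m2 - mu^2, 0), exact_q = NULL)
}

# Q over every size-k subset (exact permutation distribution support).
.gt_enumerate_q <- function(A, k) {
  combs <- utils::combn(nrow(A), k)
  apply(combs, 2L, function(S) sum(A[S, S]))
}

#' Permutation p-value for the global test
#'
#' Group labels are permuted uniformly `n_perm` times and the add-one
#' estimator `p = (1 + #\{Q_perm >= Q_obs\}) / (1 + n_perm)` is returned,
#' so the p-value can never be 0 and is bounded below by
#' `1 / (n_perm + 1)`.
#'
#' @inheritParams global_test_q
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed for the permutations; `NULL` uses the
#'   current RNG state.
#' @return Permutation p-value.
#' @export
permutation_p <- function(X, y, n_perm = 1000L, seed = NULL,
                          standardize = FALSE) {
  stopifnot(n_perm >= 1L)
  y <- as.numeric(y)
  if (standardize) X <- .gt_standardize(X)
  k <- .gt_kernel(X, y)
  q_obs <- as.numeric(crossprod(k$yc, k$A %*% k$yc))
  n1 <- sum(y == max(y))
  n <- length(y)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  tol <- 1e-8 * max(1, abs(q_obs))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    S <- sample.int(n, n1)
    if (sum(k$A[S, S]) >= q_obs - tol) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

#' Approximate analytic p-value for the global test
#'
#' Right-tail probability of Q under label exchangeability. When the number
#' of distinct label arrangements is small the tail is evaluated exactly on
#' the full enumeration of arrangements; otherwise the exact mean and
#' variance of Q over the permutation distribution (closed-form trace
#' identities) are matched to a scaled chi-square `a * chisq(df)` with
#' `a = var / (2 mean)` and `df = 2 mean^2 / var`. Zero permutation
#' variance (e.g. all genes constant) yields `p = 1`.
#'
#' @inheritParams global_test_q
#' @return Approximate p-value in `[0, 1]`.
#' @export
approx_p <- function(X, y, standardize = FALSE) {
  y <- as.numeric(y)
  if (standardize) X <- .gt_standardize(X)
  k <- .gt_kernel(X, y)
  q_obs <- as.numeric(crossprod(k$yc, k$A %*% k$yc))
  mom <- .gt_perm_moments(k$A, sum(y == max(y)))
  if (!is.null(mom$exact_q))
    return(mean(mom$exact_q >= q_obs - 1e-8 * max(1, abs(q_obs))))
  if (mom$var <= 1e-12 * max(1, mom$mean^2)) return(1)
  a <- mom$var / (2 * mom$mean)
  df <- 2 * mom$mean^2 / mom$var
  stats::pchisq(q_obs / a, df = df, lower.tail = FALSE)
}

#' Quartile-group pathway screen
#'
#' For each miRNA: samples are split into top and bottom expression
#' quartile groups; each gene set is tested for differential joint mRNA
#' expression between the groups with the global test (Q, its approximate
#' analytic p, and a label-permutation p). Benjamini-Hochberg adjustment
#' is applied to the analytic p-values across all sets tested for that
#' miRNA (one pool per miRNA; set `bh_per_mirna = FALSE` to pool across
#' the whole screen). A set is called significant under the dual
#' criterion: BH-adjusted p below `bh_threshold` *and* permutation p
#' below `perm_threshold`.
#'
#' Genes in a set but absent from the mRNA matrix are dropped and counted
#' in `n_genes_used`; sets with no gene present are reported with `NA`
#' statistics.
#'
#' @param mrna gene-level `expr_matrix`.
#' @param sets a [gene_set_collection()].
#' @param mirna miRNA `expr_matrix` (shares sample ids with `mrna`).
#' @param mirna_ids miRNAs to screen.
#' @param fraction quartile fraction (default 0.25).
#' @param n_perm permutations per set (default 1000).
#' @param seed integer seed for the permutation tests (recorded in the
#'   result); required for a reproducible stochastic criterion.
#' @param bh_threshold BH-adjusted significance cut (default 0.1).
#' @param perm_threshold permutation-p significance cut (default 0.05).
#' @param bh_per_mirna pool BH within each miRNA (default) or globally.
#' @param standardize passed to the global test.
#' @return data.frame with one row per (miRNA, set): `mirna`, `set_name`,
#'   `Q`, `p_approx`, `p_perm`, `p_bh`, `significant`, `n_genes_used`;
#'   the seed is attached as `attr(, "seed")`.
#' @export
pathway_screen <- function(mrna, sets, mirna, mirna_ids, fraction = 0.25,
                           n_perm = 1000L, seed = 1L, bh_threshold = 0.1,
                           perm_threshold = 0.05, bh_per_mirna = TRUE,
                           standardize = FALSE) {
  stopifnot(inherits(mrna, "expr_matrix"), inherits(sets, "gene_set_collection"),
            inherits(mirna, "expr_matrix"))
  unknown <- setdiff(mirna_ids, feature_ids(mirna))
  if (length(unknown))
    stop("unknown miRNA id(s): ", paste(unknown, collapse = ", "))
  shared <- intersect(sample_ids(mrna), sample_ids(mirna))
  if (length(shared) < 8L)
    stop("need >= 8 shared samples between mRNA and miRNA matrices")
  out <- list()
  seed_i <- seed
  for (mid in mirna_ids) {
    qg <- quartile_groups(mirna$values[mid, shared], fraction = fraction)
    used <- c(qg$bottom_ids, qg$top_ids)
    y <- as.numeric(used %in% qg$top_ids)
    rows <- lapply(names(sets$sets), function(sn) {
      genes <- intersect(sets$sets[[sn]], feature_ids(mrna))
      if (length(genes) == 0L)
        return(data.frame(mirna = mid, set_name = sn, Q = NA_real_,
                          p_approx = NA_real_, p_perm = NA_real_,
                          p_bh = NA_real_, significant = NA,
                          n_genes_used = 0L, stringsAsFactors = FALSE))
      X <- mrna$values[genes, used, drop = FALSE]
      data.frame(
        mirna = mid, set_name = sn,
        Q = global_test_q(X, y, standardize = standardize),
        p_approx = approx_p(X, y, standardize = standardize),
        p_perm = permutation_p(X, y, n_perm = n_perm,
                               seed = seed_i <<- seed_i + 1L,
                               standardize = standardize),
        p_bh = NA_real_, significant = NA, n_genes_used = length(genes),
        stringsAsFactors = FALSE)
    })
    out[[mid]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  pools <- if (bh_per_mirna) split(seq_len(nrow(res)), res$mirna)
  else list(seq_len(nrow(res)))
  for (idx in pools) {
    ok <- idx[!is.na(res$p_approx[idx])]
    if (length(ok)) res$p_bh[ok] <- bh_adjust(res$p_approx[ok])
  }
  res$significant <- !is.na(res$p_bh) & res$p_bh < bh_threshold &
    !is.na(res$p_perm) & res$p_perm < perm_threshold
  res$significant[is.na(res$p_approx)] <- NA
  attr(res, "seed") <- seed
  res
}
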