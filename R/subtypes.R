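#' Molecular subtype labels
#'
#' Per-sample breast-cancer subtype calls in `{basal, luminal, normal-like}`.
#' Subtype is a known confounder of drug-association studies in these
#' panels, so labels are a first-class pipeline input. They are typically
#' derived upstream by clustering mRNA expression (see [cluster_subtypes()]);
#' the mapping of clusters to named subtypes is supplied by the user, never
#' inferred here.
#'
#' @param sample_ids character vector of unique sample ids.
#' @param label character vector, one of `"basal"`, `"luminal"`,
#'   `"normal-like"` per sample.
#' @return Object of class `subtype_labels`: a named factor.
#' @export
subtype_labels <- function(sample_ids, label) {
  levels <- c("basal", "luminal", "normal-like")
  stopifnot(length(sample_ids) == length(label))
  if (anyDuplicated(sample_ids)) stop("duplicated sample id(s) in subtype labels")
  if (!all(label %in% levels))
    stop("unknown subtype label(s): ",
         paste(unique(setdiff(label, levels)), collapse = ", "))
  out <- factor(label, levels = levels)
  names(out) <- sample_ids
  class(out) <- c("subtype_labels", class(out))
  out
}

#' @rdname subtype_labels
#' @param path TSV with columns `sample` and `subtype`.
#' @export
read_subtype_labels <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  if (!all(c("sample", "subtype") %in% colnames(tab)))
    stop("subtype file must have columns 'sample' and 'subtype': ", path)
  subtype_labels(tab$sample, tab$subtype)
}

#' @rdname subtype_labels
#' @param labels a `subtype_labels` object.
#' @export
write_subtype_labels <- function(labels, path) {
  stopifnot(inherits(labels, "subtype_labels"))
  utils::write.table(
    data.frame(sample = names(labels), subtype = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Uncentered-correlation distance between sample profiles
#'
#' `d(x, y) = 1 - (sum x_i y_i) / (||x|| ||y||)`, i.e. one minus the cosine
#' similarity (the "non-centered correlation"). Ranges over `[0, 2]`;
#' `d(x, x) = 0` for any nonzero `x` and `d(x, -x) = 2`.
#'
#' @param m an `expr_matrix`; distances are between sample columns.
#' @return A `dist` object over samples.
#' @export
uncentered_cor_dist <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  x <- m$values
  nrm <- sqrt(colSums(x^2))
  if (any(nrm == 0)) stop("sample with all-zero profile has no direction")
  cosine <- crossprod(x) / tcrossprod(nrm)
  d <- 1 - cosine
  # clamp tiny negative round-off on the diagonal
  d[d < 0] <- 0
  stats::as.dist(d)
}

#' Cluster samples into candidate subtype groups
#'
#' Average-linkage agglomerative clustering of samples under the
#' uncentered-correlation distance, cut into `k` clusters. This reproduces
#' the clustering step used to derive molecular subtypes from mRNA arrays;
#' naming the resulting clusters (which cluster is "basal", etc.) is left to
#' the caller, since that mapping requires external reference calls.
#'
#' @param m an `expr_matrix` of the profiling data (features x samples).
#' @param k number of clusters (default 3, the three intrinsic subtypes).
#' @return Integer vector of cluster memberships named by sample id.
#' @export
cluster_subtypes <- function(m, k = 3L) {
  stopifnot(inherits(m, "expr_matrix"))
  n <- ncol(m$values)
  if (k > n) stop("cannot cut ", n, " samples into ", k, " clusters")
  hc <- stats::hclust(uncentered_cor_dist(m), method = "average")
  stats::cutree(hc, k = k)
}
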