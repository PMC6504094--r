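#' Expression matrix (features x samples)
#'
#' Container for a features-by-samples expression matrix with an explicit
#' scale flag, so that downstream code can refuse to double-log-transform
#' data. `"raw"` values are linear-scale intensities and must be strictly
#' positive (their base-10 logarithm must exist); `"log10"` values are
#' already log10-transformed.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Row and column names are the feature and sample identifiers and must
#'   be unique and non-empty.
#' @param scale `"raw"` or `"log10"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `scale`.
#' @examples
#' m <- expression_matrix(
#'   matrix(c(10, 100, 1, 1000), 2, 2,
#'          dimnames = list(c("miR-a", "miR-b"), c("s1", "s2"))),
#'   scale = "raw")
#' log10_transform(m)$values
#' @export
expression_matrix <- function(values, scale = c("raw", "log10")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("`values` must carry feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(fid))
    stop("duplicated feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicated sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (any(!nzchar(fid)) || any(!nzchar(sid)))
    stop("empty feature or sample id")
  if (anyNA(values))
    stop("expression values must not be missing")
  if (scale == "raw" && any(values <= 0))
    stop("raw expression values must be strictly positive (log10 must be defined)")
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @rdname expression_matrix
#' @param m an `expr_matrix`.
#' @export
feature_ids <- function(m) rownames(m$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(m) UseMethod("sample_ids")

#' @export
sample_ids.expr_matrix <- function(m) colnames(m$values)

#' Read / write an expression matrix as TSV
#'
#' The file dialect is a tab-separated table with a header row: the first
#' column holds feature identifiers, the remaining columns one sample each,
#' named in the header.
#'
#' @param path file path.
#' @param scale declared scale of the stored values (`"raw"` or `"log10"`).
#' @return `read_expression_matrix` returns an [expression_matrix()];
#'   `write_expression_matrix` returns `path` invisibly.
#' @export
read_expression_matrix <- function(path, scale = c("raw", "log10")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L)
    stop("expression matrix file needs a feature-id column plus >= 1 sample column: ", path)
  fid <- tab[[1L]]
  if (anyDuplicated(fid))
    stop("duplicated feature id(s) in ", path, ": ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1L, , drop = TRUE]
    stop(sprintf("non-numeric value %s at row %d (feature '%s'), column '%s' of %s",
                 dQuote(vals[bad[1L], bad[2L]]), bad[1L], fid[bad[1L]],
                 colnames(vals)[bad[2L]], path))
  }
  dimnames(num) <- list(fid, colnames(vals))
  expression_matrix(num, scale = scale)
}

#' @rdname read_expression_matrix
#' @param m an `expr_matrix` to write.
#' @param feature_col header name of the feature-id column.
#' @export
write_expression_matrix <- function(m, path, feature_col = "feature") {
  stopifnot(inherits(m, "expr_matrix"))
  tab <- data.frame(feature_ids(m), m$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab)[1L] <- feature_col
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log10-transform a raw-scale expression matrix
#'
#' Expression values are log10-transformed before any association test;
#' the scale flag prevents accidental double transformation.
#'
#' @param m an `expr_matrix` on the `"raw"` scale with strictly positive
#'   values.
#' @return An `expr_matrix` on the `"log10"` scale.
#' @export
log10_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale == "log10")
    stop("matrix is already log10-scaled; refusing to transform twice")
  if (any(m$values <= 0))
    stop("log10 transform undefined: nonpositive value present")
  expression_matrix(log10(m$values), scale = "log10")
}
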