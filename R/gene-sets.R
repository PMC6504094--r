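#' Gene-set collection (GMT format)
#'
#' A named collection of gene sets, as used by the pathway screen. The GMT
#' dialect is the usual one: one set per line, tab-separated — set name,
#' description, then member gene identifiers.
#'
#' @param sets named list of character vectors (set name -> gene ids).
#' @param source free-text provenance string (e.g. "KEGG").
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = "") {
  if (!is.list(sets) || is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("`sets` must be a list with unique names")
  if (any(lengths(sets) == 0L))
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  sets <- lapply(sets, as.character)
  structure(list(sets = sets, source = source), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets (%d-%d genes)%s\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
              if (nzchar(x$source)) paste0(", source: ", x$source) else ""))
  invisible(x)
}

#' @rdname gene_set_collection
#' @param path GMT file path.
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1L], " has fewer than 3 fields (name, description, genes)")
  sets <- lapply(parts, function(f) f[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  gene_set_collection(sets, source = source)
}

#' @rdname gene_set_collection
#' @param gsc a `gene_set_collection`.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(gsc, path, descriptions = NULL) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  if (is.null(descriptions)) descriptions <- rep(gsc$source, length(gsc$sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(gsc$sets), descriptions, gsc$sets)
  writeLines(lines, path)
  invisible(path)
}
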