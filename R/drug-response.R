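#' Per-drug IC50 profile with right-censoring at the maximum tested dose
#'
#' Dose-response screens test each drug up to a maximum concentration; cell
#' lines whose IC50 is not reached within the tested range are recorded *at*
#' that maximum, i.e. the IC50 is right-censored. The profile stores the raw
#' molar IC50s together with the maximum tested concentration, which defines
#' censoring for everything downstream.
#'
#' A sample is "at maximum" iff `ic50 >= max_conc * (1 - 1e-9)`; the relative
#' tolerance absorbs round-off in stored tables. Missing IC50s (`NA`) are
#' allowed and are excluded pairwise from all tests and counts.
#'
#' @param drug_name drug identifier.
#' @param ic50 named numeric vector of molar IC50 values (names = sample
#'   ids); `NA` marks a missing measurement. Non-missing values must be
#'   positive and not exceed `max_conc` (within tolerance).
#' @param max_conc positive scalar, the maximum tested concentration (molar).
#' @return An object of class `drug_response`.
#' @examples
#' p <- drug_response("drugA",
#'                    c(s1 = 1e-7, s2 = 1e-6, s3 = 1e-5), max_conc = 1e-5)
#' at_max(p)        # s3 is censored
#' neglog10_ic50(p) # -log10 scale: higher = more sensitive
#' @export
drug_response <- function(drug_name, ic50, max_conc) {
  stopifnot(is.character(drug_name), length(drug_name) == 1L)
  if (!is.numeric(ic50) || is.null(names(ic50)) || anyDuplicated(names(ic50)))
    stop("`ic50` must be a numeric vector with unique sample-id names")
  if (!is.numeric(max_conc) || length(max_conc) != 1L || !is.finite(max_conc) ||
      max_conc <= 0)
    stop("`max_conc` must be a single positive number")
  ok <- !is.na(ic50)
  if (any(ic50[ok] <= 0))
    stop("IC50 values must be positive (drug ", drug_name, ")")
  if (any(ic50[ok] > max_conc * (1 + 1e-9)))
    stop("IC50 above the maximum tested concentration for drug ", drug_name)
  structure(list(drug_name = drug_name, ic50 = ic50, max_conc = max_conc),
            class = "drug_response")
}

#' @export
print.drug_response <- function(x, ...) {
  cat(sprintf("<drug_response> %s: %d samples (%d missing, %d at max), max_conc = %g M\n",
              x$drug_name, length(x$ic50), sum(is.na(x$ic50)),
              sum(at_max(x), na.rm = TRUE), x$max_conc))
  invisible(x)
}

#' @rdname drug_response
#' @param p a `drug_response`.
#' @return `at_max` returns a logical vector (`NA` where the IC50 is
#'   missing): is the sample's IC50 censored at the maximum tested dose?
#' @export
at_max <- function(p) {
  stopifnot(inherits(p, "drug_response"))
  p$ic50 >= p$max_conc * (1 - 1e-9)
}

#' Negative log10 IC50 (sensitivity scale)
#'
#' Drug response is analysed on the -log10(IC50) scale, on which larger
#' values mean greater sensitivity. Censored (at-maximum) samples map to the
#' vector's minimum attainable value, `-log10(max_conc)`; sample ordering is
#' exactly reversed relative to raw IC50.
#'
#' @param p a `drug_response`.
#' @return Named numeric vector of `-log10(ic50)` (`NA` preserved).
#' @export
neglog10_ic50 <- function(p) {
  stopifnot(inherits(p, "drug_response"))
  ok <- !is.na(p$ic50)
  if (any(p$ic50[ok] <= 0)) stop("IC50 values must be positive")
  -log10(p$ic50)
}

#' Read / write a panel of drug-response profiles as TSV
#'
#' One row per drug: columns `drug`, `max_conc`, then one column per sample
#' holding the molar IC50 (empty / NA = missing).
#'
#' @param path file path.
#' @return `read_ic50_table` returns a named list of [drug_response()]
#'   objects.
#' @export
read_ic50_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("drug", "max_conc")
  if (!all(need %in% colnames(tab)[1:2]))
    stop("IC50 table must start with columns 'drug' and 'max_conc': ", path)
  if (anyDuplicated(tab$drug))
    stop("duplicated drug name(s) in ", path)
  samples <- colnames(tab)[-(1:2)]
  if (length(samples) == 0L) stop("IC50 table has no sample columns: ", path)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    ic50 <- as.numeric(tab[i, samples])
    names(ic50) <- samples
    drug_response(as.character(tab$drug[i]), ic50, as.numeric(tab$max_conc[i]))
  })
  names(out) <- tab$drug
  out
}

#' @rdname read_ic50_table
#' @param drugs a list of `drug_response` objects sharing sample ids.
#' @export
write_ic50_table <- function(drugs, path) {
  stopifnot(length(drugs) >= 1L, all(vapply(drugs, inherits, TRUE, "drug_response")))
  samples <- names(drugs[[1L]]$ic50)
  rows <- lapply(drugs, function(p) {
    stopifnot(identical(names(p$ic50), samples))
    c(list(drug = p$drug_name, max_conc = p$max_conc), as.list(p$ic50))
  })
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
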