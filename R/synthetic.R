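#' Configuration for the synthetic panel generator
#'
#' Builds the configuration consumed by [generate_panel()]. The defaults
#' describe a breast-cancer-like panel: 36 cell lines, 411 miRNAs, 34
#' drugs, subtype mix dominated by basal and luminal lines. Ten planted
#' miRNA-drug associations carry direct effects calibrated to population
#' Spearman correlations of about 0.7-0.8 (mixed directions); three
#' further pairs are purely subtype-confounded: one subtype shifts both
#' the miRNA and the drug response, with no direct link. Per-drug
#' censoring quantiles put most drugs on the essentially linear
#' (Spearman) branch, a few on the two-step branch and a few on the
#' heavily censored Mann-Whitney branch.
#'
#' @param n_samples,n_mirnas,n_drugs panel dimensions (defaults 36 / 411 / 34).
#' @param subtype_probs named probabilities over basal, luminal,
#'   normal-like.
#' @param planted_assocs data.frame with columns `mirna` (index), `drug`
#'   (index), `rho` (target population Pearson/Spearman-scale correlation,
#'   signed: positive = sensitivity).
#' @param confounded_assocs data.frame with columns `mirna`, `drug`,
#'   `subtype`, `shift` (shift size in units of the trait's SD).
#' @param censor_quantile numeric vector, one value in `[0, 1)` per drug:
#'   the fraction of samples recorded at the maximum tested concentration.
#' @param noise_sd residual SD of the latent `-log10(IC50)` (default 0.5).
#' @param n_genes,planted_sets mRNA side: number of genes and a data.frame
#'   with columns `set_name`, `target_mirna` (index), `loading`, `n_genes`
#'   describing sets that co-vary with a miRNA.
#' @param n_null_sets number of additional null gene sets.
#' @param genes_per_set genes per null set.
#' @param seed integer RNG seed; everything is reproducible from it.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_samples = 36L, n_mirnas = 411L, n_drugs = 34L,
    subtype_probs = c(basal = 0.50, luminal = 0.35, `normal-like` = 0.15),
    planted_assocs = data.frame(
      mirna = 1:10, drug = 1:10,
      rho = c(0.75, -0.75, 0.7, -0.7, 0.8, -0.8, 0.75, -0.75, 0.72, 0.78)),
    confounded_assocs = data.frame(
      mirna = 11:13, drug = 11:13,
      subtype = c("basal", "luminal", "basal"), shift = 3),
    censor_quantile = NULL,
    noise_sd = 0.5,
    n_genes = 300L,
    planted_sets = data.frame(
      set_name = c("SET_PLANTED_1", "SET_PLANTED_2"),
      target_mirna = c(1L, 5L), loading = 1, n_genes = 20L,
      stringsAsFactors = FALSE),
    n_null_sets = 8L, genes_per_set = 20L,
    seed = 1L) {
  if (is.null(censor_quantile)) {
    censor_quantile <- rep(0, n_drugs)
    if (n_drugs >= 30L) censor_quantile[25:30] <- 0.3
    if (n_drugs >= 34L) censor_quantile[31:34] <- 0.8
  }
  stopifnot(length(censor_quantile) == n_drugs,
            all(censor_quantile >= 0 & censor_quantile < 1))
  if (abs(sum(subtype_probs) - 1) > 1e-8 || any(subtype_probs < 0))
    stop("subtype_probs must be nonnegative and sum to 1")
  if (!all(names(subtype_probs) %in% c("basal", "luminal", "normal-like")))
    stop("subtype_probs must be named basal / luminal / normal-like")
  stopifnot(all(planted_assocs$mirna <= n_mirnas),
            all(planted_assocs$drug <= n_drugs),
            all(abs(planted_assocs$rho) < 1),
            all(confounded_assocs$mirna <= n_mirnas),
            all(confounded_assocs$drug <= n_drugs))
  if (length(intersect(planted_assocs$mirna, confounded_assocs$mirna)))
    stop("planted and confounded miRNAs must be disjoint")
  structure(list(
    n_samples = as.integer(n_samples), n_mirnas = as.integer(n_mirnas),
    n_drugs = as.integer(n_drugs), subtype_probs = subtype_probs,
    planted_assocs = planted_assocs, confounded_assocs = confounded_assocs,
    censor_quantile = censor_quantile, noise_sd = noise_sd,
    n_genes = as.integer(n_genes), planted_sets = planted_sets,
    n_null_sets = as.integer(n_null_sets),
    genes_per_set = as.integer(genes_per_set), seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Generate a synthetic cell-line panel with recorded ground truth
#'
#' Emulates the statistical structure the analysis assumes, so every
#' pipeline stage can be exercised without external downloads:
#'
#' * subtypes drawn from `subtype_probs`;
#' * miRNA log10 expression normal per feature (feature means/SDs drawn
#'   once), plus a subtype shift for confounded miRNAs;
#' * latent `-log10(IC50)` = drug intercept + planted miRNA effect +
#'   subtype shift (confounded drugs) + Gaussian noise; planted slopes are
#'   back-computed from the target correlation, the miRNA SD and the
#'   noise SD;
#' * right-censoring by quantile truncation: the drug's `censor_quantile`
#'   upper tail of latent IC50 is recorded at `max_conc`, which is set to
#'   that quantile value — so the at-max fraction is directly controlled;
#' * mRNA genes in a planted set are `loading * standardized target miRNA
#'   + N(0, 1)`; all other genes are pure noise; null sets draw from the
#'   noise genes.
#'
#' @param cfg a [synthetic_config()].
#' @return List of class `synthetic_panel` with elements `mirna`
#'   (log10-scale `expr_matrix`), `drugs` (named list of
#'   [drug_response()]), `subtypes`, `mrna` (log10-scale `expr_matrix`),
#'   `sets` ([gene_set_collection()]), and `truth` (list: `planted`,
#'   `confounded`, `pathway` data.frames of ground-truth pairs).
#' @export
generate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  samples <- sprintf("CL%03d", seq_len(n))
  mirnas <- sprintf("miR-%04d", seq_len(cfg$n_mirnas))
  drugs_id <- sprintf("drug%02d", seq_len(cfg$n_drugs))
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))

  st <- sample(names(cfg$subtype_probs), n, replace = TRUE,
               prob = cfg$subtype_probs)
  subtypes <- subtype_labels(samples, st)

  mu_f <- stats::runif(cfg$n_mirnas, 1, 3)
  sd_f <- stats::runif(cfg$n_mirnas, 0.3, 0.6)
  M <- matrix(stats::rnorm(cfg$n_mirnas * n, mean = mu_f, sd = sd_f),
              nrow = cfg$n_mirnas, ncol = n,
              dimnames = list(mirnas, samples))
  for (i in seq_len(nrow(cfg$confounded_assocs))) {
    ca <- cfg$confounded_assocs[i, ]
    ind <- as.numeric(st == ca$subtype)
    M[ca$mirna, ] <- M[ca$mirna, ] + ca$shift * sd_f[ca$mirna] * ind
  }
  mirna <- expression_matrix(M, scale = "log10")

  intercepts <- stats::runif(cfg$n_drugs, 4, 8)
  drugs <- vector("list", cfg$n_drugs)
  for (d in seq_len(cfg$n_drugs)) {
    latent <- intercepts[d] + stats::rnorm(n, 0, cfg$noise_sd)
    pa <- cfg$planted_assocs[cfg$planted_assocs$drug == d, ]
    for (j in seq_len(nrow(pa))) {
      r <- pa$rho[j]
      beta <- (r / sqrt(1 - r^2)) * cfg$noise_sd / sd_f[pa$mirna[j]]
      latent <- latent + beta * (M[pa$mirna[j], ] - mu_f[pa$mirna[j]])
    }
    ca <- cfg$confounded_assocs[cfg$confounded_assocs$drug == d, ]
    for (j in seq_len(nrow(ca)))
      latent <- latent + ca$shift[j] * cfg$noise_sd *
        as.numeric(st == ca$subtype[j])
    ic50 <- 10^(-latent)
    q <- cfg$censor_quantile[d]
    if (q > 0) {
      thr <- stats::quantile(ic50, probs = 1 - q, names = FALSE)
      ic50 <- pmin(ic50, thr)
      max_conc <- thr
    } else {
      max_conc <- max(ic50) * 1.05   # headroom: nothing at max
    }
    names(ic50) <- samples
    drugs[[d]] <- drug_response(drugs_id[d], ic50, max_conc)
  }
  names(drugs) <- drugs_id

  G <- matrix(stats::rnorm(cfg$n_genes * n), nrow = cfg$n_genes, ncol = n,
              dimnames = list(genes, samples))
  sets <- list()
  pathway_truth <- list()
  gene_cursor <- 0L
  for (i in seq_len(nrow(cfg$planted_sets))) {
    ps <- cfg$planted_sets[i, ]
    idx <- gene_cursor + seq_len(ps$n_genes)
    gene_cursor <- gene_cursor + ps$n_genes
    z <- scale(M[ps$target_mirna, ])[, 1L]
    G[idx, ] <- ps$loading * matrix(z, ps$n_genes, n, byrow = TRUE) +
      matrix(stats::rnorm(ps$n_genes * n), ps$n_genes, n)
    sets[[ps$set_name]] <- genes[idx]
    pathway_truth[[i]] <- data.frame(mirna = mirnas[ps$target_mirna],
                                     set_name = ps$set_name,
                                     stringsAsFactors = FALSE)
  }
  null_pool <- genes[(gene_cursor + 1L):cfg$n_genes]
  for (i in seq_len(cfg$n_null_sets))
    sets[[sprintf("SET_NULL_%d", i)]] <- sample(null_pool, cfg$genes_per_set)
  # mRNA intensities are reported log10-scale like the miRNA matrix
  mrna <- expression_matrix(G, scale = "log10")
  gsc <- gene_set_collection(sets, source = "synthetic")

  truth <- list(
    planted = data.frame(
      mirna = mirnas[cfg$planted_assocs$mirna],
      drug = drugs_id[cfg$planted_assocs$drug],
      rho = cfg$planted_assocs$rho,
      direction = ifelse(cfg$planted_assocs$rho >= 0, "sensitivity", "resistance"),
      stringsAsFactors = FALSE),
    confounded = data.frame(
      mirna = mirnas[cfg$confounded_assocs$mirna],
      drug = drugs_id[cfg$confounded_assocs$drug],
      subtype = cfg$confounded_assocs$subtype,
      stringsAsFactors = FALSE),
    pathway = if (length(pathway_truth)) do.call(rbind, pathway_truth)
    else data.frame(mirna = character(), set_name = character()))

  structure(list(mirna = mirna, drugs = drugs, subtypes = subtypes,
                 mrna = mrna, sets = gsc, truth = truth, config = cfg),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_panel> %d samples, %d miRNAs, %d drugs, ",
                     "%d genes, %d gene sets (seed %d)\n"),
              x$config$n_samples, x$config$n_mirnas, x$config$n_drugs,
              x$config$n_genes, length(x$sets$sets), x$config$seed))
  invisible(x)
}

#' Write a synthetic panel to disk in the pipeline's input formats
#'
#' Emits the same TSV / GMT files [run_pipeline()] reads, so the full
#' pipeline can be driven from generated files.
#'
#' @param panel a `synthetic_panel`.
#' @param dir output directory (created if missing).
#' @return Named character vector of the file paths written.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "synthetic_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mirna = file.path(dir, "mirna_log10.tsv"),
    ic50 = file.path(dir, "ic50.tsv"),
    subtypes = file.path(dir, "subtypes.tsv"),
    mrna = file.path(dir, "mrna_log10.tsv"),
    sets = file.path(dir, "gene_sets.gmt"))
  write_expression_matrix(panel$mirna, paths["mirna"], feature_col = "mirna")
  write_ic50_table(panel$drugs, paths["ic50"])
  write_subtype_labels(panel$subtypes, paths["subtypes"])
  write_expression_matrix(panel$mrna, paths["mrna"], feature_col = "gene")
  write_gmt(panel$sets, paths["sets"])
  paths
}

#' Score association results against a panel's ground truth
#'
#' @param results association data.frame with q-values attached (see
#'   [attach_q_by_branch()]).
#' @param truth the `truth` element of a generated panel.
#' @param q_threshold significance threshold on the q-value (default 0.3).
#' @return List of class `recovery_table`: `sensitivity` (fraction of
#'   planted direct pairs recovered at the threshold with the correct
#'   direction), `fdp` (fraction of significant pairs that are neither
#'   planted nor confounded — confounded pairs are genuine marginal
#'   associations), `n_significant`, `n_true_recovered`, and the
#'   significant table itself.
#' @export
evaluate_recovery <- function(results, truth, q_threshold = 0.3) {
  stopifnot(is.data.frame(results), all(c("mirna", "drug") %in% names(results)))
  sig <- results[!is.na(results$q_value) & results$q_value <= q_threshold, ,
                 drop = FALSE]
  key <- function(df) paste(df$mirna, df$drug, sep = "\r")
  planted_key <- key(truth$planted)
  true_key <- c(planted_key, key(truth$confounded))
  hit <- match(planted_key, key(sig))
  recovered <- vapply(seq_along(hit), function(i) {
    !is.na(hit[i]) &&
      identical(sig$direction[hit[i]], truth$planted$direction[i])
  }, logical(1L))
  fdp <- if (nrow(sig) == 0L) 0 else mean(!(key(sig) %in% true_key))
  structure(list(sensitivity = mean(recovered), fdp = fdp,
                 n_significant = nrow(sig),
                 n_true_recovered = sum(key(sig) %in% true_key),
                 significant = sig),
            class = "recovery_table")
}

#' @export
print.recovery_table <- function(x, ...) {
  cat(sprintf("<recovery_table> sensitivity %.2f, FDP %.2f (%d significant)\n",
              x$sensitivity, x$fdp, x$n_significant))
  invisible(x)
}
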