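#' Pipeline configuration
#'
#' Collects input paths and analysis parameters for [run_pipeline()]. All
#' thresholds default to the pipeline's standard operating values: q <=
#' 0.3 calls an association significant, 0.05 screens step 1 of the
#' two-step branch and the per-coefficient confounding tests, the pathway
#' screen uses top/bottom 25% groups, 1000 permutations, BH < 0.1 and
#' permutation p < 0.05.
#'
#' @param mirna_path,ic50_path,subtype_path,mrna_path,gmt_path input file
#'   paths (TSV / GMT; see the reader functions). `mrna_path` / `gmt_path`
#'   may be `NULL` to skip the pathway stage.
#' @param mirna_scale scale of the stored miRNA matrix (`"raw"` values are
#'   log10-transformed on load).
#' @param out_dir output directory for the report files.
#' @param q_threshold,screen_alpha,confounding_alpha,coexpression_alpha
#'   significance / screening thresholds (see module functions).
#' @param pathway_fraction,n_perm,bh_threshold,perm_threshold pathway
#'   screen parameters (see [pathway_screen()]).
#' @param spearman_only_downstream restrict confounding / co-expression /
#'   pathway stages to hits from the Spearman branch (default `TRUE`; the
#'   heavily censored branches rarely support the linear follow-up model).
#' @param seed integer seed for the stochastic stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mirna_path, ic50_path, subtype_path,
                            mrna_path = NULL, gmt_path = NULL,
                            mirna_scale = c("log10", "raw"),
                            out_dir = "mirdrug_out",
                            q_threshold = 0.3, screen_alpha = 0.05,
                            confounding_alpha = 0.05,
                            coexpression_alpha = 0.05,
                            pathway_fraction = 0.25, n_perm = 1000L,
                            bh_threshold = 0.1, perm_threshold = 0.05,
                            spearman_only_downstream = TRUE, seed = 1L) {
  mirna_scale <- match.arg(mirna_scale)
  thr <- c(q_threshold = q_threshold, screen_alpha = screen_alpha,
           confounding_alpha = confounding_alpha,
           coexpression_alpha = coexpression_alpha,
           pathway_fraction = pathway_fraction,
           bh_threshold = bh_threshold, perm_threshold = perm_threshold)
  if (any(thr < 0 | thr > 1))
    stop("thresholds must lie in [0, 1]: ",
         paste(names(thr)[thr < 0 | thr > 1], collapse = ", "))
  structure(list(mirna_path = mirna_path, ic50_path = ic50_path,
                 subtype_path = subtype_path, mrna_path = mrna_path,
                 gmt_path = gmt_path, mirna_scale = mirna_scale,
                 out_dir = out_dir, q_threshold = q_threshold,
                 screen_alpha = screen_alpha,
                 confounding_alpha = confounding_alpha,
                 coexpression_alpha = coexpression_alpha,
                 pathway_fraction = pathway_fraction,
                 n_perm = as.integer(n_perm), bh_threshold = bh_threshold,
                 perm_threshold = perm_threshold,
                 spearman_only_downstream = isTRUE(spearman_only_downstream),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s) in ", path, ": ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full association pipeline
#'
#' Executes, in order: load inputs -> classify every drug's IC50 profile ->
#' branch-aware association of every miRNA with every drug -> per-branch
#' Storey q-values -> subtype-confounding regression on the significant
#' hits -> co-expression among miRNAs hitting the same drug (drugs with
#' >= 2 retained hits) -> quartile-group pathway screen on the retained
#' miRNAs (when mRNA and gene-set inputs are configured). Writes five
#' TSV reports plus a run log into `cfg$out_dir`:
#'
#' * `associations.tsv` — every significant pair (drug, miRNA, analysis
#'   type, statistic, p, q, direction);
#' * `analysis_branches.tsv` — per drug: branch and censoring counts;
#' * `confounding.tsv` — per significant pair and subtype contrast:
#'   coefficients, p-values, confounding flags, retained;
#' * `coexpression_<drug>.tsv` — rho and p matrices per multi-hit drug;
#' * `pathways.tsv` — per (miRNA, gene set): Q, approximate p,
#'   permutation p, BH-adjusted p, significance, associated drugs (written
#'   only when the pathway stage runs, i.e. mRNA and gene-set inputs are
#'   configured and at least one miRNA was retained);
#' * `run_log.txt` — parameters, seed, stage row counts, filtered-entity
#'   counts.
#'
#' Re-running with the same config (and therefore seed) reproduces every
#' output byte-identically.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`branches`, `associations`, `confounding`, `coexpression`,
#'   `pathways`, `files`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("mirdrug run, seed %d", cfg$seed),
                 sprintf("R %s, mirdrug %s", getRversion(),
                         as.character(utils::packageVersion("mirdrug"))))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  mirna <- stage("load_mirna", {
    m <- read_expression_matrix(cfg$mirna_path, scale = cfg$mirna_scale)
    if (m$scale == "raw") log10_transform(m) else m
  })
  drugs <- stage("load_ic50", read_ic50_table(cfg$ic50_path))
  subtypes <- stage("load_subtypes", read_subtype_labels(cfg$subtype_path))

  branches <- stage("classify", {
    do.call(rbind, lapply(drugs, function(p) {
      cl <- classify_profile(p)
      data.frame(drug = p$drug_name, branch = cl$branch,
                 n_at_max = cl$n_at_max, n_variable = cl$n_variable,
                 n_missing = cl$n_missing, stringsAsFactors = FALSE)
    }))
  })
  rownames(branches) <- NULL

  assoc <- stage("associate", {
    a <- associate_all(mirna, drugs, screen_alpha = cfg$screen_alpha)
    attach_q_by_branch(a, q_threshold = cfg$q_threshold)
  })
  log_lines <- c(log_lines,
                 sprintf("associations: %d pairs tested, %d degenerate, %d significant at q <= %g",
                         nrow(assoc), attr(assoc, "n_degenerate"),
                         sum(assoc$significant, na.rm = TRUE), cfg$q_threshold))

  conf <- stage("confound",
                confounding_screen(assoc, mirna, drugs, subtypes,
                                   alpha = cfg$confounding_alpha,
                                   branches = if (cfg$spearman_only_downstream)
                                     "spearman"
                                   else unique(assoc$branch)))
  retained <- unique(conf$mirna[conf$retained %in% TRUE])

  sig <- assoc[assoc$significant %in% TRUE, , drop = FALSE]
  if (cfg$spearman_only_downstream)
    sig <- sig[sig$branch == "spearman", , drop = FALSE]
  coex <- stage("coexpress", {
    out <- list()
    for (d in unique(sig$drug)) {
      ids <- sig$mirna[sig$drug == d]
      if (length(ids) >= 2L)
        out[[d]] <- coexpression(mirna, ids, alpha = cfg$coexpression_alpha)
    }
    out
  })

  pathways <- NULL
  if (!is.null(cfg$mrna_path) && !is.null(cfg$gmt_path) && length(retained)) {
    mrna <- stage("load_mrna", read_expression_matrix(cfg$mrna_path, "log10"))
    sets <- stage("load_gmt", read_gmt(cfg$gmt_path))
    pathways <- stage("pathways",
                      pathway_screen(mrna, sets, mirna, retained,
                                     fraction = cfg$pathway_fraction,
                                     n_perm = cfg$n_perm, seed = cfg$seed,
                                     bh_threshold = cfg$bh_threshold,
                                     perm_threshold = cfg$perm_threshold))
    drug_of <- stats::aggregate(drug ~ mirna, data = sig,
                                FUN = function(d) paste(sort(unique(d)), collapse = ","))
    pathways$associated_drugs <-
      drug_of$drug[match(pathways$mirna, drug_of$mirna)]
  }

  files <- c(associations = file.path(cfg$out_dir, "associations.tsv"),
             branches = file.path(cfg$out_dir, "analysis_branches.tsv"),
             confounding = file.path(cfg$out_dir, "confounding.tsv"),
             log = file.path(cfg$out_dir, "run_log.txt"))
  if (!is.null(pathways))
    files["pathways"] <- file.path(cfg$out_dir, "pathways.tsv")
  assoc_report <- assoc[assoc$significant %in% TRUE,
                        c("drug", "mirna", "branch", "statistic", "p_value",
                          "q_value", "direction"), drop = FALSE]
  colnames(assoc_report) <- c("Drug", "MiRNA", "AssociationType", "R",
                              "p-value", "q-value", "Direction")
  utils::write.table(assoc_report, files["associations"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(branches, files["branches"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(conf, files["confounding"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (d in names(coex))
    write_coexpression(coex[[d]], file.path(cfg$out_dir,
                                            paste0("coexpression_", d, ".tsv")))
  if (!is.null(pathways)) {
    path_report <- pathways[, c("mirna", "set_name", "p_perm", "p_bh",
                                "significant", "associated_drugs")]
    colnames(path_report) <- c("MiRNA", "Pathway", "Permutation p-value",
                               "BH-adjusted p-value", "Significant",
                               "Associated drugs")
    utils::write.table(path_report, files["pathways"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  log_lines <- c(log_lines,
                 sprintf("confounding: %d associations checked, %d retained",
                         length(unique(paste(conf$drug, conf$mirna))),
                         length(retained)),
                 sprintf("coexpression: %d drugs with >= 2 hits", length(coex)),
                 sprintf("pathways: %s",
                         if (is.null(pathways)) "skipped"
                         else sprintf("%d tests, %d significant", nrow(pathways),
                                      sum(pathways$significant, na.rm = TRUE))))
  writeLines(log_lines, files["log"])
  invisible(list(branches = branches, associations = assoc,
                 confounding = conf, coexpression = coex,
                 pathways = pathways, files = files))
}
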