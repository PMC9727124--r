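#' Build a pipeline configuration
#'
#' Collects every option of the end-to-end analysis with the defaults used
#' throughout: Ward/Euclidean clustering of row-z-scored scores, majority
#' consensus for the function labels, DE thresholds padj < 0.05 and
#' |log2FC| > 1, tenfold CV for the penalised Cox screen, candidate
#' cutpoints inside the 10-90% quantiles, seeded permutations.
#'
#' @param cohort optionally a `SyntheticCohort` (in-memory input).
#' @param expr_path,scale,gmt_paths,annotations_path file inputs used when
#'   `cohort` is NULL: expression table + scale, named list of GMT paths
#'   with names used as categories (`cell_type`, `function`, `hallmark`,
#'   ...), annotation table.
#' @param housekeeping housekeeping gene ids (used when the expression
#'   scale is counts).
#' @param linkage,distance,row_zscore,consensus clustering options.
#' @param alpha_de,lfc_threshold DE thresholds.
#' @param de_contrast `"IIH-FH_vs_IIL-FL"` (default) or `"FH_vs_FL"`.
#' @param n_perm_gsea,gsea_min_size preranked GSEA options.
#' @param n_folds,quantile_bounds,n_perm_maxstat,max_cutpoint_features
#'   survival options; `survival_features` optionally restricts the Cox
#'   feature matrix to given gene ids (default: all genes).
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it by a fixed offset.
#' @param out_dir optional directory for TSV/JSON exports.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(cohort = NULL, expr_path = NULL,
                            scale = "log2norm", gmt_paths = NULL,
                            annotations_path = NULL,
                            housekeeping = housekeeping_genes(),
                            linkage = "ward", distance = "euclidean",
                            row_zscore = TRUE, consensus = "majority",
                            alpha_de = 0.05, lfc_threshold = 1,
                            de_contrast = "IIH-FH_vs_IIL-FL",
                            n_perm_gsea = 1000, gsea_min_size = 5,
                            n_folds = 10, quantile_bounds = c(0.1, 0.9),
                            n_perm_maxstat = 10000,
                            max_cutpoint_features = 5,
                            survival_features = NULL,
                            seed = 1, out_dir = NULL) {
  stopifnot(alpha_de > 0, alpha_de < 1, lfc_threshold >= 0, n_folds >= 2)
  structure(as.list(environment()), class = "PipelineConfig")
}

read_pipeline_inputs <- function(config) {
  if (!is.null(config$cohort)) {
    co <- config$cohort
    return(list(expr = co$expr, signatures = co$signatures,
                annotations = co$annotations))
  }
  if (is.null(config$expr_path)) stop_ic("no cohort and no expr_path")
  expr <- read_expression_table(config$expr_path, config$scale)
  sigs <- list()
  for (cat in names(config$gmt_paths)) {
    col <- read_gmt(config$gmt_paths[[cat]], category = cat)
    sigs <- c(sigs, col$signatures)
  }
  ann <- if (!is.null(config$annotations_path))
    read_sample_annotations(config$annotations_path) else NULL
  list(expr = expr, signatures = signature_collection(sigs),
       annotations = ann)
}

#' Run the full classification and statistics pipeline
#'
#' Executes, in order: housekeeping normalisation (when the input is
#' counts); immune cell-type scores and the ESTIMATE-style immune score;
#' the two-level IIL/IIH x FL/FH classification; Kruskal-Wallis (BH) of the
#' checkpoint genes across the four classes; differential expression for
#' the configured contrast; hypergeometric ORA of the significant genes and
#' preranked GSEA of the hallmark sets; the survival screen on
#' platinum-exposed samples (penalised Cox, maxstat cutpoints, 4-class
#' log-rank); the response association (Fisher) and the CPS vs CPS + class
#' likelihood-ratio comparison. A stage whose preconditions are unmet is
#' skipped with a recorded reason, never silently. When `config$out_dir`
#' is set, every stage's table and a JSON report are written there.
#'
#' @param config a [pipeline_config()].
#' @return a `PipelineReport` list: `class_counts`, `classes`,
#'   `cell_scores`, `immune_score`, `kruskal_wallis`, `de`, `ora`, `gsea`,
#'   `survival`, `fisher_p`, `model_comparison`, `skipped` (named reasons),
#'   `options`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  inputs <- read_pipeline_inputs(config)
  expr <- inputs$expr
  sigs <- inputs$signatures
  ann <- inputs$annotations
  skipped <- list()
  seed <- config$seed

  if (expr$scale == "counts")
    expr <- normalize_housekeeping(expr, config$housekeeping)

  cls <- classify_cohort(expr, sigs, linkage = config$linkage,
                         distance = config$distance,
                         row_zscore = config$row_zscore,
                         consensus = config$consensus)
  classes <- cls$classes
  class_vec <- stats::setNames(classes$combined, classes$sample_id)

  est_sets <- filter_signatures(sigs, "immune_estimate")
  immune_score <- if (length(est_sets) >= 1) {
    ssgsea_scores(expr, est_sets$signatures[[1]])
  } else {
    skipped$immune_score <- "no immune_estimate signature"
    NULL
  }

  ckpt <- intersect(c(checkpoint_genes(), "CDH1"), gene_ids(expr))
  kw <- if (length(ckpt) > 0 && length(unique(class_vec)) >= 2) {
    kruskal_wallis_by_class(expr$values[ckpt, , drop = FALSE], class_vec)
  } else {
    skipped$kruskal_wallis <- "no checkpoint genes in matrix or < 2 classes"
    NULL
  }

  grp <- strsplit(config$de_contrast, "_vs_")[[1]]
  pick <- function(lab) {
    if (lab %in% c("FH", "FL")) classes$sample_id[classes$`function` == lab]
    else classes$sample_id[classes$combined == lab]
  }
  gB <- pick(grp[1]); gA <- pick(grp[2])
  de <- ora <- gsea <- NULL
  if (length(gA) < 2 || length(gB) < 2) {
    skipped$de <- sprintf("contrast %s has group sizes %d vs %d",
                          config$de_contrast, length(gB), length(gA))
  } else {
    de <- differential_expression(expr, gA, gB,
                                  alpha_de = config$alpha_de,
                                  lfc_threshold = config$lfc_threshold)
    hall <- filter_signatures(sigs, "hallmark")
    test_sets <- if (length(hall) > 0) hall else
      signature_collection(c(filter_signatures(sigs, "cell_type")$signatures,
                             filter_signatures(sigs, "function")$signatures))
    hits <- de$gene[de$significant]
    if (length(hits) == 0) {
      skipped$ora <- "no significant DE genes"
    } else {
      ora <- hypergeometric_ora(hits, de$gene, test_sets)
    }
    gsea <- preranked_gsea(stats::setNames(de$log2fc, de$gene), test_sets,
                           n_perm = config$n_perm_gsea,
                           seed = derive_seed(seed, 2))
  }

  surv <- NULL
  if (is.null(ann) || !all(c("pfs_time", "pfs_event") %in% names(ann))) {
    skipped$survival <- "no PFS annotation"
  } else {
    keep <- if ("platinum_exposed" %in% names(ann))
      which(ann$platinum_exposed) else seq_len(nrow(ann))
    ann_s <- ann[keep, ]
    ann_s <- ann_s[!is.na(ann_s$pfs_time), ]
    if (nrow(ann_s) < 10 || sum(ann_s$pfs_event) < 2) {
      skipped$survival <- "too few platinum-exposed samples or events"
    } else {
      feat <- if (is.null(config$survival_features)) gene_ids(expr) else
        intersect(config$survival_features, gene_ids(expr))
      X <- t(expr$values[feat, ann_s$sample_id, drop = FALSE])
      lasso <- fit_lasso_cox(X, ann_s$pfs_time, ann_s$pfs_event,
                             n_folds = config$n_folds,
                             seed = derive_seed(seed, 3))
      sel <- lasso$selected_genes
      cuts <- list()
      for (g in utils::head(sel, config$max_cutpoint_features)) {
        cuts[[g]] <- tryCatch(
          maxstat_cutpoint(stats::setNames(X[, g], rownames(X)),
                           ann_s$pfs_time, ann_s$pfs_event,
                           quantile_bounds = config$quantile_bounds,
                           n_perm = config$n_perm_maxstat,
                           seed = derive_seed(seed, 4)),
          error = function(e) NULL)
      }
      lr <- tryCatch(
        log_rank_test(class_vec[ann_s$sample_id], ann_s$pfs_time,
                      ann_s$pfs_event),
        error = function(e) NULL)
      surv <- list(lasso = lasso, cutpoints = cuts, log_rank = lr)
    }
  }

  fisher_p <- NULL; mc <- NULL
  if (is.null(ann) || !"response" %in% names(ann) ||
      all(ann$response == "unknown")) {
    skipped$response <- "no response annotation"
  } else {
    known <- ann[ann$response %in% c("responder", "non_responder"), ]
    tab <- table(known$response, class_vec[known$sample_id])
    if (nrow(tab) < 2 || ncol(tab) < 2 || any(rowSums(tab) == 0)) {
      skipped$response <- "degenerate response-by-class table"
    } else {
      fisher_p <- fisher_exact_association(as.matrix(tab))
      resp01 <- stats::setNames(
        as.numeric(known$response == "responder"), known$sample_id)
      mc <- tryCatch(
        logistic_lrt_comparison(resp01,
                                stats::setNames(known$cps, known$sample_id),
                                class_vec[known$sample_id]),
        error = function(e) { skipped$lrt <<- conditionMessage(e); NULL })
    }
  }

  lev <- c("IIL-FL", "IIL-FH", "IIH-FL", "IIH-FH")
  report <- structure(list(
    class_counts = attr(classes, "class_counts"),
    classes = classes,
    per_signature_function = cls$per_signature_function,
    cell_scores = cls$cell_scores,
    immune_score = immune_score,
    kruskal_wallis = kw, de = de, ora = ora, gsea = gsea,
    survival = surv, fisher_p = fisher_p, model_comparison = mc,
    skipped = skipped,
    options = list(linkage = config$linkage, distance = config$distance,
                   row_zscore = config$row_zscore,
                   consensus = config$consensus,
                   alpha_de = config$alpha_de,
                   lfc_threshold = config$lfc_threshold,
                   de_contrast = config$de_contrast,
                   n_perm_gsea = config$n_perm_gsea,
                   n_folds = config$n_folds,
                   quantile_bounds = config$quantile_bounds,
                   n_perm_maxstat = config$n_perm_maxstat,
                   seed = seed)),
    class = "PipelineReport")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("PipelineReport\n  class counts: ",
      paste(names(x$class_counts), x$class_counts, sep = "=",
            collapse = ", "), "\n")
  if (!is.null(x$de))
    cat(sprintf("  DE (method-substituted rank test): %d significant gene(s)\n",
                sum(x$de$significant)))
  if (!is.null(x$fisher_p))
    cat(sprintf("  Fisher response-by-class p = %.4g\n", x$fisher_p))
  if (!is.null(x$model_comparison))
    cat(sprintf("  CPS vs CPS+class LRT p = %.4g\n", x$model_comparison$p))
  if (length(x$skipped) > 0)
    cat("  skipped:", paste(names(x$skipped), unlist(x$skipped),
                            sep = ": ", collapse = "; "), "\n")
  invisible(x)
}

#' Write a PipelineReport's tables and JSON summary to a directory
#'
#' @param report a `PipelineReport`.
#' @param dir output directory, created if needed.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df))
      utils::write.table(df, file.path(dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  cls <- report$classes
  psf <- t(report$per_signature_function)
  wt(cbind(cls, psf[cls$sample_id, , drop = FALSE]), "classes.tsv")
  wt(report$kruskal_wallis, "kruskal_wallis.tsv")
  if (!is.null(report$de)) {
    wt(report$de, "differential_expression.tsv")
    volcano <- data.frame(gene = report$de$gene, log2fc = report$de$log2fc,
                          neg_log10_p_adj = -log10(report$de$p_adj))
    wt(volcano, "volcano.tsv")
  }
  wt(report$ora, "ora.tsv")
  wt(report$gsea, "gsea.tsv")
  if (!is.null(report$survival)) {
    lasso <- report$survival$lasso
    wt(data.frame(gene = names(lasso$coefficients),
                  coefficient = lasso$coefficients),
       "lasso_coefficients.tsv")
    if (length(report$survival$cutpoints) > 0) {
      cp <- do.call(rbind, lapply(names(report$survival$cutpoints),
        function(g) {
          c0 <- report$survival$cutpoints[[g]]
          data.frame(feature = g, cutpoint = c0$cutpoint,
                     statistic = c0$max_statistic, p = c0$p)
        }))
      wt(cp, "maxstat_cutpoints.tsv")
    }
    if (!is.null(report$survival$log_rank))
      wt(report$survival$log_rank$km, "kaplan_meier.tsv")
  }
  summ <- list(class_counts = as.list(report$class_counts),
               n_de_significant = if (!is.null(report$de))
                 sum(report$de$significant) else NULL,
               fisher_p = report$fisher_p,
               model_comparison = if (!is.null(report$model_comparison))
                 unclass(report$model_comparison) else NULL,
               skipped = report$skipped,
               options = report$options)
  jsonlite::write_json(summ, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}
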