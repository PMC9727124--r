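#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values controlling the false discovery rate: sort ascending,
#' `p_adj(i) = min_{j >= i} min(1, m p(j) / j)`, returned in the input
#' order. Applied within each analysis family separately throughout the
#' package.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order and length.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (length(pvalues) == 0) stop_ic("empty p-value vector")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop_ic("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Kruskal-Wallis tests across immune classes, feature-wise
#'
#' For each feature (row), a Kruskal-Wallis rank test of the feature across
#' the class labels (tie-corrected H statistic, chi-square p with
#' #classes - 1 df), followed by BH adjustment across the features. Classes
#' with no samples are dropped with a warning.
#'
#' @param values features-by-samples numeric matrix (or a named vector for a
#'   single feature) with column names matching `classes` names.
#' @param classes named factor/character vector of class labels per sample.
#' @return data.frame: `feature`, `statistic`, `p`, `p_adj`, plus one
#'   `median_<class>` column per class.
#' @export
kruskal_wallis_by_class <- function(values, classes) {
  if (is.vector(values)) {
    values <- matrix(values, nrow = 1,
                     dimnames = list("feature", names(values)))
  }
  samples <- intersect(colnames(values), names(classes))
  if (length(samples) == 0) stop_ic("no overlapping samples")
  cls <- factor(as.character(classes[samples]))
  empty <- setdiff(unique(as.character(classes)), levels(cls))
  if (length(empty) > 0)
    warn_ic("dropping class(es) with no matched samples: %s",
            paste(empty, collapse = ", "))
  if (nlevels(cls) < 2) stop_ic("fewer than 2 classes with samples")
  v <- values[, samples, drop = FALSE]
  res <- t(apply(v, 1, function(x) {
    if (length(unique(x)) == 1)    # all observations tied: no evidence
      return(c(statistic = 0, p = 1))
    kt <- stats::kruskal.test(x, cls)
    c(statistic = unname(kt$statistic), p = kt$p.value)
  }))
  med <- t(apply(v, 1, function(x) tapply(x, cls, stats::median)))
  colnames(med) <- paste0("median_", levels(cls))
  out <- data.frame(feature = rownames(v), res, med,
                    row.names = NULL, check.names = FALSE)
  out$p_adj <- benjamini_hochberg(out$p)
  out[, c("feature", "statistic", "p", "p_adj", colnames(med))]
}

#' Rank-based differential expression between two sample groups
#'
#' Per gene: log2 fold change = mean(group B) - mean(group A) of
#' log2-normalised values; p from a two-sided Wilcoxon rank-sum test (exact
#' when the smaller group has <= 8 samples and there are no ties, normal
#' approximation with continuity and tie correction otherwise); BH across
#' genes. A gene is `significant` iff `p_adj < alpha_de` and
#' `|log2fc| > lfc_threshold`. This deliberately simple statistic replaces
#' count-model Wald tests; counts from it are method-dependent and should
#' not be compared numerically with count-model pipelines.
#'
#' @param expr `ExpressionMatrix` (`log2norm`).
#' @param groupA_samples,groupB_samples disjoint character vectors of sample
#'   ids, each of size >= 2.
#' @param alpha_de adjusted-p cutoff, default 0.05.
#' @param lfc_threshold absolute log2 fold-change cutoff, default 1.
#' @return data.frame: `gene`, `log2fc`, `statistic` (Wilcoxon W), `p`,
#'   `p_adj`, `significant`.
#' @export
differential_expression <- function(expr, groupA_samples, groupB_samples,
                                    alpha_de = 0.05, lfc_threshold = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "log2norm")
    stop_ic("differential_expression expects log2-normalised data")
  if (length(intersect(groupA_samples, groupB_samples)) > 0)
    stop_ic("groups overlap")
  miss <- setdiff(c(groupA_samples, groupB_samples), sample_ids(expr))
  if (length(miss) > 0)
    stop_ic("samples not in matrix: %s", paste(miss, collapse = ", "))
  if (length(groupA_samples) < 2 || length(groupB_samples) < 2)
    stop_ic("each group needs >= 2 samples")
  a <- expr$values[, groupA_samples, drop = FALSE]
  b <- expr$values[, groupB_samples, drop = FALSE]
  exact <- min(ncol(a), ncol(b)) <= 8
  res <- vapply(seq_len(nrow(a)), function(i) {
    if (length(unique(c(a[i, ], b[i, ]))) == 1)  # fully tied gene
      return(c(ncol(a) * ncol(b) / 2, 1))
    wt <- suppressWarnings(
      stats::wilcox.test(b[i, ], a[i, ], exact = exact, correct = TRUE))
    c(unname(wt$statistic), wt$p.value)
  }, numeric(2))
  out <- data.frame(gene = gene_ids(expr),
                    log2fc = rowMeans(b) - rowMeans(a),
                    statistic = res[1, ], p = res[2, ],
                    row.names = NULL)
  out$p_adj <- benjamini_hochberg(out$p)
  out$significant <- out$p_adj < alpha_de & abs(out$log2fc) > lfc_threshold
  out
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test of each gene set's overlap with
#' the hit list against the gene universe, BH across sets. Sets are
#' intersected with the universe first; sets disjoint from the universe are
#' dropped with a warning.
#'
#' @param hit_genes character vector, subset of `universe`.
#' @param universe character vector of background gene ids.
#' @param sets a `SignatureCollection`.
#' @return data.frame: `set_name`, `set_size` (within universe),
#'   `overlap_k`, `p`, `fdr_q`.
#' @export
hypergeometric_ora <- function(hit_genes, universe, sets) {
  stopifnot(inherits(sets, "SignatureCollection"))
  universe <- unique(universe)
  hit_genes <- unique(hit_genes)
  if (length(universe) == 0) stop_ic("empty universe")
  if (length(hit_genes) == 0) stop_ic("empty hit list")
  if (!all(hit_genes %in% universe))
    stop_ic("hit genes outside the universe: %s",
            paste(utils::head(setdiff(hit_genes, universe), 5),
                  collapse = ", "))
  n_univ <- length(universe)
  n_hit <- length(hit_genes)
  rows <- lapply(sets$signatures, function(s) {
    g <- intersect(s$genes, universe)
    if (length(g) == 0) {
      warn_ic("set '%s' disjoint from universe; dropped", s$name)
      return(NULL)
    }
    k <- length(intersect(g, hit_genes))
    # P(X >= k), X ~ Hypergeom(universe, set, draws = hits)
    p <- stats::phyper(k - 1, length(g), n_univ - length(g), n_hit,
                       lower.tail = FALSE)
    data.frame(set_name = s$name, set_size = length(g), overlap_k = k,
               p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop_ic("no set overlaps the universe")
  out <- do.call(rbind, rows)
  out$fdr_q <- benjamini_hochberg(out$p)
  rownames(out) <- NULL
  out
}

#' Fisher's exact test of response-by-class association
#'
#' Exact conditional test of a 2 x K contingency table (rows: responder /
#' non-responder; columns: immune classes). For 2 x 2 the two-sided p sums
#' all tables with point probability <= that observed; for K > 2 all tables
#' with the observed margins are enumerated (the network algorithm of the
#' canonical implementation).
#'
#' @param table 2 x K matrix of non-negative integer counts, K >= 2.
#' @return the exact p-value.
#' @export
fisher_exact_association <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2 || ncol(table) < 2)
    stop_ic("need a 2 x K table with K >= 2")
  if (any(table < 0) || any(table != round(table)))
    stop_ic("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_ic("zero margin; test undefined")
  stats::fisher.test(table)$p.value
}

#' Likelihood-ratio comparison of CPS-only vs CPS + immune class
#'
#' Fits the nested logistic models
#' `logit P(response) = b0 + b1 CPS` and the same plus indicator terms for
#' the immune class, by maximum likelihood; reports the likelihood-ratio
#' chi-square (2 * delta log-likelihood) with df = number of added class
#' parameters. Suspected perfect separation (diverging coefficients) is
#' flagged with a warning; the statistic is still reported.
#'
#' @param response named 0/1 (or logical) vector.
#' @param cps named numeric vector of PD-L1 combined positive scores.
#' @param class_label named factor/character of immune classes (>= 2
#'   observed levels).
#' @return list of class `ModelComparison`: `loglik_null`, `loglik_full`,
#'   `lr_statistic`, `df`, `p`, `separation_flag`.
#' @export
logistic_lrt_comparison <- function(response, cps, class_label) {
  s <- Reduce(intersect, list(names(response), names(cps),
                              names(class_label)))
  if (length(s) == 0) stop_ic("no overlapping samples")
  y <- as.numeric(response[s])
  if (!all(y %in% c(0, 1))) stop_ic("response must be 0/1")
  if (sum(y) == 0 || sum(y) == length(y))
    stop_ic("need at least one responder and one non-responder")
  cl <- factor(as.character(class_label[s]))
  cl <- droplevels(cl)
  x <- as.numeric(cps[s])
  null_fit <- stats::glm(y ~ x, family = stats::binomial())
  if (nlevels(cl) < 2) {
    # degenerate full model: nothing added, the comparison is vacuous
    warn_ic("class_label has a single observed level; LR statistic is 0")
    ll0 <- as.numeric(stats::logLik(null_fit))
    return(structure(list(loglik_null = ll0, loglik_full = ll0,
                          lr_statistic = 0, df = 0L, p = 1,
                          separation_flag = FALSE),
                     class = "ModelComparison"))
  }
  full_fit <- stats::glm(y ~ x + cl, family = stats::binomial())
  sep <- !full_fit$converged || any(abs(stats::coef(full_fit)) > 15,
                                    na.rm = TRUE)
  if (sep)
    warn_ic("possible perfect separation; LR statistic may be unstable")
  ll0 <- as.numeric(stats::logLik(null_fit))
  ll1 <- as.numeric(stats::logLik(full_fit))
  lr <- max(0, 2 * (ll1 - ll0))
  df <- length(stats::coef(full_fit)) - length(stats::coef(null_fit))
  structure(list(loglik_null = ll0, loglik_full = ll1, lr_statistic = lr,
                 df = df, p = stats::pchisq(lr, df, lower.tail = FALSE),
                 separation_flag = sep),
            class = "ModelComparison")
}

#' @export
print.ModelComparison <- function(x, ...) {
  cat(sprintf(
    "Likelihood-ratio model comparison: chi2 = %.3f, df = %d, p = %.4g\n",
    x$lr_statistic, x$df, x$p))
  invisible(x)
}
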