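#' Cut samples into two groups by agglomerative clustering
#'
#' Clusters the samples (columns) of a score or expression matrix and cuts
#' the dendrogram into exactly two clusters. Rows may be z-scored first,
#' the convention used for clustering heatmaps; zero-variance rows are then
#' dropped with a warning. Deterministic given inputs and options.
#'
#' @param mat a `ScoreMatrix`, `ExpressionMatrix`, or plain features-by-
#'   samples numeric matrix with column names.
#' @param linkage `"ward"` (Ward on squared Euclidean, i.e. `ward.D2`),
#'   `"complete"`, or `"average"`.
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson).
#' @param row_zscore z-score each row before computing distances.
#' @return a `ClusterCut`: list with `labels` (named integer vector in
#'   {1,2}), `linkage`, `distance`, `cophenetic_height` (height of the final
#'   merge).
#' @export
two_group_hierarchical_cut <- function(mat, linkage = c("ward", "complete",
                                                        "average"),
                                       distance = c("euclidean",
                                                    "correlation"),
                                       row_zscore = TRUE) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  v <- if (inherits(mat, c("ScoreMatrix", "ExpressionMatrix"))) mat$values
       else mat
  if (is.null(colnames(v))) stop_ic("matrix must have sample (column) names")
  if (ncol(v) < 2) stop_ic("need at least 2 samples to cluster")
  if (row_zscore) {
    sds <- apply(v, 1, stats::sd)
    if (any(sds == 0)) {
      warn_ic("dropping %d zero-variance row(s) before z-scoring",
              sum(sds == 0))
      v <- v[sds > 0, , drop = FALSE]
      sds <- sds[sds > 0]
      if (nrow(v) == 0) stop_ic("no rows left after dropping zero variance")
    }
    v <- (v - rowMeans(v)) / sds
  }
  d <- switch(distance,
              euclidean = stats::dist(t(v)),
              correlation = stats::as.dist(1 - stats::cor(v)))
  if (all(d == 0)) stop_ic("all pairwise distances are zero; degenerate input")
  method <- switch(linkage, ward = "ward.D2", complete = "complete",
                   average = "average")
  hc <- stats::hclust(d, method = method)
  labels <- stats::cutree(hc, k = 2)
  structure(list(labels = labels, linkage = linkage, distance = distance,
                 cophenetic_height = max(hc$height)),
            class = "ClusterCut")
}

#' Label the two clusters as immune-infiltrate high / low
#'
#' The cluster whose mean total cell-type score (averaged over all cell-type
#' signatures and member samples) is higher is labelled IIH, the other IIL.
#' An exact tie is broken toward the smaller cluster being IIH, with a
#' warning.
#'
#' @param cell_scores a `ScoreMatrix` of cell-type signature scores.
#' @param cut a `ClusterCut` computed on the same samples.
#' @return named character vector, `"IIL"` / `"IIH"` per sample.
#' @export
assign_infiltrate_class <- function(cell_scores, cut) {
  stopifnot(inherits(cell_scores, "ScoreMatrix"), inherits(cut, "ClusterCut"))
  samples <- colnames(cell_scores$values)
  if (!setequal(samples, names(cut$labels)))
    stop_ic("cluster cut was not computed on these samples")
  lab <- cut$labels[samples]
  m1 <- mean(cell_scores$values[, lab == 1, drop = FALSE])
  m2 <- mean(cell_scores$values[, lab == 2, drop = FALSE])
  if (m1 == m2) {
    warn_ic("tied cluster means; labelling the smaller cluster IIH")
    high <- if (sum(lab == 1) <= sum(lab == 2)) 1 else 2
  } else {
    high <- if (m1 > m2) 1 else 2
  }
  stats::setNames(ifelse(lab == high, "IIH", "IIL"), samples)
}

#' Per-signature and consensus immune-function labels
#'
#' For each functional signature, samples are clustered on the submatrix of
#' that signature's genes with [two_group_hierarchical_cut()]; the cluster
#' with higher mean expression of those genes is "high". The consensus calls
#' a sample FH iff strictly more than half of its per-signature labels are
#' "high"; an exact tie is broken by the sign of the sample's mean z-score
#' over all functional-signature genes (>= 0 is FH). As an alternative
#' integration rule, `consensus = "two_level"` clusters the samples once on
#' the matrix of per-signature mean scores and orients that single cut.
#'
#' @param expr `ExpressionMatrix` (`log2norm`).
#' @param function_sigs `SignatureCollection` of category `function`; each
#'   signature must match at least 2 genes.
#' @param linkage,distance passed to [two_group_hierarchical_cut()].
#' @param consensus `"majority"` (default) or `"two_level"`.
#' @return list with `per_signature` (signatures x samples character matrix
#'   of "low"/"high") and `consensus` (named "FL"/"FH" vector).
#' @export
assign_function_labels <- function(expr, function_sigs, linkage = "ward",
                                   distance = "euclidean",
                                   consensus = c("majority", "two_level")) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(function_sigs, "SignatureCollection"))
  consensus <- match.arg(consensus)
  if (length(function_sigs) == 0) stop_ic("no functional signatures supplied")
  samples <- sample_ids(expr)
  per_sig <- list()
  sig_means <- list()
  for (s in function_sigs$signatures) {
    g <- intersect(s$genes, gene_ids(expr))
    if (length(g) < 2)
      stop_ic("functional signature '%s' matches %d gene(s); need >= 2",
              s$name, length(g))
    sub <- expr$values[g, , drop = FALSE]
    cut <- two_group_hierarchical_cut(sub, linkage = linkage,
                                      distance = distance, row_zscore = TRUE)
    lab <- cut$labels[samples]
    mu <- colMeans(sub)
    m1 <- mean(mu[lab == 1]); m2 <- mean(mu[lab == 2])
    high <- if (m1 >= m2) 1 else 2
    per_sig[[s$name]] <- ifelse(lab == high, "high", "low")
    sig_means[[s$name]] <- mu
  }
  per_sig_mat <- do.call(rbind, per_sig)
  colnames(per_sig_mat) <- samples
  all_genes <- unique(unlist(lapply(function_sigs$signatures,
                                    function(s) intersect(s$genes,
                                                          gene_ids(expr)))))
  zsub <- expr$values[all_genes, , drop = FALSE]
  zsub <- (zsub - rowMeans(zsub)) /
    pmax(apply(zsub, 1, stats::sd), .Machine$double.eps)
  mean_z <- colMeans(zsub)
  if (consensus == "majority") {
    n_high <- colSums(per_sig_mat == "high")
    k <- nrow(per_sig_mat)
    lab <- ifelse(n_high * 2 > k, "FH",
                  ifelse(n_high * 2 < k, "FL",
                         ifelse(mean_z >= 0, "FH", "FL")))
  } else {
    sig_score <- do.call(rbind, sig_means)
    colnames(sig_score) <- samples
    cut <- two_group_hierarchical_cut(sig_score, linkage = linkage,
                                      distance = distance, row_zscore = TRUE)
    cl <- cut$labels[samples]
    m1 <- mean(mean_z[cl == 1]); m2 <- mean(mean_z[cl == 2])
    high <- if (m1 >= m2) 1 else 2
    lab <- ifelse(cl == high, "FH", "FL")
  }
  list(per_signature = per_sig_mat,
       consensus = stats::setNames(as.character(lab), samples))
}

#' Combine infiltrate and function labels into the four-class profile
#'
#' @param infiltrate_labels named "IIL"/"IIH" vector.
#' @param function_labels named "FL"/"FH" vector over the same samples.
#' @return a data.frame with columns `sample_id`, `infiltrate`, `function`,
#'   `combined` (one of IIL-FL, IIL-FH, IIH-FL, IIH-FH), plus an attribute
#'   `class_counts` (named integer vector over the four classes).
#' @export
combine_immune_class <- function(infiltrate_labels, function_labels) {
  if (!setequal(names(infiltrate_labels), names(function_labels))) {
    diff <- c(setdiff(names(infiltrate_labels), names(function_labels)),
              setdiff(names(function_labels), names(infiltrate_labels)))
    stop_ic("sample sets differ: %s", paste(diff, collapse = ", "))
  }
  s <- names(infiltrate_labels)
  fl <- function_labels[s]
  out <- data.frame(sample_id = s,
                    infiltrate = unname(infiltrate_labels),
                    `function` = unname(fl),
                    combined = paste(unname(infiltrate_labels), unname(fl),
                                     sep = "-"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  lev <- c("IIL-FL", "IIL-FH", "IIH-FL", "IIH-FH")
  attr(out, "class_counts") <-
    stats::setNames(as.integer(table(factor(out$combined, levels = lev))),
                    lev)
  out
}

#' Full two-level immune classification of a cohort
#'
#' Convenience wrapper running the infiltrate cut on cell-type scores, the
#' per-signature function labelling, and the 4-class combination.
#'
#' @param expr `ExpressionMatrix` (`log2norm`).
#' @param signatures `SignatureCollection` containing `cell_type` and
#'   `function` categories.
#' @param linkage,distance,row_zscore clustering options.
#' @param consensus function-integration rule, see
#'   [assign_function_labels()].
#' @return list with `classes` (the [combine_immune_class()] data.frame),
#'   `per_signature_function`, `cell_scores`, `infiltrate_cut`.
#' @export
classify_cohort <- function(expr, signatures, linkage = "ward",
                            distance = "euclidean", row_zscore = TRUE,
                            consensus = "majority") {
  cell_sigs <- filter_signatures(signatures, "cell_type")
  fun_sigs <- filter_signatures(signatures, "function")
  cell_scores <- marker_mean_scores(expr, cell_sigs)
  cut <- two_group_hierarchical_cut(cell_scores, linkage = linkage,
                                    distance = distance,
                                    row_zscore = row_zscore)
  infiltrate <- assign_infiltrate_class(cell_scores, cut)
  fun <- assign_function_labels(expr, fun_sigs, linkage = linkage,
                                distance = distance, consensus = consensus)
  classes <- combine_immune_class(infiltrate, fun$consensus)
  list(classes = classes, per_signature_function = fun$per_signature,
       cell_scores = cell_scores, infiltrate_cut = cut)
}
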