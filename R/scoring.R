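#' Score matrix container
#'
#' Signatures-by-samples matrix of per-sample scores, tagged with the method
#' that produced it.
#'
#' @param values numeric matrix, signatures in rows, samples in columns.
#' @param method `"marker_mean"` or `"ssgsea"`.
#' @return a `ScoreMatrix`.
#' @export
score_matrix <- function(values, method = c("marker_mean", "ssgsea")) {
  method <- match.arg(method)
  if (!is.matrix(values) || !is.numeric(values) || anyNA(values))
    stop_ic("'values' must be a numeric matrix without missing values")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_ic("signature and sample names are required")
  structure(list(values = values, method = method), class = "ScoreMatrix")
}

#' @export
print.ScoreMatrix <- function(x, ...) {
  cat(sprintf("ScoreMatrix: %d signatures x %d samples (method: %s)\n",
              nrow(x$values), ncol(x$values), x$method))
  invisible(x)
}

#' Housekeeping-gene normalisation of a count matrix
#'
#' Emulates panel-style housekeeping control normalisation: each sample's
#' scale factor is the geometric mean of its housekeeping-gene counts; counts
#' are rescaled so that every sample's factor equals the cohort mean factor,
#' then log2-transformed with a pseudocount:
#' \deqn{v \to \log_2(1 + v\, \bar s / s_j)}
#' where \eqn{s_j} is sample \eqn{j}'s factor and \eqn{\bar s} their
#' arithmetic mean. Multiplying a whole sample (housekeeping genes included)
#' by a constant leaves its normalised column unchanged. If a housekeeping
#' count is zero the factor falls back to the geometric mean of counts + 1,
#' with a warning. Housekeeping rows are retained in the output.
#'
#' @param expr an `ExpressionMatrix` with `scale = "counts"`.
#' @param housekeeping_genes character vector of housekeeping gene ids; at
#'   least one must be present in the matrix.
#' @return an `ExpressionMatrix` with `scale = "log2norm"`.
#' @export
normalize_housekeeping <- function(expr, housekeeping_genes) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "counts")
    stop_ic("normalize_housekeeping expects scale 'counts'")
  hk <- intersect(housekeeping_genes, gene_ids(expr))
  if (length(hk) == 0)
    stop_ic("no housekeeping gene found in matrix; requested: %s",
            paste(housekeeping_genes, collapse = ", "))
  hk_counts <- expr$values[hk, , drop = FALSE]
  if (any(hk_counts == 0)) {
    warn_ic("zero housekeeping count(s); using pseudocount in scale factors")
    sf <- apply(hk_counts + 1, 2, geomean)
  } else {
    sf <- apply(hk_counts, 2, geomean)
  }
  norm <- log2(1 + sweep(expr$values, 2, mean(sf) / sf, `*`))
  expression_matrix(norm, scale = "log2norm")
}

#' Marker-mean immune cell-type / functional scores
#'
#' The score of a signature in a sample is the arithmetic mean of the
#' log2-normalised expression of the signature's genes present in the matrix
#' (the published cell-score construction for panel data; median available
#' as an option). Signatures matching no genes are dropped with a warning.
#'
#' @param expr an `ExpressionMatrix` with `scale = "log2norm"`.
#' @param sigs a `SignatureCollection`.
#' @param summary `"mean"` (default) or `"median"`.
#' @return a `ScoreMatrix` (method `marker_mean`) with attribute
#'   `matched_genes`: named integer vector of per-signature matched counts.
#' @export
marker_mean_scores <- function(expr, sigs, summary = c("mean", "median")) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(sigs, "SignatureCollection"))
  summary <- match.arg(summary)
  if (length(sigs) == 0) stop_ic("empty signature collection")
  fun <- if (summary == "mean") colMeans else
    function(m) apply(m, 2, stats::median)
  rows <- list(); matched <- integer(0)
  for (s in sigs$signatures) {
    g <- intersect(s$genes, gene_ids(expr))
    if (length(g) == 0) {
      warn_ic("signature '%s' matches no genes; dropped", s$name)
      next
    }
    rows[[s$name]] <- fun(expr$values[g, , drop = FALSE])
    matched[s$name] <- length(g)
  }
  if (length(rows) == 0) stop_ic("no signature matched any gene")
  values <- do.call(rbind, rows)
  colnames(values) <- sample_ids(expr)
  out <- score_matrix(values, method = "marker_mean")
  attr(out, "matched_genes") <- matched
  out
}

#' Single-sample GSEA (ssGSEA) score of one gene set
#'
#' Per sample, genes are ranked by expression (average ranks for ties; the
#' highest-expressed gene has the largest rank). Walking down the ranked
#' list, the score is the sum over all positions of the difference between
#' the weighted in-set empirical CDF (steps proportional to rank^alpha) and
#' the unweighted out-of-set ECDF. With `alpha = 0` this reduces to the
#' classical unweighted KS running-sum integral. Used here as the
#' ESTIMATE-style immune score.
#'
#' @param expr an `ExpressionMatrix` (log2 scale recommended; the score is
#'   rank-based, so any strictly monotone per-sample transform gives the
#'   same result).
#' @param gene_set a `GeneSignature` whose genes form a non-empty strict
#'   subset of the matrix genes.
#' @param alpha rank-weighting exponent, default 0.25.
#' @return named numeric vector, one score per sample.
#' @export
ssgsea_scores <- function(expr, gene_set, alpha = 0.25) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(gene_set, "GeneSignature"))
  genes <- gene_ids(expr)
  in_set <- genes %in% gene_set$genes
  m <- sum(in_set)
  n_genes <- length(genes)
  if (m == 0) stop_ic("gene set shares no genes with the matrix")
  if (m == n_genes) stop_ic("gene set covers every matrix gene; score undefined")
  vapply(seq_len(ncol(expr$values)), function(j) {
    r <- rank(expr$values[, j], ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    inset_ord <- in_set[ord]
    w <- r[ord]^alpha
    w[!inset_ord] <- 0
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!inset_ord) / (n_genes - m)
    sum(p_in - p_out)
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(sample_ids(expr))
}

#' Export a ScoreMatrix as TSV
#'
#' Writes a header comment recording the method, then a signatures-by-samples
#' table.
#'
#' @param scores a `ScoreMatrix`.
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method: %s", scores$method), con)
  df <- data.frame(signature = rownames(scores$values), scores$values,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
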