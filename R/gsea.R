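# Weighted Kolmogorov-Smirnov enrichment score from hit positions in the
# ranked list. `w` are the per-gene weights in ranked order (descending
# statistic), `pos` the (sorted) positions of the set's genes. Returns the
# signed running-sum extremum. O(set size) after O(N) setup.
es_from_positions <- function(pos, w, n_genes) {
  m <- length(pos)
  w_hit <- w[pos]
  tot <- sum(w_hit)
  if (tot == 0) {           # degenerate weights: fall back to unweighted KS
    w_hit <- rep(1, m)
    tot <- m
  }
  p_in <- cumsum(w_hit) / tot
  denom_out <- n_genes - m
  # deviation right after each hit and right before each hit
  d_at <- p_in - (pos - seq_len(m)) / denom_out
  d_before <- c(0, p_in[-m]) - (pos - 1 - (seq_len(m) - 1)) / denom_out
  cand <- c(d_at, d_before)
  cand[which.max(abs(cand))]
}

#' Preranked gene set enrichment analysis
#'
#' Weighted KS enrichment score (gene weight = |ranking statistic|^1) over
#' the list ranked by the statistic, with a gene-label permutation null:
#' each permutation draws a random same-size gene set from the ranked list.
#' NES divides the ES by the mean |ES*| of same-sign permuted scores for
#' that set; the FDR q pools same-sign permuted NES across sets
#' (tail fraction of pooled permuted NES over tail fraction of observed
#' NES, capped at 1). Gene-label permutation is used because the cohort
#' class sizes this package targets are too small for phenotype
#' permutation.
#'
#' @param ranked_stats named numeric vector, one ranking statistic per gene
#'   (e.g. DE log2 fold change), no missing values.
#' @param hallmark_sets a `SignatureCollection`; sets are intersected with
#'   the ranked genes, minimum size 5 after intersection.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation draw.
#' @return data.frame: `set_name`, `size`, `es`, `nes`, `p`, `fdr_q`.
#' @export
preranked_gsea <- function(ranked_stats, hallmark_sets, n_perm = 1000,
                           seed = 1) {
  stopifnot(inherits(hallmark_sets, "SignatureCollection"))
  if (n_perm < 100) stop_ic("n_perm must be >= 100 (FDR undefined below)")
  if (anyNA(ranked_stats) || is.null(names(ranked_stats)))
    stop_ic("ranked_stats must be a complete named vector")
  ord <- order(ranked_stats, decreasing = TRUE)
  genes <- names(ranked_stats)[ord]
  w <- abs(ranked_stats)[ord]
  n_genes <- length(genes)
  gene_pos <- stats::setNames(seq_len(n_genes), genes)

  sets <- list()
  for (s in hallmark_sets$signatures) {
    g <- intersect(s$genes, genes)
    if (length(g) >= 5) sets[[s$name]] <- sort(unname(gene_pos[g]))
    else warn_ic("set '%s' has %d gene(s) in the ranking; dropped (min 5)",
                 s$name, length(g))
  }
  if (length(sets) == 0) stop_ic("no set of size >= 5 in the ranked list")

  es_obs <- vapply(sets, es_from_positions, numeric(1), w = w,
                   n_genes = n_genes)
  sizes <- lengths(sets)

  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  # one permutation matrix per distinct set size
  es_perm <- lapply(sizes, function(m) {
    vapply(seq_len(n_perm), function(i) {
      es_from_positions(sort(sample.int(n_genes, m)), w, n_genes)
    }, numeric(1))
  })

  nes <- numeric(length(sets)); pval <- numeric(length(sets))
  nes_perm <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    ep <- es_perm[[i]]
    pos_mean <- mean(ep[ep >= 0]); neg_mean <- mean(abs(ep[ep < 0]))
    norm_one <- function(e) {
      if (e >= 0) {
        if (is.finite(pos_mean) && pos_mean > 0) e / pos_mean else 0
      } else {
        if (is.finite(neg_mean) && neg_mean > 0) e / neg_mean else 0
      }
    }
    nes[i] <- norm_one(es_obs[i])
    nes_perm[[i]] <- vapply(ep, norm_one, numeric(1))
    same <- if (es_obs[i] >= 0) ep[ep >= 0] else ep[ep < 0]
    pval[i] <- if (length(same) == 0) 1 else
      (1 + sum(abs(same) >= abs(es_obs[i]))) / (1 + length(same))
  }

  pooled <- unlist(nes_perm)
  fdr_q <- vapply(seq_along(sets), function(i) {
    if (nes[i] >= 0) {
      num_den <- sum(pooled >= 0)
      num <- if (num_den == 0) 1 else sum(pooled >= nes[i]) / num_den
      obs_den <- sum(nes >= 0)
      den <- if (obs_den == 0) 1 else sum(nes >= nes[i]) / obs_den
    } else {
      num_den <- sum(pooled < 0)
      num <- if (num_den == 0) 1 else sum(pooled <= nes[i]) / num_den
      obs_den <- sum(nes < 0)
      den <- if (obs_den == 0) 1 else sum(nes <= nes[i]) / obs_den
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  data.frame(set_name = names(sets), size = as.integer(sizes), es = es_obs,
             nes = nes, p = pval, fdr_q = fdr_q, row.names = NULL,
             stringsAsFactors = FALSE)
}
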