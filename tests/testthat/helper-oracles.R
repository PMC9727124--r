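# Independent oracles used to validate the package's statistics. These are
# deliberately naive (enumeration, Newton iteration from scratch) and share
# no code with the implementations they check.

# Exact Fisher p for a 2 x K table by full enumeration of all tables with
# the observed margins; two-sided by the probability-mass rule.
enumerate_fisher_p <- function(tab) {
  tab <- as.matrix(tab)
  r1 <- sum(tab[1, ]); cs <- colSums(tab); n <- sum(tab)
  log_prob <- function(row1) {
    sum(lchoose(cs, row1)) - lchoose(n, r1)
  }
  k <- ncol(tab)
  # enumerate all non-negative integer row1 vectors with sum r1, row1 <= cs
  rows <- as.matrix(expand.grid(lapply(seq_len(k - 1),
                                       function(j) 0:min(cs[j], r1))))
  last <- r1 - rowSums(rows)
  ok <- last >= 0 & last <= cs[k]
  rows <- cbind(rows[ok, , drop = FALSE], last[ok])
  lp <- apply(rows, 1, log_prob)
  lp_obs <- log_prob(tab[1, ])
  sum(exp(lp[lp <= lp_obs + 1e-7]))
}

# Maximised logistic log-likelihood by plain Newton-Raphson.
newton_logistic_loglik <- function(X, y, tol = 1e-12, max_iter = 200) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    g <- t(X) %*% (y - mu)
    W <- mu * (1 - mu)
    H <- t(X) %*% (X * W)
    step <- solve(H + diag(1e-10, ncol(X)), g)
    beta <- beta + step
    if (sqrt(sum(g^2)) < tol) break
  }
  eta <- as.numeric(X %*% beta)
  sum(y * eta - log(1 + exp(eta)))
}

# Naive maximally selected log-rank statistic: recompute the Nelson-Aalen
# based scores and the standardised statistic for every dichotomisation by
# direct summation (no cumulative-sum machinery).
naive_maxstat <- function(x, time, event, bounds = c(0.1, 0.9)) {
  n <- length(x)
  # scores: delta_i - sum over event times <= t_i of d/n_at_risk
  a <- numeric(n)
  for (i in seq_len(n)) {
    ch <- 0
    for (t in sort(unique(time[event == 1]))) {
      if (t <= time[i]) ch <- ch + sum(time == t & event == 1) / sum(time >= t)
    }
    a[i] <- event[i] - ch
  }
  qb <- quantile(x, bounds, names = FALSE)
  u <- sort(unique(x)); u <- u[u >= qb[1] & u <= qb[2]]
  cuts <- (u[-length(u)] + u[-1]) / 2
  abar <- mean(a); ss <- sum((a - abar)^2)
  stats <- vapply(cuts, function(cc) {
    left <- x <= cc
    n1 <- sum(left)
    s <- sum(a[left])
    v <- n1 * (n - n1) / (n * (n - 1)) * ss
    abs(s - n1 * abar) / sqrt(v)
  }, numeric(1))
  list(cuts = cuts, stats = stats, max = max(stats),
       cut = cuts[which.max(stats)])
}

# Unweighted KS running-sum integral over a ranked list (oracle for the
# alpha = 0 single-sample score and for the zero-stat GSEA case).
running_sum_integral <- function(expr_values, in_set) {
  ord <- order(expr_values, decreasing = TRUE)
  hits <- in_set[ord]
  m <- sum(hits); n <- length(hits)
  run <- 0; total <- 0
  for (i in seq_len(n)) {
    run <- run + if (hits[i]) 1 / m else -1 / (n - m)
    total <- total + run
  }
  total
}

# Signed extremum of the weighted KS running sum, computed by a plain walk.
walk_es <- function(stat_named, set_genes, weighted = TRUE) {
  ord <- order(stat_named, decreasing = TRUE)
  g <- names(stat_named)[ord]
  w <- if (weighted) abs(stat_named)[ord] else rep(1, length(g))
  hits <- g %in% set_genes
  if (sum(w[hits]) == 0) w <- rep(1, length(g))
  pin <- 0; pout <- 0; best <- 0
  tot_in <- sum(w[hits]); n_out <- sum(!hits)
  for (i in seq_along(g)) {
    if (hits[i]) pin <- pin + w[i] / tot_in else pout <- pout + 1 / n_out
    if (abs(pin - pout) > abs(best)) best <- pin - pout
  }
  unname(best)
}

# small deterministic expression fixture
toy_expr <- function(n_genes = 20, n_samples = 6, seed = 1,
                     scale = "log2norm") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 5), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  if (scale == "counts") m <- matrix(rpois(n_genes * n_samples, 50),
                                     n_genes, n_samples,
                                     dimnames = dimnames(m))
  expression_matrix(m, scale)
}
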