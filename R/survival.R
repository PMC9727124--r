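#' L1-penalised Cox screening of expression features against PFS
#'
#' Cox proportional-hazards regression with a lasso penalty over a
#' log-spaced lambda path (from the smallest lambda that zeroes every
#' coefficient down two decades), with k-fold cross-validated partial-
#' likelihood deviance selecting the penalty. Fold assignment is seeded and
#' stratified by event status so no fold is event-free. Features are
#' standardised internally; coefficients are returned on the original
#' scale. Fitting is delegated to the coordinate-descent solver of
#' \pkg{glmnet} with Breslow handling of ties.
#'
#' @param X samples-by-features numeric matrix (column names = feature ids).
#' @param time positive follow-up times.
#' @param event 0/1 or logical event indicator; >= 2 events required.
#' @param n_folds folds for cross-validation, default 10.
#' @param lambda_grid optional decreasing positive lambda sequence;
#'   computed from the data when `NULL`.
#' @param seed integer seed for fold assignment.
#' @return a `CoxLassoFit`: `coefficients` (named, at the selected lambda;
#'   exact zeros outside `selected_genes`), `lambda_path`, `cv_error`
#'   (mean CV deviance per lambda), `selected_lambda`, `selected_genes`,
#'   and `glmnet_fit`, the underlying coefficient path object (coefficients
#'   at any lambda via `coef(fit$glmnet_fit, s = )`).
#' @export
fit_lasso_cox <- function(X, time, event, n_folds = 10, lambda_grid = NULL,
                          seed = 1) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop_ic("non-finite feature value")
  event <- as.numeric(event)
  if (sum(event) < 2) stop_ic("need >= 2 events")
  if (any(time <= 0)) stop_ic("times must be positive")
  y <- survival::Surv(time, event)
  # event-stratified fold assignment
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  foldid <- integer(nrow(X))
  for (grp in unique(event)) {
    idx <- which(event == grp)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  cv <- glmnet::cv.glmnet(X, y, family = "cox", foldid = foldid,
                          lambda = lambda_grid, nlambda = 100,
                          lambda.min.ratio = 0.01, standardize = TRUE,
                          thresh = 1e-10)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(beta) <- colnames(X)
  structure(list(coefficients = beta,
                 lambda_path = cv$lambda,
                 cv_error = stats::setNames(cv$cvm, cv$lambda),
                 selected_lambda = cv$lambda.min,
                 selected_genes = names(beta)[beta != 0],
                 glmnet_fit = cv$glmnet.fit),
            class = "CoxLassoFit")
}

#' @export
print.CoxLassoFit <- function(x, ...) {
  cat(sprintf("CoxLassoFit: lambda = %.4g, %d feature(s) selected: %s\n",
              x$selected_lambda, length(x$selected_genes),
              paste(x$selected_genes, collapse = ", ")))
  invisible(x)
}

# Log-rank scores (Nelson-Aalen residuals): a_i = event_i - cumulative
# hazard at the sample's follow-up time.
logrank_scores <- function(time, event) {
  n <- length(time)
  ord <- order(time)
  t_s <- time[ord]; e_s <- as.numeric(event)[ord]
  # at risk at each ordered time; tied times share the at-risk count of the
  # first member of the tie and the cumulative hazard of the last
  risk_at <- n - match(t_s, t_s) + 1
  cumhaz <- cumsum(e_s / risk_at)
  last_of_tie <- vapply(t_s, function(t) max(which(t_s == t)), numeric(1))
  cumhaz <- cumhaz[last_of_tie]
  a <- numeric(n)
  a[ord] <- e_s - cumhaz
  a
}

#' Maximally selected rank statistics cutpoint for survival
#'
#' Dichotomises a continuous feature into High/Low at the cutpoint
#' maximising the standardised two-group log-rank statistic. Candidate
#' cutpoints are midpoints between consecutive sorted unique feature values
#' within the given quantile bounds (avoiding degenerate extreme splits).
#' The statistic at a cutpoint is the linear rank statistic with log-rank
#' scores, standardised by its permutation mean and variance; inference is
#' by a seeded permutation test of the maximum (feature labels permuted
#' against survival), so no large-sample approximation is involved.
#'
#' @param feature named numeric vector (one value per sample).
#' @param time,event survival outcome, same order/names as `feature`.
#' @param quantile_bounds candidate-cutpoint range, default c(0.1, 0.9).
#' @param n_perm permutations for the p-value, default 10000.
#' @param seed integer seed.
#' @return a `CutpointResult`: `feature_name` (if available), `cutpoint`,
#'   `max_statistic`, `p`, `labels` (named "Low"/"High"; High means
#'   feature > cutpoint), `candidates` (data.frame of cutpoint,
#'   statistic).
#' @export
maxstat_cutpoint <- function(feature, time, event,
                             quantile_bounds = c(0.1, 0.9), n_perm = 10000,
                             seed = 1) {
  x <- as.numeric(feature)
  n <- length(x)
  stopifnot(length(time) == n, length(event) == n)
  if (sum(event) < 2) stop_ic("need >= 2 events")
  if (length(unique(x)) < 2) stop_ic("all feature values equal")
  qb <- stats::quantile(x, quantile_bounds, names = FALSE)
  u <- sort(unique(x))
  u_in <- u[u >= qb[1] & u <= qb[2]]
  if (length(u_in) < 2)
    stop_ic("fewer than 2 distinct feature values inside the quantile bounds")
  cut_cand <- (u_in[-length(u_in)] + u_in[-1]) / 2

  a <- logrank_scores(time, event)
  a_bar <- mean(a)
  ss <- sum((a - a_bar)^2)
  ordx <- order(x)
  x_sorted <- x[ordx]
  n_left <- vapply(cut_cand, function(cc) sum(x_sorted <= cc), numeric(1))

  stat_from <- function(a_ordered) {
    cs <- cumsum(a_ordered)
    s <- cs[n_left]
    e <- n_left * a_bar
    v <- n_left * (n - n_left) / (n * (n - 1)) * ss
    abs(s - e) / sqrt(v)
  }
  stats_obs <- stat_from(a[ordx])
  best <- which.max(stats_obs)            # ties -> lower cutpoint
  max_stat <- stats_obs[best]

  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (max(stat_from(sample(a))) >= max_stat) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (1 + n_perm)

  labels <- ifelse(x > cut_cand[best], "High", "Low")
  names(labels) <- names(feature)
  structure(list(feature_name = deparse(substitute(feature)),
                 cutpoint = cut_cand[best], max_statistic = max_stat,
                 p = p, labels = labels,
                 candidates = data.frame(cutpoint = cut_cand,
                                         statistic = stats_obs)),
            class = "CutpointResult")
}

#' @export
print.CutpointResult <- function(x, ...) {
  cat(sprintf(
    "CutpointResult: cutpoint = %.4g, max standardized statistic = %.3f, p = %.4g\n",
    x$cutpoint, x$max_statistic, x$p))
  invisible(x)
}

#' K-group log-rank test with Kaplan-Meier tables
#'
#' Log-rank chi-square across the immune classes (df = #groups - 1) and a
#' Kaplan-Meier step-function table per class. Classes without samples are
#' dropped with a warning.
#'
#' @param classes named class label vector.
#' @param time,event survival outcome in the same sample order as
#'   `classes`.
#' @return a `LogRankResult`: `groups`, `statistic`, `df`, `p`, `km`
#'   (data.frame: class, time, n_risk, n_event, survival).
#' @export
log_rank_test <- function(classes, time, event) {
  cl <- factor(as.character(classes))
  cl <- droplevels(cl)
  if (nlevels(cl) < 2) stop_ic("need >= 2 classes")
  if (sum(event) < 1) stop_ic("need >= 1 event")
  sd <- survival::survdiff(survival::Surv(time, as.numeric(event)) ~ cl)
  df <- nlevels(cl) - 1
  sf <- survival::survfit(survival::Surv(time, as.numeric(event)) ~ cl)
  strata <- rep(names(sf$strata), sf$strata)
  km <- data.frame(class = sub("^cl=", "", strata), time = sf$time,
                   n_risk = sf$n.risk, n_event = sf$n.event,
                   survival = sf$surv, row.names = NULL)
  structure(list(groups = levels(cl), statistic = unname(sd$chisq),
                 df = df,
                 p = stats::pchisq(unname(sd$chisq), df, lower.tail = FALSE),
                 km = km),
            class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat(sprintf("Log-rank test over %d groups: chi2 = %.3f, df = %d, p = %.4g\n",
              length(x$groups), x$statistic, x$df, x$p))
  invisible(x)
}
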