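test_that("BH step-up matches hand calculation and basic properties", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(numeric(0)), "empty")
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")

  # step-up adjustment is monotone on sorted input, dominates the raw
  # p-values, and is idempotent on vectors it has flattened completely
  set.seed(1)
  p <- sort(runif(50))
  adj <- benjamini_hochberg(p)
  expect_true(all(diff(adj) >= -1e-15))
  expect_true(all(adj >= p) && all(adj <= 1))
  flat <- benjamini_hochberg(rep(0.04, 10))
  expect_equal(benjamini_hochberg(flat), flat)
})

test_that("Kruskal-Wallis H matches the rank-formula oracle and permutation", {
  x <- c(1, 2, 3, 10, 11, 12)
  cl <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  v <- matrix(x, 1, dimnames = list("f", names(cl)))
  res <- kruskal_wallis_by_class(v, cl)
  # H by direct rank computation: no ties, R_A = 6, R_B = 15
  H_hand <- 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7
  expect_equal(res$statistic, H_hand)
  expect_equal(res$median_A, 2)

  # exact permutation distribution of H over all 20 assignments
  combos <- combn(6, 3)
  H_all <- apply(combos, 2, function(idx) {
    g <- factor(seq_len(6) %in% idx)
    kruskal.test(x, g)$statistic
  })
  p_exact <- mean(H_all >= H_hand - 1e-12)
  expect_equal(p_exact, 0.1)
  # chi-square approximation is close to exact at these depths, not equal
  expect_lt(abs(res$p - p_exact), 0.06)
})

test_that("Kruskal-Wallis handles degenerate and relabelled input", {
  cl <- setNames(rep(c("A", "B", "C"), each = 4), paste0("s", 1:12))
  v <- matrix(5, 1, 12, dimnames = list("flat", names(cl)))
  res <- kruskal_wallis_by_class(v, cl)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  set.seed(2)
  v2 <- matrix(rnorm(12), 1, dimnames = list("f", names(cl)))
  r1 <- kruskal_wallis_by_class(v2, cl)
  relab <- setNames(c(A = "Z", B = "Y", C = "X")[cl], names(cl))
  r2 <- kruskal_wallis_by_class(v2, relab)
  expect_equal(r2$statistic, r1$statistic)

  cl_extra <- c(cl, extra = "D")
  expect_warning(kruskal_wallis_by_class(v2, cl_extra), "D")
  expect_error(kruskal_wallis_by_class(v2, setNames(rep("A", 12), names(cl))),
               "2 classes")
})

test_that("exact-permutation p matches the chi-square approximation closely at n=6 per group", {
  set.seed(42)
  for (rep_i in 1:3) {
    x <- sample(1:8, 12, replace = TRUE)   # ties on purpose
    cl <- setNames(rep(c("A", "B"), each = 6), paste0("s", 1:12))
    v <- matrix(x, 1, dimnames = list("f", names(cl)))
    res <- kruskal_wallis_by_class(v, cl)
    combos <- combn(12, 6)
    H_all <- apply(combos, 2, function(idx) {
      g <- factor(seq_len(12) %in% idx)
      suppressWarnings(kruskal.test(x, g)$statistic)
    })
    p_exact <- mean(H_all >= res$statistic - 1e-12)
    expect_lt(abs(res$p - p_exact), 0.1)
  }
})

test_that("differential expression honours trivial contracts", {
  set.seed(3)
  m <- matrix(rnorm(40 * 10, 5), 40, 10,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:10)))
  m[1, ] <- 7                                  # identical in both groups
  ex <- expression_matrix(m, "log2norm")
  A <- sprintf("s%02d", 1:5); B <- sprintf("s%02d", 6:10)
  de <- differential_expression(ex, A, B)
  expect_equal(de$log2fc[de$gene == "g01"], 0)
  expect_equal(de$p[de$gene == "g01"], 1)

  # swapping groups negates fold changes and preserves p-values
  de_sw <- differential_expression(ex, B, A)
  expect_equal(de_sw$log2fc, -de$log2fc)
  expect_equal(de_sw$p, de$p)

  expect_error(differential_expression(ex, A, c(B, "s01")), "overlap")
  expect_error(differential_expression(ex, A[1], B), ">= 2")
})

test_that("significance requires both the FDR and fold-change thresholds", {
  set.seed(4)
  m <- matrix(rnorm(30 * 20, 5, 0.2), 30, 20,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:20)))
  m[1, 11:20] <- m[1, 11:20] + 3     # big shift -> significant
  m[2, 11:20] <- m[2, 11:20] + 0.5   # clear but small shift -> not significant
  ex <- expression_matrix(m, "log2norm")
  de <- differential_expression(ex, sprintf("s%02d", 1:10),
                                sprintf("s%02d", 11:20))
  expect_true(de$significant[de$gene == "g01"])
  expect_false(de$significant[de$gene == "g02"])
  expect_true(de$p_adj[de$gene == "g02"] < 0.05)  # fails only the lfc gate
  expect_true(all(de$p_adj >= de$p - 1e-15))
})

test_that("hypergeometric ORA matches closed forms", {
  universe <- sprintf("u%02d", 1:20)
  hits <- universe[1:5]
  sets <- signature_collection(list(
    gene_signature("perfect", "pathway", universe[1:5]),
    gene_signature("disjoint_small", "pathway", universe[10:12])))
  res <- hypergeometric_ora(hits, universe, sets)
  expect_equal(res$p[res$set_name == "perfect"], 1 / choose(20, 5))
  expect_equal(res$overlap_k[res$set_name == "perfect"], 5L)
  # overlap 0: P(X >= 0) = 1
  expect_equal(res$p[res$set_name == "disjoint_small"], 1)

  off <- signature_collection(list(
    gene_signature("in", "pathway", universe[1:3]),
    gene_signature("out", "pathway", c("zz1", "zz2"))))
  expect_warning(res2 <- hypergeometric_ora(hits, universe, off), "out")
  expect_equal(nrow(res2), 1L)
  expect_error(hypergeometric_ora(c(hits, "alien"), universe, sets),
               "outside")
})

test_that("Fisher's exact test equals full fixed-margin enumeration", {
  t22 <- matrix(c(8, 4, 4, 29), 2, byrow = TRUE)
  expect_equal(fisher_exact_association(t22), enumerate_fisher_p(t22),
               tolerance = 1e-9)
  expect_equal(fisher_exact_association(matrix(1, 2, 2)), 1)
  t23 <- matrix(c(3, 2, 1, 1, 2, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact_association(t23), enumerate_fisher_p(t23),
               tolerance = 1e-9)
  expect_error(fisher_exact_association(matrix(c(0, 0, 3, 4), 2,
                                               byrow = TRUE)), "margin")
  expect_error(fisher_exact_association(matrix(c(1.5, 1, 1, 1), 2)),
               "integer")
})

test_that("Fisher enumeration agreement holds across random small tables", {
  set.seed(10)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    repeat {
      tab <- matrix(rpois(2 * k, 2.5), 2, k)
      if (sum(tab) <= 30 && all(rowSums(tab) > 0) && all(colSums(tab) > 0))
        break
    }
    expect_equal(fisher_exact_association(tab), enumerate_fisher_p(tab),
                 tolerance = 1e-8, label = paste("table", i))
  }
})

test_that("logistic LRT reproduces an independent Newton fit", {
  y <- c(0, 0, 1, 0, 1, 1)
  cps <- c(0, 1, 2, 3, 4, 4)
  cl <- rep(c("other", "IIH-FH"), 3)
  names(y) <- names(cps) <- names(cl) <- paste0("p", 1:6)
  mc <- suppressWarnings(logistic_lrt_comparison(y, cps, cl))
  ll0 <- newton_logistic_loglik(matrix(cps, ncol = 1), y)
  X1 <- cbind(cps, as.numeric(cl == "other"))
  ll1 <- newton_logistic_loglik(X1, y)
  expect_equal(mc$loglik_null, ll0, tolerance = 1e-6)
  expect_equal(mc$loglik_full, ll1, tolerance = 1e-6)
  expect_equal(mc$lr_statistic, 2 * (ll1 - ll0), tolerance = 1e-6)
  expect_equal(mc$df, 1L)
  expect_true(mc$lr_statistic >= 0)
})

test_that("degenerate model comparisons collapse to the null", {
  y <- setNames(c(0, 1, 0, 1), paste0("p", 1:4))
  cps <- setNames(c(1, 2, 3, 4), names(y))
  single <- setNames(rep("IIH-FH", 4), names(y))
  expect_warning(mc <- logistic_lrt_comparison(y, cps, single), "single")
  expect_equal(mc$lr_statistic, 0)
  expect_equal(mc$p, 1)
  all_resp <- setNames(rep(1, 4), names(y))
  expect_error(logistic_lrt_comparison(all_resp, cps,
                                       setNames(rep(c("a", "b"), 2),
                                                names(y))),
               "non-responder")
})

test_that("preranked GSEA scores extremal sets highest and is deterministic", {
  set.seed(6)
  stats_v <- setNames(sort(rnorm(60), decreasing = TRUE), paste0("g", 1:60))
  top <- gene_signature("top", "hallmark", paste0("g", 1:8))
  rand_sets <- lapply(1:10, function(i)
    gene_signature(paste0("r", i), "hallmark",
                   paste0("g", sample(60, 8))))
  col <- signature_collection(c(list(top), rand_sets))
  res <- preranked_gsea(stats_v, col, n_perm = 200, seed = 3)
  expect_gt(res$es[res$set_name == "top"], 0)
  expect_equal(which.max(res$es), which(res$set_name == "top"))

  res2 <- preranked_gsea(stats_v, col, n_perm = 200, seed = 3)
  expect_identical(res, res2)
  expect_error(preranked_gsea(stats_v, col, n_perm = 50), "100")
})

test_that("GSEA ES matches the running-sum oracle, including the zero-stat case", {
  set.seed(7)
  stats_v <- setNames(rnorm(30), paste0("g", 1:30))
  set <- gene_signature("s", "hallmark", paste0("g", c(1, 5, 9, 14, 22)))
  res <- preranked_gsea(stats_v, signature_collection(list(set)),
                        n_perm = 100, seed = 1)
  expect_equal(res$es, walk_es(stats_v, set$genes, weighted = TRUE),
               tolerance = 1e-12)

  # all-zero metric: weights degenerate to the unweighted KS statistic
  zero <- setNames(rep(0, 10), paste0("z", 1:10))
  zset <- gene_signature("z", "hallmark", paste0("z", c(1, 3, 5, 7, 9)))
  rz <- preranked_gsea(zero, signature_collection(list(zset)),
                       n_perm = 100, seed = 1)
  expect_equal(rz$es, walk_es(zero, zset$genes, weighted = FALSE),
               tolerance = 1e-12)
})

test_that("GSEA enrichment scores agree with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(8)
  stats_v <- setNames(rnorm(100), paste0("g", 1:100))
  sets <- lapply(1:5, function(i)
    gene_signature(paste0("s", i), "hallmark", paste0("g", sample(100, 12))))
  res <- preranked_gsea(stats_v, signature_collection(sets),
                        n_perm = 100, seed = 1)
  for (i in 1:5) {
    es_ref <- fgsea::calcGseaStat(sort(stats_v, decreasing = TRUE),
                                  selectedStats = which(
                                    names(sort(stats_v, decreasing = TRUE))
                                    %in% sets[[i]]$genes),
                                  gseaParam = 1)
    expect_equal(res$es[res$set_name == paste0("s", i)], es_ref,
                 tolerance = 1e-6)
  }
})
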