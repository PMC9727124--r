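hk <- c("HK1", "HK2")

make_counts <- function(values) {
  expression_matrix(values, "counts")
}

test_that("housekeeping normalisation is symmetric and scale-invariant", {
  m <- matrix(c(10, 20, 100, 50), 4, 1,
              dimnames = list(c("HK1", "HK2", "G1", "G2"), "A"))
  m2 <- cbind(A = m[, 1], B = m[, 1], C = m[, 1])
  rownames(m2) <- rownames(m)
  norm <- normalize_housekeeping(make_counts(m2), hk)
  # identical columns stay identical
  expect_equal(norm$values[, "A"], norm$values[, "B"])
  expect_equal(norm$values[, "A"], norm$values[, "C"])

  # single sample: output is log2(v + 1)
  single <- normalize_housekeeping(make_counts(m), hk)
  expect_equal(unname(single$values[, 1]), unname(log2(m[, 1] + 1)))

  # doubling a whole sample (housekeeping included) changes nothing
  m3 <- cbind(A = m[, 1], B = 2 * m[, 1])
  rownames(m3) <- rownames(m)
  norm3 <- normalize_housekeeping(make_counts(m3), hk)
  expect_equal(unname(norm3$values[, "A"]), unname(norm3$values[, "B"]),
               tolerance = 1e-9)
  expect_identical(norm3$scale, "log2norm")
  expect_true(all(c("HK1", "HK2") %in% gene_ids(norm3)))
})

test_that("housekeeping normalisation rejects bad input", {
  ex <- toy_expr(5, 3, scale = "counts")
  expect_error(normalize_housekeeping(ex, c("NOPE1", "NOPE2")), "NOPE1")
  exl <- toy_expr(5, 3)
  expect_error(normalize_housekeeping(exl, hk), "counts")
})

test_that("marker-mean scores reduce to single rows and plain means", {
  m <- matrix(c(2, 4, 1, 7), 2, 2,
              dimnames = list(c("G1", "G2"), c("A", "B")))
  ex <- expression_matrix(m, "log2norm")
  one <- signature_collection(list(gene_signature("solo", "cell_type", "G1")))
  sc <- marker_mean_scores(ex, one)
  expect_equal(unname(sc$values["solo", ]), unname(m["G1", ]))
  both <- signature_collection(list(gene_signature("all", "cell_type",
                                                   c("G1", "G2"))))
  sc2 <- marker_mean_scores(ex, both)
  expect_equal(unname(sc2$values["all", "A"]), 3)
  expect_identical(attr(sc2, "matched_genes")[["all"]], 2L)
})

test_that("marker-mean scores are linear in a constant expression shift", {
  ex <- toy_expr(30, 5, seed = 11)
  sigs <- signature_collection(list(
    gene_signature("s1", "cell_type", sprintf("G%03d", 1:7)),
    gene_signature("s2", "cell_type", sprintf("G%03d", 10:20))))
  base <- marker_mean_scores(ex, sigs)
  for (c0 in c(-1.5, 0.3, 2)) {
    shifted <- expression_matrix(ex$values + c0, "log2norm")
    expect_equal(marker_mean_scores(shifted, sigs)$values,
                 base$values + c0, tolerance = 1e-12)
  }
  # order invariance
  perm <- expression_matrix(ex$values[sample(30), sample(5)], "log2norm")
  sc_perm <- marker_mean_scores(perm, sigs)
  expect_equal(sc_perm$values[, colnames(base$values)], base$values)
})

test_that("unmatched signatures are dropped with a warning; empty sets error", {
  ex <- toy_expr(10, 3)
  sigs <- signature_collection(list(
    gene_signature("ok", "cell_type", "G001"),
    gene_signature("ghost", "cell_type", "ZZZ")))
  expect_warning(sc <- marker_mean_scores(ex, sigs), "ghost")
  expect_equal(rownames(sc$values), "ok")
  expect_error(marker_mean_scores(ex, signature_collection(list())), "empty")
})

test_that("ssGSEA ranks monotonically and ignores gene order", {
  ex <- toy_expr(20, 4, seed = 5)
  top <- rownames(ex$values)[which.max(ex$values[, 1])]
  bottom <- rownames(ex$values)[which.min(ex$values[, 1])]
  s_top <- ssgsea_scores(ex, gene_signature("t", "immune_estimate", top))
  s_bot <- ssgsea_scores(ex, gene_signature("b", "immune_estimate", bottom))
  expect_gt(s_top[1], s_bot[1])

  set <- gene_signature("s", "immune_estimate", sprintf("G%03d", c(2, 7, 13)))
  base <- ssgsea_scores(ex, set)
  shuf <- expression_matrix(ex$values[sample(20), ], "log2norm")
  expect_equal(ssgsea_scores(shuf, set), base)
})

test_that("ssGSEA with alpha = 0 equals the unweighted KS running-sum integral", {
  m <- matrix(c(5, 3, 9, 1, 7), 5, 1,
              dimnames = list(paste0("g", 1:5), "S1"))
  ex <- expression_matrix(m, "log2norm")
  set <- gene_signature("s", "immune_estimate", c("g1", "g3"))
  got <- ssgsea_scores(ex, set, alpha = 0)
  want <- running_sum_integral(m[, 1], rownames(m) %in% c("g1", "g3"))
  expect_equal(unname(got), want)
})

test_that("ssGSEA is invariant to strictly monotone transforms", {
  ex <- toy_expr(25, 3, seed = 9)
  set <- gene_signature("s", "immune_estimate", sprintf("G%03d", c(1, 4, 9)))
  base <- ssgsea_scores(ex, set)
  mono <- expression_matrix(exp(ex$values / 3) + 2, "log2norm")
  expect_equal(ssgsea_scores(mono, set), base)
})

test_that("ssGSEA refuses degenerate gene sets", {
  ex <- toy_expr(5, 2)
  expect_error(ssgsea_scores(ex, gene_signature("none", "immune_estimate",
                                                "ZZZ")), "no genes")
  all_set <- gene_signature("all", "immune_estimate", gene_ids(ex))
  expect_error(ssgsea_scores(ex, all_set), "every")
})
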