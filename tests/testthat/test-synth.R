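test_that("cohorts are bit-identical under a fixed seed and differ otherwise", {
  sp <- cohort_spec(n_samples = 20, n_genes = 300, seed = 5)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth, b$truth)
  sp2 <- sp; sp2$seed <- 6
  expect_false(identical(generate_cohort(sp2)$expr$values, a$expr$values))
})

test_that("spec invariants are enforced", {
  expect_error(cohort_spec(class_proportions = c(0.5, 0.5, 0.2, 0)), "sum")
  expect_error(cohort_spec(noise_sd = 0), "noise_sd")
  expect_error(cohort_spec(cdh1_effect = 1), "cdh1")
  expect_error(cohort_spec(censoring_rate = 1), "censoring")
  expect_error(generate_cohort(cohort_spec(n_samples = 4)), "8")
  expect_error(generate_cohort(cohort_spec(n_genes = 150)), "200")
})

test_that("a null cohort carries no recoverable class structure", {
  aris <- vapply(1:20, function(s) {
    sp <- cohort_spec(n_samples = 30, n_genes = 300,
                      infiltrate_effect = 0, function_effect = 0,
                      checkpoint_effect = 0, cdh1_effect = 0,
                      il18_effect = 0, seed = 500 + s)
    co <- generate_cohort(sp)
    cls <- classify_cohort(co$expr, co$signatures)
    truth <- setNames(co$truth$combined, co$truth$sample_id)
    pred <- setNames(cls$classes$combined, cls$classes$sample_id)
    adjusted_rand_index(truth[names(pred)], pred)
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.15)
})

test_that("default effects give essentially perfect class recovery", {
  sp <- cohort_spec(seed = 11)
  co <- generate_cohort(sp)
  cls <- classify_cohort(co$expr, co$signatures)
  truth <- setNames(co$truth$combined, co$truth$sample_id)
  pred <- setNames(cls$classes$combined, cls$classes$sample_id)
  expect_gte(adjusted_rand_index(truth[names(pred)], pred), 0.9)
})

test_that("stronger infiltrate effects never hurt infiltrate recovery", {
  effects <- c(0.5, 1, 2, 3)
  mean_ari <- vapply(effects, function(e) {
    mean(vapply(1:10, function(s) {
      sp <- cohort_spec(n_samples = 30, n_genes = 300,
                        infiltrate_effect = e, seed = 900 + s)
      co <- generate_cohort(sp)
      cls <- classify_cohort(co$expr, co$signatures)
      truth <- setNames(co$truth$infiltrate, co$truth$sample_id)
      pred <- setNames(cls$classes$infiltrate, cls$classes$sample_id)
      adjusted_rand_index(truth[names(pred)], pred)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ari) >= -0.05))
  expect_gt(mean_ari[length(effects)], 0.95)
})

test_that("unplanted genes are class-independent and censoring is calibrated", {
  sp <- cohort_spec(n_samples = 200, n_genes = 500, seed = 21)
  co <- generate_cohort(sp)
  filler <- grep("^GENE", rownames(co$expr$values), value = TRUE)
  iih <- co$truth$sample_id[co$truth$infiltrate == "IIH"]
  iil <- co$truth$sample_id[co$truth$infiltrate == "IIL"]
  pvals <- apply(co$expr$values[filler, ], 1, function(v)
    t.test(v[iih], v[iil])$p.value)
  expect_lt(mean(benjamini_hochberg(pvals) < 0.05), 0.05)
  # realised censoring within +-0.05 of the target at n = 200
  expect_lt(abs(mean(1 - co$annotations$pfs_event) - sp$censoring_rate),
            0.05)
})

test_that("planted group contrasts point the documented directions", {
  sp <- cohort_spec(seed = 31)
  co <- generate_cohort(sp)
  v <- co$expr$values
  iihfh <- co$truth$sample_id[co$truth$combined == "IIH-FH"]
  iilfl <- co$truth$sample_id[co$truth$combined == "IIL-FL"]
  for (g in c("PDCD1", "CD274", "LAG3", "TIGIT", "TGFB1"))
    expect_gt(mean(v[g, iihfh]) - mean(v[g, iilfl]), 0)
  expect_lt(mean(v["CDH1", iihfh]) - mean(v["CDH1", iilfl]), 0)
  fh <- co$truth$sample_id[co$truth$`function` == "FH"]
  fl <- co$truth$sample_id[co$truth$`function` == "FL"]
  il18 <- setNames(co$annotations$il18, co$annotations$sample_id)
  expect_gt(mean(il18[fh]), mean(il18[fl]))
  expect_true(all(co$annotations$cps %in% 0:4))   # CPS < 5 cohort by design
})

test_that("counts mode produces valid counts that normalise back to log2 space", {
  sp <- cohort_spec(n_samples = 20, n_genes = 300, seed = 41)
  co <- generate_cohort(sp, mode = "counts")
  expect_identical(co$expr$scale, "counts")
  expect_true(all(co$expr$values >= 0))
  expect_true(all(co$expr$values == round(co$expr$values)))
  norm <- normalize_housekeeping(co$expr, co$housekeeping)
  ref <- generate_cohort(sp)$expr$values
  expect_gt(cor(as.vector(norm$values), as.vector(ref)), 0.9)
})

test_that("the external cohort has three classes and both response levels", {
  sp <- cohort_spec(seed = 51)
  co <- generate_external_cohort(sp)
  expect_equal(nrow(co$annotations), 45L)
  expect_setequal(unique(co$truth$combined),
                  c("IIL-FL", "IIH-FL", "IIH-FH"))
  expect_true(all(c("responder", "non_responder") %in%
                    co$annotations$response))
})

test_that("Fisher p-values are uniform under a class-free response model", {
  # balanced response margins keep the exact test's support fine enough for
  # a distributional check; sparse margins make exact p discrete by design
  n <- 500
  fp <- numeric(n)
  for (i in 1:n) {
    sp <- cohort_spec(seed = 40000 + i, n_genes = 200,
                      response_model = c(0, 0.3, 0))
    co <- suppressWarnings(generate_external_cohort(sp))
    cl <- setNames(co$truth$combined, co$truth$sample_id)
    tab <- table(co$annotations$response, cl[co$annotations$sample_id])
    fp[i] <- fisher_exact_association(as.matrix(tab))
  }
  ks <- suppressWarnings(ks.test(fp, "punif")$statistic)
  expect_lt(ks, 0.08)
})

test_that("the class effect is detectable by the LRT at the default effect size", {
  rej <- vapply(1:200, function(i) {
    sp <- cohort_spec(seed = 60000 + i, n_genes = 200)
    co <- suppressWarnings(generate_external_cohort(sp))
    ann <- co$annotations
    cl <- setNames(co$truth$combined, co$truth$sample_id)
    resp <- setNames(as.numeric(ann$response == "responder"), ann$sample_id)
    mc <- suppressWarnings(
      logistic_lrt_comparison(resp, setNames(ann$cps, ann$sample_id), cl))
    mc$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})
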