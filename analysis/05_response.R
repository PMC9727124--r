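#!/usr/bin/env Rscript
# Step 5 — does the immune class add response prediction beyond CPS?
#
# The external CPI-exposed cohort is classified with the same pipeline;
# class membership is tested against response (Fisher's exact test) and the
# nested logistic models CPS vs CPS + class are compared by likelihood
# ratio. All patients have CPS < 5, the stratum where PD-L1 alone is least
# informative.

suppressPackageStartupMessages(library(immunoclass))

expr <- read_expression_table("results/external_cohort/expression.tsv",
                              "log2norm")
sigs <- read_gmt_by_category("results/external_cohort/signatures.gmt")
ann <- read_sample_annotations("results/external_cohort/annotations.tsv")

cls <- classify_cohort(expr, sigs)
cl <- setNames(cls$classes$combined, cls$classes$sample_id)
cat("External-cohort class counts:\n")
print(attr(cls$classes, "class_counts"))

tab <- table(ann$response, cl[ann$sample_id])
print(tab)
fp <- fisher_exact_association(as.matrix(tab))
cat(sprintf("\nFisher's exact test, response x class: p = %.4g\n", fp))

ri <- ann$response == "responder"
cat(sprintf("Responders in IIH-FH: %d of %d (%.0f%%)\n",
            sum(cl[ann$sample_id[ri]] == "IIH-FH"), sum(ri),
            100 * mean(cl[ann$sample_id[ri]] == "IIH-FH")))

resp <- setNames(as.numeric(ann$response == "responder"), ann$sample_id)
mc <- logistic_lrt_comparison(resp, setNames(ann$cps, ann$sample_id), cl)
print(mc)
cat(sprintf("Adding the immune class to CPS %s the model fit (LRT p = %.4g).\n",
            if (mc$p < 0.05) "significantly improves" else
              "does not significantly improve", mc$p))

out <- data.frame(quantity = c("fisher_p", "lrt_p", "lr_statistic", "df"),
                  value = c(fp, mc$p, mc$lr_statistic, mc$df))
write.table(out, "results/response_association.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
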