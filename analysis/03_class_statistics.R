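#!/usr/bin/env Rscript
# Step 3 — cross-class statistics on the discovery cohort.
#
# Checkpoint / immunomodulatory genes across the four classes
# (Kruskal-Wallis, BH within the panel), rank-based differential expression
# for the IIH-FH vs IIL-FL contrast at padj < 0.05 and |log2FC| > 1,
# hypergeometric over-representation of the significant genes, and
# preranked GSEA of the hallmark-style sets.

suppressPackageStartupMessages(library(immunoclass))

expr <- read_expression_table("results/discovery_cohort/expression.tsv",
                              "log2norm")
sigs <- read_gmt_by_category("results/discovery_cohort/signatures.gmt")
classes <- read.delim("results/classes.tsv", check.names = FALSE)
cl <- setNames(classes$combined, classes$sample_id)

ck <- intersect(c(checkpoint_genes(), "CDH1"), gene_ids(expr))
kw <- kruskal_wallis_by_class(expr$values[ck, ], cl)
write.table(kw, "results/checkpoint_kruskal_wallis.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Checkpoint genes with BH-adjusted Kruskal-Wallis p < 0.05:",
    sum(kw$p_adj < 0.05), "of", nrow(kw), "\n")
cdh1 <- kw[kw$feature == "CDH1", ]
cat(sprintf("CDH1: median %.2f in IIH-FH vs %.2f in IIL-FL (padj = %.3g)\n",
            cdh1$`median_IIH-FH`, cdh1$`median_IIL-FL`, cdh1$p_adj))

gA <- classes$sample_id[classes$combined == "IIL-FL"]
gB <- classes$sample_id[classes$combined == "IIH-FH"]
de <- differential_expression(expr, gA, gB)
write.table(de, "results/de_iihfh_vs_iilfl.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\nDE (method-substituted rank test), IIH-FH vs IIL-FL: %d of %d genes significant\n",
            sum(de$significant), nrow(de)))

hits <- de$gene[de$significant]
test_sets <- signature_collection(c(
  filter_signatures(sigs, "hallmark")$signatures,
  filter_signatures(sigs, "function")$signatures))
ora <- hypergeometric_ora(hits, de$gene, test_sets)
write.table(ora, "results/ora.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("ORA sets with BH q < 0.05:",
    paste(ora$set_name[ora$fdr_q < 0.05], collapse = ", "), "\n")

gsea <- preranked_gsea(setNames(de$log2fc, de$gene),
                       filter_signatures(sigs, "hallmark"),
                       n_perm = 1000, seed = 20222)
write.table(gsea, "results/gsea_hallmark.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
up <- gsea[gsea$nes > 0 & gsea$fdr_q < 0.25, "set_name"]
cat("Hallmark-style sets enriched in IIH-FH at FDR < 25%:",
    paste(up, collapse = ", "), "\n")
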