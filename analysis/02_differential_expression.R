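#!/usr/bin/env Rscript
# Stage 2: paired differential-expression calling and QC summaries.
#
# Applies the triple filter (fold change >= 2 or <= 0.5, paired-t p < 0.05,
# BH FDR < 0.05) separately within the lncRNA and mRNA probe families, then
# selects the top up- and down-regulated lncRNAs by |log2 FC| and exports
# the volcano/PCA/dendrogram tables behind the usual overview figures.

suppressPackageStartupMessages(library(lncscape))

em <- read_expression_matrix("results/dataset/expression.tsv",
                             "results/dataset/pairing.tsv")
em <- attach_annotation(em, read_annotation("results/dataset/annotation.bed"))

de <- call_differential(em, verbose = TRUE)
de_lnc <- de[de$biotype == "lncRNA", ]
top <- rbind(suppressWarnings(select_top_k(de_lnc, 200, "up")),
             suppressWarnings(select_top_k(de_lnc, 200, "down")))

dir.create("results", showWarnings = FALSE)
write.table(de, "results/differential.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(top, "results/selected_lncRNAs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

qc <- qc_summary(em)
write.table(qc$volcano, "results/volcano.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(qc$pca, "results/pca.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(qc$newick, "results/sample_dendrogram.nwk")

for (fam in c("lncRNA", "mRNA")) {
  sub <- de[de$biotype == fam, ]
  cat(sprintf("%s: %d significant (%d up, %d down) of %d probes\n", fam,
              sum(sub$significant), sum(sub$direction == "up"),
              sum(sub$direction == "down"), nrow(sub)))
}
cat(sprintf("selected %d lncRNAs for target prediction\n", nrow(top)))
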