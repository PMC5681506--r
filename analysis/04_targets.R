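#!/usr/bin/env Rscript
# Stage 4: cis and trans target prediction.
#
# cis: co-expressed genes within 300 kb (inclusive) of their lncRNA on the
# same chromosome. trans: per-lncRNA hypergeometric overlap of the
# co-expressed gene set with each TF target set, BH-corrected across TFs,
# summarized as the TF frequency table.

suppressPackageStartupMessages(library(lncscape))

em <- read_expression_matrix("results/dataset/expression.tsv",
                             "results/dataset/pairing.tsv")
em <- attach_annotation(em, read_annotation("results/dataset/annotation.bed"))
anno <- read_annotation("results/dataset/annotation.bed")
edges <- read.delim("results/coexpression_edges.tsv")
tf_sets <- read_gmt("results/dataset/tf_sets.gmt")

cis <- cis_assign(edges, anno)
write.table(cis, "results/cis_assignments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("cis: %d assignments for %d lncRNAs (%d edges skipped unannotated)\n",
            nrow(cis), length(unique(cis$lnc_id)),
            attr(cis, "n_skipped")))

universe <- intersect(na.omit(em$gene_symbol),
                      unique(unlist(tf_sets$sets)))
lncs <- unique(edges$lnc_id)
trans_list <- setNames(lapply(lncs, function(l) {
  trans_enrich(l, edges, tf_sets, universe)
}), lncs)
trans <- do.call(rbind, lapply(names(trans_list), function(l) {
  cbind(lnc_id = l, trans_list[[l]], stringsAsFactors = FALSE)
}))
write.table(trans, "results/trans_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

freq <- tf_frequency(trans_list)
write.table(freq, "results/tf_frequency.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("trans: %d TFs significantly enriched for >= 1 lncRNA (universe %d genes)\n",
            nrow(freq), length(universe)))
print(head(freq, 10))
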