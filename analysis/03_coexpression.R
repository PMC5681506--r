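#!/usr/bin/env Rscript
# Stage 3: lncRNA-mRNA co-expression edges for the selected lncRNAs.
#
# Pearson correlation over all 12 pooled arrays; an edge needs |r| > 0.7
# and p < 0.05 (both signs kept, so inverse regulation is visible). Also
# prints the top-30 target table of the most-downregulated lncRNA, the
# package's analog of a per-lncRNA target listing.

suppressPackageStartupMessages(library(lncscape))

em <- read_expression_matrix("results/dataset/expression.tsv",
                             "results/dataset/pairing.tsv")
em <- attach_annotation(em, read_annotation("results/dataset/annotation.bed"))
top <- read.delim("results/selected_lncRNAs.tsv")

edges <- build_edges(em, lnc_ids = top$probe_id)
write.table(edges, "results/coexpression_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d edges (%d positive, %d negative) for %d lncRNAs\n",
            nrow(edges), sum(edges$sign == "pos"),
            sum(edges$sign == "neg"), length(unique(edges$lnc_id))))

most_down <- top$probe_id[order(top$log2_fc)][1]
tt <- suppressWarnings(target_table(most_down, edges, k = 30))
write.table(tt, "results/top_target_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("top target table for %s (most downregulated): %d rows\n",
            most_down, nrow(tt)))
print(head(tt, 5))
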