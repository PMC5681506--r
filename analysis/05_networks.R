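#!/usr/bin/env Rscript
# Stage 5: two- and three-element regulatory networks.
#
# For the most frequently enriched TF: the TF->lncRNA star (lncRNA nodes
# carry DE direction and |log2 FC|) and its extension by the lncRNAs'
# co-expression edges. Exported as Cytoscape-compatible SIF and GraphML.

suppressPackageStartupMessages(library(lncscape))

de <- read.delim("results/differential.tsv")
edges <- read.delim("results/coexpression_edges.tsv")
trans <- read.delim("results/trans_enrichment.tsv")
freq <- read.delim("results/tf_frequency.tsv")

if (!nrow(freq)) {
  cat("no significantly enriched TF; no network emitted\n")
  quit(status = 0)
}
tf <- freq$set_id[1]
net2 <- two_element(tf, trans, de)
net3 <- three_element(tf, trans, edges, de)
write_network(net2, sprintf("results/%s_two_element.sif", tf), "sif")
write_network(net2, sprintf("results/%s_two_element.graphml", tf), "graphml")
write_network(net3, sprintf("results/%s_three_element.sif", tf), "sif")
write_network(net3, sprintf("results/%s_three_element.graphml", tf),
              "graphml")

cat(sprintf("top TF %s: two-element %d nodes / %d edges; three-element %d nodes / %d edges\n",
            tf, nrow(net2$nodes), nrow(net2$edges), nrow(net3$nodes),
            nrow(net3$edges)))
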