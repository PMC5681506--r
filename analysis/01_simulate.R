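#!/usr/bin/env Rscript
# Stage 1: generate the synthetic paired tumor/normal study.
#
# Emulates the study design downstream stages expect: 6 patients with
# paired arrays, lncRNA and mRNA probe families, planted DE lncRNAs,
# co-expression blocks with cis-proximal members inside the 300 kb window,
# matched TF target sets, a 42-patient qPCR/clinical cohort and a survival
# cohort with a hazard ratio of 3 between expression groups. All seven
# artifacts plus the truth record land in results/dataset/.

suppressPackageStartupMessages(library(lncscape))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cfg <- simulation_config(n_lnc = 2000, n_mrna = 4000, n_blocks = 5,
                         seed = seed)
ds <- generate_dataset(cfg)
paths <- write_dataset(ds, "results/dataset")

cat(sprintf("generated %d lncRNA + %d mRNA probes x %d arrays\n",
            cfg$n_lnc, cfg$n_mrna, ncol(ds$expression$values)))
cat(sprintf("planted: %d DE lncRNAs, %d blocks (%d cis pairs), %d TF sets\n",
            nrow(ds$truth$de_lnc), cfg$n_blocks, nrow(ds$truth$cis_pairs),
            cfg$n_tf))
cat("artifacts:\n")
for (p in paths) cat(" ", p, "\n")
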