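#!/usr/bin/env Rscript
# Stage 6: clinical arm.
#
# 2^-ddCt relative quantification of the validation qPCR gene per patient,
# up/down classification against the paired normal tissue, Pearson
# chi-square association with N classification and clinical stage, and the
# median-split Kaplan-Meier / log-rank survival comparison.

suppressPackageStartupMessages(library(lncscape))

qpcr <- read_qpcr("results/dataset/qpcr.tsv")
clin <- read_clinical("results/dataset/clinical.tsv")
surv <- read_survival("results/dataset/survival.tsv")

gene <- qpcr$gene[1]
qp <- qpcr[qpcr$gene == gene, ]
pats <- unique(qp$patient_id)
ratios <- vapply(pats, function(p) {
  ddct(qp[qp$patient_id == p & qp$tissue == "tumor", ],
       qp[qp$patient_id == p & qp$tissue == "normal", ])$ratio
}, 1)
grp <- suppressWarnings(expression_group(ratios, rep(1, length(ratios))))
write.table(data.frame(patient_id = pats, ratio_2mddct = ratios,
                       group = grp),
            "results/qpcr_groups.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("qPCR gene %s: %d up, %d down of %d patients\n", gene,
            sum(grp == "up"), sum(grp == "down"), length(grp)))

clin <- clin[match(pats, clin$patient_id), ]
for (cov in c("N_class", "clinical_stage", "age_group", "gender")) {
  if (cov == "age_group") {
    clin$age_group <- ifelse(clin$age > median(clin$age), ">median",
                             "<=median")
  }
  if (!cov %in% names(clin)) next
  res <- tryCatch(suppressWarnings(chi_square_association(grp, clin[[cov]])),
                  error = function(e) NULL)
  if (is.null(res)) next
  cat(sprintf("  association with %-14s chi2 = %6.2f (dof %d), p = %.4g\n",
              cov, res$chi2, res$dof, res$p_value))
}

sr <- survival_by_median_split(surv)
write.table(sr$km_high, "results/km_high.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sr$km_low, "results/km_low.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(list(chi2 = sr$chi2, p_value = sr$p_value,
                          n_high = sum(sr$groups == "high"),
                          n_low = sum(sr$groups == "low")),
                     "results/survival_logrank.json", auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("median-split survival: log-rank chi2 = %.2f, p = %.3g (%d high / %d low)\n",
            sr$chi2, sr$p_value, sum(sr$groups == "high"),
            sum(sr$groups == "low")))
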