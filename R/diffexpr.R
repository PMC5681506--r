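#' Paired t-test on patient-aligned log2 values
#'
#' Tests the per-patient tumor-minus-normal differences against zero with a
#' Student t on n-1 degrees of freedom, two-sided. Degenerate difference
#' vectors are given a total order instead of NaN: all differences exactly
#' zero gives t = 0, p = 1; constant nonzero differences give t = +/-Inf,
#' p = 0.
#'
#' @param tumor,normal numeric vectors of equal length >= 2, element i of
#'   both coming from the same patient (log2 scale).
#' @return list with `t_stat` and `p_value`.
#' @export
paired_t_test <- function(tumor, normal) {
  if (length(tumor) != length(normal)) {
    stop("tumor and normal must have equal length", call. = FALSE)
  }
  n <- length(tumor)
  if (n < 2) stop("need >= 2 patient pairs", call. = FALSE)
  d <- tumor - normal
  s <- stats::sd(d)
  m <- mean(d)
  if (s == 0) {
    if (m == 0) return(list(t_stat = 0, p_value = 1))
    return(list(t_stat = sign(m) * Inf, p_value = 0))
  }
  t_stat <- m / (s / sqrt(n))
  list(t_stat = t_stat, p_value = 2 * stats::pt(-abs(t_stat), df = n - 1))
}

# Row-wise paired t over a matrix of differences; same conventions as
# paired_t_test. Returns list of vectors t_stat, p_value.
.row_paired_t <- function(d) {
  n <- ncol(d)
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  t_stat <- ifelse(s == 0, ifelse(m == 0, 0, sign(m) * Inf),
                   m / (s / sqrt(n)))
  p <- ifelse(is.infinite(t_stat), 0,
              2 * stats::pt(-abs(t_stat), df = n - 1))
  list(t_stat = t_stat, p_value = p)
}

#' Tumor/normal fold change on the linear scale
#'
#' Two conventions are supported. `arm_mean` (default): ratio of the
#' linear-scale arm means, `mean(2^tumor) / mean(2^normal)`, under which a
#' uniform +1 log2 shift gives exactly FC = 2. `pair_ratio`: mean of the
#' per-patient linear ratios `2^(tumor - normal)`.
#'
#' @inheritParams paired_t_test
#' @param mode fold-change convention.
#' @return linear-scale fold change (positive scalar).
#' @export
fold_change <- function(tumor, normal, mode = c("arm_mean", "pair_ratio")) {
  mode <- match.arg(mode)
  if (length(tumor) != length(normal)) {
    stop("tumor and normal must have equal length", call. = FALSE)
  }
  if (mode == "arm_mean") {
    mean(2^tumor) / mean(2^normal)
  } else {
    mean(2^(tumor - normal))
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q(i) = min over j >= i of p(j) * m / j on the
#' sorted p-values, capped at 1, returned in input order. Thin wrapper over
#' `stats::p.adjust(method = "BH")` with input validation.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed probes with the triple filter
#'
#' For every probe, computes the paired t statistic and two-sided p on the
#' per-patient tumor-minus-normal log2 differences, the linear fold change,
#' and the BH q-value; a probe is called significant when
#' (FC >= `fc_min` or FC <= 1/`fc_min`) and p < `p_max` and q < `q_max`.
#' By default the BH correction is applied separately within the lncRNA and
#' the mRNA probe families, matching the convention of reporting the two
#' families as separate result sets; `fdr_scope = "pooled"` corrects across
#' all probes at once.
#'
#' @param em an [expression_matrix()] with complete pairing.
#' @param fc_min linear fold-change threshold (default 2).
#' @param p_max p-value threshold (default 0.05).
#' @param q_max FDR threshold (default 0.05).
#' @param fdr_scope `"by_biotype"` or `"pooled"`.
#' @param fc_mode fold-change convention, see [fold_change()].
#' @param verbose emit per-family summary counts as messages.
#' @return data.frame with one row per probe (input order): `probe_id`,
#'   `biotype`, `fold_change`, `log2_fc`, `t_stat`, `p_value`, `q_value`,
#'   `direction` (up/down/ns), `significant`.
#' @export
call_differential <- function(em, fc_min = 2, p_max = 0.05, q_max = 0.05,
                              fdr_scope = c("by_biotype", "pooled"),
                              fc_mode = c("arm_mean", "pair_ratio"),
                              verbose = FALSE) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  fdr_scope <- match.arg(fdr_scope)
  fc_mode <- match.arg(fc_mode)
  arms <- paired_arms(em)
  tt <- .row_paired_t(arms$tumor - arms$normal)
  fc <- if (fc_mode == "arm_mean") {
    rowMeans(2^arms$tumor) / rowMeans(2^arms$normal)
  } else {
    rowMeans(2^(arms$tumor - arms$normal))
  }
  biotype <- em$biotype
  res <- data.frame(
    probe_id = rownames(em$values),
    biotype = unname(biotype),
    fold_change = unname(fc),
    log2_fc = unname(log2(fc)),
    t_stat = unname(tt$t_stat),
    p_value = unname(tt$p_value),
    q_value = NA_real_,
    stringsAsFactors = FALSE
  )
  if (fdr_scope == "by_biotype" && !all(is.na(biotype))) {
    fam <- ifelse(is.na(biotype), "unannotated", biotype)
    for (f in unique(fam)) {
      idx <- fam == f
      res$q_value[idx] <- bh_fdr(res$p_value[idx])
    }
  } else {
    res$q_value <- bh_fdr(res$p_value)
  }
  res$significant <- (res$fold_change >= fc_min |
                        res$fold_change <= 1 / fc_min) &
    res$p_value < p_max & res$q_value < q_max
  res$direction <- ifelse(!res$significant, "ns",
                          ifelse(res$fold_change >= fc_min, "up", "down"))
  if (verbose) {
    for (f in unique(stats::na.omit(res$biotype))) {
      sub <- res[res$biotype %in% f, ]
      message(sprintf("%s: %d significant (%d up, %d down) of %d",
                      f, sum(sub$significant), sum(sub$direction == "up"),
                      sum(sub$direction == "down"), nrow(sub)))
    }
  }
  res
}

#' Select the top-k most differentially expressed probes of one direction
#'
#' Significant probes of the requested direction, ranked by descending
#' absolute log2 fold change; ties broken by ascending p-value, then by
#' probe id. At most `k` rows are returned; a warning is emitted when fewer
#' than `k` are available.
#'
#' @param results data.frame from [call_differential()].
#' @param k maximum number of probes.
#' @param direction `"up"` or `"down"`.
#' @return ranked sub-data.frame of `results`.
#' @export
select_top_k <- function(results, k, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(k >= 1)
  sub <- results[results$significant & results$direction == direction, ]
  ord <- order(-abs(sub$log2_fc), sub$p_value, sub$probe_id)
  sub <- sub[ord, ]
  if (nrow(sub) < k) {
    warning(sprintf("only %d %s-regulated probes available (k = %d)",
                    nrow(sub), direction, k), call. = FALSE)
  }
  utils::head(sub, k)
}

#' QC summaries: volcano table, PCA coordinates, sample dendrogram
#'
#' The volcano table carries per-probe log2 fold change and -log10 p from
#' the paired t-test. Sample PCA is computed on centered sample profiles
#' (probes as variables). Hierarchical clustering uses average linkage on
#' the correlation distance 1 - r between sample profiles and is returned
#' both as an `hclust` object and as Newick bracket text.
#'
#' @param em an [expression_matrix()] with >= 3 samples.
#' @return list with `volcano` (data.frame `probe_id`, `log2_fc`,
#'   `neg_log10_p`), `pca` (data.frame `sample_id`, `PC1`, `PC2`, ...),
#'   `hclust`, and `newick` (character).
#' @export
qc_summary <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (ncol(em$values) < 3) stop("need >= 3 samples", call. = FALSE)
  arms <- paired_arms(em)
  tt <- .row_paired_t(arms$tumor - arms$normal)
  fc <- rowMeans(2^arms$tumor) / rowMeans(2^arms$normal)
  volcano <- data.frame(probe_id = rownames(em$values),
                        log2_fc = unname(log2(fc)),
                        neg_log10_p = unname(-log10(pmax(tt$p_value,
                                                         .Machine$double.xmin))),
                        stringsAsFactors = FALSE)
  pc <- stats::prcomp(t(em$values), center = TRUE, scale. = FALSE)
  k <- min(4, ncol(pc$x))
  pca <- data.frame(sample_id = colnames(em$values),
                    pc$x[, seq_len(k), drop = FALSE],
                    stringsAsFactors = FALSE, row.names = NULL)
  cr <- suppressWarnings(stats::cor(em$values))
  cr[!is.finite(cr)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - cr), method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(volcano = volcano, pca = pca, hclust = hc, newick = newick)
}
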