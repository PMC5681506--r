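#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length n >= 3 with nonzero variance.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Two-sided p-value of a Pearson correlation
#'
#' Uses the exact null distribution under bivariate normality:
#' t = r * sqrt(n - 2) / sqrt(1 - r^2) referred to a Student t with n - 2
#' degrees of freedom, two-sided. |r| = 1 returns p = 0 by convention.
#'
#' @param r correlation coefficient(s), |r| <= 1 (vectorized).
#' @param n number of samples the correlation was computed from (>= 3).
#' @return two-sided p-value(s).
#' @export
pearson_p <- function(r, n) {
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1", call. = FALSE)
  r <- pmin(1, pmax(-1, r))
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  t_stat <- r[ok] * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p
}

# Collapse mRNA probes to gene symbols, keeping the max-variance probe per
# symbol. Returns a matrix with symbol rownames.
.collapse_to_symbols <- function(values, symbols) {
  keep <- !is.na(symbols)
  values <- values[keep, , drop = FALSE]
  symbols <- symbols[keep]
  v <- apply(values, 1, stats::var)
  ord <- order(symbols, -v)
  first <- !duplicated(symbols[ord])
  out <- values[ord, , drop = FALSE][first, , drop = FALSE]
  rownames(out) <- symbols[ord][first]
  out
}

#' Build the lncRNA-mRNA co-expression edge set
#'
#' Computes Pearson correlations between every selected lncRNA probe and
#' every mRNA gene across all samples (tumor and normal arrays pooled;
#' with 6 patient pairs the correlations are over n = 12 arrays). mRNA
#' probes are collapsed to gene symbols by keeping the maximum-variance
#' probe per symbol. An edge is retained when p < `p_max` and r > `r_min`
#' (`positive_only`) or |r| > `r_min` (`both_signs`, the default, so that
#' inverse regulation is captured). Edges are sorted by ascending p, then
#' descending |r|.
#'
#' @param em an [expression_matrix()] with biotype annotation attached.
#' @param lnc_ids lncRNA probe ids to use as edge sources; default all
#'   lncRNA probes.
#' @param r_min correlation threshold (default 0.7).
#' @param p_max p-value threshold (default 0.05).
#' @param mode `"both_signs"` or `"positive_only"`.
#' @return data.frame with columns `lnc_id`, `mrna_symbol`, `r`, `p_value`,
#'   `n_samples`, `sign` (pos/neg).
#' @export
build_edges <- function(em, lnc_ids = NULL, r_min = 0.7, p_max = 0.05,
                        mode = c("both_signs", "positive_only")) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  mode <- match.arg(mode)
  all_lnc <- rownames(em$values)[em$biotype %in% "lncRNA"]
  if (is.null(lnc_ids)) lnc_ids <- all_lnc
  unknown <- setdiff(lnc_ids, all_lnc)
  if (length(unknown)) {
    stop("not lncRNA probes of this matrix: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  mrna <- em$biotype %in% "mRNA"
  mr <- .collapse_to_symbols(em$values[mrna, , drop = FALSE],
                             em$gene_symbol[mrna])
  if (!length(lnc_ids) || !nrow(mr)) {
    return(data.frame(lnc_id = character(), mrna_symbol = character(),
                      r = numeric(), p_value = numeric(),
                      n_samples = integer(), sign = character(),
                      stringsAsFactors = FALSE))
  }
  n <- ncol(em$values)
  cm <- suppressWarnings(
    stats::cor(t(em$values[lnc_ids, , drop = FALSE]), t(mr)))
  cm[!is.finite(cm)] <- 0
  keep <- if (mode == "both_signs") abs(cm) > r_min else cm > r_min
  idx <- which(keep, arr.ind = TRUE)
  r <- cm[keep]
  p <- pearson_p(r, n)
  sel <- p < p_max
  edges <- data.frame(
    lnc_id = lnc_ids[idx[sel, 1]],
    mrna_symbol = rownames(mr)[idx[sel, 2]],
    r = r[sel],
    p_value = p[sel],
    n_samples = rep(n, sum(sel)),
    sign = ifelse(r[sel] > 0, "pos", "neg"),
    stringsAsFactors = FALSE
  )
  edges[order(edges$p_value, -abs(edges$r), edges$lnc_id,
              edges$mrna_symbol), , drop = FALSE]
}

#' Top-k co-expressed target genes of one lncRNA
#'
#' Ranks the lncRNA's edges by ascending p-value (ties broken by larger
#' |r|, then symbol) and returns at most `k` rows; both correlation signs
#' are admitted.
#'
#' @param lnc_id lncRNA probe id.
#' @param edges data.frame from [build_edges()].
#' @param k maximum number of target genes (default 30).
#' @return data.frame with columns `mrna_symbol`, `p_value`, `r`.
#' @export
target_table <- function(lnc_id, edges, k = 30) {
  sub <- edges[edges$lnc_id == lnc_id, c("mrna_symbol", "p_value", "r")]
  if (!nrow(sub)) {
    warning(sprintf("no edges for lncRNA '%s'", lnc_id), call. = FALSE)
    return(sub)
  }
  sub <- sub[order(sub$p_value, -abs(sub$r), sub$mrna_symbol), , drop = FALSE]
  rownames(sub) <- NULL
  utils::head(sub, k)
}
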