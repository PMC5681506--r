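#' Strand-agnostic genomic distance between two intervals
#'
#' Intervals are 0-based half-open (BED convention). Records on different
#' chromosomes are incomparable and give `NA`; overlapping or touching
#' intervals give 0; otherwise the gap between the nearest interval
#' boundaries.
#'
#' @param a,b single annotation records (1-row data.frames or lists with
#'   `chrom`, `start`, `end`).
#' @return non-negative integer distance, or `NA_integer_` when on
#'   different chromosomes.
#' @export
genomic_distance <- function(a, b) {
  if (a$chrom != b$chrom) return(NA_integer_)
  gap <- max(a$start, b$start) - min(a$end, b$end)
  as.integer(max(0L, gap))
}

# Vectorized interval gap for equal-length coordinate vectors on the same
# chromosome (callers must pre-filter chromosomes).
.interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

#' Assign cis targets of lncRNAs by a genomic window rule
#'
#' A co-expression edge (lncRNA, mRNA) becomes a cis assignment when both
#' endpoints are annotated, lie on the same chromosome, the gap between
#' their nearest interval boundaries is at most `window_bp` (inclusive; 0
#' for overlapping intervals), and the edge's correlation p-value is at most
#' `p_max`. lncRNAs are matched to annotation by record name, mRNAs by gene
#' symbol; a symbol with several records contributes its minimum distance.
#' Edges with unannotated endpoints are skipped; their count is attached as
#' attribute `n_skipped`.
#'
#' @param edges data.frame from [build_edges()].
#' @param annotation data.frame from [read_annotation()].
#' @param window_bp window size in bp (default 300000, i.e. 300 kb up- or
#'   downstream).
#' @param p_max correlation p-value cutoff (default 0.05).
#' @return data.frame with columns `lnc_id`, `mrna_symbol`, `distance_bp`,
#'   `r`, `p_value`, sorted by lnc_id then distance.
#' @export
cis_assign <- function(edges, annotation, window_bp = 300000, p_max = 0.05) {
  empty <- data.frame(lnc_id = character(), mrna_symbol = character(),
                      distance_bp = integer(), r = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  if (!nrow(edges)) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  lnc_idx <- match(edges$lnc_id, annotation$name)
  # mRNA symbols may map to several records; expand to all and keep min
  sym_anno <- annotation[annotation$biotype == "mRNA", , drop = FALSE]
  hits <- split(seq_len(nrow(sym_anno)), sym_anno$symbol)
  known_sym <- edges$mrna_symbol %in% names(hits)
  skipped <- is.na(lnc_idx) | !known_sym
  keep <- which(!skipped & edges$p_value <= p_max)
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    e <- keep[i]
    la <- annotation[lnc_idx[e], ]
    ga <- sym_anno[hits[[edges$mrna_symbol[e]]], , drop = FALSE]
    same <- ga$chrom == la$chrom
    if (!any(same)) next
    d <- .interval_gap(la$start, la$end, ga$start[same], ga$end[same])
    dmin <- min(d)
    if (dmin <= window_bp) {
      rows[[i]] <- data.frame(lnc_id = edges$lnc_id[e],
                              mrna_symbol = edges$mrna_symbol[e],
                              distance_bp = as.integer(dmin),
                              r = edges$r[e], p_value = edges$p_value[e],
                              stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$lnc_id, out$distance_bp, out$mrna_symbol), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(skipped)
  out
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Exact tail sum of the hypergeometric distribution: the probability of
#' observing at least `k` annotated members in a query of size `n_query`
#' drawn without replacement from a universe of `N` genes of which `K` are
#' annotated. Computed in log-gamma space via `lchoose`, numerically stable
#' for N up to 1e5.
#'
#' @param k observed overlap count (0 <= k <= min(n_query, K)).
#' @param K annotated-set size within the universe.
#' @param n_query query-set size.
#' @param N universe size.
#' @return p-value in (0, 1\].
#' @export
hypergeom_upper <- function(k, K, n_query, N) {
  if (any(c(k, K, n_query, N) < 0) || K > N || n_query > N ||
      k > min(n_query, K)) {
    stop("invalid hypergeometric bounds", call. = FALSE)
  }
  if (k <= 0) return(1)
  i <- k:min(n_query, K)
  # also need enough unannotated genes to fill the query
  i <- i[n_query - i <= N - K]
  lp <- lchoose(K, i) + lchoose(N - K, n_query - i) - lchoose(N, n_query)
  min(1, sum(exp(lp)))
}

# Core enrichment engine shared by trans_enrich and functional_enrich.
.set_enrich <- function(query, gs, universe) {
  stopifnot(inherits(gs, "GeneSets"))
  universe <- unique(universe)
  if (!length(universe)) stop("empty enrichment universe", call. = FALSE)
  query <- intersect(unique(query), universe)
  N <- length(universe)
  rows <- lapply(names(gs$sets), function(id) {
    members <- intersect(gs$sets[[id]], universe)
    ov <- intersect(query, members)
    data.frame(set_id = id, k = length(ov), n_query = length(query),
               K = length(members), N = N,
               p_value = hypergeom_upper(length(ov), length(members),
                                         length(query), N),
               overlap = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- bh_fdr(res$p_value)
  res <- res[order(res$p_value, -res$k, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("set_id", "k", "n_query", "K", "N", "p_value", "q_value",
          "overlap")]
}

#' Trans regulator inference by TF-target overlap
#'
#' For one lncRNA, tests every TF target set for over-representation among
#' the lncRNA's co-expressed mRNA symbols with the upper-tail hypergeometric
#' probability, then BH-adjusts across TF sets. The universe should be the
#' intersection of the expression-matrix symbols with the union of all TF
#' set members, so that N is not inflated by genes that could never
#' overlap.
#'
#' @param lnc_id lncRNA probe id.
#' @param edges data.frame from [build_edges()].
#' @param tf_sets a `GeneSets` collection of TF target sets.
#' @param universe character vector of symbols defining N.
#' @return data.frame with columns `set_id`, `k`, `n_query`, `K`, `N`,
#'   `p_value`, `q_value`, `overlap`, sorted by ascending p.
#' @export
trans_enrich <- function(lnc_id, edges, tf_sets, universe) {
  query <- edges$mrna_symbol[edges$lnc_id == lnc_id]
  .set_enrich(query, tf_sets, universe)
}

#' Generic gene-set enrichment of a query symbol set
#'
#' Same engine as [trans_enrich()] with arbitrary (e.g. functional) gene-set
#' collections.
#'
#' @param query character vector of gene symbols.
#' @param anno_sets a `GeneSets` collection.
#' @param universe character vector of symbols defining N.
#' @return see [trans_enrich()].
#' @export
functional_enrich <- function(query, anno_sets, universe) {
  .set_enrich(query, anno_sets, universe)
}

#' Count, per TF, the lncRNAs significantly enriched for its targets
#'
#' @param results named list (by lncRNA id) of [trans_enrich()] results.
#' @param q_max significance threshold on the BH q-value (default 0.05).
#' @return data.frame with columns `set_id` and `n_lnc`, sorted by
#'   descending count with lexicographic tie order.
#' @export
tf_frequency <- function(results, q_max = 0.05) {
  hits <- unlist(lapply(results, function(res) {
    res$set_id[res$q_value < q_max]
  }), use.names = FALSE)
  if (!length(hits)) {
    return(data.frame(set_id = character(), n_lnc = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(hits)
  out <- data.frame(set_id = names(tab), n_lnc = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_lnc, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
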