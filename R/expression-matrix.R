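#' Paired expression matrix container
#'
#' Bundles a probes-by-samples matrix of log2 intensities with the
#' tumor/normal pairing map and per-probe biotype / gene-symbol annotation.
#' This is the object every downstream stage consumes.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids), log2 scale, all finite.
#' @param pairing data.frame with columns `patient_id`, `tumor`, `normal`;
#'   `tumor`/`normal` are sample ids of `values`. Each sample may belong to
#'   at most one pair.
#' @param biotype optional named character vector mapping probe id to
#'   `"lncRNA"` or `"mRNA"`. May be `NA` for unannotated probes.
#' @param gene_symbol optional named character vector mapping probe id to a
#'   gene symbol (`NA` where no symbol exists, typical for lncRNA probes).
#'
#' @return an object of class `ExpressionMatrix` (a list with elements
#'   `values`, `pairing`, `biotype`, `gene_symbol`).
#' @export
expression_matrix <- function(values, pairing, biotype = NULL,
                              gene_symbol = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  probe_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("`values` must carry probe rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe ids: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at probe '%s', sample '%s'",
                 probe_ids[bad[1]], sample_ids[bad[2]]), call. = FALSE)
  }
  pairing <- as.data.frame(pairing, stringsAsFactors = FALSE)
  req <- c("patient_id", "tumor", "normal")
  if (!all(req %in% names(pairing))) {
    stop("pairing must have columns patient_id, tumor, normal", call. = FALSE)
  }
  pairing <- pairing[, req]
  paired_samples <- c(pairing$tumor, pairing$normal)
  missing <- setdiff(paired_samples, sample_ids)
  if (length(missing)) {
    stop("pairing references samples absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(paired_samples)) {
    stop("a sample appears in more than one pair: ",
         paste(unique(paired_samples[duplicated(paired_samples)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(pairing$patient_id)) {
    stop("duplicate patient ids in pairing", call. = FALSE)
  }
  bt <- rep(NA_character_, length(probe_ids))
  names(bt) <- probe_ids
  if (!is.null(biotype)) {
    known <- intersect(names(biotype), probe_ids)
    bad_tok <- setdiff(unique(stats::na.omit(biotype)), c("lncRNA", "mRNA"))
    if (length(bad_tok)) {
      stop("unknown biotype token(s): ", paste(bad_tok, collapse = ", "),
           call. = FALSE)
    }
    bt[known] <- biotype[known]
  }
  sym <- rep(NA_character_, length(probe_ids))
  names(sym) <- probe_ids
  if (!is.null(gene_symbol)) {
    known <- intersect(names(gene_symbol), probe_ids)
    sym[known] <- gene_symbol[known]
  }
  structure(
    list(values = values, pairing = pairing, biotype = bt, gene_symbol = sym),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  nbt <- table(factor(x$biotype, levels = c("lncRNA", "mRNA")), useNA = "ifany")
  cat(sprintf("ExpressionMatrix: %d probes x %d samples, %d patient pairs\n",
              nrow(x$values), ncol(x$values), nrow(x$pairing)))
  cat(sprintf("  biotypes: %d lncRNA, %d mRNA, %d unannotated\n",
              nbt[["lncRNA"]], nbt[["mRNA"]],
              sum(is.na(x$biotype))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Attach genomic annotation to an expression matrix
#'
#' Fills the `biotype` and `gene_symbol` maps of an [expression_matrix()]
#' from an annotation table (see [read_annotation()]); probes are matched by
#' `name`.
#'
#' @param em an `ExpressionMatrix`.
#' @param annotation data.frame with at least columns `name`, `symbol`,
#'   `biotype`.
#' @return the updated `ExpressionMatrix`.
#' @export
attach_annotation <- function(em, annotation) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  idx <- match(rownames(em$values), annotation$name)
  hit <- !is.na(idx)
  em$biotype[hit] <- annotation$biotype[idx[hit]]
  em$gene_symbol[hit] <- annotation$symbol[idx[hit]]
  bad_tok <- setdiff(unique(stats::na.omit(em$biotype)), c("lncRNA", "mRNA"))
  if (length(bad_tok)) {
    stop("unknown biotype token(s): ", paste(bad_tok, collapse = ", "),
         call. = FALSE)
  }
  em
}

#' Extract paired tumor and normal sub-matrices
#'
#' Columns are ordered by patient so that column i of the tumor slice and
#' column i of the normal slice come from the same patient.
#'
#' @param em an `ExpressionMatrix`.
#' @return list with matrices `tumor` and `normal` (probes x patients).
#' @export
paired_arms <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  list(tumor  = em$values[, em$pairing$tumor,  drop = FALSE],
       normal = em$values[, em$pairing$normal, drop = FALSE])
}

#' Subset an expression matrix by probe id
#'
#' @param em an `ExpressionMatrix`.
#' @param probe_ids probes to keep (order preserved).
#' @return an `ExpressionMatrix` restricted to `probe_ids`.
#' @export
subset_probes <- function(em, probe_ids) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  missing <- setdiff(probe_ids, rownames(em$values))
  if (length(missing)) {
    stop("unknown probe ids: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  expression_matrix(em$values[probe_ids, , drop = FALSE], em$pairing,
                    em$biotype[probe_ids], em$gene_symbol[probe_ids])
}
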