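#' Read a probes-by-samples expression matrix with its pairing map
#'
#' The matrix file is TSV with a header; the first column holds probe ids,
#' the remaining columns are numeric log2 intensities, one per sample. The
#' pairing file is TSV with columns `patient_id`, `tumor`, `normal` naming
#' the sample columns of each patient's arrays. Column order of the matrix
#' is preserved.
#'
#' @param path TSV expression matrix file.
#' @param pairing_path TSV pairing file.
#' @return an [expression_matrix()] (biotype/symbol maps unset; see
#'   [attach_annotation()]).
#' @export
read_expression_matrix <- function(path, pairing_path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("expression matrix needs >= 1 sample column",
                          call. = FALSE)
  probe_ids <- raw[[1]]
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe row(s): ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression value at probe '%s', sample '%s'",
                 probe_ids[bad[1]], colnames(vals)[bad[2]]), call. = FALSE)
  }
  dimnames(num) <- list(probe_ids, colnames(vals))
  pairing <- utils::read.delim(pairing_path, header = TRUE, sep = "\t",
                               colClasses = "character")
  expression_matrix(num, pairing)
}

#' Write an expression matrix and its pairing map to TSV
#'
#' @param em an `ExpressionMatrix`.
#' @param path output TSV for the matrix (first column `probe_id`).
#' @param pairing_path output TSV for the pairing map.
#' @return invisibly, `path`.
#' @export
write_expression_matrix <- function(em, path, pairing_path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  df <- data.frame(probe_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(em$pairing, pairing_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.BED_BIOTYPES <- c("lncRNA", "mRNA")

#' Read a BED6+2 genomic annotation file
#'
#' Expected columns (no header): chrom, start, end, name, score, strand,
#' symbol, biotype. Coordinates are 0-based half-open and are kept verbatim;
#' biotype must be `lncRNA` or `mRNA`; strand one of `+`, `-`, `.`.
#'
#' @param path BED6+2 file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `symbol`, `biotype`.
#' @export
read_annotation <- function(path) {
  anno <- utils::read.delim(path, header = FALSE, sep = "\t",
                            col.names = c("chrom", "start", "end", "name",
                                          "score", "strand", "symbol",
                                          "biotype"),
                            colClasses = c("character", "integer", "integer",
                                           "character", "character",
                                           "character", "character",
                                           "character"))
  bad <- which(anno$end <= anno$start | anno$start < 0)
  if (length(bad)) {
    stop("invalid interval (end <= start or start < 0) for record(s): ",
         paste(anno$name[utils::head(bad, 5)], collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(anno$chrom))) stop("empty chrom field", call. = FALSE)
  bad_bt <- which(!anno$biotype %in% .BED_BIOTYPES)
  if (length(bad_bt)) {
    stop("unknown biotype token for record(s): ",
         paste(anno$name[utils::head(bad_bt, 5)], collapse = ", "),
         call. = FALSE)
  }
  bad_strand <- which(!anno$strand %in% c("+", "-", "."))
  if (length(bad_strand)) {
    stop("invalid strand for record(s): ",
         paste(anno$name[utils::head(bad_strand, 5)], collapse = ", "),
         call. = FALSE)
  }
  anno
}

#' Write a BED6+2 annotation table
#'
#' Inverse of [read_annotation()]; round-trips byte-identically.
#'
#' @param annotation data.frame as returned by [read_annotation()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_annotation <- function(annotation, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand", "symbol",
            "biotype")
  stopifnot(all(cols %in% names(annotation)))
  utils::write.table(annotation[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line: set id, description, then one or more member symbols, all
#' tab-separated.
#'
#' @param path GMT file.
#' @return object of class `GeneSets`: list with `sets` (named list of
#'   character vectors) and `description` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(utils::head(short, 5), collapse = ", "), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate set id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(members) <- ids
  names(desc) <- ids
  gene_sets(members, desc)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (members, non-empty, unique
#'   within a set).
#' @param description optional named character vector of descriptions.
#' @return object of class `GeneSets`.
#' @export
gene_sets <- function(sets, description = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (any(!vapply(sets, length, 1L))) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  dup <- vapply(sets, anyDuplicated, 1L) > 0
  if (any(dup)) {
    stop("duplicate members within set(s): ",
         paste(names(sets)[dup], collapse = ", "), call. = FALSE)
  }
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, description = description[names(sets)]),
            class = "GeneSets")
}

#' @export
print.GeneSets <- function(x, ...) {
  cat(sprintf("GeneSets: %d sets, median size %d\n", length(x$sets),
              as.integer(stats::median(lengths(x$sets)))))
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' @param gs a `GeneSets` object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(gs, path) {
  stopifnot(inherits(gs, "GeneSets"))
  lines <- vapply(names(gs$sets), function(id) {
    paste(c(id, gs$description[[id]], gs$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read the clinical covariate table
#'
#' TSV with header; requires a `patient_id` column, all other columns are
#' kept as-is. Optional `survival_time` (days, >= 0) and `event` (0/1)
#' columns are validated when present.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  clin <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(clin)) {
    stop("clinical table needs a patient_id column", call. = FALSE)
  }
  if ("survival_time" %in% names(clin) &&
      any(clin$survival_time < 0, na.rm = TRUE)) {
    stop("negative survival_time", call. = FALSE)
  }
  if ("event" %in% names(clin) &&
      !all(clin$event %in% c(0L, 1L, NA))) {
    stop("event must be 0/1", call. = FALSE)
  }
  clin
}

#' Read a qPCR Ct table
#'
#' TSV with header and columns `patient_id`, `tissue` (tumor/normal),
#' `gene`, `replicate`, `ct_target`, `ct_reference`. Ct values must lie in
#' (0, 45).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_qpcr <- function(path) {
  q <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  req <- c("patient_id", "tissue", "gene", "replicate", "ct_target",
           "ct_reference")
  missing <- setdiff(req, names(q))
  if (length(missing)) {
    stop("qPCR table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(q$tissue %in% c("tumor", "normal"))) {
    stop("tissue must be tumor/normal", call. = FALSE)
  }
  ct <- c(q$ct_target, q$ct_reference)
  if (any(!is.finite(ct)) || any(ct <= 0 | ct >= 45)) {
    stop("Ct values must be finite and in (0, 45)", call. = FALSE)
  }
  q
}

#' Read a survival table
#'
#' TSV with header and columns `subject_id`, `time` (days), `event` (0/1)
#' and `expression` (the marker used for the median split).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_survival <- function(path) {
  s <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  req <- c("subject_id", "time", "event", "expression")
  missing <- setdiff(req, names(s))
  if (length(missing)) {
    stop("survival table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(s$time < 0)) stop("negative survival time", call. = FALSE)
  if (!all(s$event %in% c(0L, 1L))) stop("event must be 0/1", call. = FALSE)
  s
}
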