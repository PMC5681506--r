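#' Run the full analysis pipeline on one dataset
#'
#' Executes, in order: paired differential-expression calling with the
#' triple filter; top-k selection of up- and down-regulated lncRNAs;
#' lncRNA-mRNA co-expression edges for the selected lncRNAs; cis target
#' assignment by the genomic window rule; per-lncRNA trans TF enrichment
#' and the TF frequency table; two- and three-element networks for the
#' top-ranked TF; and the clinical arm (2^-ddCt per qPCR gene, chi-square
#' association of the up/down grouping against N classification and
#' clinical stage, median-split log-rank survival). When `out_dir` is
#' given, every table is written as TSV (networks as SIF + GraphML) and an
#' md5 manifest of all outputs is returned, so identical inputs yield
#' identical manifests.
#'
#' @param dataset a [generate_dataset()] result, or any list with the same
#'   elements (`expression`, `annotation`, `tf_sets`, `clinical`, `qpcr`,
#'   `survival`).
#' @param fc_min,p_max,q_max differential-expression thresholds (defaults
#'   2, 0.05, 0.05).
#' @param r_min co-expression correlation threshold (default 0.7).
#' @param window_bp cis window (default 300000).
#' @param top_k lncRNAs selected per direction (default 200).
#' @param enrich_q TF-enrichment significance threshold (default 0.05).
#' @param out_dir optional output directory.
#' @return list with elements `de`, `selected`, `edges`, `cis`, `trans`,
#'   `tf_freq`, `networks`, `clinical_assoc`, `survival`, and `manifest`
#'   (data.frame of file md5 sums; empty when `out_dir` is NULL).
#' @export
run_pipeline <- function(dataset, fc_min = 2, p_max = 0.05, q_max = 0.05,
                         r_min = 0.7, window_bp = 300000, top_k = 200,
                         enrich_q = 0.05, out_dir = NULL) {
  em <- dataset$expression

  de <- call_differential(em, fc_min = fc_min, p_max = p_max, q_max = q_max)
  de_lnc <- de[de$biotype %in% "lncRNA", , drop = FALSE]
  up <- suppressWarnings(select_top_k(de_lnc, top_k, "up"))
  down <- suppressWarnings(select_top_k(de_lnc, top_k, "down"))
  selected <- rbind(up, down)

  edges <- build_edges(em, lnc_ids = selected$probe_id, r_min = r_min,
                       p_max = p_max, mode = "both_signs")
  cis <- cis_assign(edges, dataset$annotation, window_bp = window_bp,
                    p_max = p_max)

  universe <- intersect(stats::na.omit(em$gene_symbol),
                        unique(unlist(dataset$tf_sets$sets)))
  lnc_with_edges <- unique(edges$lnc_id)
  trans_list <- stats::setNames(lapply(lnc_with_edges, function(l) {
    trans_enrich(l, edges, dataset$tf_sets, universe)
  }), lnc_with_edges)
  trans <- do.call(rbind, lapply(names(trans_list), function(l) {
    cbind(lnc_id = l, trans_list[[l]], stringsAsFactors = FALSE)
  }))
  if (is.null(trans)) {
    trans <- data.frame(lnc_id = character(), set_id = character(),
                        k = integer(), n_query = integer(), K = integer(),
                        N = integer(), p_value = numeric(),
                        q_value = numeric(), overlap = character(),
                        stringsAsFactors = FALSE)
  }
  tf_freq <- tf_frequency(trans_list, q_max = enrich_q)

  networks <- list()
  if (nrow(tf_freq)) {
    top_tf <- tf_freq$set_id[1]
    networks[[top_tf]] <- list(
      two = suppressWarnings(two_element(top_tf, trans, de,
                                         q_max = enrich_q)),
      three = suppressWarnings(three_element(top_tf, trans, edges, de,
                                             q_max = enrich_q)))
  }

  clinical_assoc <- NULL
  if (nrow(dataset$qpcr)) {
    gene1 <- dataset$qpcr$gene[1]
    qp <- dataset$qpcr[dataset$qpcr$gene == gene1, ]
    ratios <- vapply(unique(qp$patient_id), function(p) {
      ddct(qp[qp$patient_id == p & qp$tissue == "tumor", ],
           qp[qp$patient_id == p & qp$tissue == "normal", ])$ratio
    }, 1)
    grp <- suppressWarnings(expression_group(ratios, rep(1, length(ratios))))
    clin <- dataset$clinical[match(names(ratios),
                                   dataset$clinical$patient_id), ]
    clinical_assoc <- list(
      gene = gene1, groups = grp,
      n_class = tryCatch(chi_square_association(grp, clin$N_class),
                         error = function(e) NULL),
      stage = tryCatch(chi_square_association(grp, clin$clinical_stage),
                       error = function(e) NULL))
  }

  surv_res <- NULL
  if (nrow(dataset$survival)) {
    surv_res <- survival_by_median_split(dataset$survival)
  }

  manifest <- data.frame(file = character(), md5 = character(),
                         stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, name) {
      p <- file.path(out_dir, name)
      utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    files <- c(wt(de, "differential.tsv"),
               wt(selected, "selected_lncRNAs.tsv"),
               wt(edges, "coexpression_edges.tsv"),
               wt(cis, "cis_assignments.tsv"),
               wt(trans, "trans_enrichment.tsv"),
               wt(tf_freq, "tf_frequency.tsv"))
    if (length(networks)) {
      tf <- names(networks)[1]
      p1 <- file.path(out_dir, paste0(tf, "_two_element.sif"))
      p2 <- file.path(out_dir, paste0(tf, "_three_element.graphml"))
      write_network(networks[[tf]]$two, p1, "sif")
      write_network(networks[[tf]]$three, p2, "graphml")
      files <- c(files, p1, p2)
    }
    if (!is.null(surv_res)) {
      files <- c(files, wt(surv_res$km_high, "km_high.tsv"),
                 wt(surv_res$km_low, "km_low.tsv"))
    }
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(de = de, selected = selected, edges = edges, cis = cis,
       trans = trans, tf_freq = tf_freq, networks = networks,
       clinical_assoc = clinical_assoc, survival = surv_res,
       manifest = manifest)
}
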