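#' Typed regulatory network container
#'
#' A small graph with nodes typed `TF`, `lncRNA` or `mRNA` and signed,
#' weighted edges of relation `tf_reg` (TF to lncRNA), `coexp_pos` or
#' `coexp_neg` (lncRNA to mRNA). lncRNA nodes may carry `direction`
#' (up/down) and `log2_fc` attributes mirroring the dot color/size encoding
#' of the usual network figures.
#'
#' @param nodes data.frame with columns `id`, `type` and optionally
#'   `direction`, `log2_fc`.
#' @param edges data.frame with columns `source`, `target`, `relation`,
#'   `weight`.
#' @return object of class `TypedNetwork`.
#' @export
typed_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("id", "type") %in% names(nodes))) {
    stop("nodes need columns id, type", call. = FALSE)
  }
  if (!all(c("source", "target", "relation", "weight") %in% names(edges))) {
    stop("edges need columns source, target, relation, weight", call. = FALSE)
  }
  if (!"direction" %in% names(nodes)) {
    nodes$direction <- rep(NA_character_, nrow(nodes))
  }
  if (!"log2_fc" %in% names(nodes)) {
    nodes$log2_fc <- rep(NA_real_, nrow(nodes))
  }
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (!all(nodes$type %in% c("TF", "lncRNA", "mRNA"))) {
    stop("node types must be TF/lncRNA/mRNA", call. = FALSE)
  }
  if (!all(edges$relation %in% c("tf_reg", "coexp_pos", "coexp_neg"))) {
    stop("edge relations must be tf_reg/coexp_pos/coexp_neg", call. = FALSE)
  }
  if (any(edges$source == edges$target)) {
    stop("self-edges are not allowed", call. = FALSE)
  }
  endpoints <- unique(c(edges$source, edges$target))
  if (nrow(edges) && !setequal(nodes$id, endpoints)) {
    stop("node set must equal the union of edge endpoints", call. = FALSE)
  }
  ntype <- stats::setNames(nodes$type, nodes$id)
  if (nrow(edges)) {
    tfr <- edges$relation == "tf_reg"
    if (any(ntype[edges$source[tfr]] != "TF" |
            ntype[edges$target[tfr]] != "lncRNA")) {
      stop("tf_reg edges must run TF -> lncRNA", call. = FALSE)
    }
    cox <- !tfr
    if (any(ntype[edges$source[cox]] != "lncRNA" |
            ntype[edges$target[cox]] != "mRNA")) {
      stop("coexp edges must run lncRNA -> mRNA", call. = FALSE)
    }
  }
  structure(list(nodes = nodes[, c("id", "type", "direction", "log2_fc")],
                 edges = edges[, c("source", "target", "relation", "weight")]),
            class = "TypedNetwork")
}

#' @export
print.TypedNetwork <- function(x, ...) {
  cat(sprintf("TypedNetwork: %d nodes (%s), %d edges\n", nrow(x$nodes),
              paste(names(table(x$nodes$type)), table(x$nodes$type),
                    sep = ":", collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Two-element TF-lncRNA network
#'
#' Star graph from one TF to every lncRNA significantly enriched for its
#' target set; lncRNA nodes carry the differential-expression direction and
#' log2 fold change, edge weights are -log10 of the enrichment p-value.
#'
#' @param tf_id TF set id.
#' @param trans_results data.frame of combined [trans_enrich()] results with
#'   an extra `lnc_id` column (one block of rows per lncRNA).
#' @param de_results data.frame from [call_differential()].
#' @param q_max enrichment significance threshold (default 0.05).
#' @return a [typed_network()]; empty (with a warning) when no lncRNA is
#'   significantly enriched for `tf_id`.
#' @export
two_element <- function(tf_id, trans_results, de_results, q_max = 0.05) {
  hit <- trans_results[trans_results$set_id == tf_id &
                         trans_results$q_value < q_max, , drop = FALSE]
  if (!nrow(hit)) {
    warning(sprintf("no lncRNA significantly enriched for '%s'", tf_id),
            call. = FALSE)
    return(typed_network(
      data.frame(id = character(), type = character(),
                 stringsAsFactors = FALSE),
      data.frame(source = character(), target = character(),
                 relation = character(), weight = numeric(),
                 stringsAsFactors = FALSE)))
  }
  de_idx <- match(hit$lnc_id, de_results$probe_id)
  nodes <- rbind(
    data.frame(id = tf_id, type = "TF", direction = NA_character_,
               log2_fc = NA_real_, stringsAsFactors = FALSE),
    data.frame(id = hit$lnc_id, type = "lncRNA",
               direction = de_results$direction[de_idx],
               log2_fc = de_results$log2_fc[de_idx],
               stringsAsFactors = FALSE)
  )
  edges <- data.frame(source = tf_id, target = hit$lnc_id,
                      relation = "tf_reg",
                      weight = -log10(pmax(hit$p_value,
                                           .Machine$double.xmin)),
                      stringsAsFactors = FALSE)
  typed_network(nodes, edges)
}

#' Three-element TF-lncRNA-mRNA network
#'
#' The [two_element()] star extended by the co-expression edges of every
#' included lncRNA; coexp edges are signed by the correlation and weighted
#' by r.
#'
#' @inheritParams two_element
#' @param edges data.frame from [build_edges()].
#' @return a [typed_network()].
#' @export
three_element <- function(tf_id, trans_results, edges, de_results,
                          q_max = 0.05) {
  net <- two_element(tf_id, trans_results, de_results, q_max)
  lncs <- net$nodes$id[net$nodes$type == "lncRNA"]
  co <- edges[edges$lnc_id %in% lncs, , drop = FALSE]
  if (!nrow(co)) return(net)
  mrna_nodes <- data.frame(id = unique(co$mrna_symbol), type = "mRNA",
                           direction = NA_character_, log2_fc = NA_real_,
                           stringsAsFactors = FALSE)
  co_edges <- data.frame(source = co$lnc_id, target = co$mrna_symbol,
                         relation = ifelse(co$r > 0, "coexp_pos",
                                           "coexp_neg"),
                         weight = co$r, stringsAsFactors = FALSE)
  typed_network(rbind(net$nodes, mrna_nodes), rbind(net$edges, co_edges))
}

#' Export a typed network to SIF or GraphML
#'
#' SIF rows are `source TAB relation TAB target`. GraphML (via igraph)
#' carries node `type`, `direction`, `log2_fc` and edge `relation`,
#' `weight` attributes; both dialects load in Cytoscape.
#'
#' @param network a [typed_network()].
#' @param path output file.
#' @param dialect `"sif"` or `"graphml"`.
#' @return invisibly, `path`.
#' @export
write_network <- function(network, path, dialect = c("sif", "graphml")) {
  stopifnot(inherits(network, "TypedNetwork"))
  dialect <- match.arg(dialect)
  if (dialect == "sif") {
    lines <- sprintf("%s\t%s\t%s", network$edges$source,
                     network$edges$relation, network$edges$target)
    writeLines(lines, path)
  } else {
    g <- igraph::graph_from_data_frame(
      network$edges[, c("source", "target", "relation", "weight")],
      directed = TRUE, vertices = network$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a typed network written by [write_network()]
#'
#' @param path input file.
#' @param dialect `"sif"` or `"graphml"`.
#' @param nodes for SIF (which carries no attributes), an optional node
#'   table to restore types; when absent, types are inferred from edge
#'   relations.
#' @return a [typed_network()].
#' @export
read_network <- function(path, dialect = c("sif", "graphml"), nodes = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "sif") {
    fields <- strsplit(readLines(path), "\t", fixed = TRUE)
    edges <- data.frame(
      source = vapply(fields, `[[`, "", 1L),
      relation = vapply(fields, `[[`, "", 2L),
      target = vapply(fields, `[[`, "", 3L),
      weight = NA_real_, stringsAsFactors = FALSE)
    if (is.null(nodes)) {
      src_type <- ifelse(edges$relation == "tf_reg", "TF", "lncRNA")
      tgt_type <- ifelse(edges$relation == "tf_reg", "lncRNA", "mRNA")
      ids <- c(edges$source, edges$target)
      types <- c(src_type, tgt_type)
      nodes <- data.frame(id = ids, type = types,
                          stringsAsFactors = FALSE)
      nodes <- nodes[!duplicated(nodes$id), ]
    }
    return(typed_network(nodes,
                         edges[, c("source", "target", "relation", "weight")]))
  }
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  dir_attr <- if (!is.null(va$direction)) va$direction else
    rep(NA_character_, length(va$name))
  dir_attr[dir_attr == "NA"] <- NA_character_  # igraph serializes NA as "NA"
  nodes <- data.frame(id = va$name, type = va$type,
                      direction = dir_attr,
                      log2_fc = if (!is.null(va$log2_fc)) va$log2_fc
                                else rep(NA_real_, length(va$name)),
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  ea <- igraph::edge_attr(g)
  edges <- data.frame(source = el[, 1], target = el[, 2],
                      relation = ea$relation, weight = ea$weight,
                      stringsAsFactors = FALSE)
  typed_network(nodes, edges)
}
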