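# Shared fixtures: small, fast configurations of the synthetic study and a
# hand-built expression matrix whose numbers can be verified on paper.

desk_config <- function(seed = 1, ...) {
  args <- list(n_lnc = 300, n_mrna = 600, n_blocks = 4, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

# 3 probes x 4 samples (2 patients), values chosen so fold changes and
# paired t statistics are hand-checkable
tiny_matrix <- function() {
  v <- matrix(c(5, 6, 4, 5,    # probe A: tumor = normal + 1
                7, 7, 7, 7,    # probe B: flat
                3, 5, 6, 2),   # probe C: mixed
              nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"),
                              c("P1_T", "P2_T", "P1_N", "P2_N")))
  expression_matrix(
    v,
    data.frame(patient_id = c("P1", "P2"),
               tumor = c("P1_T", "P2_T"),
               normal = c("P1_N", "P2_N")),
    biotype = c(A = "lncRNA", B = "lncRNA", C = "mRNA"),
    gene_symbol = c(C = "GENEC")
  )
}

# brute-force hypergeometric upper tail by direct ratio-of-binomials sum
# (independent of the package's log-space path)
hyper_tail_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  i <- i[n - i <= N - K]
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# brute-force all-pairs cis scan: quadratic oracle over the edge list
cis_oracle <- function(edges, annotation, window_bp = 300000, p_max = 0.05) {
  out <- list()
  for (i in seq_len(nrow(edges))) {
    la <- annotation[annotation$name == edges$lnc_id[i], ]
    if (!nrow(la)) next
    ga <- annotation[annotation$symbol == edges$mrna_symbol[i] &
                       annotation$biotype == "mRNA", ]
    if (!nrow(ga)) next
    if (edges$p_value[i] > p_max) next
    dmin <- Inf
    for (j in seq_len(nrow(ga))) {
      if (ga$chrom[j] != la$chrom) next
      d <- max(0, max(la$start, ga$start[j]) - min(la$end, ga$end[j]))
      dmin <- min(dmin, d)
    }
    if (dmin <= window_bp) {
      out[[length(out) + 1]] <- data.frame(
        lnc_id = edges$lnc_id[i], mrna_symbol = edges$mrna_symbol[i],
        distance_bp = as.integer(dmin), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(lnc_id = character(), mrna_symbol = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# edge list built directly from the truth block membership, for checks of
# the deterministic window arithmetic
truth_block_edges <- function(ds) {
  do.call(rbind, lapply(ds$truth$block_membership, function(bk) {
    data.frame(lnc_id = bk$lnc_id, mrna_symbol = bk$mrna_symbols,
               r = 1, p_value = 0, n_samples = 12, sign = "pos",
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

published_target_table <- function() {
  utils::read.delim(system.file("extdata", "nr038190_top30.tsv",
                                package = "lncscape"))
}
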