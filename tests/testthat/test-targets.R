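# Window rule, hypergeometric tail, and enrichment: oracle equality with
# brute-force enumeration/scans and null calibration.

test_that("genomic_distance handles overlap, gaps and chromosomes", {
  rec <- function(chrom, start, end) list(chrom = chrom, start = start,
                                          end = end)
  expect_equal(genomic_distance(rec("chr1", 100, 500),
                                rec("chr1", 400, 900)), 0L)
  expect_equal(genomic_distance(rec("chr1", 0, 1000),
                                rec("chr1", 301000, 302000)), 300000L)
  # symmetric and strand-agnostic
  expect_equal(genomic_distance(rec("chr1", 301000, 302000),
                                rec("chr1", 0, 1000)), 300000L)
  # half-open adjacency is distance 0
  expect_equal(genomic_distance(rec("chr1", 0, 100),
                                rec("chr1", 100, 200)), 0L)
  expect_true(is.na(genomic_distance(rec("chr1", 0, 10),
                                     rec("chr2", 0, 10))))
})

test_that("cis_assign honors the inclusive 300 kb boundary", {
  anno <- data.frame(
    chrom = "chr1",
    start = c(0L, 301000L, 301001L),
    end = c(1000L, 302000L, 302001L),
    name = c("L1", "M1", "M2"),
    score = "0", strand = "+",
    symbol = c("L1", "GENEA", "GENEB"),
    biotype = c("lncRNA", "mRNA", "mRNA"),
    stringsAsFactors = FALSE)
  edges <- data.frame(lnc_id = "L1", mrna_symbol = c("GENEA", "GENEB"),
                      r = 0.9, p_value = 0.001, n_samples = 12,
                      sign = "pos", stringsAsFactors = FALSE)
  res <- cis_assign(edges, anno, window_bp = 300000)
  expect_equal(res$mrna_symbol, "GENEA")       # gap 300000 retained
  expect_equal(res$distance_bp, 300000L)       # gap 300001 excluded
  # p filter applies
  edges$p_value <- c(0.001, 0.04)
  edges$mrna_symbol <- c("GENEA", "GENEA")
  res2 <- cis_assign(edges, anno, p_max = 0.01)
  expect_equal(nrow(res2), 1)
})

test_that("cis_assign skips unannotated endpoints with a count", {
  anno <- data.frame(chrom = "chr1", start = 0L, end = 1000L, name = "L1",
                     score = "0", strand = "+", symbol = "L1",
                     biotype = "lncRNA", stringsAsFactors = FALSE)
  edges <- data.frame(lnc_id = c("L1", "L2"), mrna_symbol = "GENEX",
                      r = 0.9, p_value = 0.001, n_samples = 12,
                      sign = "pos", stringsAsFactors = FALSE)
  res <- cis_assign(edges, anno)
  expect_equal(nrow(res), 0)
  expect_equal(attr(res, "n_skipped"), 2L)
})

test_that("cis_assign equals the brute-force all-pairs scan on synthetic data", {
  for (s in 1:5) {
    ds <- generate_dataset(desk_config(seed = s, n_lnc = 60, n_mrna = 150,
                                       n_blocks = 2))
    edges <- build_edges(ds$expression,
                         lnc_ids = ds$truth$de_lnc$lnc_id)
    got <- cis_assign(edges, ds$annotation)
    want <- cis_oracle(edges, ds$annotation)
    expect_setequal(paste(got$lnc_id, got$mrna_symbol, got$distance_bp),
                    paste(want$lnc_id, want$mrna_symbol, want$distance_bp))
  }
})

test_that("cis_assign on truth block pairs reproduces the planted cis pairs", {
  for (s in 1:5) {
    ds <- generate_dataset(desk_config(seed = s + 20))
    got <- cis_assign(truth_block_edges(ds), ds$annotation)
    want <- ds$truth$cis_pairs
    expect_setequal(paste(got$lnc_id, got$mrna_symbol, got$distance_bp),
                    paste(want$lnc_id, want$mrna_symbol, want$distance_bp))
  }
})

test_that("hypergeom_upper matches closed forms and validates bounds", {
  expect_equal(hypergeom_upper(5, 5, 5, 20), 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_upper(0, 5, 5, 20), 1)
  expect_error(hypergeom_upper(6, 5, 5, 20), "bounds")
  expect_error(hypergeom_upper(2, 25, 5, 20), "bounds")
})

test_that("hypergeom_upper equals brute-force enumeration at small N", {
  # literal enumeration over all C(N, n) draws
  for (case in list(c(3, 6, 7, 12), c(2, 4, 5, 10), c(1, 3, 3, 9))) {
    k <- case[1]; K <- case[2]; n <- case[3]; N <- case[4]
    draws <- combn(N, n)
    annotated <- seq_len(K)
    overlaps <- colSums(matrix(draws %in% annotated, nrow = n))
    expect_equal(hypergeom_upper(k, K, n, N), mean(overlaps >= k),
                 tolerance = 1e-12)
  }
})

test_that("hypergeometric tail properties hold across the parameter grid", {
  # distribution sums to 1; tail monotone in k; symmetric in (K, n)
  set.seed(7)
  for (i in 1:20) {
    N <- sample(10:200, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    ks <- 0:min(K, n)
    tails <- vapply(ks, hypergeom_upper, 1, K = K, n_query = n, N = N)
    expect_true(all(diff(tails) <= 1e-12))
    pmf <- c(tails[-length(tails)] - tails[-1], tails[length(tails)])
    expect_equal(sum(pmf), 1, tolerance = 1e-10)
    k <- sample(ks, 1)
    expect_equal(hypergeom_upper(k, K, n, N), hypergeom_upper(k, n, K, N),
                 tolerance = 1e-10)
    expect_equal(hypergeom_upper(k, K, n, N),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("trans_enrich finds the matched TF and handles the null", {
  ds <- generate_dataset(desk_config(seed = 12, tf_overlap = 1.0))
  edges <- build_edges(ds$expression, lnc_ids = ds$truth$de_lnc$lnc_id)
  universe <- intersect(na.omit(ds$expression$gene_symbol),
                        unique(unlist(ds$tf_sets$sets)))
  blk <- ds$truth$block_membership[[1]]
  matched <- names(ds$truth$tf_block_match)[
    ds$truth$tf_block_match == "block1"]
  res <- trans_enrich(blk$lnc_id, edges, ds$tf_sets, universe)
  expect_equal(res$set_id[1], matched)
  expect_lt(res$q_value[1], 0.05)
  # disjoint set -> k = 0 -> p = 1
  gs2 <- gene_sets(list(EMPTYOV = c("NOT1", "NOT2", universe[1])))
  res2 <- trans_enrich(blk$lnc_id, edges, gs2, universe)
  expect_equal(res2$k, 0)
  expect_equal(res2$p_value, 1)
  expect_error(trans_enrich(blk$lnc_id, edges, gs2, character()),
               "empty")
})

test_that("shuffled TF sets are calibrated (super-uniform p-values)", {
  set.seed(13)
  universe <- sprintf("GENE%05d", 1:400)
  ps <- unlist(lapply(1:20, function(s) {
    set.seed(s)
    sets <- setNames(lapply(1:8, function(i) sample(universe, 40)),
                     sprintf("TF%02d", 1:8))
    query <- sample(universe, 30)
    functional_enrich(query, gene_sets(sets), universe)$p_value
  }))
  frac <- mean(ps < 0.05)
  mc_se <- sqrt(0.05 * 0.95 / length(ps))
  expect_lte(frac, 0.05 + 2 * mc_se)
})

test_that("functional_enrich agrees with hypergeom_upper row by row", {
  set.seed(14)
  universe <- sprintf("G%03d", 1:60)
  gs <- gene_sets(list(S1 = sample(universe, 10),
                       S2 = sample(universe, 25),
                       S3 = c(sample(universe, 5), "OUTSIDE1")))
  query <- sample(universe, 12)
  res <- functional_enrich(query, gs, universe)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p_value[i],
                 hypergeom_upper(res$k[i], res$K[i], res$n_query[i],
                                 res$N[i]))
  }
  # members outside the universe are not counted in K
  expect_equal(res$K[res$set_id == "S3"], 5)
  # a query equal to a full set is maximally enriched for it
  res_full <- functional_enrich(gs$sets$S1, gs, universe)
  expect_equal(res_full$set_id[1], "S1")
  expect_equal(res_full$k[res_full$set_id == "S1"], 10)
})

test_that("tf_frequency counts significant lncRNAs per TF deterministically", {
  r1 <- data.frame(set_id = c("TF1", "TF2"), q_value = c(0.01, 0.2))
  r2 <- data.frame(set_id = c("TF1", "TF2"), q_value = c(0.03, 0.6))
  tab <- tf_frequency(list(L1 = r1, L2 = r2))
  expect_equal(tab$set_id, "TF1")
  expect_equal(tab$n_lnc, 2)
  expect_equal(nrow(tf_frequency(list(L1 = r1[0, ]))), 0)
  # ties ordered lexicographically
  r3 <- data.frame(set_id = c("TFB", "TFA"), q_value = c(0.01, 0.01))
  tab3 <- tf_frequency(list(L1 = r3))
  expect_equal(tab3$set_id, c("TFA", "TFB"))
})
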