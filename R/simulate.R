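#' Configuration of a synthetic paired tumor/normal study
#'
#' Defines every knob of the synthetic dataset generator. The defaults
#' emulate the study design the pipeline is built for: 6 patients with
#' paired tumor/normal arrays, separate lncRNA and mRNA probe families,
#' planted differential expression, planted lncRNA-mRNA co-expression
#' blocks with cis-proximal gene placement inside a 300 kb window, TF
#' target sets overlapping the blocks, a 42-patient qPCR/clinical cohort
#' and an exponential survival cohort with a group hazard ratio.
#'
#' @param n_patients number of tumor/normal pairs (default 6).
#' @param n_lnc,n_mrna numbers of lncRNA and mRNA probes. Desk-scale
#'   defaults; the array-scale design would use ~1e4 of each.
#' @param frac_de fraction of lncRNA probes with planted differential
#'   expression.
#' @param lfc_de mean absolute planted log2 fold change (magnitudes are
#'   jittered uniformly within +/- 25%).
#' @param noise_sd residual s.d. of log2 intensities.
#' @param n_blocks number of planted co-expression blocks (one lncRNA hub
#'   plus `block_size` mRNAs each).
#' @param block_size mRNA members per block.
#' @param block_r target within-block Pearson correlation (latent factor
#'   construction, see Details).
#' @param neg_frac fraction of block mRNAs with a negated factor loading
#'   (inverse co-expression).
#' @param cis_frac fraction of block mRNAs placed within `window_bp` of
#'   their hub lncRNA.
#' @param window_bp cis window in bp (default 300000).
#' @param n_tf number of TF target sets (>= `n_blocks`; the first
#'   `n_blocks` sets are matched to blocks).
#' @param tf_set_size members per TF set.
#' @param tf_overlap fraction of a block's mRNAs included in its matched TF
#'   set.
#' @param n_qpcr_genes number of validation qPCR genes (taken from the
#'   planted DE lncRNAs).
#' @param ct_noise_sd replicate-level Ct noise (cycles).
#' @param n_clinical patients in the qPCR/clinical cohort (default 42).
#' @param n_surv subjects in the survival cohort.
#' @param surv_hr hazard ratio of the low- over the high-expression group
#'   (> 1 means low expression does worse).
#' @param surv_median_days median survival of the high-expression group.
#' @param surv_censor_days administrative censoring horizon.
#' @param seed integer; single global seed, all sub-generators derive their
#'   streams from it (see [generate_dataset()]).
#'
#' @details Co-expression blocks use a single-factor Gaussian construction:
#' member j is `mu_j + s_j * lambda * u + eps` with a per-patient factor
#' `u` (shared by a patient's tumor and normal arrays) and
#' `lambda^2 = block_r * noise_sd^2 / (1 - block_r)`, so the expected
#' pairwise within-block correlation is `lambda^2 / (lambda^2 +
#' noise_sd^2) = block_r`. The hub lncRNA receives its planted DE effect
#' as a plain tumor-arm shift plus an enlarged factor loading chosen so
#' that its pooled correlation with the members also equals `block_r`
#' despite the extra between-arm variance; because the factor is
#' per-patient, paired tumor-minus-normal differences cancel it and the
#' hub's differential expression stays recoverable. Members carry no
#' planted DE, so blocks do not cross-correlate through the shared
#' tumor/normal separation.
#'
#' @return validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_patients = 6, n_lnc = 1000, n_mrna = 1000,
                              frac_de = 0.1, lfc_de = 2, noise_sd = 0.3,
                              n_blocks = 5, block_size = 20, block_r = 0.9,
                              neg_frac = 0.2, cis_frac = 0.5,
                              window_bp = 300000L, n_tf = 10,
                              tf_set_size = 40, tf_overlap = 0.8,
                              n_qpcr_genes = 9, ct_noise_sd = 0.2,
                              n_clinical = 42, n_surv = 200, surv_hr = 3,
                              surv_median_days = 1000,
                              surv_censor_days = 2000, seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(frac_de = frac_de, neg_frac = neg_frac, cis_frac = cis_frac,
             tf_overlap = tf_overlap)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (n_patients < 2) stop("need n_patients >= 2", call. = FALSE)
  if (block_r <= 0 || block_r >= 1) stop("block_r must be in (0, 1)",
                                         call. = FALSE)
  if (surv_hr <= 0) stop("surv_hr must be > 0", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (n_blocks * block_size > n_mrna) {
    stop("infeasible config: block members exceed n_mrna", call. = FALSE)
  }
  n_de <- round(frac_de * n_lnc)
  if (n_blocks > 0 && frac_de > 0 && n_blocks > n_de) {
    stop("infeasible config: more blocks than planted DE lncRNAs",
         call. = FALSE)
  }
  if (n_tf < n_blocks) stop("need n_tf >= n_blocks", call. = FALSE)
  if (n_blocks > 0 && n_tf > 0) {
    if (tf_set_size < ceiling(tf_overlap * block_size)) {
      stop("tf_set_size too small for the requested overlap", call. = FALSE)
    }
    n_fill <- tf_set_size - round(tf_overlap * block_size)
    if (n_fill > n_mrna - n_blocks * block_size) {
      stop("infeasible config: not enough non-block mRNAs to fill TF sets",
           call. = FALSE)
    }
  }
  if (n_tf > 0 && tf_set_size > n_mrna) {
    stop("tf_set_size exceeds n_mrna", call. = FALSE)
  }
  cfg$window_bp <- as.integer(window_bp)
  structure(cfg, class = "SimulationConfig")
}

# Documented seed-derivation scheme: stream k of global seed s is
# (|s| mod 1e5) * 20011 + k * 7919 + 1, always a positive 32-bit integer.
.derive_seed <- function(seed, stream) {
  as.integer((abs(as.integer(seed)) %% 100000L) * 20011 + stream * 7919 + 1)
}

.CHROMS <- paste0("chr", 1:5)
.CHROM_LEN <- 10000000L

# Place an interval of width w at gap d from anchor [s, e), on a random
# side (right if possible else left). Returns c(start, end).
.place_at_gap <- function(s, e, d, w, side) {
  if (side > 0) c(e + d, e + d + w) else c(s - d - w, s - d)
}

#' Generate a complete synthetic study dataset with its truth record
#'
#' Produces every artifact the pipeline consumes: the paired expression
#' matrix, BED-style genomic annotation on a small synthetic genome (5
#' chromosomes of 10 Mb), TF target gene sets, a clinical covariate table,
#' a qPCR Ct table for the clinical cohort, a survival table, and a
#' machine-readable truth record of everything planted. Deterministic given
#' `config$seed`; sub-generators (expression, annotation, TF sets,
#' clinical/qPCR, survival) use fixed derived streams of the global seed.
#'
#' @param config a [simulation_config()].
#' @return list of class `SyntheticDataset` with elements `expression`
#'   (an [expression_matrix()]), `annotation`, `tf_sets`, `clinical`,
#'   `qpcr`, `survival`, `truth` and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cf <- config
  lnc_ids <- sprintf("LNC%05d", seq_len(cf$n_lnc))
  mrna_ids <- sprintf("MRNA%05d", seq_len(cf$n_mrna))
  symbols <- sprintf("GENE%05d", seq_len(cf$n_mrna))
  patients <- sprintf("P%02d", seq_len(cf$n_patients))
  tumor_ids <- paste0(patients, "_T")
  normal_ids <- paste0(patients, "_N")
  sample_ids <- c(tumor_ids, normal_ids)
  is_tumor <- c(rep(TRUE, cf$n_patients), rep(FALSE, cf$n_patients))
  z <- ifelse(is_tumor, 0.5, -0.5)
  pat_of_sample <- rep(seq_len(cf$n_patients), 2)

  ## ---- expression (stream 1) ----
  set.seed(.derive_seed(cf$seed, 1))
  n_probes <- cf$n_lnc + cf$n_mrna
  probe_ids <- c(lnc_ids, mrna_ids)
  mu <- stats::rnorm(n_probes, 8, 1.5)
  values <- matrix(stats::rnorm(n_probes * length(sample_ids), 0,
                                cf$noise_sd),
                   nrow = n_probes,
                   dimnames = list(probe_ids, sample_ids)) + mu

  n_de <- round(cf$frac_de * cf$n_lnc)
  de_idx <- sort(sample.int(cf$n_lnc, n_de))
  de_sign <- sample(c(-1, 1), n_de, replace = TRUE)
  de_mag <- cf$lfc_de * stats::runif(n_de, 0.75, 1.25)
  de_effect <- de_sign * de_mag
  names(de_effect) <- lnc_ids[de_idx]

  # blocks: hub lncRNAs drawn from the planted DE set (or from all lncRNAs
  # when frac_de = 0)
  lambda_m <- cf$noise_sd * sqrt(cf$block_r / (1 - cf$block_r))
  if (cf$n_blocks > 0) {
    if (n_de > 0) {
      block_lnc_pos <- sample(de_idx, cf$n_blocks)
    } else {
      block_lnc_pos <- sample.int(cf$n_lnc, cf$n_blocks)
    }
    block_mrna_pos <- matrix(sample.int(cf$n_mrna,
                                        cf$n_blocks * cf$block_size),
                             nrow = cf$n_blocks)
  } else {
    block_lnc_pos <- integer()
    block_mrna_pos <- matrix(integer(), nrow = 0)
  }
  block_membership <- list()
  for (b in seq_len(cf$n_blocks)) {
    hub <- lnc_ids[block_lnc_pos[b]]
    eff <- if (hub %in% names(de_effect)) de_effect[[hub]] else 0
    # hub loading solves r(hub, member) = block_r given the hub's extra
    # between-arm variance eff^2/4 from its plain DE shift
    A <- eff^2 / 4 + cf$noise_sd^2
    B <- lambda_m^2 + cf$noise_sd^2
    lambda_h <- sqrt(cf$block_r^2 * A * B /
                       (lambda_m^2 - cf$block_r^2 * B))
    # factor conditioned to zero mean / unit variance across patients so
    # the realized block correlation concentrates at block_r even with
    # few patients
    u_pat <- as.vector(scale(stats::rnorm(cf$n_patients)))
    u <- u_pat[pat_of_sample]
    signs <- c(1, ifelse(stats::runif(cf$block_size - 1) < cf$neg_frac,
                         -1, 1))
    values[block_lnc_pos[b], ] <- values[block_lnc_pos[b], ] + lambda_h * u
    mem_rows <- cf$n_lnc + block_mrna_pos[b, ]
    values[mem_rows, ] <- values[mem_rows, ] + outer(signs * lambda_m, u)
    block_membership[[paste0("block", b)]] <- list(
      lnc_id = hub,
      mrna_symbols = symbols[block_mrna_pos[b, ]],
      signs = signs,
      effect = unname(eff))
  }
  # every planted DE lncRNA (hub or not) gets a plain tumor-arm shift
  if (n_de > 0) {
    values[de_idx, is_tumor] <- values[de_idx, is_tumor] +
      de_effect[lnc_ids[de_idx]]
  }
  pairing <- data.frame(patient_id = patients, tumor = tumor_ids,
                        normal = normal_ids, stringsAsFactors = FALSE)
  biotype <- stats::setNames(rep(c("lncRNA", "mRNA"),
                                 c(cf$n_lnc, cf$n_mrna)), probe_ids)
  gene_symbol <- stats::setNames(c(rep(NA_character_, cf$n_lnc), symbols),
                                 probe_ids)
  em <- expression_matrix(values, pairing, biotype, gene_symbol)

  ## ---- annotation (stream 2) ----
  set.seed(.derive_seed(cf$seed, 2))
  chrom <- sample(.CHROMS, n_probes, replace = TRUE)
  width <- c(sample(500:3000, cf$n_lnc, replace = TRUE),
             sample(1000:20000, cf$n_mrna, replace = TRUE))
  start <- vapply(width, function(w) sample.int(.CHROM_LEN - w, 1), 1L)
  end <- start + width
  cis_pairs <- list()
  for (b in seq_len(cf$n_blocks)) {
    hub_pos <- block_lnc_pos[b]
    # hub placed with margins so cis/non-cis placements stay on-chromosome
    hub_w <- width[hub_pos]
    hub_start <- sample(2000000:7000000, 1)
    chrom[hub_pos] <- sample(.CHROMS, 1)
    start[hub_pos] <- hub_start
    end[hub_pos] <- hub_start + hub_w
    members <- block_mrna_pos[b, ]
    n_cis <- round(cf$cis_frac * cf$block_size)
    cis_members <- if (n_cis > 0) members[seq_len(n_cis)] else integer()
    far_members <- setdiff(members, cis_members)
    for (m in cis_members) {
      row <- cf$n_lnc + m
      d <- sample(0:cf$window_bp, 1)
      side <- sample(c(-1, 1), 1)
      se <- .place_at_gap(start[hub_pos], end[hub_pos], d, width[row], side)
      chrom[row] <- chrom[hub_pos]
      start[row] <- se[1]
      end[row] <- se[2]
      cis_pairs[[length(cis_pairs) + 1]] <- data.frame(
        lnc_id = lnc_ids[hub_pos], mrna_symbol = symbols[m],
        distance_bp = as.integer(d), stringsAsFactors = FALSE)
    }
    # non-cis members: half beyond the window on the same chromosome,
    # half on another chromosome
    for (j in seq_along(far_members)) {
      m <- far_members[j]
      row <- cf$n_lnc + m
      if (j %% 2 == 1) {
        d <- sample((cf$window_bp + 1):(cf$window_bp + 1000000), 1)
        side <- sample(c(-1, 1), 1)
        se <- .place_at_gap(start[hub_pos], end[hub_pos], d, width[row],
                            side)
        chrom[row] <- chrom[hub_pos]
        start[row] <- se[1]
        end[row] <- se[2]
      } else {
        chrom[row] <- sample(setdiff(.CHROMS, chrom[hub_pos]), 1)
        start[row] <- sample.int(.CHROM_LEN - width[row], 1)
        end[row] <- start[row] + width[row]
      }
    }
  }
  annotation <- data.frame(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    name = probe_ids, score = "0",
    strand = sample(c("+", "-"), n_probes, replace = TRUE),
    symbol = unname(ifelse(is.na(gene_symbol), probe_ids, gene_symbol)),
    biotype = unname(biotype), stringsAsFactors = FALSE,
    row.names = NULL)
  cis_pairs <- if (length(cis_pairs)) do.call(rbind, cis_pairs) else
    data.frame(lnc_id = character(), mrna_symbol = character(),
               distance_bp = integer(), stringsAsFactors = FALSE)

  ## ---- TF target sets (stream 3) ----
  set.seed(.derive_seed(cf$seed, 3))
  tf_ids <- sprintf("TF%02d", seq_len(cf$n_tf))
  sets <- stats::setNames(list(), character())
  tf_block_match <- character()
  nonblock_sym <- setdiff(symbols, unlist(lapply(block_membership,
                                                 `[[`, "mrna_symbols")))
  for (i in seq_len(cf$n_tf)) {
    if (i <= cf$n_blocks) {
      blk <- block_membership[[i]]
      n_ov <- round(cf$tf_overlap * cf$block_size)
      core <- sample(blk$mrna_symbols, n_ov)
      fill <- sample(nonblock_sym, cf$tf_set_size - n_ov)
      sets[[tf_ids[i]]] <- sample(c(core, fill))
      tf_block_match[tf_ids[i]] <- names(block_membership)[i]
    } else {
      sets[[tf_ids[i]]] <- sample(symbols, cf$tf_set_size)
    }
  }
  tf_sets <- gene_sets(sets, stats::setNames(
    rep("synthetic TF target set", cf$n_tf), tf_ids))

  ## ---- clinical + qPCR cohort (stream 4) ----
  set.seed(.derive_seed(cf$seed, 4))
  qpcr_genes <- utils::head(names(de_effect), cf$n_qpcr_genes)
  cp <- sprintf("CP%03d", seq_len(cf$n_clinical))
  responder <- stats::rbinom(cf$n_clinical, 1, 0.85) == 1
  concordant <- stats::rbinom(cf$n_clinical, 1, 0.85) == 1
  n_class <- ifelse(responder == concordant, "N1-N2", "N0")
  clinical <- data.frame(
    patient_id = cp,
    age = pmin(80, pmax(40, round(stats::rnorm(cf$n_clinical, 60, 8)))),
    gender = sample(c("F", "M"), cf$n_clinical, replace = TRUE),
    smoking_index = sample(c("0", "1-400", ">400"), cf$n_clinical,
                           replace = TRUE),
    differentiation = sample(c("well", "moderate", "poor"), cf$n_clinical,
                             replace = TRUE),
    T_class = sample(c("T1", "T2", "T3"), cf$n_clinical, replace = TRUE),
    N_class = n_class,
    clinical_stage = ifelse(n_class == "N1-N2",
                            sample(c("II", "III"), cf$n_clinical,
                                   replace = TRUE),
                            sample(c("I", "II"), cf$n_clinical,
                                   replace = TRUE)),
    stringsAsFactors = FALSE)
  qpcr <- list()
  for (g in qpcr_genes) {
    eff <- de_effect[[g]]
    x_n <- stats::rnorm(cf$n_clinical, 8, 0.5)
    x_t <- x_n + ifelse(responder, eff, -0.3 * eff) +
      stats::rnorm(cf$n_clinical, 0, 0.1)
    for (tissue in c("tumor", "normal")) {
      x <- if (tissue == "tumor") x_t else x_n
      for (rep_i in 1:3) {
        qpcr[[length(qpcr) + 1]] <- data.frame(
          patient_id = cp, tissue = tissue, gene = g, replicate = rep_i,
          ct_target = 30 - x + stats::rnorm(cf$n_clinical, 0,
                                            cf$ct_noise_sd),
          ct_reference = 15 + stats::rnorm(cf$n_clinical, 0,
                                           cf$ct_noise_sd),
          stringsAsFactors = FALSE)
      }
    }
  }
  qpcr <- if (length(qpcr)) do.call(rbind, qpcr) else
    data.frame(patient_id = character(), tissue = character(),
               gene = character(), replicate = integer(),
               ct_target = numeric(), ct_reference = numeric())
  clinical_group <- stats::setNames(ifelse(responder, "up", "down"), cp)

  ## ---- survival cohort (stream 5) ----
  set.seed(.derive_seed(cf$seed, 5))
  sid <- sprintf("S%04d", seq_len(cf$n_surv))
  grp <- sample(rep(c("high", "low"), length.out = cf$n_surv))
  expr <- stats::rnorm(cf$n_surv, ifelse(grp == "high", 10, 6), 0.5)
  rate_high <- log(2) / cf$surv_median_days
  rate <- ifelse(grp == "low", cf$surv_hr * rate_high, rate_high)
  t_raw <- stats::rexp(cf$n_surv, rate)
  event <- as.integer(t_raw <= cf$surv_censor_days)
  surv <- data.frame(subject_id = sid,
                     time = round(pmin(t_raw, cf$surv_censor_days), 2),
                     event = event, expression = expr,
                     stringsAsFactors = FALSE)

  truth <- list(
    de_lnc = data.frame(lnc_id = names(de_effect),
                        effect = unname(de_effect),
                        stringsAsFactors = FALSE),
    block_membership = block_membership,
    cis_pairs = cis_pairs,
    tf_block_match = tf_block_match,
    surv_groups = stats::setNames(grp, sid),
    qpcr_genes = qpcr_genes,
    clinical_group = clinical_group)

  structure(list(expression = em, annotation = annotation,
                 tf_sets = tf_sets, clinical = clinical, qpcr = qpcr,
                 survival = surv, truth = truth, config = cf),
            class = "SyntheticDataset")
}

#' Simulate a validation qPCR table from an expression matrix
#'
#' Emulates qRT-PCR re-measurement of selected probes on the array cohort:
#' target Ct is linear in minus the log2 expression (one cycle per
#' doubling), the internal control gene contributes an approximately
#' constant reference Ct, and replicate noise is Gaussian on the cycle
#' scale. With `ct_noise_sd = 0` the 2^-ddCt ratio recomputed from the
#' table equals the linear tumor/normal expression ratio exactly.
#'
#' @param expression an [expression_matrix()].
#' @param reference_gene internal control; must be a gene symbol or probe
#'   id present in `expression`.
#' @param seed integer seed for the replicate noise.
#' @param genes probe ids to assay (default: first 9 probes).
#' @param ct_noise_sd replicate-level Ct noise, cycles (default 0.2).
#' @param n_replicates replicates per measurement (default 3).
#' @return data.frame with columns `patient_id`, `tissue`, `gene`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @export
generate_qpcr <- function(expression, reference_gene, seed = 1L,
                          genes = NULL, ct_noise_sd = 0.2,
                          n_replicates = 3) {
  stopifnot(inherits(expression, "ExpressionMatrix"))
  known <- c(rownames(expression$values),
             stats::na.omit(expression$gene_symbol))
  if (!reference_gene %in% known) {
    stop(sprintf("reference gene '%s' absent from the expression matrix",
                 reference_gene), call. = FALSE)
  }
  if (is.null(genes)) genes <- utils::head(rownames(expression$values), 9)
  missing <- setdiff(genes, rownames(expression$values))
  if (length(missing)) {
    stop("unknown probe id(s): ", paste(utils::head(missing, 5),
                                        collapse = ", "), call. = FALSE)
  }
  set.seed(as.integer(seed))
  pairing <- expression$pairing
  out <- list()
  for (g in genes) {
    for (tissue in c("tumor", "normal")) {
      sample_col <- if (tissue == "tumor") pairing$tumor else pairing$normal
      x <- expression$values[g, sample_col]
      for (rep_i in seq_len(n_replicates)) {
        out[[length(out) + 1]] <- data.frame(
          patient_id = pairing$patient_id, tissue = tissue, gene = g,
          replicate = rep_i,
          ct_target = 30 - x + stats::rnorm(length(x), 0, ct_noise_sd),
          ct_reference = 15 + stats::rnorm(length(x), 0, ct_noise_sd),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write every artifact of a synthetic dataset to a directory
#'
#' Writes `expression.tsv`, `pairing.tsv`, `annotation.bed`,
#' `tf_sets.gmt`, `clinical.tsv`, `qpcr.tsv`, `survival.tsv` in the
#' package's interchange dialects, plus `truth.json` with the planted
#' truth record.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of the written paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "SyntheticDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             pairing = file.path(dir, "pairing.tsv"),
             annotation = file.path(dir, "annotation.bed"),
             tf_sets = file.path(dir, "tf_sets.gmt"),
             clinical = file.path(dir, "clinical.tsv"),
             qpcr = file.path(dir, "qpcr.tsv"),
             survival = file.path(dir, "survival.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression_matrix(dataset$expression, paths["expression"],
                          paths["pairing"])
  write_annotation(dataset$annotation, paths["annotation"])
  write_gmt(dataset$tf_sets, paths["tf_sets"])
  for (nm in c("clinical", "qpcr", "survival")) {
    utils::write.table(dataset[[nm]], paths[nm], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  truth <- dataset$truth
  truth$surv_groups <- as.list(truth$surv_groups)
  truth$clinical_group <- as.list(truth$clinical_group)
  truth$tf_block_match <- as.list(truth$tf_block_match)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
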