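# Clinical arm: ddCt arithmetic, chi-square association, KM/log-rank and
# the median split.

meas <- function(ct_t, ct_r) data.frame(ct_target = ct_t,
                                        ct_reference = ct_r)

test_that("ddct reproduces hand arithmetic", {
  # dCt_T = 20 - 15 = 5, dCt_N = 22 - 15 = 7, ddCt = -2 -> ratio 4
  res <- ddct(meas(20, 15), meas(22, 15))
  expect_equal(res$ddct, -2)
  expect_equal(res$ratio, 4)
  # equal dCt -> ratio 1
  expect_equal(ddct(meas(21, 16), meas(20, 15))$ratio, 1)
  # ddCt = +1 -> one-cycle halving
  expect_equal(ddct(meas(21, 15), meas(20, 15))$ratio, 0.5)
  # replicates averaged first
  res3 <- ddct(meas(c(20, 20.2, 19.8), c(15, 15, 15)), meas(22, 15))
  expect_equal(res3$ratio, 4)
  expect_error(ddct(meas(20, NA), meas(22, 15)), "reference")
})

test_that("ddct is invariant only under shifts applied to both channels", {
  t0 <- meas(c(20, 20.4), c(15, 15.2))
  n0 <- meas(c(22, 21.8), c(15.1, 14.9))
  base <- ddct(t0, n0)$ratio
  # shift target and reference of the tumor sample together: unchanged
  t_both <- meas(t0$ct_target + 3, t0$ct_reference + 3)
  expect_equal(ddct(t_both, n0)$ratio, base)
  # shift only the target channel: changed
  t_tgt <- meas(t0$ct_target + 3, t0$ct_reference)
  expect_false(isTRUE(all.equal(ddct(t_tgt, n0)$ratio, base)))
})

test_that("noise-free simulated qPCR inverts to the expression ratio", {
  ds <- generate_dataset(desk_config(seed = 16, n_lnc = 40, n_mrna = 80,
                                     n_blocks = 1))
  em <- ds$expression
  sym <- na.omit(em$gene_symbol)[1]
  qp <- generate_qpcr(em, reference_gene = sym, seed = 2,
                      genes = rownames(em$values)[1:3], ct_noise_sd = 0)
  g <- rownames(em$values)[1]
  p1 <- em$pairing[1, ]
  r <- ddct(qp[qp$gene == g & qp$patient_id == p1$patient_id &
                 qp$tissue == "tumor", ],
            qp[qp$gene == g & qp$patient_id == p1$patient_id &
                 qp$tissue == "normal", ])$ratio
  expect_equal(r, 2^(em$values[g, p1$tumor] - em$values[g, p1$normal]),
               tolerance = 1e-12)
  # doubling expression lowers Ct by one cycle at noise 0
  em2 <- em
  em2$values[g, p1$tumor] <- em2$values[g, p1$tumor] + 1
  qp2 <- generate_qpcr(em2, reference_gene = sym, seed = 2,
                       genes = g, ct_noise_sd = 0)
  ct1 <- qp[qp$gene == g & qp$tissue == "tumor" &
              qp$patient_id == p1$patient_id, "ct_target"][1]
  ct2 <- qp2[qp2$gene == g & qp2$tissue == "tumor" &
               qp2$patient_id == p1$patient_id, "ct_target"][1]
  expect_equal(ct2 - ct1, -1)
  expect_error(generate_qpcr(em, reference_gene = "ABSENT"), "absent")
})

test_that("noisy qPCR recovers planted log2 ratios across 40 genes", {
  ds <- generate_dataset(desk_config(seed = 17, n_lnc = 60, n_mrna = 80,
                                     n_blocks = 1))
  em <- ds$expression
  genes <- rownames(em$values)[1:40]
  qp <- generate_qpcr(em, reference_gene = na.omit(em$gene_symbol)[1],
                      seed = 3, genes = genes, ct_noise_sd = 0.2)
  arms <- paired_arms(em)
  truth_lfc <- rowMeans(arms$tumor - arms$normal)[genes]
  rec_lfc <- vapply(genes, function(g) {
    sub <- qp[qp$gene == g, ]
    mean(vapply(unique(sub$patient_id), function(p) {
      ddct(sub[sub$patient_id == p & sub$tissue == "tumor", ],
           sub[sub$patient_id == p & sub$tissue == "normal", ])$ddct
    }, 1))
  }, 1)
  expect_gt(cor(-rec_lfc, truth_lfc), 0.9)
})

test_that("expression_group classifies pairs with the tie convention", {
  expect_equal(expression_group(4, 2), "up")
  expect_warning(g <- expression_group(c(2, 5), c(2, 1)), "tie")
  expect_equal(g, c("down", "up"))
})

test_that("chi-square association matches closed forms", {
  # diagonal 2x2 table
  g <- rep(c("up", "down"), each = 10)
  cl <- rep(c("N1", "N0"), each = 10)
  res <- chi_square_association(g, cl)
  expect_equal(res$chi2, 20)
  expect_equal(res$dof, 1)
  expect_equal(res$p_value, pchisq(20, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$p_value, 7.74e-6, tolerance = 1e-2)
  # independence
  g2 <- rep(c("up", "down"), 10)
  cl2 <- rep(c("N1", "N1", "N0", "N0"), 5)
  res2 <- chi_square_association(g2, cl2)
  expect_equal(res2$chi2, 0)
  expect_equal(res2$p_value, 1)
  # closed-form (ad-bc)^2 N / margins identity on random 2x2 tables
  set.seed(19)
  for (i in 1:10) {
    tab <- matrix(sample(5:30, 4), 2)
    g3 <- rep(rep(c("a", "b"), each = 2), times = as.vector(t(tab)))
    c3 <- rep(rep(c("x", "y"), 2), times = as.vector(t(tab)))
    res3 <- suppressWarnings(chi_square_association(g3, c3))
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    chi_closed <- (a * d - b * cc)^2 * n /
      ((a + b) * (cc + d) * (a + cc) * (b + d))
    expect_equal(res3$chi2, chi_closed, tolerance = 1e-10)
  }
  # degenerate margins rejected; label permutation invariance
  expect_error(chi_square_association(rep("up", 5), rep(c("x", "y"),
                                                        c(2, 3))),
               "degenerate")
  res4 <- chi_square_association(rev(g), rev(cl))
  expect_equal(res4$p_value, res$p_value)
})

test_that("km_estimate reproduces the product-limit arithmetic", {
  # all events at distinct times: S = 2/3, 1/3, 0
  km <- km_estimate(data.frame(time = c(1, 2, 3), event = 1))
  expect_equal(km$survival, c(1, 2/3, 1/3, 0))
  expect_equal(km$time, c(0, 1, 2, 3))
  # censoring only: S = 1 throughout
  km2 <- km_estimate(data.frame(time = c(5, 8), event = 0))
  expect_true(all(km2$survival == 1))
  # worked 6-subject fixture with censoring, computed by hand:
  # times 1(event) 2(cens) 3(event) 4(event) 5(cens) 6(event)
  # S: 5/6, then 5/6 * 3/4 = 0.625, * 2/3 = 5/12, * 0 at t=6
  km3 <- km_estimate(data.frame(time = 1:6,
                                event = c(1, 0, 1, 1, 0, 1)))
  ev <- km3[km3$n_event > 0, ]
  expect_equal(ev$survival, c(5/6, 5/6 * 3/4, 5/6 * 3/4 * 2/3, 0),
               tolerance = 1e-12)
  # no-censoring KM equals the empirical survival function
  set.seed(23)
  tt <- rexp(50)
  km4 <- km_estimate(data.frame(time = tt, event = 1))
  emp <- vapply(km4$time, function(t) mean(tt > t), 1)
  expect_equal(km4$survival, emp, tolerance = 1e-12)
  expect_error(km_estimate(data.frame(time = numeric(),
                                      event = integer())), "empty")
})

test_that("log_rank is symmetric, null on identical groups, powered at HR 3", {
  g <- data.frame(time = c(1, 3, 5, 7), event = c(1, 1, 0, 1))
  same <- log_rank(g, g)
  expect_equal(same$chi2, 0, tolerance = 1e-10)
  expect_equal(same$p_value, 1, tolerance = 1e-6)
  set.seed(29)
  a <- data.frame(time = rexp(40, 1), event = 1)
  b <- data.frame(time = rexp(40, 2.5), event = 1)
  expect_equal(log_rank(a, b)$chi2, log_rank(b, a)$chi2, tolerance = 1e-10)
  # power at the generator's default hazard ratio, 100 subjects per arm
  rej <- vapply(1:20, function(s) {
    ds <- generate_dataset(desk_config(seed = s + 100, n_lnc = 20, n_mrna = 120,
                                       n_blocks = 1,
                                       n_surv = 200))
    sr <- survival_by_median_split(ds$survival)
    sr$p_value < 0.01
  }, TRUE)
  expect_gte(mean(rej), 0.95)
})

test_that("median_split follows the strict-above rule and recovers truth", {
  expect_equal(unname(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_warning(all_low <- median_split(c(2, 2, 2)), "degenerate")
  expect_equal(unname(all_low), rep("low", 3))
  expect_error(median_split(1), ">= 2")
  # planted bimodal survival cohort: split recovers truth groups
  ds <- generate_dataset(desk_config(seed = 31, n_lnc = 20, n_mrna = 120,
                                     n_blocks = 1))
  grp <- median_split(setNames(ds$survival$expression,
                               ds$survival$subject_id))
  expect_equal(unname(grp), unname(ds$truth$surv_groups[names(grp)]))
})

test_that("null log-rank rejects at the nominal rate", {
  set.seed(37)
  rej <- vapply(1:500, function(i) {
    grp <- sample(rep(c("a", "b"), 30))
    tt <- rexp(60, log(2) / 1000)
    ev <- as.integer(tt <= 2000)
    tt <- pmin(tt, 2000)
    log_rank(data.frame(time = tt[grp == "a"], event = ev[grp == "a"]),
             data.frame(time = tt[grp == "b"], event = ev[grp == "b"]))$
      p_value < 0.05
  }, TRUE)
  mc_se <- sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(mean(rej) - 0.05), 2.5 * mc_se)
})

test_that("noise-free qPCR group vector matches the planted DE signs", {
  ds <- generate_dataset(desk_config(seed = 41, n_lnc = 60, n_mrna = 80,
                                     n_blocks = 1, ct_noise_sd = 0))
  # clinical-cohort qPCR at noise 0: responders mirror the planted sign
  qp <- ds$qpcr
  g <- ds$truth$qpcr_genes[1]
  eff <- ds$truth$de_lnc$effect[ds$truth$de_lnc$lnc_id == g]
  sub <- qp[qp$gene == g, ]
  pats <- unique(sub$patient_id)
  grp <- vapply(pats, function(p) {
    r <- ddct(sub[sub$patient_id == p & sub$tissue == "tumor", ],
              sub[sub$patient_id == p & sub$tissue == "normal", ])$ratio
    if (r > 1) "up" else "down"
  }, "")
  truth_dir <- ifelse(ds$truth$clinical_group[pats] == "up",
                      ifelse(eff > 0, "up", "down"),
                      ifelse(eff > 0, "down", "up"))
  expect_gte(mean(grp == truth_dir), 0.95)
})
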