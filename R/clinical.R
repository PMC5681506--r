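#' Relative expression by the 2^-ddCt method
#'
#' Replicates are averaged first; per tissue, dCt = mean target Ct minus
#' mean reference Ct; ddCt = dCt(tumor) - dCt(normal); the returned relative
#' expression is 2^-ddCt (tumor over normal, reference-normalized).
#'
#' @param tumor,normal data.frames of Ct measurements with columns
#'   `ct_target` and `ct_reference` (rows = replicates).
#' @return list with `ratio` (2^-ddCt), `ddct`, `dct_tumor`, `dct_normal`.
#' @export
ddct <- function(tumor, normal) {
  for (tab in list(tumor, normal)) {
    if (!all(c("ct_target", "ct_reference") %in% names(tab))) {
      stop("measurements need ct_target and ct_reference columns",
           call. = FALSE)
    }
    if (!nrow(tab)) stop("need >= 1 replicate per tissue", call. = FALSE)
    if (anyNA(tab$ct_reference)) stop("missing reference Ct", call. = FALSE)
  }
  dct_t <- mean(tumor$ct_target) - mean(tumor$ct_reference)
  dct_n <- mean(normal$ct_target) - mean(normal$ct_reference)
  dd <- dct_t - dct_n
  list(ratio = 2^(-dd), ddct = dd, dct_tumor = dct_t, dct_normal = dct_n)
}

#' Classify paired tumor/normal expression as up or down
#'
#' `up` when the tumor value exceeds the normal value; ties are classed
#' `down` with a warning (vectorized).
#'
#' @param tumor_value,normal_value paired numeric vectors.
#' @return character vector of `"up"`/`"down"`.
#' @export
expression_group <- function(tumor_value, normal_value) {
  stopifnot(length(tumor_value) == length(normal_value))
  ties <- tumor_value == normal_value
  if (any(ties)) {
    warning(sprintf("%d tie(s) classed 'down'", sum(ties)), call. = FALSE)
  }
  ifelse(tumor_value > normal_value, "up", "down")
}

#' Pearson chi-square association between expression group and a
#' clinicopathological factor
#'
#' Builds the R x C contingency table of `groups` against
#' `clinical_category` and applies the Pearson chi-square test without
#' continuity correction; dof = (R-1)(C-1). A warning is logged when any
#' expected cell count falls below 5.
#'
#' @param groups factor-like per-patient classification (e.g. up/down).
#' @param clinical_category factor-like per-patient covariate.
#' @return list with `chi2`, `dof`, `p_value` and the contingency `table`.
#' @export
chi_square_association <- function(groups, clinical_category) {
  stopifnot(length(groups) == length(clinical_category))
  tab <- table(groups, clinical_category)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("degenerate contingency table: need >= 2 non-empty levels in each margin",
         call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    warning("expected count < 5 in at least one cell; chi-square approximation may be poor",
            call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), dof = unname(res$parameter),
       p_value = unname(res$p.value), table = tab)
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Right-censoring is handled; the returned step function starts at
#' S(0) = 1 and is non-increasing. Thin wrapper over
#' [survival::survfit()].
#'
#' @param group data.frame with columns `time` (days, >= 0) and `event`
#'   (1 = death, 0 = censored).
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(group) {
  if (!nrow(group)) stop("empty survival group", call. = FALSE)
  stopifnot(all(c("time", "event") %in% names(group)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = group)
  data.frame(time = c(0, fit$time),
             n_risk = c(fit$n, fit$n.risk),
             n_event = c(0, fit$n.event),
             survival = c(1, fit$surv))
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on 1 degree of freedom via
#' [survival::survdiff()].
#'
#' @param a,b data.frames with columns `time` and `event`.
#' @return list with `chi2` and `p_value`.
#' @export
log_rank <- function(a, b) {
  if (!nrow(a) || !nrow(b)) stop("both groups must be non-empty",
                                 call. = FALSE)
  dat <- rbind(data.frame(time = a$time, event = a$event, grp = "a"),
               data.frame(time = b$time, event = b$event, grp = "b"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = dat)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1,
                                            lower.tail = FALSE))
}

#' Median split of an expression vector into high/low groups
#'
#' `high` strictly above the median; values at or below the median
#' (including exact ties at the median) are `low`. A degenerate all-equal
#' vector yields all `low` with a warning.
#'
#' @param values numeric vector, >= 2 subjects; names are preserved.
#' @return character vector of `"high"`/`"low"`.
#' @export
median_split <- function(values) {
  if (length(values) < 2) stop("need >= 2 subjects", call. = FALSE)
  med <- stats::median(values)
  out <- ifelse(values > med, "high", "low")
  if (all(out == "low")) {
    warning("degenerate split: no value above the median", call. = FALSE)
  }
  names(out) <- names(values)
  out
}

#' Median-split survival comparison
#'
#' Splits subjects into high/low expression groups at the median and
#' compares their survival with the log-rank test; also returns both KM
#' curves.
#'
#' @param surv data.frame with columns `subject_id`, `time`, `event`,
#'   `expression` (see [read_survival()]).
#' @return list with `groups` (named character vector), `km_high`,
#'   `km_low` (see [km_estimate()]), `chi2`, `p_value`.
#' @export
survival_by_median_split <- function(surv) {
  grp <- median_split(stats::setNames(surv$expression, surv$subject_id))
  hi <- surv[grp == "high", , drop = FALSE]
  lo <- surv[grp == "low", , drop = FALSE]
  lr <- log_rank(hi, lo)
  list(groups = grp, km_high = km_estimate(hi), km_low = km_estimate(lo),
       chi2 = lr$chi2, p_value = lr$p_value)
}
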