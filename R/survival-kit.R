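#' Kaplan-Meier estimate
#'
#' Product-limit estimate of the survival function, via
#' [survival::survfit()]. Input with only censored observations gives a flat
#' curve at 1.
#'
#' @param time Positive follow-up times (days).
#' @param event Logical; `TRUE` if the endpoint (progression/death) was
#'   observed, `FALSE` if censored.
#' @return A tibble of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (non-increasing, in (0, 1]).
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("km_estimate() needs at least one observation", call. = FALSE)
  stopifnot(length(time) == length(event), all(time > 0))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "none")
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        surv = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' Median survival time from a Kaplan-Meier curve
#'
#' The smallest observed time at which the estimated survival drops to 0.5
#' or below (the "<= 0.5" convention, so a curve touching 0.5 exactly
#' reports the earlier time). `NA` ("not reached") if the curve never
#' reaches 0.5.
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @return Median time in days, or `NA_real_` if not reached.
#' @export
median_survival <- function(curve) {
  hit <- which(curve$surv <= 0.5 + 1e-12)
  if (length(hit) == 0L) return(NA_real_)
  curve$time[hit[1L]]
}

# Weighted two-sample test for right-censored data (the G-family with
# arbitrary event-time weights). Returns the group-A observed-minus-expected
# sum alongside the chi-square statistic so callers can read off direction.
weighted_survtest <- function(time, event, in_a,
                              weight = c("logrank", "gehan", "peto")) {
  weight <- match.arg(weight)
  stopifnot(length(time) == length(event), length(time) == length(in_a))
  if (!any(in_a) || all(in_a)) stop("both groups must be non-empty", call. = FALSE)
  event <- as.logical(event)
  n <- length(time)

  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; a_s <- in_a[ord]

  # distinct event times with per-group event and at-risk counts
  ut <- unique(t_s[e_s])
  if (length(ut) == 0L) {
    return(list(statistic = 0, p_value = 1, oe_a = 0, var = 0,
                test_name = if (weight == "logrank") "logrank" else "gehan_wilcoxon"))
  }
  # at risk just before each distinct event time
  n_risk  <- n - findInterval(ut - 1e-9, t_s)
  n_riskA <- sum(a_s) - vapply(ut, function(tt) sum(a_s & t_s < tt - 1e-9), numeric(1))
  d  <- vapply(ut, function(tt) sum(e_s & abs(t_s - tt) < 1e-9), numeric(1))
  dA <- vapply(ut, function(tt) sum(e_s & a_s & abs(t_s - tt) < 1e-9), numeric(1))

  w <- switch(weight,
    logrank = rep(1, length(ut)),
    gehan = n_risk,
    peto = {
      # left-continuous pooled survival estimate (Peto-Peto modification)
      s <- cumprod(1 - d / (n_risk + 1))
      c(1, s[-length(s)])
    })

  exp_a <- d * n_riskA / n_risk
  keep <- n_risk > 1
  v <- d * (n_riskA / n_risk) * (1 - n_riskA / n_risk) * (n_risk - d) / (n_risk - 1)
  v[!keep] <- 0
  oe <- sum(w * (dA - exp_a))
  vv <- sum(w^2 * v)
  if (vv <= 0) {
    stat <- 0; p <- 1
  } else {
    stat <- oe^2 / vv
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, p_value = p, oe_a = oe, var = vv,
       test_name = if (weight == "logrank") "logrank" else "gehan_wilcoxon")
}

two_sample_result <- function(res, time, event, in_a, test_name) {
  med_a <- median_survival(km_estimate(time[in_a], event[in_a]))
  med_b <- median_survival(km_estimate(time[!in_a], event[!in_a]))
  structure(list(statistic = res$statistic, p_value = res$p_value,
                 test_name = test_name, oe_a = res$oe_a,
                 group_medians = c(a = med_a, b = med_b)),
            class = "two_sample_test")
}

#' Two-sample survival tests
#'
#' `logrank_test()` is the standard (unweighted) log-rank test;
#' `gehan_wilcoxon_test()` is the generalized Wilcoxon test for censored
#' data with Gehan-Breslow weighting (each event time weighted by the total
#' number at risk), which up-weights early differences; the Peto-Peto
#' variant (weights = left-continuous pooled Kaplan-Meier estimate) is
#' available via `variant = "peto"`. Both return a 1-df chi-square
#' statistic, a two-sided p-value, the observed-minus-expected event sum for
#' group A (positive when group A fares worse), and the Kaplan-Meier median
#' of each group (`NA` = not reached).
#'
#' @param time,event Follow-up times and event indicators for all patients.
#' @param in_a Logical: membership in group A.
#' @param variant For the Wilcoxon-type test, `"gehan"` (default,
#'   at-risk-count weights) or `"peto"`.
#' @return A `two_sample_test` list: `statistic`, `p_value`, `test_name`,
#'   `oe_a`, `group_medians`.
#' @export
logrank_test <- function(time, event, in_a) {
  res <- weighted_survtest(time, event, in_a, "logrank")
  two_sample_result(res, time, event, in_a, "logrank")
}

#' @rdname logrank_test
#' @export
gehan_wilcoxon_test <- function(time, event, in_a, variant = c("gehan", "peto")) {
  variant <- match.arg(variant)
  res <- weighted_survtest(time, event, in_a, variant)
  two_sample_result(res, time, event, in_a, "gehan_wilcoxon")
}

survtest_fun <- function(test = c("gehan_wilcoxon", "logrank")) {
  test <- match.arg(test)
  if (test == "logrank") logrank_test else gehan_wilcoxon_test
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wrapper around
#' [stats::p.adjust()] with `method = "BH"`), kept as a named operation
#' because every screen in the package routes through it.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' ROC AUC with Hanley-McNeil confidence interval and null test
#'
#' The AUC is the pairwise concordance probability (ties credited 0.5): the
#' probability that a randomly chosen positive-class observation scores
#' higher than a randomly chosen negative-class one. Orientation is fixed by
#' the caller: `positive` marks the class that higher scores are expected to
#' predict (in this package, higher risk score <-> no durable benefit). The
#' confidence interval uses the Hanley-McNeil standard error with a normal
#' approximation, and the null test is a two-sided z-test of AUC = 0.5.
#'
#' @param scores Numeric predictor values.
#' @param positive Logical class labels (`TRUE` = positive class).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A `roc_result` list: `auc`, `ci_low`, `ci_high`, `null_p`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, positive, conf_level = 0.95) {
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
               (n1 * n0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_eff <- max(se, .Machine$double.eps)
  structure(list(
    auc = auc,
    ci_low = max(0, auc - z * se),
    ci_high = min(1, auc + z * se),
    null_p = 2 * stats::pnorm(-abs(auc - 0.5) / se_eff),
    n_pos = n1, n_neg = n0, se = se
  ), class = "roc_result")
}

#' Minimum-p-value cutoff scan for a survival biomarker
#'
#' Scans candidate cutoffs of a continuous predictor from low to high,
#' stratifies patients at each candidate, and selects the cutoff giving the
#' smallest two-group survival-test p-value. Candidates are midpoints
#' between consecutive distinct predictor values whose split leaves at least
#' `min_group` patients in each arm. Ties in minimal p resolve to the
#' smallest candidate. The reported p-values are the raw scan p-values (not
#' adjusted for the multiplicity of the scan); interpret `chosen_p` as a
#' selection criterion, not a calibrated significance level.
#'
#' @param values Predictor values (one per patient).
#' @param time,event Survival endpoint used for stratification.
#' @param min_group Minimum patients per arm for an admissible split (default 3).
#' @param test `"gehan_wilcoxon"` (default) or `"logrank"`.
#' @return A `cutoff_result` list: `cutoff`, `chosen_p`, and `p_profile`
#'   (tibble of `candidate`, `n_below`, `n_above`, `p`).
#' @export
ward_cutoff_scan <- function(values, time, event, min_group = 3L,
                             test = c("gehan_wilcoxon", "logrank")) {
  test <- match.arg(test)
  stopifnot(length(values) == length(time), length(time) == length(event))
  if (length(values) < 2L * min_group) {
    stop("need at least 2 * min_group patients for a cutoff scan", call. = FALSE)
  }
  sv <- sort(unique(values))
  if (length(sv) < 2L) stop("predictor values are all equal; no admissible cutoff", call. = FALSE)
  cand <- (sv[-1] + sv[-length(sv)]) / 2
  n_below <- vapply(cand, function(cc) sum(values < cc), integer(1))
  ok <- n_below >= min_group & (length(values) - n_below) >= min_group
  if (!any(ok)) stop("no admissible candidate cutoff (min_group too large)", call. = FALSE)
  cand <- cand[ok]; n_below <- n_below[ok]
  tf <- survtest_fun(test)
  p <- vapply(cand, function(cc) tf(time, event, values < cc)$p_value, numeric(1))
  best <- which.min(p) # which.min takes the first (= smallest candidate) on ties
  structure(list(
    cutoff = cand[best],
    chosen_p = p[best],
    test = test,
    p_profile = tibble::tibble(candidate = cand, n_below = n_below,
                               n_above = length(values) - n_below, p = p)
  ), class = "cutoff_result")
}
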