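test_that("Kaplan-Meier estimate matches hand product-limit computation", {
  # {5 censored, 10 event, 15 event}: S(10) = 1 * (1 - 1/2) = 0.5, S(15) = 0
  curve <- km_estimate(c(5, 10, 15), c(FALSE, TRUE, TRUE))
  expect_equal(curve$surv[curve$time == 10], 0.5)
  expect_equal(curve$surv[curve$time == 15], 0)
  expect_true(all(diff(curve$surv) <= 1e-12))

  # all censored: flat at 1
  flat <- km_estimate(c(3, 7, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(flat$surv == 1))

  # single event: step from 1 to 0
  single <- km_estimate(42, TRUE)
  expect_equal(single$surv, 0)
  expect_equal(single$time, 42)

  # without censoring the KM curve is the empirical survival function
  set.seed(3)
  tt <- sample(1:100, 20)
  curve2 <- km_estimate(tt, rep(TRUE, 20))
  ecdf_surv <- vapply(curve2$time, function(x) mean(tt > x), numeric(1))
  expect_equal(curve2$surv, ecdf_surv)

  expect_error(km_estimate(numeric(0), logical(0)), "at least one")
})

test_that("median survival follows the <= 0.5 convention", {
  curve <- km_estimate(c(5, 10, 15), c(FALSE, TRUE, TRUE))
  expect_equal(median_survival(curve), 10)
  expect_true(is.na(median_survival(km_estimate(c(3, 7), c(FALSE, FALSE)))))
  # symmetric 2-event curve hits 0.5 exactly at the first event time
  sym <- km_estimate(c(10, 20), c(TRUE, TRUE))
  expect_equal(median_survival(sym), 10)
})

test_that("two-sample tests: degenerate inputs, symmetry, and direction", {
  time <- c(10, 20, 30, 40, 50, 60)
  event <- rep(TRUE, 6)
  grp <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)

  # identical groups: statistic 0, p 1
  same <- logrank_test(rep(time, 2), rep(event, 2), rep(c(TRUE, FALSE), each = 6))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # label swap leaves p unchanged
  a <- logrank_test(time, event, grp)
  b <- logrank_test(time, event, !grp)
  expect_equal(a$p_value, b$p_value)
  g1 <- gehan_wilcoxon_test(time, event, grp)
  g2 <- gehan_wilcoxon_test(time, event, !grp)
  expect_equal(g1$p_value, g2$p_value)

  # group A with early events has positive observed-minus-expected (worse)
  expect_gt(a$oe_a, 0)
  expect_equal(unname(a$group_medians), c(20, 50))

  # a group with zero events still yields a finite statistic
  z <- logrank_test(c(5, 6, 7, 50, 60), c(TRUE, TRUE, TRUE, FALSE, FALSE),
                    c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(is.finite(z$statistic))

  expect_error(logrank_test(time, event, rep(TRUE, 6)), "non-empty")
})

test_that("logrank agrees exactly with survival::survdiff", {
  set.seed(7)
  for (r in 1:5) {
    n <- 40
    time <- sample(1:365, n, replace = TRUE)
    event <- runif(n) < 0.8
    grp <- runif(n) < 0.5
    if (!any(grp) || all(grp)) next
    mine <- logrank_test(time, event, grp)
    ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(mine$statistic, unname(ref$chisq), tolerance = 1e-10)
    expect_equal(mine$p_value,
                 stats::pchisq(ref$chisq, df = 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("gehan and logrank coincide when all events fall at one time", {
  # single event time: every weighting reduces to the same 2x2 comparison
  time <- c(10, 10, 10, 25, 30, 40)
  event <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  grp <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  lr <- logrank_test(time, event, grp)
  gw <- gehan_wilcoxon_test(time, event, grp)
  expect_equal(lr$p_value, gw$p_value, tolerance = 1e-12)
  expect_equal(lr$statistic, gw$statistic, tolerance = 1e-12)
})

test_that("asymptotic p stays in the same ballpark as the exact permutation p", {
  # small-sample envelope: the chi-square approximation is known to be loose
  # on a coarse permutation lattice (documented limitation); assert sanity,
  # not asymptotic-level agreement
  set.seed(11)
  for (r in 1:6) {
    n <- sample(6:8, 1)
    time <- sample(1:40, n)
    event <- runif(n) < 0.8
    in_a <- rep(FALSE, n); in_a[sample(n, n %/% 2)] <- TRUE
    for (w in c("logrank", "gehan")) {
      p_asym <- tmindex:::weighted_survtest(time, event, in_a, w)$p_value
      p_perm <- perm_survtest_p(time, event, in_a, w)
      expect_lt(abs(p_asym - p_perm), 0.2)
    }
  }
  # the permutation oracle itself is exact on a no-signal configuration:
  # all event times equal -> every assignment gives statistic 0 -> p = 1
  expect_equal(perm_survtest_p(rep(10, 6), rep(TRUE, 6),
                               rep(c(TRUE, FALSE), 3), "logrank"), 1)
})

test_that("bh_adjust matches brute-force step-up and its invariants", {
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(5)
  for (r in 1:20) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_bruteforce(p))
    expect_true(all(adj >= p - 1e-12))
    # adjusting already-adjusted values never lowers them
    expect_true(all(bh_adjust(adj) >= adj - 1e-12))
    # monotone in the order statistics
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("roc_auc equals pair counting and handles edge cases", {
  perfect <- roc_auc(c(1, 2, 3, 10, 11, 12), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(perfect$auc, 1)
  expect_true(perfect$ci_low <= perfect$auc && perfect$auc <= perfect$ci_high)

  ties <- roc_auc(rep(3, 8), rep(c(TRUE, FALSE), 4))
  expect_equal(ties$auc, 0.5)
  expect_gt(ties$null_p, 0.9)

  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")

  set.seed(9)
  for (r in 1:30) {
    n <- sample(4:20, 1)
    scores <- sample(1:8, n, replace = TRUE)
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    res <- roc_auc(scores, labels)
    expect_equal(res$auc, auc_pairs(scores, labels))
    expect_true(res$ci_low <= res$auc && res$auc <= res$ci_high)
  }
})

test_that("roc_auc agrees with pROC on the AUC value", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- rnorm(40)
  labels <- runif(40) < 0.4
  mine <- roc_auc(scores, labels)
  ref <- suppressMessages(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                              direction = "<", quiet = TRUE)))
  expect_equal(mine$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("ward cutoff scan equals the exhaustive brute-force scan", {
  brute <- function(values, time, event, min_group, test) {
    sv <- sort(unique(values))
    cands <- (sv[-1] + sv[-length(sv)]) / 2
    tf <- if (test == "logrank") logrank_test else gehan_wilcoxon_test
    best <- NULL
    for (cc in cands) {
      lo <- sum(values < cc)
      if (lo < min_group || length(values) - lo < min_group) next
      p <- tf(time, event, values < cc)$p_value
      if (is.null(best) || p < best$p - 1e-15) best <- list(cutoff = cc, p = p)
    }
    best
  }
  set.seed(21)
  for (r in 1:10) {
    n <- sample(12:30, 1)
    values <- sample(1:12, n, replace = TRUE)
    if (length(unique(values)) < 2) next
    time <- sample(1:300, n, replace = TRUE)
    event <- runif(n) < 0.8
    for (test in c("gehan_wilcoxon", "logrank")) {
      ref <- brute(values, time, event, 3, test)
      if (is.null(ref)) {
        expect_error(ward_cutoff_scan(values, time, event, 3, test), "admissible")
      } else {
        scan <- ward_cutoff_scan(values, time, event, 3, test)
        expect_equal(scan$chosen_p, ref$p)
        expect_equal(scan$cutoff, ref$cutoff)
        expect_equal(scan$chosen_p, min(scan$p_profile$p))
      }
    }
  }
})

test_that("ward cutoff scan degenerate inputs are rejected or resolved", {
  # only one admissible candidate: it is returned
  values <- c(1, 1, 1, 5, 5, 5)
  time <- c(10, 20, 30, 100, 110, 120)
  scan <- ward_cutoff_scan(values, time, rep(TRUE, 6), min_group = 3)
  expect_equal(scan$cutoff, 3)
  expect_equal(nrow(scan$p_profile), 1L)

  expect_error(ward_cutoff_scan(rep(2, 8), 1:8, rep(TRUE, 8)), "all equal")
  expect_error(ward_cutoff_scan(1:4, 1:4, rep(TRUE, 4), min_group = 3), "2 \\* min_group")
})
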