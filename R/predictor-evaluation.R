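#' Demographic subgroup membership
#'
#' The ten demographic subgroups used for composition and subgroup-response
#' analysis: male, female, smoking, non-smoking, LUAD, LUSC, driver-gene
#' positive, driver-gene negative, more than 3 metastases, 3 or fewer
#' metastases. Every patient belongs to exactly one subgroup of each of the
#' five dichotomies.
#'
#' @param clinical Clinical tibble.
#' @return Logical matrix, one row per patient, one column per subgroup.
#' @export
subgroup_membership <- function(clinical) {
  m <- cbind(
    male = clinical$gender == "M",
    female = clinical$gender == "F",
    smoking = clinical$smoking,
    nonsmoking = !clinical$smoking,
    LUAD = clinical$pathology == "LUAD",
    LUSC = clinical$pathology == "LUSC",
    driver_positive = clinical$driver_positive,
    driver_negative = !clinical$driver_positive,
    mets_gt3 = clinical$metastases > 3,
    mets_le3 = clinical$metastases <= 3
  )
  rownames(m) <- clinical$patient_id
  m
}

eval_one_group <- function(clinical, values, responder, os_median, test_fn,
                           min_group) {
  n_resp <- sum(responder); n_non <- sum(!responder)
  row <- tibble::tibble(n_responder = n_resp, n_nonresponder = n_non,
                        evaluable = FALSE,
                        km_pfs_p = NA_real_, km_os_p = NA_real_,
                        auc_pfs = NA_real_, null_p_pfs = NA_real_,
                        auc_os = NA_real_, null_p_os = NA_real_)
  if (n_resp < min_group || n_non < min_group) return(row)

  benefit <- classify_benefit(clinical$pfs_days, clinical$pfs_event,
                              clinical$intolerance)
  lab_pfs <- benefit == "NDB"             # poor PFS outcome class
  det_pfs <- benefit %in% c("NDB", "DCB")
  lab_os <- clinical$os_days <= os_median # short-survivor class
  res <- tryCatch({
    km_pfs <- test_fn(clinical$pfs_days, clinical$pfs_event, responder)
    km_os <- test_fn(clinical$os_days, clinical$os_event, responder)
    roc_pfs <- if (sum(lab_pfs & det_pfs) > 0 && sum(!lab_pfs & det_pfs) > 0) {
      roc_auc(values[det_pfs], lab_pfs[det_pfs])
    } else NULL
    roc_os <- if (sum(lab_os) > 0 && sum(!lab_os) > 0) {
      roc_auc(values, lab_os)
    } else NULL
    list(km_pfs = km_pfs, km_os = km_os, roc_pfs = roc_pfs, roc_os = roc_os)
  }, error = function(e) NULL)
  if (is.null(res) || is.null(res$roc_pfs) || is.null(res$roc_os)) return(row)

  row$evaluable <- TRUE
  row$km_pfs_p <- res$km_pfs$p_value
  row$km_os_p <- res$km_os$p_value
  row$auc_pfs <- res$roc_pfs$auc
  row$null_p_pfs <- res$roc_pfs$null_p
  row$auc_os <- res$roc_os$auc
  row$null_p_os <- res$roc_os$null_p
  row
}

#' Subgroup response evaluation of a predictor
#'
#' For the full cohort ("overall") and each of the ten demographic
#' subgroups, compares predictor responders against non-responders:
#' Kaplan-Meier two-sample p-values for PFS and OS, and ROC AUC (with
#' null-test p) of the predictor values against the poor-outcome class (no
#' durable benefit for PFS; OS at or below the cohort median for OS,
#' computed on the evaluation cohort). A subgroup with fewer than
#' `min_group` patients in either arm, or with an outcome class absent, is
#' marked not evaluable and carries `NA` statistics.
#'
#' @param clinical Clinical tibble for the evaluation cohort.
#' @param values Predictor values, aligned with `clinical` rows (higher =
#'   higher risk).
#' @param responder Logical responder classification, aligned with rows.
#' @param min_group Minimum patients per arm (default 3).
#' @param test `"gehan_wilcoxon"` (default) or `"logrank"`.
#' @return Tibble with one row per group (`overall` + 10 subgroups):
#'   `subgroup`, `n_responder`, `n_nonresponder`, `evaluable`, `km_pfs_p`,
#'   `km_os_p`, `auc_pfs`, `null_p_pfs`, `auc_os`, `null_p_os`.
#' @export
subgroup_evaluation <- function(clinical, values, responder, min_group = 3L,
                                test = c("gehan_wilcoxon", "logrank")) {
  test <- match.arg(test)
  stopifnot(nrow(clinical) == length(values), length(values) == length(responder))
  test_fn <- survtest_fun(test)
  os_median <- stats::median(clinical$os_days)
  member <- subgroup_membership(clinical)
  groups <- c("overall", colnames(member))
  rows <- lapply(groups, function(g) {
    idx <- if (g == "overall") rep(TRUE, nrow(clinical)) else member[, g]
    eval_one_group(clinical[idx, , drop = FALSE], values[idx], responder[idx],
                   os_median, test_fn, min_group)
  })
  dplyr::bind_cols(tibble::tibble(subgroup = groups), dplyr::bind_rows(rows))
}

#' Evaluate a predictor on a discovery cohort
#'
#' Determines the responder rule for a predictor and evaluates it overall
#' and per subgroup. For continuous burden-type predictors (and the TMI),
#' the cutoff is chosen by the minimum-p-value scan ([ward_cutoff_scan()])
#' on PFS and responders are patients strictly below it. For the UMS, the
#' rule is fixed: negative score (below `highrisk_min`) = responder.
#'
#' @param clinical Discovery-cohort clinical tibble.
#' @param values Predictor values aligned with `clinical` rows.
#' @param name Predictor name (e.g. `"GS_MB"`).
#' @param type `"burden"` (cutoff scan; also used for TMI) or `"ums"`
#'   (negative/positive rule).
#' @param min_group Minimum arm size for the scan and subgroup evaluation.
#' @param test Survival test for the scan and subgroup evaluation.
#' @param highrisk_min UMS positivity threshold (default 1).
#' @return A `predictor_eval` list: `name`, `type`, `cutoff` (`NA` for
#'   UMS), `highrisk_min`, `scan` (the `cutoff_result`, or `NULL`),
#'   `subgroups` (from [subgroup_evaluation()]).
#' @export
evaluate_predictor <- function(clinical, values, name, type = c("burden", "ums"),
                               min_group = 3L,
                               test = c("gehan_wilcoxon", "logrank"),
                               highrisk_min = 1L) {
  type <- match.arg(type)
  test <- match.arg(test)
  scan <- NULL
  if (type == "burden") {
    scan <- ward_cutoff_scan(values, clinical$pfs_days, clinical$pfs_event,
                             min_group = min_group, test = test)
    cutoff <- scan$cutoff
  } else {
    cutoff <- NA_real_
  }
  eval <- structure(list(name = name, type = type, cutoff = cutoff,
                         highrisk_min = highrisk_min, scan = scan),
                    class = "predictor_eval")
  responder <- classify_responder(eval, values)
  eval$subgroups <- subgroup_evaluation(clinical, values, responder,
                                        min_group = min_group, test = test)
  eval
}

#' Responder classification under a frozen predictor rule
#'
#' Applies a predictor evaluation's frozen rule to (possibly new) predictor
#' values: strictly below the cutoff for burden-type predictors, below
#' `highrisk_min` (i.e. negative) for the UMS.
#'
#' @param eval A `predictor_eval`.
#' @param values Predictor values.
#' @return Logical responder status.
#' @export
classify_responder <- function(eval, values) {
  if (eval$type == "ums") values < eval$highrisk_min else values < eval$cutoff
}
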