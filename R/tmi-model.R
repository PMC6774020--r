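#' Clinical benefit classification
#'
#' Classifies each patient's response by progression-free survival: `NB`
#' (no benefit) for progression within 45 days or drug intolerance; `NDB`
#' (no durable benefit) for progression after 45 but within 130 days;
#' `DCB` (durable clinical benefit) for benefit lasting beyond 130 days —
#' including patients censored beyond 130 days with response ongoing.
#' Patients censored at or before 130 days cannot be assigned
#' (`indeterminate`): they are excluded from benefit-labelled analyses such
#' as ROC labels, but still receive burden and TMI scores.
#'
#' @param pfs_days Positive PFS times in days.
#' @param pfs_event Logical; `TRUE` if progression was observed.
#' @param intolerance Logical; `TRUE` if therapy was stopped for
#'   intolerance (classified `NB`).
#' @return Character vector with values `"NB"`, `"NDB"`, `"DCB"`,
#'   `"indeterminate"`.
#' @export
classify_benefit <- function(pfs_days, pfs_event, intolerance = FALSE) {
  stopifnot(all(pfs_days > 0))
  n <- length(pfs_days)
  intolerance <- rep_len(intolerance, n)
  pfs_event <- rep_len(as.logical(pfs_event), n)
  out <- rep("indeterminate", n)
  out[pfs_days > 130] <- "DCB"
  out[pfs_event & pfs_days > 45 & pfs_days <= 130] <- "NDB"
  out[(pfs_event & pfs_days <= 45) | intolerance] <- "NB"
  out
}

#' Significance points for a Kaplan-Meier comparison
#'
#' The score-card rule for survival-curve p-values: p < 0.001 scores 3,
#' p < 0.01 scores 2, p < 0.05 scores 1, otherwise 0.
#'
#' @param p P-value(s) in \[0, 1\] (`NA` scores 0).
#' @return Integer points in 0..3.
#' @export
significance_points <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]", call. = FALSE)
  pts <- ifelse(is.na(p), 0L, (p < 0.05) + (p < 0.01) + (p < 0.001))
  as.integer(pts)
}

#' AUC points for an ROC analysis
#'
#' The score-card rule for ROC results: an AUC above 0.7 scores 1 point,
#' and the null-hypothesis test p-value against AUC = 0.5 scores
#' significance-style points (1 / 2 / 3 below 0.05 / 0.01 / 0.001); the two
#' contributions add.
#'
#' @param auc AUC value(s) in \[0, 1\] (`NA` scores 0).
#' @param null_p Null-hypothesis test p-value(s).
#' @return Integer points in 0..4.
#' @export
auc_points <- function(auc, null_p) {
  if (any(auc < 0 | auc > 1, na.rm = TRUE)) stop("auc must lie in [0, 1]", call. = FALSE)
  pts <- ifelse(is.na(auc), 0L, as.integer(auc > 0.7)) +
    ifelse(is.na(null_p), 0L, significance_points(null_p))
  as.integer(pts)
}

#' Baseline responder points for one predictor
#'
#' A patient on the responder side of a predictor (burden or TMI strictly
#' below its cutoff; UMS negative) scores 50 baseline points for that
#' predictor; otherwise 0.
#'
#' @param responder Logical vector from [classify_responder()].
#' @return Integer vector of 0/50.
#' @export
predictor_baseline_points <- function(responder) {
  as.integer(ifelse(as.logical(responder), 50L, 0L))
}

#' Subgroup points for one predictor
#'
#' For each patient, the sum over their five matching demographic subgroups
#' (one from each dichotomy: gender, smoking status, pathology, driver-gene
#' status, metastasis count) of the subgroup's score-card points:
#' significance points for the subgroup Kaplan-Meier PFS and OS p-values
#' plus AUC points for the subgroup PFS and OS ROC results. Points are
#' awarded only to patients classified responder by the predictor, and the
#' per-predictor sum is capped at `cap` (default 50) so that three
#' predictors contribute at most 300 total together with the baseline
#' points. Not-evaluable subgroups contribute 0.
#'
#' @param clinical Clinical tibble (rows aligned with `responder`).
#' @param eval A `predictor_eval` from [evaluate_predictor()].
#' @param responder Logical responder status per patient.
#' @param cap Maximum subgroup points per predictor (default 50).
#' @return Integer vector of subgroup points.
#' @export
subgroup_points <- function(clinical, eval, responder, cap = 50L) {
  sg <- eval$subgroups[eval$subgroups$subgroup != "overall", , drop = FALSE]
  pts_per_subgroup <- ifelse(
    sg$evaluable,
    significance_points(sg$km_pfs_p) + significance_points(sg$km_os_p) +
      auc_points(sg$auc_pfs, sg$null_p_pfs) + auc_points(sg$auc_os, sg$null_p_os),
    0L)
  names(pts_per_subgroup) <- sg$subgroup
  member <- subgroup_membership(clinical)
  common <- intersect(colnames(member), names(pts_per_subgroup))
  raw <- as.vector(member[, common, drop = FALSE] %*% pts_per_subgroup[common])
  as.integer(ifelse(as.logical(responder), pmin(cap, raw), 0L))
}

#' TMI score cards
#'
#' Builds the six-component score card per patient from three predictor
#' evaluations (germline+somatic burden `GS_MB`, nonsynonymous+synonymous
#' burden `NS_MB`, and `UMS`): a baseline 0/50 responder score and a capped
#' subgroup score for each predictor. The six values are summed and
#' homogenized to the Tumor Mutation Index,
#' `TMI = 100 * (300 - total) / 300`, a strictly decreasing affine map of
#' the total with TMI(0) = 100 and TMI(300) = 0, so *low* TMI marks likely
#' responders. TMI is kept unrounded here; round to one decimal for
#' reporting.
#'
#' @param clinical Clinical tibble, one row per patient to score.
#' @param values Tibble with `patient_id` and one column per predictor
#'   (`GS_MB`, `NS_MB`, `UMS`) holding the patient's predictor values.
#' @param evals Named list of the three `predictor_eval` objects
#'   (names `GS_MB`, `NS_MB`, `UMS`).
#' @param cap Subgroup-point cap per predictor (default 50).
#' @return Tibble with columns `patient_id`, `bl_<pred>` and `sub_<pred>`
#'   for each predictor, `total` (0..300) and `tmi` (0..100).
#' @export
tmi_scorecards <- function(clinical, values, evals, cap = 50L) {
  stopifnot(all(c("GS_MB", "NS_MB", "UMS") %in% names(evals)))
  clinical <- dplyr::semi_join(clinical, values, by = "patient_id")
  values <- values[match(clinical$patient_id, values$patient_id), , drop = FALSE]
  out <- tibble::tibble(patient_id = clinical$patient_id)
  total <- integer(nrow(out))
  for (pred in c("GS_MB", "NS_MB", "UMS")) {
    resp <- classify_responder(evals[[pred]], values[[pred]])
    bl <- predictor_baseline_points(resp)
    sub <- subgroup_points(clinical, evals[[pred]], resp, cap = cap)
    out[[paste0("bl_", tolower(sub("_MB", "", pred)))]] <- bl
    out[[paste0("sub_", tolower(sub("_MB", "", pred)))]] <- sub
    total <- total + bl + sub
  }
  out$total <- total
  out$tmi <- tmi_from_total(total)
  out
}

#' Homogenize a total score to the TMI scale
#'
#' @param total Summed six-component score(s) in \[0, 300\].
#' @return `100 * (300 - total) / 300`.
#' @export
tmi_from_total <- function(total) {
  if (any(total < 0 | total > 300)) stop("total score must lie in [0, 300]", call. = FALSE)
  100 * (300 - total) / 300
}

#' Classify patients by TMI cutoff
#'
#' `low` (responder side) iff TMI is strictly below the cutoff; a TMI equal
#' to the cutoff is `high`.
#'
#' @param tmi Unrounded TMI values.
#' @param cutoff Cutoff from a TMI cutoff scan.
#' @return Character vector `"low"`/`"high"`.
#' @export
tmi_classify <- function(tmi, cutoff) {
  ifelse(tmi < cutoff, "low", "high")
}

#' Combined TMI + IDH1 exon-4 classifier
#'
#' A patient is `unfavorable` only when classed high-TMI *and* carrying an
#' IDH1 exon-4 mutation; every other combination is `favorable` (high-TMI
#' patients without the mutation respond well, so TMI alone over-excludes).
#'
#' @param tmi_class `"low"`/`"high"` from [tmi_classify()].
#' @param idh1_exon4_mutant Logical IDH1 exon-4 mutation status.
#' @return Character vector `"favorable"`/`"unfavorable"`.
#' @export
combined_tmi_idh1 <- function(tmi_class, idh1_exon4_mutant) {
  ifelse(tmi_class == "high" & as.logical(idh1_exon4_mutant),
         "unfavorable", "favorable")
}
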