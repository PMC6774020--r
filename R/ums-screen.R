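#' Screen baseline mutations for unfavorable survival effect
#'
#' Tests every baseline mutation carried by at least one but not all
#' patients against PFS: patients are split into carriers ("positive") and
#' non-carriers ("negative") and compared with a two-sample survival test
#' (Gehan-Breslow Wilcoxon by default, matching discovery-phase usage).
#' P-values are adjusted across all tested mutations by the
#' Benjamini-Hochberg method, and mutations with adjusted p below `alpha`
#' whose carriers have *worse* survival (direction check via the sign of the
#' carriers' observed-minus-expected event sum) are retained as unfavorable.
#' Thresholding on the raw p instead of the adjusted p is available via
#' `adjust = "raw"` since reported mutation counts in the field are
#' sometimes quoted against the unadjusted scale.
#'
#' Mutation carriage is defined on the germline+somatic retained set
#' (`in_gs`) of the baseline sample.
#'
#' @param calls Filtered calls (from [apply_call_filters()]).
#' @param clinical Clinical tibble with `patient_id`, `pfs_days`,
#'   `pfs_event`; only these patients enter the screen (>= 2 required).
#' @param alpha Retention threshold (default 0.01).
#' @param test `"gehan_wilcoxon"` (default) or `"logrank"`.
#' @param adjust `"BH"` (default; threshold the adjusted p) or `"raw"`.
#' @param direction_filter Keep only mutations whose carriers fare worse
#'   (default `TRUE`).
#' @return A tibble of class `ums_set`, sorted by adjusted then raw p:
#'   columns `key`, `gene`, `raw_p`, `adjusted_p`, `carriers`, `worse`.
#'   Attributes: `alpha`, `n_tested`, `test`, `adjust`, `status`
#'   (`"ok"` or `"no_splittable_mutations"`).
#' @export
screen_unfavorable_mutations <- function(calls, clinical, alpha = 0.01,
                                         test = c("gehan_wilcoxon", "logrank"),
                                         adjust = c("BH", "raw"),
                                         direction_filter = TRUE) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  if (is.null(attr(calls, "filters"))) {
    stop("calls must be passed through apply_call_filters() first", call. = FALSE)
  }
  if (nrow(clinical) < 2L) stop("need at least 2 patients to screen", call. = FALSE)
  n <- nrow(clinical)

  bl <- calls[calls$timepoint == "BL" & calls$in_gs &
                calls$patient_id %in% clinical$patient_id, , drop = FALSE]
  carriage <- unique(bl[, c("key", "gene", "patient_id")])
  tally <- dplyr::summarise(dplyr::group_by(carriage, .data$key, .data$gene),
                            carriers = dplyr::n(), .groups = "drop")
  splittable <- tally[tally$carriers >= 1L & tally$carriers < n, , drop = FALSE]

  empty <- tibble::tibble(key = character(), gene = character(),
                          raw_p = numeric(), adjusted_p = numeric(),
                          carriers = integer(), worse = logical())
  if (nrow(splittable) == 0L) {
    warning("no splittable mutations: every mutation is carried by 0 or all patients",
            call. = FALSE)
    return(structure(empty, alpha = alpha, n_tested = 0L, test = test,
                     adjust = adjust, status = "no_splittable_mutations",
                     class = c("ums_set", class(empty))))
  }

  time <- clinical$pfs_days
  event <- clinical$pfs_event
  pid <- clinical$patient_id
  carriers_of <- split(carriage$patient_id, carriage$key)

  raw_p <- numeric(nrow(splittable))
  worse <- logical(nrow(splittable))
  for (j in seq_len(nrow(splittable))) {
    in_a <- pid %in% carriers_of[[splittable$key[j]]]
    res <- weighted_survtest(time, event, in_a,
                             if (test == "logrank") "logrank" else "gehan")
    raw_p[j] <- res$p_value
    worse[j] <- res$oe_a > 0 # carriers had more events than expected
  }
  adjusted_p <- bh_adjust(raw_p)
  out <- tibble::tibble(key = splittable$key, gene = splittable$gene,
                        raw_p = raw_p, adjusted_p = adjusted_p,
                        carriers = splittable$carriers, worse = worse)
  thr <- if (adjust == "BH") out$adjusted_p else out$raw_p
  keep <- thr < alpha & (!direction_filter | out$worse)
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$adjusted_p, out$raw_p, out$key), , drop = FALSE]
  structure(out, alpha = alpha, n_tested = nrow(splittable), test = test,
            adjust = adjust, status = "ok",
            class = c("ums_set", class(empty)))
}

#' Unfavorable Mutation Score
#'
#' The UMS of a patient is the number of distinct mutations from the
#' screened unfavorable set carried at baseline; every unfavorable mutation
#' has equal weight 1 (a patient carrying 10 of them scores 10). Patients
#' are grouped as `negative` (score below `highrisk_min`, default:
#' score 0) or `positive`.
#'
#' @param calls Filtered calls with baseline samples.
#' @param ums_set A `ums_set` from [screen_unfavorable_mutations()], or any
#'   tibble with a `key` column.
#' @param patients Patient ids to score (default: all with a BL sample in
#'   `calls`).
#' @param highrisk_min Minimum score for the `positive` group (default 1,
#'   so the two groups partition the cohort; set 2 to reproduce a
#'   "more than 1 mutation" high-risk reading).
#' @return Tibble with columns `patient_id`, `score`, `group`.
#' @export
ums_score <- function(calls, ums_set, patients = NULL, highrisk_min = 1L) {
  if (is.null(attr(calls, "filters"))) {
    stop("calls must be passed through apply_call_filters() first", call. = FALSE)
  }
  bl <- calls[calls$timepoint == "BL" & calls$in_gs, , drop = FALSE]
  if (is.null(patients)) patients <- sort(unique(bl$patient_id))
  carried <- unique(bl[bl$key %in% ums_set$key, c("patient_id", "key")])
  counts <- table(factor(carried$patient_id, levels = patients))
  score <- as.integer(counts[patients])
  score[is.na(score)] <- 0L
  tibble::tibble(patient_id = patients, score = score,
                 group = ifelse(score >= highrisk_min, "positive", "negative"))
}
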