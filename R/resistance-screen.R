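#' Acquired mutations between baseline and progression
#'
#' Compares a patient's baseline (BL) and progression-of-disease (PD)
#' profiles and reports the mutations acquired at PD: the set difference
#' PD \ BL by mutation key, restricted to nonsynonymous records with HIGH
#' effect in the somatic retained set. Presence is defined post-filter: a
#' mutation below the filters at BL but above them at PD counts as
#' acquired.
#'
#' @param calls Filtered calls (from [apply_call_filters()]) containing the
#'   patient's BL and PD samples.
#' @param patient_id The patient to analyse.
#' @return An `acquired_report` list: `patient_id`, `acquired` (tibble of
#'   `key`, `gene`), `per_gene_counts` (named integer vector).
#' @export
acquired_mutation_set <- function(calls, patient_id) {
  if (is.null(attr(calls, "filters"))) {
    stop("calls must be passed through apply_call_filters() first", call. = FALSE)
  }
  sub <- calls[calls$patient_id == patient_id, , drop = FALSE]
  if (nrow(sub) == 0L && !patient_id %in% calls$patient_id) {
    stop("no samples for patient ", patient_id, call. = FALSE)
  }
  eligible <- sub$in_nonsyn & sub$effect_class == "HIGH"
  bl_keys <- unique(sub$key[eligible & sub$timepoint == "BL"])
  pd <- sub[eligible & sub$timepoint == "PD", , drop = FALSE]
  pd <- pd[!duplicated(pd$key), , drop = FALSE]
  acq <- pd[!pd$key %in% bl_keys, c("key", "gene"), drop = FALSE]
  counts <- table(acq$gene)
  structure(list(patient_id = patient_id,
                 acquired = tibble::as_tibble(acq),
                 per_gene_counts = stats::setNames(as.integer(counts), names(counts))),
            class = "acquired_report")
}

#' Per-gene acquired-mutation frequencies in a subgroup
#'
#' For a collection of acquired-mutation reports, the fraction of subgroup
#' patients with at least one acquired mutation in each gene (denominator =
#' subgroup size).
#'
#' @param reports List of `acquired_report` objects.
#' @param subgroup_ids Character vector of patient ids forming the subgroup
#'   (non-empty); reports for other patients are ignored.
#' @return Tibble with columns `gene`, `n_patients`, `frequency`.
#' @export
acquired_gene_frequencies <- function(reports, subgroup_ids) {
  if (length(subgroup_ids) == 0L) stop("subgroup must be non-empty", call. = FALSE)
  reports <- Filter(function(r) r$patient_id %in% subgroup_ids, reports)
  gene_patient <- unique(dplyr::bind_rows(lapply(reports, function(r) {
    if (nrow(r$acquired) == 0L) return(NULL)
    tibble::tibble(patient_id = r$patient_id, gene = unique(r$acquired$gene))
  })))
  if (is.null(gene_patient) || nrow(gene_patient) == 0L) {
    return(tibble::tibble(gene = character(), n_patients = integer(),
                          frequency = numeric()))
  }
  out <- dplyr::summarise(dplyr::group_by(gene_patient, .data$gene),
                          n_patients = dplyr::n(), .groups = "drop")
  out$frequency <- out$n_patients / length(subgroup_ids)
  dplyr::arrange(out, dplyr::desc(.data$frequency), .data$gene)
}

#' Baseline no-benefit exclusion flag
#'
#' Flags a patient whose baseline profile carries at least one mutation from
#' the ARID1A/BRCA2 resistance panel (exact key match). Patients flagged at
#' baseline are those likely to receive no benefit from anlotinib.
#'
#' @param calls Filtered calls containing the patient's BL sample.
#' @param patient_id Patient to screen.
#' @param panel Resistance panel tibble (default
#'   [default_resistance_panel()]); must be non-empty, with a `key` column.
#' @return List: `flagged` (logical), `matched_keys` (character).
#' @export
nb_exclusion_flag <- function(calls, patient_id, panel = default_resistance_panel()) {
  if (nrow(panel) == 0L) stop("resistance panel must be non-empty", call. = FALSE)
  if (is.null(attr(calls, "filters"))) {
    stop("calls must be passed through apply_call_filters() first", call. = FALSE)
  }
  bl <- calls[calls$patient_id == patient_id & calls$timepoint == "BL" & calls$in_gs, ,
              drop = FALSE]
  matched <- intersect(unique(bl$key), panel$key)
  list(flagged = length(matched) > 0L, matched_keys = matched)
}

#' Screen every patient's baseline profile against the resistance panel
#'
#' @inheritParams nb_exclusion_flag
#' @param patients Character vector of patient ids to screen.
#' @return Tibble with columns `patient_id`, `flagged`, `matched_keys`
#'   (list-column).
#' @export
nb_exclusion_screen <- function(calls, patients, panel = default_resistance_panel()) {
  res <- lapply(patients, function(p) nb_exclusion_flag(calls, p, panel))
  tibble::tibble(patient_id = patients,
                 flagged = vapply(res, `[[`, logical(1), "flagged"),
                 matched_keys = lapply(res, `[[`, "matched_keys"))
}
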