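#' Pipeline run configuration
#'
#' Collects every threshold and decision flag of the end-to-end analysis so
#' a run is fully reproducible from its manifest.
#'
#' @param discovery_fraction Fraction of the analysis cohort allocated to
#'   discovery (default 62/85; set 1 to evaluate on the full cohort with no
#'   held-out validation set).
#' @param min_depth,germline_vaf_threshold,panel Filter-chain parameters
#'   (see [apply_call_filters()]).
#' @param alpha UMS screening threshold (default 0.01).
#' @param ums_adjust `"BH"` or `"raw"` (see
#'   [screen_unfavorable_mutations()]).
#' @param highrisk_min UMS positivity threshold (default 1).
#' @param min_group Minimum arm size for cutoff scans and subgroup
#'   evaluation (default 3).
#' @param discovery_test Survival test used for discovery-phase screens and
#'   burden cutoff scans (default `"gehan_wilcoxon"`, the generalized
#'   Wilcoxon used while assembling the score card).
#' @param tmi_test Survival test used for the TMI cutoff scan and TMI
#'   stratification (default `"logrank"`, the test reported for TMI-based
#'   Kaplan-Meier comparisons).
#' @param validation_test Survival test used for validation stratification
#'   (default `"logrank"`).
#' @param subgroup_cap Subgroup-point cap per predictor (default 50).
#' @param resistance_panel Baseline resistance panel (default
#'   [default_resistance_panel()]).
#' @param discovery_ids Optional character vector pinning the discovery
#'   split; otherwise the split is drawn at random using `seed`.
#' @param seed Integer seed for the split.
#' @return A `run_config` list.
#' @export
run_config <- function(discovery_fraction = 62 / 85,
                       min_depth = 100L,
                       germline_vaf_threshold = 0.20,
                       panel = panel_genes_168(),
                       alpha = 0.01,
                       ums_adjust = "BH",
                       highrisk_min = 1L,
                       min_group = 3L,
                       discovery_test = "gehan_wilcoxon",
                       tmi_test = "logrank",
                       validation_test = "logrank",
                       subgroup_cap = 50L,
                       resistance_panel = default_resistance_panel(),
                       discovery_ids = NULL,
                       seed = 1L) {
  if (!(discovery_fraction > 0 && discovery_fraction <= 1)) {
    stop("discovery_fraction must lie in (0, 1]", call. = FALSE)
  }
  structure(list(discovery_fraction = discovery_fraction, min_depth = min_depth,
                 germline_vaf_threshold = germline_vaf_threshold, panel = panel,
                 alpha = alpha, ums_adjust = ums_adjust,
                 highrisk_min = highrisk_min, min_group = min_group,
                 discovery_test = discovery_test, tmi_test = tmi_test,
                 validation_test = validation_test,
                 subgroup_cap = subgroup_cap, resistance_panel = resistance_panel,
                 discovery_ids = discovery_ids, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the discovery analysis
#'
#' Orchestrates the full discovery pipeline on a cohort: filter the calls,
#' compute baseline burdens, classify clinical benefit, exclude no-benefit
#' patients (screening their baseline profiles against the ARID1A/BRCA2
#' resistance panel and reporting the concordance), split the remaining
#' patients into discovery and validation cohorts, screen unfavorable
#' mutations and score the UMS, evaluate the three predictors (G+S MB,
#' N+S MB, UMS) with discovery-cohort cutoff scans and subgroup statistics,
#' build TMI score cards for every analysis patient from the
#' discovery-frozen evaluations, scan the discovery TMI values for the TMI
#' cutoff, and apply the combined TMI + IDH1 exon-4 classifier.
#'
#' @param cohort A `synthetic_cohort`, or a list with elements `calls`
#'   (long-form call tibble) and `clinical`.
#' @param config A [run_config()].
#' @return A `tmi_discovery` list; key elements: `calls` (filtered),
#'   `clinical` (with `benefit`, `nb_flagged`, `cohort_role`), `burdens`,
#'   `ums_set`, `values` (per-patient predictor values), `evals` (the three
#'   frozen `predictor_eval`s), `scorecards`, `tmi_cutoff_scan`,
#'   `tmi_cutoff`, `classification` (per-patient TMI class and combined
#'   class), `manifest`.
#' @export
run_discovery <- function(cohort, config = run_config()) {
  calls_raw <- if (inherits(cohort, "synthetic_cohort")) mutation_calls(cohort)
               else cohort$calls
  clinical <- cohort$clinical
  stopifnot(!is.null(clinical), !is.null(calls_raw))

  fcalls <- apply_call_filters(calls_raw, min_depth = config$min_depth,
                               germline_vaf_threshold = config$germline_vaf_threshold,
                               panel = config$panel)
  burdens <- compute_burdens(fcalls, patients = clinical$patient_id)

  clinical <- dplyr::mutate(clinical,
    benefit = classify_benefit(.data$pfs_days, .data$pfs_event, .data$intolerance))
  nb_screen <- nb_exclusion_screen(fcalls, clinical$patient_id,
                                   panel = config$resistance_panel)
  clinical$nb_flagged <- nb_screen$flagged[match(clinical$patient_id,
                                                 nb_screen$patient_id)]

  analysis <- clinical[clinical$benefit != "NB", , drop = FALSE]
  n_analysis <- nrow(analysis)
  if (n_analysis < 2L * config$min_group) {
    stop("analysis cohort too small after NB exclusion (", n_analysis,
         " patients) for min_group = ", config$min_group, call. = FALSE)
  }

  # discovery / validation split (seeded, or pinned by discovery_ids)
  if (!is.null(config$discovery_ids)) {
    disc_ids <- intersect(config$discovery_ids, analysis$patient_id)
  } else {
    n_disc <- max(2L * config$min_group,
                  round(config$discovery_fraction * n_analysis))
    set.seed(config$seed)
    disc_ids <- sort(sample(analysis$patient_id, min(n_disc, n_analysis)))
  }
  valid_ids <- setdiff(analysis$patient_id, disc_ids)
  analysis$cohort_role <- ifelse(analysis$patient_id %in% disc_ids,
                                 "discovery", "validation")
  disc <- analysis[analysis$cohort_role == "discovery", , drop = FALSE]

  # unfavorable-mutation screen on the discovery cohort at baseline
  ums_set <- screen_unfavorable_mutations(
    fcalls, disc, alpha = config$alpha, test = config$discovery_test,
    adjust = config$ums_adjust)
  ums <- ums_score(fcalls, ums_set, patients = analysis$patient_id,
                   highrisk_min = config$highrisk_min)

  bl_burdens <- burdens[burdens$timepoint == "BL", , drop = FALSE]
  values <- tibble::tibble(patient_id = analysis$patient_id)
  values$GS_MB <- bl_burdens$gs_mb[match(values$patient_id, bl_burdens$patient_id)]
  values$NS_MB <- bl_burdens$ns_mb[match(values$patient_id, bl_burdens$patient_id)]
  values$UMS <- ums$score[match(values$patient_id, ums$patient_id)]

  disc_values <- values[match(disc$patient_id, values$patient_id), , drop = FALSE]
  evals <- list(
    GS_MB = evaluate_predictor(disc, disc_values$GS_MB, "GS_MB", type = "burden",
                               min_group = config$min_group, test = config$discovery_test),
    NS_MB = evaluate_predictor(disc, disc_values$NS_MB, "NS_MB", type = "burden",
                               min_group = config$min_group, test = config$discovery_test),
    UMS = evaluate_predictor(disc, disc_values$UMS, "UMS", type = "ums",
                             min_group = config$min_group, test = config$discovery_test,
                             highrisk_min = config$highrisk_min)
  )

  scorecards <- tmi_scorecards(analysis, values, evals, cap = config$subgroup_cap)

  disc_tmi <- scorecards$tmi[match(disc$patient_id, scorecards$patient_id)]
  tmi_scan <- ward_cutoff_scan(disc_tmi, disc$pfs_days, disc$pfs_event,
                               min_group = config$min_group,
                               test = config$tmi_test)
  tmi_class <- tmi_classify(scorecards$tmi, tmi_scan$cutoff)
  classification <- tibble::tibble(
    patient_id = scorecards$patient_id,
    tmi = scorecards$tmi,
    tmi_class = tmi_class,
    idh1_exon4_mutant = analysis$idh1_exon4_mutant[match(scorecards$patient_id,
                                                         analysis$patient_id)]
  )
  classification$combined_class <- combined_tmi_idh1(classification$tmi_class,
                                                     classification$idh1_exon4_mutant)

  manifest <- list(
    config = unclass(config)[setdiff(names(config), c("panel", "resistance_panel"))],
    n_patients = nrow(clinical), n_nb_excluded = sum(clinical$benefit == "NB"),
    nb_flag_concordance = if (any(clinical$benefit == "NB")) {
      mean(clinical$nb_flagged[clinical$benefit == "NB"])
    } else NA_real_,
    discovery_ids = disc_ids, validation_ids = valid_ids,
    cutoffs = c(GS_MB = evals$GS_MB$cutoff, NS_MB = evals$NS_MB$cutoff,
                TMI = tmi_scan$cutoff),
    n_unfavorable = nrow(ums_set), n_tested = attr(ums_set, "n_tested")
  )

  structure(list(calls = fcalls, clinical = clinical, analysis = analysis,
                 burdens = burdens, nb_screen = nb_screen, ums_set = ums_set,
                 ums = ums, values = values, evals = evals,
                 scorecards = scorecards, tmi_cutoff_scan = tmi_scan,
                 tmi_cutoff = tmi_scan$cutoff, classification = classification,
                 manifest = manifest),
            class = "tmi_discovery")
}

stratify_group <- function(clinical, in_low, test_fn) {
  out <- tibble::tibble(
    n_low = sum(in_low), n_high = sum(!in_low),
    pfs_p = NA_real_, median_pfs_low = NA_real_, median_pfs_high = NA_real_,
    os_p = NA_real_, median_os_low = NA_real_, median_os_high = NA_real_)
  if (out$n_low == 0L || out$n_high == 0L) return(out) # one-class strata: sizes only
  pfs <- test_fn(clinical$pfs_days, clinical$pfs_event, !in_low)
  os <- test_fn(clinical$os_days, clinical$os_event, !in_low)
  out$pfs_p <- pfs$p_value
  out$median_pfs_low <- unname(pfs$group_medians["b"])
  out$median_pfs_high <- unname(pfs$group_medians["a"])
  out$os_p <- os$p_value
  out$median_os_low <- unname(os$group_medians["b"])
  out$median_os_high <- unname(os$group_medians["a"])
  out
}

#' Validate the frozen stratification on held-out patients
#'
#' Applies the discovery-frozen TMI cutoff and combined classifier to the
#' validation cohort (and to the pooled analysis cohort) without any
#' re-screening or re-scanning, and reports Kaplan-Meier stratification:
#' log-rank p (by default) and group medians for PFS and OS, for both the
#' TMI classes and the combined TMI + IDH1 classes. Errors if the
#' validation set is empty or overlaps discovery.
#'
#' @param discovery A `tmi_discovery` from [run_discovery()].
#' @param test Survival test for validation stratification (default the
#'   config's `validation_test`).
#' @return A list of tibbles: `validation_tmi`, `pooled_tmi`,
#'   `validation_combined`, `pooled_combined`, each one row of group sizes,
#'   p-values and medians.
#' @export
run_validation <- function(discovery, test = NULL) {
  stopifnot(inherits(discovery, "tmi_discovery"))
  test <- test %||% discovery$manifest$config$validation_test
  test_fn <- survtest_fun(test)
  disc_ids <- discovery$manifest$discovery_ids
  valid_ids <- discovery$manifest$validation_ids
  if (length(valid_ids) == 0L) stop("no validation patients in this run", call. = FALSE)
  if (length(intersect(disc_ids, valid_ids)) > 0L) {
    stop("discovery and validation cohorts overlap", call. = FALSE)
  }
  cl <- discovery$analysis
  cls <- discovery$classification
  stopifnot(identical(cl$patient_id, cls$patient_id))
  in_valid <- cl$patient_id %in% valid_ids
  low <- cls$tmi_class == "low"
  fav <- cls$combined_class == "favorable"
  list(
    validation_tmi = stratify_group(cl[in_valid, ], low[in_valid], test_fn),
    pooled_tmi = stratify_group(cl, low, test_fn),
    validation_combined = stratify_group(cl[in_valid, ], fav[in_valid], test_fn),
    pooled_combined = stratify_group(cl, fav, test_fn)
  )
}

#' Human-readable summary tables of a discovery run
#'
#' Builds (a) composition tables: within each predictor's responder and
#' non-responder class, the fraction of patients in each of the ten
#' demographic subgroups (fractions over a dichotomy sum to 1 within a
#' class), and (b) an oncoprint-style acquired-mutation table (genes x
#' patients, 0/1) for patients with a progression sample.
#'
#' @param discovery A `tmi_discovery`.
#' @return List: `composition` (tibble: predictor, class, subgroup, n,
#'   fraction), `acquired_matrix` (integer matrix genes x patients, or
#'   `NULL` when no PD samples exist), `acquired_frequencies` (tibble from
#'   [acquired_gene_frequencies()], or `NULL`).
#' @export
pipeline_report <- function(discovery) {
  stopifnot(inherits(discovery, "tmi_discovery"))
  cl <- discovery$analysis
  member <- subgroup_membership(cl)
  dichotomy <- c(male = "gender", female = "gender",
                 smoking = "smoking", nonsmoking = "smoking",
                 LUAD = "pathology", LUSC = "pathology",
                 driver_positive = "driver", driver_negative = "driver",
                 mets_gt3 = "metastases", mets_le3 = "metastases")

  comp_rows <- list()
  preds <- c("GS_MB", "NS_MB", "UMS", "TMI")
  for (pred in preds) {
    resp <- if (pred == "TMI") {
      discovery$classification$tmi_class[match(cl$patient_id,
                                               discovery$classification$patient_id)] == "low"
    } else {
      classify_responder(discovery$evals[[pred]],
                         discovery$values[[pred]][match(cl$patient_id,
                                                        discovery$values$patient_id)])
    }
    for (class_name in c("responder", "nonresponder")) {
      idx <- if (class_name == "responder") resp else !resp
      n_class <- sum(idx)
      for (g in colnames(member)) {
        n_g <- sum(member[idx, g])
        comp_rows[[length(comp_rows) + 1L]] <- tibble::tibble(
          predictor = pred, class = class_name, subgroup = g,
          dichotomy = unname(dichotomy[g]), n = n_g, n_class = n_class,
          fraction = if (n_class > 0L) n_g / n_class else NA_real_)
      }
    }
  }
  composition <- dplyr::bind_rows(comp_rows)

  pd_patients <- unique(discovery$calls$patient_id[discovery$calls$timepoint == "PD"])
  acquired_matrix <- NULL
  acquired_frequencies <- NULL
  if (length(pd_patients) > 0L) {
    reports <- lapply(pd_patients, function(p) acquired_mutation_set(discovery$calls, p))
    genes <- sort(unique(unlist(lapply(reports, function(r) r$acquired$gene))))
    if (length(genes) > 0L) {
      acquired_matrix <- matrix(0L, nrow = length(genes), ncol = length(pd_patients),
                                dimnames = list(genes, pd_patients))
      for (r in reports) {
        g <- unique(r$acquired$gene)
        acquired_matrix[g, r$patient_id] <- 1L
      }
    }
    acquired_frequencies <- acquired_gene_frequencies(reports, pd_patients)
  }

  list(composition = composition, acquired_matrix = acquired_matrix,
       acquired_frequencies = acquired_frequencies)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
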