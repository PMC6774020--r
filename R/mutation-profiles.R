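#' Read a mutation x sample call table
#'
#' Reads the TSV dialect used throughout the package: one row per mutation,
#' fixed columns `chrom`, `pos`, `ref`, `alt`, `gene`, `effect_class`,
#' `synonymous_flag`, followed by one column per sample named
#' `<patient>_<BL|PD|WBC>` whose cells hold `depth:vaf`. A cell with zero
#' depth (`"0:0.0"`) encodes absence and produces no record. Positions may
#' contain grouping spaces (as in printed reports, `26 779 439`); these are
#' stripped on parse.
#'
#' @param path Path to the TSV file.
#' @return A tibble of mutation calls in long form, one row per
#'   (mutation, sample) with depth > 0: columns `patient_id`, `timepoint`,
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `effect_class`, `synonymous`,
#'   `depth`, `vaf`, `key`.
#' @export
read_mutation_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  calls_from_wide(raw)
}

# shared core: wide mutation x sample table (columns possibly all-character,
# as read from TSV, or typed, as built by the simulator) -> long call tibble
calls_from_wide <- function(raw) {
  fixed <- c("chrom", "pos", "ref", "alt", "gene", "effect_class", "synonymous_flag")
  missing_cols <- setdiff(fixed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("mutation table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sample_cols <- setdiff(names(raw), fixed)
  if (nrow(raw) == 0L) {
    return(empty_calls())
  }

  raw$chrom <- gsub("[[:space:]]+", "", raw$chrom)
  if (is.character(raw$pos)) {
    pos_chr <- gsub("[[:space:]]+", "", raw$pos)
    if (any(!grepl("^[0-9]+$", pos_chr))) {
      bad <- which(!grepl("^[0-9]+$", pos_chr))[1L]
      stop("malformed position in row ", bad, ": '", raw$pos[bad], "'", call. = FALSE)
    }
    raw$pos <- as.numeric(pos_chr)
  }
  bad_eff <- !(raw$effect_class %in% EFFECT_CLASSES)
  if (any(bad_eff)) {
    stop("unknown effect_class in row ", which(bad_eff)[1L], ": '",
         raw$effect_class[which(bad_eff)[1L]], "'", call. = FALSE)
  }
  key <- mut_key(raw$chrom, raw$pos, raw$ref, raw$alt)
  if (anyDuplicated(key)) {
    stop("duplicate mutation row: ", key[duplicated(key)][1L], call. = FALSE)
  }

  if (length(sample_cols) == 0L) return(empty_calls())
  tp_ok <- grepl("_(BL|PD|WBC)$", sample_cols)
  if (any(!tp_ok)) {
    stop("sample column '", sample_cols[!tp_ok][1L],
         "' does not end in _BL, _PD or _WBC", call. = FALSE)
  }

  long <- tidyr::pivot_longer(
    dplyr::mutate(raw, key = key),
    cols = dplyr::all_of(sample_cols),
    names_to = "sample", values_to = "cell"
  )
  cell_ok <- grepl("^[0-9]+:[0-9.eE+-]+$", long$cell)
  if (any(!cell_ok)) {
    bad <- which(!cell_ok)[1L]
    stop("malformed cell '", long$cell[bad], "' for mutation ", long$key[bad],
         " in sample column ", long$sample[bad], call. = FALSE)
  }
  sep <- regexpr(":", long$cell, fixed = TRUE)
  long$depth <- as.integer(substr(long$cell, 1L, sep - 1L))
  long$vaf <- as.numeric(substr(long$cell, sep + 1L, nchar(long$cell)))
  if (any(long$vaf < 0 | long$vaf > 1)) {
    stop("VAF outside [0, 1] for mutation ",
         long$key[which(long$vaf < 0 | long$vaf > 1)[1L]], call. = FALSE)
  }
  long <- long[long$depth > 0L, , drop = FALSE]
  long$patient_id <- sub("_(BL|PD|WBC)$", "", long$sample)
  long$timepoint <- sub("^.*_(BL|PD|WBC)$", "\\1", long$sample)
  long$synonymous <- long$synonymous_flag %in% c("1", "TRUE", "true", "yes")

  out <- tibble::as_tibble(long[, c("patient_id", "timepoint", "chrom", "pos", "ref",
                                    "alt", "gene", "effect_class", "synonymous",
                                    "depth", "vaf", "key")])
  dplyr::arrange(out, .data$patient_id, .data$timepoint, .data$chrom, .data$pos)
}

empty_calls <- function() {
  tibble::tibble(patient_id = character(), timepoint = character(),
                 chrom = character(), pos = numeric(), ref = character(),
                 alt = character(), gene = character(), effect_class = character(),
                 synonymous = logical(), depth = integer(), vaf = numeric(),
                 key = character())
}

#' Read a per-patient clinical table
#'
#' @param path Path to the clinical TSV written by [write_fixture()] (columns
#'   `patient_id`, `gender`, `smoking`, `pathology`, `driver_positive`,
#'   `metastases`, `pfs_days`, `pfs_event`, `os_days`, `os_event`,
#'   `intolerance`, `idh1_exon4_mutant`).
#' @return A tibble, one row per patient.
#' @export
read_clinical_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    gender = readr::col_character(),
    smoking = readr::col_logical(),
    pathology = readr::col_character(),
    driver_positive = readr::col_logical(),
    metastases = readr::col_integer(),
    pfs_days = readr::col_double(),
    pfs_event = readr::col_logical(),
    os_days = readr::col_double(),
    os_event = readr::col_logical(),
    intolerance = readr::col_logical(),
    idh1_exon4_mutant = readr::col_logical()
  ), progress = FALSE)
}

#' Apply the plasma SNV filter chain
#'
#' Labels every call with the retained-set flags used downstream; no record
#' is destroyed. The chain is: (1) depth — records with sequencing depth
#' below `min_depth` (default 100x) fail `pass_depth`; (2) panel — records
#' in genes outside the capture panel fail `in_panel`; (3) origin —
#' germline/somatic assignment, by matched white-blood-cell (WBC) sample
#' where one is present for the patient, otherwise by the VAF proxy
#' (VAF > `germline_vaf_threshold`, default 20%, is treated as
#' germline-like, since clonal somatic plasma VAFs are low); (4) effect —
#' low-effect records (`MODIFIER`, `LOW`) are excluded from the somatic
#' retained set. The germline+somatic set (`in_gs`) is all depth-passing
#' panel records regardless of origin or effect; the somatic set
#' (`in_somatic`) additionally requires somatic origin and
#' `MODERATE`/`HIGH` effect; the nonsynonymous set (`in_nonsyn`) further
#' drops synonymous records. The function is idempotent: flags are
#' recomputed from the raw columns each call.
#'
#' @param calls Long-form call tibble from [read_mutation_table()] or
#'   [mutation_calls()]; may be a subset (e.g. one sample).
#' @param min_depth Minimum sequencing depth (default 100).
#' @param germline_vaf_threshold VAF above which a record is treated as
#'   germline-like when no WBC sample is available (default 0.20).
#' @param panel Character vector of panel gene symbols (default the
#'   168-gene panel).
#' @return The input tibble plus columns `pass_depth`, `in_panel`, `origin`
#'   (`"germline"`/`"somatic"`), `in_gs`, `in_somatic`, `in_nonsyn`, with
#'   attribute `filters` recording the parameters and the germline
#'   assignment mode per patient.
#' @export
apply_call_filters <- function(calls, min_depth = 100L,
                               germline_vaf_threshold = 0.20,
                               panel = panel_genes_168()) {
  if (length(panel) == 0L) stop("panel must be non-empty", call. = FALSE)
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0L) {
    out <- dplyr::mutate(calls, pass_depth = logical(0), in_panel = logical(0),
                         origin = character(0), in_gs = logical(0),
                         in_somatic = logical(0), in_nonsyn = logical(0))
    attr(out, "filters") <- list(min_depth = min_depth,
                                 germline_vaf_threshold = germline_vaf_threshold,
                                 germline_mode = character(0))
    return(out)
  }

  calls$pass_depth <- calls$depth >= min_depth
  calls$in_panel <- calls$gene %in% panel

  # germline assignment: WBC sample where available, VAF proxy otherwise
  wbc <- calls[calls$timepoint == "WBC" & calls$pass_depth, c("patient_id", "key")]
  wbc_patients <- unique(wbc$patient_id)
  in_wbc <- paste(calls$patient_id, calls$key) %in% paste(wbc$patient_id, wbc$key)
  has_wbc <- calls$patient_id %in% wbc_patients
  germline <- ifelse(has_wbc, in_wbc, calls$vaf > germline_vaf_threshold)
  calls$origin <- ifelse(germline, "germline", "somatic")

  calls$in_gs <- calls$pass_depth & calls$in_panel & calls$timepoint != "WBC"
  calls$in_somatic <- calls$in_gs & calls$origin == "somatic" &
    calls$effect_class %in% c("MODERATE", "HIGH")
  calls$in_nonsyn <- calls$in_somatic & !calls$synonymous

  attr(calls, "filters") <- list(
    min_depth = min_depth,
    germline_vaf_threshold = germline_vaf_threshold,
    germline_mode = stats::setNames(
      ifelse(unique(calls$patient_id) %in% wbc_patients, "wbc", "vaf_proxy"),
      unique(calls$patient_id))
  )
  calls
}

#' Mutation-burden predictors per sample
#'
#' Computes the two plasma burden predictors for every `BL`/`PD` sample in a
#' filtered call set: `gs_mb`, the germline+somatic mutation burden (all
#' depth-passing panel records), and `ns_mb`, the nonsynonymous+synonymous
#' somatic burden (somatic retained set: somatic origin, MODERATE/HIGH
#' effect, synonymous and nonsynonymous alike). Always `0 <= ns_mb <= gs_mb`.
#'
#' @param calls Filtered calls from [apply_call_filters()].
#' @param patients Optional character vector of patient ids to guarantee a
#'   row (with zero burdens) for samples that retained no records.
#' @param timepoints Timepoints to include (default `"BL"` and `"PD"`).
#' @return Tibble with columns `patient_id`, `timepoint`, `gs_mb`, `ns_mb`.
#' @export
compute_burdens <- function(calls, patients = NULL, timepoints = c("BL", "PD")) {
  if (is.null(attr(calls, "filters")) && nrow(calls) > 0L) {
    stop("calls must be passed through apply_call_filters() first", call. = FALSE)
  }
  sub <- calls[calls$timepoint %in% timepoints, , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(sub, .data$patient_id, .data$timepoint),
    gs_mb = sum(.data$in_gs), ns_mb = sum(.data$in_somatic), .groups = "drop")
  if (!is.null(patients)) {
    # guarantee a BL row for every requested patient (zero burdens if the
    # sample retained no records), keeping any observed PD rows
    want <- tibble::tibble(patient_id = patients, timepoint = "BL")
    miss <- dplyr::anti_join(want, out, by = c("patient_id", "timepoint"))
    if (nrow(miss) > 0L) {
      out <- dplyr::bind_rows(out, dplyr::mutate(miss, gs_mb = 0L, ns_mb = 0L))
    }
  }
  dplyr::arrange(out, .data$patient_id, .data$timepoint)
}
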