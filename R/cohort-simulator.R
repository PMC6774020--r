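#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated circulating-DNA cohort:
#' a mixture of low- and high-burden patients, planted unfavorable mutations
#' with multiplicative hazard effects on progression-free survival (PFS), an
#' IDH1 exon-4 hazard effect, no-benefit (NB) patients who carry baseline
#' ARID1A/BRCA2 resistance-panel mutations with high probability, and
#' acquired mutations at progression for durable-benefit patients. All
#' randomness is driven by one shared stream seeded once from `seed`, so a
#' config fully determines the cohort.
#'
#' @param n_patients Number of patients (>= 2). Default 111, the size of a
#'   plasma-profiled third-line anlotinib cohort.
#' @param panel_genes Capture-panel gene symbols; must include `ARID1A`,
#'   `BRCA2`, `TGFBR2` and `IDH1`. Default [panel_genes_168()].
#' @param mean_gs_burden_low,mean_gs_burden_high Mean germline+somatic
#'   burden (mutation counts per baseline sample) in the low- and
#'   high-burden groups. Defaults 2500 and 5500 place the two groups either
#'   side of a burden cutoff near 4000.
#' @param frac_high_burden Proportion of patients in the high-burden group
#'   (default 19/62).
#' @param n_unfavorable Number of planted unfavorable somatic mutations
#'   (default 20).
#' @param prev_unfavorable Carrier probability per planted unfavorable
#'   mutation per patient (default 0.08).
#' @param hr_unfavorable Hazard ratio per carried unfavorable mutation
#'   (multiplicative across carried mutations, so it is also the marginal
#'   carrier/non-carrier hazard ratio of any one mutation; default 1.25,
#'   keeping the total planted load moderate).
#' @param hr_high_burden Hazard ratio of the high-burden group (default
#'   1.65, matching planted group medians of about 210 vs 127 days).
#' @param hr_idh1 Hazard ratio for IDH1 exon-4 mutants (default 1.8).
#' @param prob_idh1 Probability a patient is IDH1 exon-4 mutant (default 0.15).
#' @param prob_intolerance Probability a patient stops therapy for
#'   intolerance (classified NB regardless of PFS; default 0.02).
#' @param prob_nb_resistance_panel Probability an NB patient (progression
#'   within 45 days under the hazard model, or intolerant) carries at least
#'   one resistance-panel mutation at baseline (default 0.92).
#' @param prob_bl_resistance_other Probability a non-NB patient carries a
#'   resistance-panel mutation at baseline (default 0.05).
#' @param baseline_median_pfs_days Median PFS of the reference group
#'   (low-burden, no unfavorable mutations, IDH1 wild-type; default 210).
#' @param censor_rate Probability that PFS (and OS) is censored, via an
#'   independent exponential censoring time (default 0.15).
#' @param acquired_rate Mean number of acquired mutations per
#'   progression-of-disease (PD) sample (Poisson; default 4).
#' @param prob_pd_sample Probability that an eligible durable-benefit
#'   patient contributes a PD sample (default 0.6).
#' @param prob_acquired_resistance Probability that a PD patient is planted
#'   "resistant", acquiring ARID1A/BRCA2 resistance-panel mutations
#'   preferentially (default 0.4).
#' @param os_factor_shape,os_factor_scale Gamma parameters of the
#'   patient-level factor (>1) linking OS to PFS (`OS = PFS * factor +
#'   noise`); defaults give a mean factor of 2.2.
#' @param weibull_shape Shape of the event-time distribution (1 =
#'   exponential, the default; medians are preserved across shapes).
#' @param n_background_variants Size of the shared background variant pool;
#'   default `2 * mean_gs_burden_high`.
#' @param frac_offpanel Fraction of background variants in genes outside
#'   the capture panel (exercises the panel filter; default 0.03).
#' @param frac_lowdepth Fraction of cells with sequencing depth below 100x
#'   (exercises the depth filter; default 0.05).
#' @param germline_frac Fraction of background variants that are germline
#'   (VAF centred at 0.5; default 0.7).
#' @param seed Integer seed; fully determines the cohort.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 111L,
                              panel_genes = panel_genes_168(),
                              mean_gs_burden_low = 2500,
                              mean_gs_burden_high = 5500,
                              frac_high_burden = 19 / 62,
                              n_unfavorable = 20L,
                              prev_unfavorable = 0.08,
                              hr_unfavorable = 1.25,
                              hr_high_burden = 1.65,
                              hr_idh1 = 1.8,
                              prob_idh1 = 0.15,
                              prob_intolerance = 0.02,
                              prob_nb_resistance_panel = 0.92,
                              prob_bl_resistance_other = 0.05,
                              baseline_median_pfs_days = 210,
                              censor_rate = 0.15,
                              acquired_rate = 4,
                              prob_pd_sample = 0.6,
                              prob_acquired_resistance = 0.4,
                              os_factor_shape = 2,
                              os_factor_scale = 0.6,
                              weibull_shape = 1,
                              n_background_variants = NULL,
                              frac_offpanel = 0.03,
                              frac_lowdepth = 0.05,
                              germline_frac = 0.7,
                              seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), panel_genes = panel_genes,
              mean_gs_burden_low = mean_gs_burden_low,
              mean_gs_burden_high = mean_gs_burden_high,
              frac_high_burden = frac_high_burden,
              n_unfavorable = as.integer(n_unfavorable),
              prev_unfavorable = prev_unfavorable,
              hr_unfavorable = hr_unfavorable, hr_high_burden = hr_high_burden,
              hr_idh1 = hr_idh1, prob_idh1 = prob_idh1,
              prob_intolerance = prob_intolerance,
              prob_nb_resistance_panel = prob_nb_resistance_panel,
              prob_bl_resistance_other = prob_bl_resistance_other,
              baseline_median_pfs_days = baseline_median_pfs_days,
              censor_rate = censor_rate, acquired_rate = acquired_rate,
              prob_pd_sample = prob_pd_sample,
              prob_acquired_resistance = prob_acquired_resistance,
              os_factor_shape = os_factor_shape, os_factor_scale = os_factor_scale,
              weibull_shape = weibull_shape,
              n_background_variants =
                if (is.null(n_background_variants)) NULL else as.integer(n_background_variants),
              frac_offpanel = frac_offpanel, frac_lowdepth = frac_lowdepth,
              germline_frac = germline_frac, seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  chk <- function(ok, param, why) {
    if (!isTRUE(ok)) stop("invalid simulation config: `", param, "` ", why, call. = FALSE)
  }
  chk(cfg$n_patients >= 2L, "n_patients", "must be >= 2")
  chk(length(cfg$panel_genes) > 0 &&
        all(c("ARID1A", "BRCA2", "TGFBR2", "IDH1") %in% cfg$panel_genes),
      "panel_genes", "must include ARID1A, BRCA2, TGFBR2 and IDH1")
  for (p in c("frac_high_burden", "prev_unfavorable", "prob_idh1",
              "prob_intolerance",
              "prob_nb_resistance_panel", "prob_bl_resistance_other",
              "censor_rate", "prob_pd_sample", "prob_acquired_resistance",
              "frac_offpanel", "frac_lowdepth", "germline_frac")) {
    chk(is.numeric(cfg[[p]]) && cfg[[p]] >= 0 && cfg[[p]] <= 1, p, "must be in [0, 1]")
  }
  for (p in c("hr_unfavorable", "hr_high_burden", "hr_idh1")) {
    chk(is.numeric(cfg[[p]]) && cfg[[p]] > 0, p, "must be > 0 (hazard ratio)")
  }
  for (p in c("mean_gs_burden_low", "mean_gs_burden_high",
              "baseline_median_pfs_days", "acquired_rate", "weibull_shape",
              "os_factor_shape", "os_factor_scale")) {
    chk(is.numeric(cfg[[p]]) && cfg[[p]] >= 0, p, "must be non-negative")
  }
  chk(cfg$baseline_median_pfs_days > 0, "baseline_median_pfs_days", "must be > 0")
  chk(cfg$weibull_shape > 0, "weibull_shape", "must be > 0")
  chk(cfg$n_unfavorable >= 0L, "n_unfavorable", "must be >= 0")
  chk(is.numeric(cfg$seed) && !is.na(cfg$seed), "seed", "must be an integer")
  invisible(cfg)
}

#' The default baseline resistance panel
#'
#' The four ARID1A/BRCA2 frameshift point mutations screened at baseline to
#' exclude likely no-benefit patients: ARID1A A1850fs (chr1:26779439 TG/T),
#' ARID1A G766fs (chr1:26762190 TC/T), BRCA2 T3033fs (chr13:32379885 CA/C)
#' and BRCA2 chr13:32379885 C/CA. Matching is by exact mutation key; the
#' panel can be extended by row-binding further entries.
#'
#' @return Tibble with columns `gene`, `chrom`, `pos`, `ref`, `alt`,
#'   `label`, `key`.
#' @export
default_resistance_panel <- function() {
  tb <- tibble::tibble(
    gene = c("ARID1A", "ARID1A", "BRCA2", "BRCA2"),
    chrom = c("chr1", "chr1", "chr13", "chr13"),
    pos = c(26779439, 26762190, 32379885, 32379885),
    ref = c("TG", "TC", "CA", "C"),
    alt = c("T", "T", "C", "CA"),
    label = c("A1850fs", "G766fs", "T3033fs", "dup")
  )
  tb$key <- mut_key(tb$chrom, tb$pos, tb$ref, tb$alt)
  tb
}

idh1_exon4_variant <- function() {
  tibble::tibble(gene = "IDH1", chrom = "chr2", pos = 208248389,
                 ref = "C", alt = "T",
                 key = mut_key("chr2", 208248389, "C", "T"))
}

#' Simulate a synthetic circulating-DNA cohort
#'
#' Generates a mutation x sample table (cells = `depth:vaf`), a clinical
#' table and a truth block recording every planted effect. Event times
#' follow a Weibull model (exponential by default) whose per-patient hazard
#' is `baseline x hr_high_burden^[high burden] x
#' hr_unfavorable^(#unfavorable carried) x hr_idh1^[IDH1 mutant]`. Patients
#' whose observed progression falls within 45 days (or who are intolerant)
#' are the no-benefit (NB) class; they carry a resistance-panel mutation at
#' baseline with probability `prob_nb_resistance_panel`. OS is
#' PFS times a patient-level factor > 1 plus noise. Censoring is by an
#' independent exponential time calibrated so that a fraction
#' `censor_rate` of observations are censored. Durable-benefit patients may
#' contribute a PD sample whose calls are the baseline calls plus acquired
#' mutations (Poisson, mean `acquired_rate`), drawn preferentially from
#' ARID1A/BRCA2 for planted resistant patients.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_cohort` list: `mutations` (wide tibble in the
#'   fixture dialect), `clinical` (tibble), `truth` (list of planted
#'   effects, including the full config for regeneration).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  validate_simulation_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_patients
  ids <- sprintf("P%03d", seq_len(n))

  clinical <- tibble::tibble(
    patient_id = ids,
    gender = sample(c("M", "F"), n, replace = TRUE, prob = c(0.6, 0.4)),
    smoking = stats::runif(n) < 0.55,
    pathology = sample(c("LUAD", "LUSC"), n, replace = TRUE, prob = c(0.8, 0.2)),
    driver_positive = stats::runif(n) < 0.45,
    metastases = stats::rpois(n, 2.2),
    idh1_exon4_mutant = stats::runif(n) < cfg$prob_idh1
  )
  high_burden <- stats::runif(n) < cfg$frac_high_burden

  ## ---- variant pool -------------------------------------------------------
  n_bg <- if (is.null(cfg$n_background_variants)) {
    max(0L, as.integer(round(2 * cfg$mean_gs_burden_high)))
  } else cfg$n_background_variants
  panel_only <- cfg$panel_genes
  bases <- c("A", "C", "G", "T")
  rand_variants <- function(m, genes, effect = NULL, synonymous = NULL,
                            germline = NULL, prefix = "v") {
    if (m == 0L) {
      return(tibble::tibble(gene = character(), chrom = character(),
                            pos = numeric(), ref = character(), alt = character(),
                            germline = logical(), effect_class = character(),
                            synonymous = logical(), key = character()))
    }
    chrom <- sample(paste0("chr", 1:22), m, replace = TRUE)
    pos <- sample(1e6:2e8, m, replace = FALSE)
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    tibble::tibble(
      gene = genes,
      chrom = chrom, pos = as.numeric(pos), ref = ref, alt = unname(alt),
      germline = if (is.null(germline)) stats::runif(m) < cfg$germline_frac else germline,
      effect_class = if (is.null(effect)) {
        sample(EFFECT_CLASSES, m, replace = TRUE, prob = c(0.15, 0.15, 0.4, 0.3))
      } else rep(effect, m),
      synonymous = if (is.null(synonymous)) stats::runif(m) < 0.3 else rep(synonymous, m),
      key = mut_key(chrom, pos, ref, alt)
    )
  }

  bg_genes <- sample(panel_only, n_bg, replace = TRUE)
  off <- stats::runif(n_bg) < cfg$frac_offpanel
  bg_genes[off] <- sprintf("OFFPANEL%02d", sample(1:40, sum(off), replace = TRUE))
  bg <- rand_variants(n_bg, bg_genes)

  unf <- rand_variants(cfg$n_unfavorable, sample(panel_only, cfg$n_unfavorable, replace = TRUE),
                       effect = "HIGH", synonymous = FALSE, germline = FALSE)
  idh1v <- idh1_exon4_variant()
  idh1v$germline <- FALSE; idh1v$effect_class <- "HIGH"; idh1v$synonymous <- FALSE
  rpanel <- default_resistance_panel()
  rp <- tibble::tibble(gene = rpanel$gene, chrom = rpanel$chrom, pos = rpanel$pos,
                       ref = rpanel$ref, alt = rpanel$alt, germline = FALSE,
                       effect_class = "HIGH", synonymous = FALSE, key = rpanel$key)

  ## ---- carriage -----------------------------------------------------------
  target_burden <- stats::rpois(n, ifelse(high_burden, cfg$mean_gs_burden_high,
                                          cfg$mean_gs_burden_low))
  q <- if (n_bg > 0L) pmin(target_burden / n_bg, 1) else rep(0, n)
  carried_bg <- lapply(seq_len(n), function(i) which(stats::runif(n_bg) < q[i]))
  carried_unf <- lapply(seq_len(n), function(i) {
    if (cfg$n_unfavorable == 0L) integer(0)
    else which(stats::runif(cfg$n_unfavorable) < cfg$prev_unfavorable)
  })
  n_unf_carried <- vapply(carried_unf, length, integer(1))

  ## ---- survival -----------------------------------------------------------
  hz_mult <- cfg$hr_high_burden^high_burden *
    cfg$hr_unfavorable^n_unf_carried *
    cfg$hr_idh1^clinical$idh1_exon4_mutant
  h <- log(2) / cfg$baseline_median_pfs_days * hz_mult
  k <- cfg$weibull_shape
  t_true <- if (abs(k - 1) < 1e-12) stats::rexp(n, rate = h) else {
    stats::rweibull(n, shape = k, scale = log(2)^(1 - 1 / k) / h)
  }
  cens_rate <- if (cfg$censor_rate > 0) h * cfg$censor_rate / (1 - cfg$censor_rate) else NULL
  c_time <- if (is.null(cens_rate)) rep(Inf, n) else stats::rexp(n, rate = cens_rate)
  pfs_days <- pmax(1, round(pmin(t_true, c_time)))
  pfs_event <- t_true <= c_time
  intolerance <- stats::runif(n) < cfg$prob_intolerance

  # no-benefit status follows from the hazard model; the resistance-panel
  # carriage is then planted conditional on it
  nb <- (pfs_event & pfs_days <= 45) | intolerance
  carried_rp <- lapply(seq_len(n), function(i) {
    if (nb[i]) {
      if (stats::runif(1) < cfg$prob_nb_resistance_panel) {
        sample(seq_len(nrow(rp)), sample(1:2, 1L))
      } else integer(0)
    } else if (stats::runif(1) < cfg$prob_bl_resistance_other) {
      sample(seq_len(nrow(rp)), 1L)
    } else integer(0)
  })

  os_factor <- 1 + stats::rgamma(n, shape = cfg$os_factor_shape, scale = cfg$os_factor_scale)
  os_true <- t_true * os_factor + stats::rexp(n, 1 / 10)
  os_cens <- if (is.null(cens_rate)) rep(Inf, n) else {
    stats::rexp(n, rate = (h / mean(os_factor)) * cfg$censor_rate / (1 - cfg$censor_rate))
  }
  os_days <- pmax(pfs_days, round(pmin(os_true, os_cens)))
  os_event <- os_true <= os_cens

  clinical$pfs_days <- as.numeric(pfs_days)
  clinical$pfs_event <- pfs_event
  clinical$os_days <- as.numeric(os_days)
  clinical$os_event <- os_event
  clinical$intolerance <- intolerance
  clinical <- clinical[, c("patient_id", "gender", "smoking", "pathology",
                           "driver_positive", "metastases", "pfs_days", "pfs_event",
                           "os_days", "os_event", "intolerance", "idh1_exon4_mutant")]

  ## ---- PD samples and acquired mutations ----------------------------------
  dcb_true <- !nb & t_true > 130
  has_pd <- dcb_true & stats::runif(n) < cfg$prob_pd_sample
  resistant <- has_pd & stats::runif(n) < cfg$prob_acquired_resistance

  acq_gene_weights <- rep(1, length(panel_only))
  names(acq_gene_weights) <- panel_only
  acq_gene_weights[c("ARID1A", "BRCA2", "TGFBR2")] <- c(12, 10, 8)

  acquired <- vector("list", n)
  acq_rows <- list()
  for (i in which(has_pd)) {
    n_acq <- stats::rpois(1, cfg$acquired_rate)
    keys_i <- character(0)
    if (resistant[i]) {
      cand <- setdiff(seq_len(nrow(rp)), carried_rp[[i]])
      if (length(cand) > 0L) {
        pick <- sample(cand, min(length(cand), sample(1:2, 1L)))
        keys_i <- rp$key[pick]
        acq_rows[[length(acq_rows) + 1L]] <-
          dplyr::mutate(rp[pick, ], patient_id = ids[i])
      }
      n_acq <- max(0L, n_acq - length(keys_i))
    }
    if (n_acq > 0L) {
      g <- sample(panel_only, n_acq, replace = TRUE, prob = acq_gene_weights)
      nv <- rand_variants(n_acq, g, effect = "HIGH", synonymous = FALSE, germline = FALSE)
      acq_rows[[length(acq_rows) + 1L]] <- dplyr::mutate(nv, patient_id = ids[i])
      keys_i <- c(keys_i, nv$key)
    }
    acquired[[i]] <- keys_i
  }
  names(acquired) <- ids
  acq_all <- if (length(acq_rows) > 0L) dplyr::bind_rows(acq_rows) else NULL

  ## ---- assemble cell entries ----------------------------------------------
  variants <- dplyr::bind_rows(bg, unf, idh1v[, names(rp)], rp)
  variants <- variants[!duplicated(variants$key), , drop = FALSE]
  if (!is.null(acq_all)) {
    new_acq <- acq_all[!acq_all$key %in% variants$key, names(rp)]
    variants <- dplyr::bind_rows(variants, new_acq[!duplicated(new_acq$key), ])
  }
  vindex <- stats::setNames(seq_len(nrow(variants)), variants$key)

  entry_list <- list()
  add_entries <- function(keys, patient, timepoints, depth, vaf) {
    if (length(keys) == 0L) return(invisible(NULL))
    for (tp in timepoints) {
      entry_list[[length(entry_list) + 1L]] <<- tibble::tibble(
        vi = unname(vindex[keys]), sample = paste0(patient, "_", tp),
        depth = depth, vaf = vaf)
    }
    invisible(NULL)
  }

  draw_depth <- function(m) {
    d <- stats::rpois(m, 600)
    low <- stats::runif(m) < cfg$frac_lowdepth
    if (any(low)) d[low] <- sample(20:99, sum(low), replace = TRUE)
    pmax(1L, d)
  }

  for (i in seq_len(n)) {
    tps <- if (has_pd[i]) c("BL", "PD") else "BL"
    # background variants
    kb <- bg$key[carried_bg[[i]]]
    if (length(kb) > 0L) {
      germ <- bg$germline[carried_bg[[i]]]
      vaf <- ifelse(germ, stats::rbeta(length(kb), 30, 30), stats::rbeta(length(kb), 2, 18))
      add_entries(kb, ids[i], tps, draw_depth(length(kb)), round(vaf, 4))
    }
    ku <- unf$key[carried_unf[[i]]]
    if (length(ku) > 0L) {
      add_entries(ku, ids[i], tps, pmax(150L, draw_depth(length(ku))),
                  round(stats::runif(length(ku), 0.03, 0.18), 4))
    }
    if (clinical$idh1_exon4_mutant[i]) {
      add_entries(idh1v$key, ids[i], tps, pmax(150L, draw_depth(1L)),
                  round(stats::runif(1, 0.03, 0.18), 4))
    }
    kr <- rp$key[carried_rp[[i]]]
    if (length(kr) > 0L) {
      add_entries(kr, ids[i], tps, pmax(150L, draw_depth(length(kr))),
                  round(stats::runif(length(kr), 0.03, 0.18), 4))
    }
    ka <- acquired[[i]]
    if (!is.null(ka) && length(ka) > 0L) {
      add_entries(ka, ids[i], "PD", pmax(150L, draw_depth(length(ka))),
                  round(stats::runif(length(ka), 0.03, 0.18), 4))
    }
  }

  sample_names <- unlist(lapply(seq_len(n), function(i) {
    c(paste0(ids[i], "_BL"), if (has_pd[i]) paste0(ids[i], "_PD"))
  }))

  ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
  variants <- variants[ord, , drop = FALSE]
  wide <- tibble::tibble(chrom = variants$chrom,
                         pos = variants$pos,
                         ref = variants$ref, alt = variants$alt,
                         gene = variants$gene,
                         effect_class = variants$effect_class,
                         synonymous_flag = as.integer(variants$synonymous))
  for (s in sample_names) wide[[s]] <- "0:0.0"
  if (length(entry_list) > 0L) {
    entries <- dplyr::bind_rows(entry_list)
    # map old variant index -> new row order
    row_of <- integer(length(ord)); row_of[ord] <- seq_along(ord)
    cell <- paste0(entries$depth, ":", format(entries$vaf, trim = TRUE, scientific = FALSE))
    for (s in unique(entries$sample)) {
      sel <- entries$sample == s
      wide[[s]][row_of[entries$vi[sel]]] <- cell[sel]
    }
  }

  # a call table only lists mutations observed in at least one sample
  if (nrow(wide) > 0L && length(sample_names) > 0L) {
    observed <- rowSums(as.matrix(wide[, sample_names, drop = FALSE]) != "0:0.0") > 0
    wide <- wide[observed, , drop = FALSE]
  }

  present_keys <- mut_key(wide$chrom, wide$pos, wide$ref, wide$alt)
  truth <- list(
    config = unclass(cfg),
    nb_patients = ids[nb],
    high_burden = ids[high_burden],
    idh1_mutant = ids[clinical$idh1_exon4_mutant],
    # planted unfavorable keys carried by at least one patient (an uncarried
    # planted key has no row in the call table and cannot be screened)
    unfavorable_keys = intersect(unf$key, present_keys),
    resistance_bl = stats::setNames(lapply(carried_rp, function(ix) rp$key[ix]), ids),
    acquired = acquired[has_pd],
    pd_patients = ids[has_pd],
    resistant_at_pd = ids[resistant],
    hazard_multiplier = stats::setNames(hz_mult, ids),
    n_unfavorable_carried = stats::setNames(n_unf_carried, ids)
  )

  structure(list(mutations = wide, clinical = clinical, truth = truth),
            class = "synthetic_cohort")
}

#' Long-form mutation calls of a synthetic cohort
#'
#' Converts the wide mutation x sample table of a [simulate_cohort()] result
#' into the long call form produced by [read_mutation_table()], without a
#' round trip through disk.
#'
#' @param cohort A `synthetic_cohort`.
#' @return Long-form call tibble (see [read_mutation_table()]).
#' @export
mutation_calls <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  calls_from_wide(cohort$mutations)
}

#' Write a cohort fixture to disk
#'
#' Emits `mutations.tsv` (wide mutation x sample table), `clinical.tsv` and
#' `truth.json` into `dir`. The files round-trip losslessly through
#' [read_mutation_table()] / [read_clinical_table()], and the truth JSON
#' records the full generating config (including the seed), so the fixture
#' can be regenerated identically.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths of the three files.
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  paths <- c(mutations = file.path(dir, "mutations.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.json"))
  readr::write_tsv(cohort$mutations, paths[["mutations"]], progress = FALSE)
  readr::write_tsv(cohort$clinical, paths[["clinical"]], progress = FALSE)
  jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(paths)
}

#' Regenerate a cohort from a fixture's truth block
#'
#' @param truth_path Path to a `truth.json` written by [write_fixture()].
#' @return The regenerated `synthetic_cohort` (identical to the original,
#'   since the truth block records the full config and seed).
#' @export
regenerate_cohort <- function(truth_path) {
  truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  cfg_list <- truth$config
  cfg_list$panel_genes <- as.character(cfg_list$panel_genes)
  simulate_cohort(do.call(simulation_config, cfg_list))
}
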