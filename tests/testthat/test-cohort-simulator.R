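test_that("invalid configs are rejected with the offending parameter named", {
  expect_error(simulation_config(n_patients = 1), "n_patients")
  expect_error(simulation_config(censor_rate = 1.4), "censor_rate")
  expect_error(simulation_config(hr_idh1 = -2), "hr_idh1")
  expect_error(simulation_config(panel_genes = c("TP53", "EGFR")), "panel_genes")
})

test_that("the same config and seed reproduce the cohort exactly", {
  cfg <- small_sim_config(seed = 77, n = 25L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  # a different seed changes the cohort
  c2 <- simulate_cohort(small_sim_config(seed = 78, n = 25L))
  expect_false(identical(a$mutations, c2$mutations))
})

test_that("cohort structure invariants hold", {
  co <- simulate_cohort(small_sim_config(seed = 5, n = 40L))
  samples <- setdiff(names(co$mutations),
                     c("chrom", "pos", "ref", "alt", "gene", "effect_class",
                       "synonymous_flag"))
  pid <- sub("_(BL|PD)$", "", samples)
  expect_true(all(pid %in% co$clinical$patient_id))
  expect_true(all(co$clinical$patient_id %in% pid)) # every patient has a BL column

  keys <- mut_key(gsub(" ", "", co$mutations$chrom), co$mutations$pos,
                  co$mutations$ref, co$mutations$alt)
  expect_true(all(co$truth$unfavorable_keys %in% c(keys, character(0))) ||
                length(co$truth$unfavorable_keys) == 0)
  acq_keys <- unlist(co$truth$acquired)
  if (length(acq_keys) > 0) expect_true(all(acq_keys %in% keys))

  # PD columns exist exactly for truth$pd_patients
  pd_cols <- samples[grepl("_PD$", samples)]
  expect_setequal(sub("_PD$", "", pd_cols), co$truth$pd_patients)

  # NB truth matches the clinical benefit classification
  ben <- classify_benefit(co$clinical$pfs_days, co$clinical$pfs_event,
                          co$clinical$intolerance)
  expect_setequal(co$truth$nb_patients, co$clinical$patient_id[ben == "NB"])
})

test_that("fixtures round-trip losslessly and regenerate from the recorded seed", {
  co <- simulate_cohort(small_sim_config(seed = 9, n = 20L))
  dir <- withr::local_tempdir()
  paths <- write_fixture(co, dir)

  calls_disk <- read_mutation_table(paths[["mutations"]])
  calls_mem <- mutation_calls(co)
  expect_equal(calls_disk, calls_mem)
  expect_equal(read_clinical_table(paths[["clinical"]]), co$clinical)

  # regeneration from the truth block's config is file-identical
  co2 <- regenerate_cohort(paths[["truth"]])
  dir2 <- withr::local_tempdir()
  paths2 <- write_fixture(co2, dir2)
  for (f in names(paths)) {
    expect_identical(readLines(paths[[f]]), readLines(paths2[[f]]))
  }
})

test_that("a mutation-free cohort writes valid header-only tables", {
  cfg <- simulation_config(n_patients = 2, mean_gs_burden_low = 0,
                           mean_gs_burden_high = 0, n_background_variants = 0L,
                           n_unfavorable = 0L, prob_idh1 = 0, prob_intolerance = 0,
                           prob_bl_resistance_other = 0,
                           prob_nb_resistance_panel = 0, seed = 2)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture(co, dir)
  expect_equal(nrow(read_mutation_table(paths[["mutations"]])), 0L)
  expect_equal(nrow(read_clinical_table(paths[["clinical"]])), 2L)
})

test_that("planted hazard ratio is recovered in carrier vs non-carrier medians", {
  # closed-form oracle: exponential median = ln 2 / hazard, so the
  # non-carrier / carrier KM median ratio estimates the planted HR of 3
  ratios <- c()
  for (seed in 1:20) {
    cfg <- simulation_config(n_patients = 400, n_unfavorable = 20L,
                             hr_unfavorable = 3, prev_unfavorable = 0.05,
                             hr_high_burden = 1, hr_idh1 = 1,
                             mean_gs_burden_low = 5, mean_gs_burden_high = 5,
                             n_background_variants = 20L, acquired_rate = 0,
                             prob_pd_sample = 0, seed = 1000 + seed)
    co <- simulate_cohort(cfg)
    calls <- apply_call_filters(mutation_calls(co))
    cl <- co$clinical
    bl <- calls[calls$timepoint == "BL" & calls$in_gs, ]
    for (k in co$truth$unfavorable_keys) {
      carriers <- unique(bl$patient_id[bl$key == k])
      if (length(carriers) < 15) next
      in_c <- cl$patient_id %in% carriers
      med_c <- median_survival(km_estimate(cl$pfs_days[in_c], cl$pfs_event[in_c]))
      med_n <- median_survival(km_estimate(cl$pfs_days[!in_c], cl$pfs_event[!in_c]))
      if (is.na(med_c) || is.na(med_n)) next
      ratios <- c(ratios, med_n / med_c)
    }
  }
  expect_gt(length(ratios), 50)
  expect_lt(abs(mean(ratios) - 3) / 3, 0.15)
})

test_that("with all hazard ratios 1 the planted groups are exchangeable", {
  pvals <- vapply(1:20, function(seed) {
    cfg <- simulation_config(n_patients = 60, hr_high_burden = 1,
                             hr_unfavorable = 1, hr_idh1 = 1,
                             mean_gs_burden_low = 10, mean_gs_burden_high = 30,
                             n_background_variants = 60L, prob_pd_sample = 0,
                             seed = 3000 + seed)
    co <- simulate_cohort(cfg)
    grp <- co$clinical$patient_id %in% co$truth$high_burden
    if (!any(grp) || all(grp)) return(NA_real_)
    logrank_test(co$clinical$pfs_days, co$clinical$pfs_event, grp)$p_value
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  # under the null about 5% of log-rank p-values fall below 0.05
  expect_lte(sum(pvals < 0.05), 4)
  expect_gt(mean(pvals), 0.25)
})
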