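test_that("printed mutation labels parse with grouping spaces stripped", {
  parsed <- parse_mut_key("chr 1: 26 779 439:TG/T")
  expect_equal(parsed$chrom, "chr1")
  expect_equal(parsed$pos, 26779439)
  expect_equal(parsed$ref, "TG")
  expect_equal(parsed$alt, "T")
  expect_equal(parsed$key, "chr1:26779439:TG:T")
  expect_error(parse_mut_key("chr1-12345-A-T"), "cannot parse")
})

write_wide_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("mutation tables read the fixture dialect, including spaced positions", {
  path <- write_wide_tsv(c(
    "chrom\tpos\tref\talt\tgene\teffect_class\tsynonymous_flag\tP1_BL\tP2_BL",
    "chr 1\t26 779 439\tTG\tT\tARID1A\tHIGH\t0\t200:0.12\t0:0.0",
    "chr2\t555\tA\tG\tTP53\tMODERATE\t1\t150:0.4\t90:0.05"
  ))
  calls <- read_mutation_table(path)
  expect_equal(nrow(calls), 3L)  # the 0:0.0 cell produced no record
  arid <- calls[calls$gene == "ARID1A", ]
  expect_equal(arid$pos, 26779439)
  expect_equal(arid$key, "chr1:26779439:TG:T")
  expect_equal(arid$patient_id, "P1")
  expect_false("P2" %in% calls$patient_id[calls$gene == "ARID1A"])
  expect_true(all(calls$synonymous[calls$gene == "TP53"]))
})

test_that("malformed tables produce named parse errors", {
  p1 <- write_wide_tsv(c(
    "chrom\tpos\tref\talt\tgene\teffect_class\tsynonymous_flag\tP1_BL",
    "chr1\t100\tA\tT\tTP53\tWEIRD\t0\t100:0.1"))
  expect_error(read_mutation_table(p1), "effect_class.*WEIRD")

  p2 <- write_wide_tsv(c(
    "chrom\tpos\tref\talt\tgene\teffect_class\tsynonymous_flag\tP1_BL",
    "chr1\t100\tA\tT\tTP53\tHIGH\t0\t100:0.1",
    "chr1\t100\tA\tT\tEGFR\tHIGH\t0\t100:0.1"))
  expect_error(read_mutation_table(p2), "duplicate mutation row")

  p3 <- write_wide_tsv(c(
    "chrom\tpos\tref\talt\tgene\teffect_class\tsynonymous_flag\tP1_BL",
    "chr1\t100\tA\tT\tTP53\tHIGH\t0\toops"))
  expect_error(read_mutation_table(p3), "malformed cell.*P1_BL")
})

test_that("filter chain assigns retained sets per the depth/panel/VAF/effect rules", {
  calls <- make_calls(
    call_row(pos = 1, depth = 99, vaf = 0.1, effect_class = "HIGH"),     # depth fail
    call_row(pos = 2, depth = 500, vaf = 0.5, effect_class = "HIGH"),    # germline-like
    call_row(pos = 3, depth = 500, vaf = 0.1, effect_class = "LOW"),     # low effect
    call_row(pos = 4, depth = 500, vaf = 0.1, effect_class = "HIGH"),    # somatic nonsyn
    call_row(pos = 5, depth = 500, vaf = 0.1, effect_class = "MODERATE",
             synonymous = TRUE),                                         # somatic syn
    call_row(pos = 6, depth = 500, vaf = 0.1, gene = "NOT_A_PANEL_GENE") # off panel
  )
  f <- apply_call_filters(calls)
  expect_equal(nrow(f), nrow(calls)) # no record destroyed

  r <- function(pos, col) f[[col]][f$pos == pos]
  expect_false(r(1, "in_gs"))  # depth 99 excluded from every retained set
  expect_false(r(1, "in_somatic"))
  expect_true(r(2, "in_gs"))   # VAF 0.5 HIGH counts on the germline side of G+S
  expect_false(r(2, "in_somatic"))
  expect_equal(r(2, "origin"), "germline")
  expect_true(r(3, "in_gs"))   # low effect stays in G+S, not in the somatic set
  expect_false(r(3, "in_somatic"))
  expect_true(r(4, "in_somatic"))
  expect_true(r(4, "in_nonsyn"))
  expect_true(r(5, "in_somatic"))
  expect_false(r(5, "in_nonsyn")) # synonymous somatic counts in N+S, not nonsyn
  expect_false(r(6, "in_panel"))
  expect_false(r(6, "in_gs"))

  # empty input: valid empty output, not an error
  empty <- apply_call_filters(calls[0, ])
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("in_gs", "in_somatic", "origin") %in% names(empty)))
})

test_that("filters are idempotent and burdens monotone under stricter settings", {
  co <- simulate_cohort(small_sim_config(seed = 4, n = 30L))
  calls <- mutation_calls(co)
  f1 <- apply_call_filters(calls)
  f2 <- apply_call_filters(f1)
  expect_equal(tibble::as_tibble(f1), tibble::as_tibble(f2))

  b1 <- compute_burdens(f1)
  expect_true(all(b1$ns_mb <= b1$gs_mb))
  expect_true(all(b1$ns_mb >= 0))

  # raising min_depth never increases either burden
  b_strict <- compute_burdens(apply_call_filters(calls, min_depth = 400L))
  j <- dplyr::inner_join(b1, b_strict, by = c("patient_id", "timepoint"))
  expect_true(all(j$gs_mb.y <= j$gs_mb.x))
  expect_true(all(j$ns_mb.y <= j$ns_mb.x))

  # shrinking the panel never increases either burden
  small_panel <- panel_genes_168()[1:20]
  b_small <- compute_burdens(apply_call_filters(calls, panel = small_panel))
  j2 <- dplyr::inner_join(b1, b_small, by = c("patient_id", "timepoint"))
  expect_true(all(j2$gs_mb.y <= j2$gs_mb.x))
})

test_that("burden counts match a hand count on a 10-record profile", {
  rows <- c(
    lapply(1:3, function(i) call_row(pos = i, vaf = 0.45, effect_class = "HIGH")),
    lapply(4:5, function(i) call_row(pos = i, vaf = 0.1, effect_class = "LOW")),
    lapply(6:10, function(i) call_row(pos = i, vaf = 0.1,
                                      effect_class = if (i %% 2) "MODERATE" else "HIGH"))
  )
  calls <- do.call(make_calls, rows)
  b <- compute_burdens(apply_call_filters(calls))
  expect_equal(b$gs_mb, 10L) # 3 germline-like + 2 low-effect + 5 somatic
  expect_equal(b$ns_mb, 5L)

  # germline-only profile: ns_mb = 0
  germ <- do.call(make_calls, lapply(1:4, function(i) call_row(pos = i, vaf = 0.5)))
  bg <- compute_burdens(apply_call_filters(germ))
  expect_equal(bg$ns_mb, 0L)

  # empty profile scores (0, 0) when the patient list is supplied
  b0 <- compute_burdens(apply_call_filters(calls[0, ]), patients = "P9")
  expect_equal(b0$gs_mb, 0L)
  expect_equal(b0$ns_mb, 0L)
})

test_that("a matched WBC sample overrides the VAF proxy for germline assignment", {
  calls <- make_calls(
    call_row(patient_id = "P1", pos = 1, vaf = 0.08),        # in WBC -> germline
    call_row(patient_id = "P1", pos = 2, vaf = 0.45),        # not in WBC -> somatic
    call_row(patient_id = "P1", timepoint = "WBC", pos = 1, vaf = 0.5),
    call_row(patient_id = "P2", pos = 3, vaf = 0.45)         # no WBC -> VAF proxy
  )
  f <- apply_call_filters(calls)
  expect_equal(f$origin[f$patient_id == "P1" & f$pos == 1 & f$timepoint == "BL"], "germline")
  expect_equal(f$origin[f$patient_id == "P1" & f$pos == 2], "somatic")
  expect_equal(f$origin[f$patient_id == "P2" & f$pos == 3], "germline")
  # WBC rows never count toward burdens
  expect_true(all(!f$in_gs[f$timepoint == "WBC"]))
  modes <- attr(f, "filters")$germline_mode
  expect_equal(unname(modes[c("P1", "P2")]), c("wbc", "vaf_proxy"))
})
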