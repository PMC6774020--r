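# Shared fixture builders. Everything is generated in code; no stored data.

# a small, fast simulation: modest burdens either side of a clear gap
small_sim_config <- function(seed = 1L, n = 80L, ...) {
  simulation_config(n_patients = n,
                    mean_gs_burden_low = 30, mean_gs_burden_high = 90,
                    n_background_variants = 200L, seed = seed, ...)
}

# hand-built long-form call tibble (already in read_mutation_table() shape)
make_calls <- function(...) {
  rows <- list(...)
  df <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(patient_id = r$patient_id, timepoint = r$timepoint,
                   chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
                   gene = r$gene, effect_class = r$effect_class,
                   synonymous = r$synonymous, depth = as.integer(r$depth),
                   vaf = r$vaf)
  }))
  df$key <- mut_key(df$chrom, df$pos, df$ref, df$alt)
  df
}

call_row <- function(patient_id = "P1", timepoint = "BL", chrom = "chr1",
                     pos = 1000, ref = "A", alt = "T", gene = "TP53",
                     effect_class = "HIGH", synonymous = FALSE,
                     depth = 500L, vaf = 0.10) {
  list(patient_id = patient_id, timepoint = timepoint, chrom = chrom, pos = pos,
       ref = ref, alt = alt, gene = gene, effect_class = effect_class,
       synonymous = synonymous, depth = depth, vaf = vaf)
}

# clinical table with explicit survival outcomes
make_clinical <- function(patient_id, pfs_days, pfs_event,
                          os_days = pfs_days * 2, os_event = pfs_event,
                          gender = "M", smoking = TRUE, pathology = "LUAD",
                          driver_positive = FALSE, metastases = 1L,
                          intolerance = FALSE, idh1 = FALSE) {
  n <- length(patient_id)
  tibble::tibble(patient_id = patient_id,
                 gender = rep_len(gender, n), smoking = rep_len(smoking, n),
                 pathology = rep_len(pathology, n),
                 driver_positive = rep_len(driver_positive, n),
                 metastases = rep_len(as.integer(metastases), n),
                 pfs_days = as.numeric(pfs_days),
                 pfs_event = as.logical(pfs_event),
                 os_days = as.numeric(os_days), os_event = as.logical(os_event),
                 intolerance = rep_len(intolerance, n),
                 idh1_exon4_mutant = rep_len(idh1, n))
}

# exhaustive permutation p-value for a weighted survival test: all ways of
# assigning the observed group sizes to the observations
perm_survtest_p <- function(time, event, in_a, weight) {
  n <- length(time)
  k <- sum(in_a)
  combos <- utils::combn(n, k)
  stat_of <- function(idx) {
    aa <- rep(FALSE, n); aa[idx] <- TRUE
    tmindex:::weighted_survtest(time, event, aa, weight)$statistic
  }
  obs <- stat_of(which(in_a))
  stats <- apply(combos, 2, stat_of)
  mean(stats >= obs - 1e-12)
}

# brute-force step-up BH, independent of stats::p.adjust
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in seq(m, 1)) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# brute-force AUC by pair counting with 0.5 credit for ties
auc_pairs <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
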