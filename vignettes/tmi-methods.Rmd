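---
title: "Stratifying anlotinib response from circulating DNA: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying anlotinib response from circulating DNA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmindex)
```

## The problem

Advanced non-small cell lung cancer (NSCLC) patients on third-line
multitargeted antiangiogenic therapy (anlotinib) respond very unevenly, and
no molecular predictor of benefit is established. Plasma circulating DNA
(cfDNA/ctDNA) profiled with a targeted 168-gene capture panel offers a
non-invasive readout of the tumor's mutational landscape at baseline (BL)
and at progression (PD). `tmindex` implements a complete stratification
pipeline over such mutation-call tables:

1. a **filter chain** producing two burden predictors — the
   germline+somatic mutation burden (G+S MB) and the
   nonsynonymous+synonymous somatic burden (N+S MB);
2. a baseline **resistance screen** on four ARID1A/BRCA2 frameshift
   mutations that identifies most no-benefit (NB) patients before therapy,
   plus a BL-to-PD **acquired-mutation analysis**;
3. a per-mutation survival screen yielding the **Unfavorable Mutation
   Score (UMS)**;
4. a composite **Tumor Mutation Index (TMI)** built from the three
   predictors, and a combined **TMI + IDH1 exon-4** classifier.

Because the study data behind this design are access-restricted, the
package ships a first-class synthetic cohort generator
(`simulate_cohort()`) that reproduces the statistical structure the
analysis assumes, with every planted effect recorded in a truth block.
All tests and the acceptance script run end-to-end on generated cohorts.

## Benefit classes and endpoints

Progression-free survival (PFS) and overall survival (OS) are in days,
right-censored. Clinical benefit is classified from PFS
(`classify_benefit()`): progression within 45 days (or therapy
intolerance) is *no benefit* (NB); progression after 45 but within 130
days is *no durable benefit* (NDB); benefit beyond 130 days — including
censored follow-up beyond 130 days — is *durable clinical benefit* (DCB).
A patient censored at or before 130 days cannot be assigned; we flag these
`indeterminate` and exclude them from benefit-labelled analyses (ROC
labels), while they still receive burdens and TMI scores. The study cohort
description contains no such patients, so the flag only matters for
simulated or external data.

## The filter chain and the burden predictors

`apply_call_filters()` labels every call without destroying records:

* **depth**: records under 100x are dropped from every retained set;
* **panel**: genes outside the 168-gene capture set are dropped;
* **origin**: germline vs somatic. With a matched white-blood-cell (WBC)
  sample, germline = called in the WBC sample; otherwise the VAF proxy is
  used — VAF > 20% is treated as germline-like, since clonal somatic
  plasma VAFs are low. The mode used per patient is recorded in the
  output's `filters` attribute.
* **effect**: low-effect records (`MODIFIER`, `LOW`) are excluded from the
  somatic set; `MODERATE`/`HIGH` records remain, synonymous and
  nonsynonymous alike.

G+S MB counts all depth-passing panel records (germline-like records with
VAF > 20% count on the germline side, so `0 <= ns_mb <= gs_mb` always);
N+S MB counts the somatic retained set. Whether the original study counted
the germline side before or after effect filtering is not stated; we count
it before (all depth-passing panel records), and the convention is visible
in the code and covered by tests, so the alternative is a one-line change.

Coordinates are 1-based and fully closed, as printed in clinical reports;
grouping spaces in positions (`26 779 439`) are stripped on parse. Indels
keep the table's ref/alt slash representation (`TG/T` = 1-bp deletion):
keys are matched exactly, with no left-normalization.

## The resistance screen

`nb_exclusion_flag()` matches a baseline profile against the default
four-mutation panel (ARID1A A1850fs chr1:26779439 TG/T, ARID1A G766fs
chr1:26762190 TC/T, BRCA2 T3033fs chr13:32379885 CA/C, BRCA2
chr13:32379885 C/CA) by exact key. The printed source mentions five
examined point mutations but lists four distinct keys; the default panel
ships the four printed keys and accepts user extension rows.

`acquired_mutation_set()` compares BL and PD by key on nonsynonymous
records with HIGH effect ("high-effect" acquisition calls; MODERATE
records are excluded). Presence is defined post-filter: a mutation below
the depth filter at BL but above it at PD counts as acquired.

## The UMS screen

`screen_unfavorable_mutations()` tests every baseline mutation carried by
at least one but not all patients: carriers vs non-carriers on PFS with a
two-sample survival test, Benjamini-Hochberg adjustment across all tested
mutations, retention at adjusted p below `alpha` (default 0.01). Two
deliberate design points:

* **Direction filter.** Only mutations whose carriers fare *worse*
  (positive observed-minus-expected event sum in the carrier group) are
  "unfavorable". Without this, protective mutations would inflate the
  score. The filter can be disabled.
* **Raw vs adjusted threshold.** The source narrative is ambiguous about
  whether its 120 retained mutations passed the raw or the BH-adjusted
  threshold; both modes are implemented (`adjust = "BH"` default,
  `"raw"` optional) and the mode is recorded in the result attributes.

`ums_score()` counts carried unfavorable keys with unit weights; `group`
is `negative` at score 0 and `positive` otherwise. The published group
definitions conflict slightly (positive = any mutation vs high-risk =
more than one); we default to positive = score >= 1 so the groups
partition the cohort, and expose `highrisk_min = 2` for the other reading.

## Survival machinery

* `km_estimate()` wraps `survival::survfit`; `median_survival()` returns
  the smallest time with S(t) <= 0.5 (so a curve that touches 0.5 exactly
  reports the earlier time), or `NA` for "not reached".
* `logrank_test()` / `gehan_wilcoxon_test()` are a hand-implemented
  weighted log-rank family. "Wilcoxon" for survival curves is implemented
  as the Gehan-Breslow generalized Wilcoxon (event-time weights = number
  at risk), with the Peto-Peto variant as an option; `survival::survdiff`
  offers only the G-rho family, so it serves as an independent
  cross-check for the unweighted case in the tests. P-values are
  two-sided, from the 1-df chi-square approximation. At very small n
  (<= 8) this approximation deviates from the exhaustive permutation
  distribution by up to ~0.1 — an inherent small-sample property
  documented by the test suite, not an implementation defect.
* `roc_auc()` computes the pairwise-concordance AUC (ties credited 0.5)
  with a Hanley-McNeil standard error, normal-approximation confidence
  interval, and a two-sided z null test against AUC = 0.5. The risk
  orientation is fixed: higher score predicts the poor-outcome class.
* `bh_adjust()` wraps `stats::p.adjust(method = "BH")`.

### The minimum-p cutoff scan

`ward_cutoff_scan()` implements the study's cutoff selection: candidates
are midpoints between consecutive distinct predictor values leaving at
least `min_group` (default 3) patients per arm; each candidate is scored
by a two-sample survival test; the candidate with minimal p is the
cutoff, ties resolving to the smallest. Two caveats the user should know:

* The scan's p-values are reported unadjusted, as in the source; because
  the minimum over many correlated tests is anti-conservative,
  `chosen_p` is a selection criterion, not a calibrated significance
  level. Validation on held-out patients (below) is the honest check.
* The *location* of the chosen cutoff is indeterminate within the
  boundary region: splits that differ by one or two borderline patients
  have stochastically near-equivalent p, so the scan reliably separates
  two well-separated predictor populations but does not reliably land in
  the exact empty interval between them. The recovery tests therefore
  assert separation of the planted distributions, not membership in the
  literal gap.

## Predictor evaluation and the TMI score card

`evaluate_predictor()` freezes a responder rule on a discovery cohort —
strictly below the scanned cutoff for burdens (and the TMI), negative
score for the UMS — and computes, overall and in the ten demographic
subgroups (male/female, smoking/non-smoking, LUAD/LUSC, driver-gene
positive/negative, more than 3 / at most 3 metastases), the two-sample
PFS and OS p-values and the ROC results. ROC labels: NDB vs DCB for PFS;
for OS, where the source defines no benefit dichotomy, we label patients
at or below the evaluation cohort's median OS as the poor-outcome class.
Subgroups with under `min_group` patients in either arm, or a missing
outcome class, are not evaluable and contribute nothing.

The score card (`tmi_scorecards()`) gives, per predictor: 50 baseline
points for responders, plus subgroup points — for each of the patient's
five matching subgroups, significance points for the subgroup PFS and OS
comparisons (1/2/3 below 0.05/0.01/0.001) and AUC points (1 for AUC >
0.7, plus significance-style points on the null-test p). Three published
rules are under-specified and resolved here as the only reading that
keeps the TMI in [0, 100] given its printed normalization constant 300:

* subgroup points are awarded only to patients the predictor classifies
  as responders (non-responders score 0 for that predictor);
* the subgroup sum is capped at 50 per predictor, so the maximum total is
  3 x 50 baseline + 3 x 50 subgroup = 300;
* "responder" means per-predictor classification, not clinical benefit —
  using DCB labels would leak the outcome into the score.

`TMI = 100 x (300 - total) / 300` is kept unrounded for classification
(round to one decimal only for display). `tmi_classify()` is strict:
low (responder side) only below the cutoff. `combined_tmi_idh1()` labels
a patient unfavorable only when high-TMI *and* IDH1 exon-4 mutant; a
low-TMI patient is never unfavorable.

## Pipeline

`run_discovery()` orchestrates: filter, burdens, benefit classes, NB
exclusion, discovery/validation split, UMS screen, three predictor
evaluations, score cards for all analysis patients from discovery-frozen
statistics, TMI cutoff scan, combined classifier, and a manifest of every
threshold and seed. NB exclusion is clinical (benefit class NB), mirroring
the source cohort construction; the resistance-panel flags are computed
alongside and their concordance reported, since the panel is the
prospective surrogate for that exclusion. The discovery split is seeded
random at fraction 62/85 by default and can be pinned with a patient list.

Burden and UMS cutoff scans use the Gehan-Wilcoxon test (the test used
while assembling the score card); the TMI scan and stratification use the
log-rank test (the test reported for TMI-based Kaplan-Meier analysis);
`run_validation()` applies only frozen artifacts to held-out patients and
reports log-rank stratification for the validation and pooled cohorts.
`pipeline_report()` produces composition tables (subgroup fractions per
predictor class) and an oncoprint-style acquired-mutation matrix.

## The synthetic cohort generator

`simulate_cohort()` draws, per patient: demographics; a low/high burden
group (fraction 19/62 high); a target G+S burden (Poisson with group mean,
defaults 2500/5500 — either side of a cutoff near 4000); carriage of a
shared background variant pool sized `2 x mean_gs_burden_high` (carriage
probability = target burden / pool size); planted unfavorable mutations
(Bernoulli `prev_unfavorable` each); an IDH1 exon-4 mutation; and event
times from a Weibull model (exponential by default, shape exposed) with
per-patient hazard

```
log(2)/baseline_median_pfs_days x hr_high_burden^[high] x
hr_unfavorable^(#unfavorable carried) x hr_idh1^[IDH1 mutant]
```

Exponential defaults make closed-form medians (`ln 2 / hazard`) exact
oracles for the tests. Censoring is an independent exponential time with
rate chosen so a fraction `censor_rate` of observations are censored; OS
is PFS times a patient-level Gamma factor (>1) plus noise. NB status
*emerges* from the model — progression within 45 days or intolerance —
and NB patients then carry a resistance-panel mutation at baseline with
probability 0.92 (the planted concordance); non-NB patients with
probability 0.05. Durable-benefit patients contribute a PD sample whose
calls are the BL calls plus Poisson-many acquired HIGH nonsynonymous
mutations, drawn preferentially from ARID1A/BRCA2 (and the resistance
panel itself) for planted-resistant patients. VAFs are Beta: germline
centred at 0.5, somatic centred near 0.1 with a tail crossing the 20%
threshold, so the VAF proxy separates the classes imperfectly — a
realistic stress for the filter. A small fraction of cells are
low-depth (5%) and of variants off-panel (3%) to exercise those filters.

Default hazard ratios are `hr_high_burden = 1.65` (group medians near the
reported 210 vs 127 days), `hr_unfavorable = 1.25` per mutation at
prevalence 0.08 (multiplicative stacking keeps the total load moderate
and the NB fraction near the reported 26/111), and `hr_idh1 = 1.8` at
prevalence 0.15. One shared random stream is seeded once per cohort; the
truth block records the full config, so `regenerate_cohort()` reproduces
a fixture file-identically.

What the generator does *not* emulate: read-level noise and sequencing
error, tumor-fraction and clonal structure, VAF trajectories between
timepoints, correlated carriage beyond the burden effect, or non-
proportional hazards. Passing tests therefore demonstrate that the
pipeline recovers the structure this model plants at desk scale — not
that the clinical effect sizes themselves are reproducible, which would
require the restricted patient data. The study's printed cutoffs (4000
for G+S MB, 60 for TMI) are defaults and worked-example values, never
re-derivation targets.

## Problem sizes used by the test suite

The suite runs cohorts of 20-200 patients with background pools of
200-300 variants and burden means 30/90 (the same generative structure as
the full-scale defaults, scaled so the whole suite completes in a few
minutes): type-I calibration uses 50 null cohorts (n = 100, ~200 tested
mutations); screen recovery uses 20 cohorts (n = 200, two isolated
hazard-ratio-3 mutations at 20% prevalence among ~200 null background
mutations — isolating the per-mutation property, since stacking twenty
HR-3 mutations would collapse median survival to days); scan recovery and
TMI stratification use 50 replicates at n = 200 under default planted
effects. Numerical conventions worth noting: day-rounded event times (so
ties are exercised), strict-inequality responder boundaries, smallest-
candidate tie-breaks in the scan, and BH inputs validated to [0, 1].

## Known limitations

* The minimum-p scan is anti-conservative by construction; treat
  discovery p-values as selection scores and rely on validation.
* The chi-square p of the weighted log-rank tests is loose below n ~ 10;
  an exact permutation option is deliberately not the default to keep the
  implementation and its test oracle independent.
* The OS ROC labels (median-OS dichotomy) are a package convention where
  the source is silent; AUC values for OS are comparable within, not
  across, conventions.
* With default effect sizes and BH screening at alpha 0.01, small cohorts
  often yield an *empty* unfavorable set; the UMS then contributes a
  constant 50-point baseline to every patient's TMI. This mirrors the
  score's behaviour, not a failure: the raw-p mode reproduces the more
  permissive published count.
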