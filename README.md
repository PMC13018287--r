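# methstab

DNA methylation instability analysis for blood cohorts: discovery of
**epigenetically stable loci (ESLs)**, calibration of a destabilization
threshold, per-sample **DNA methylation instability (DMI)** scoring,
epi-clone tracking between diagnosis and relapse, outcome stratification,
and promoter-centred gene prioritization.

## The scientific problem

Most CpG sites on methylation arrays vary between individuals and cell
types.  A minority are *epigenetically stable*: across large healthy
cohorts they sit hard against one methylation pole (β ≈ 0 or β ≈ 1) with
almost no variance.  Because their background is so uniform, methylation
gained (or lost) at these loci is an unusually clean readout of somatic
epigenetic change — clonal hematopoiesis, leukemia burden, and age-related
drift all leave a footprint there.  `methstab` implements the full analysis
stack around this idea for anyone working with β-value matrices
(CpG probes × samples, values in [0, 1]):

1. **ESL discovery** — rank probes by cohort β variance (unbiased n − 1
   estimator), keep the least-variable fraction (default 10%), drop
   blocklisted probes (SNP-adjacent, cross-reactive, age-predictive, sex
   chromosomes, non-CpG), drop candidates that are outliers in purified
   cell types, and classify the survivors by their bimodal means into
   stably unmethylated vs stably methylated loci.
2. **Destabilization threshold** — per control cohort, compute each ESL's
   mean β; pool all cohort × ESL means; the threshold is the 99.9th
   percentile of the pool (type-7 linear interpolation).  A sample
   destabilizes a low-pole ESL when its β strictly exceeds the threshold
   (mirrored for the high pole).
3. **Recurrence** — per-ESL fraction of samples perturbed; `< 5%` is
   low-recurrence (patient-specific, epi-clone material), `≥ 5%` recurrent
   (used for DMI).
4. **DMI** — a per-sample scalar: the standard deviation of the sample's β
   values over a designated ESL subset.  On mixture cohorts DMI rises
   monotonically with clone fraction and with age.
5. **Epi-clone matching** — per patient, the k = 15 low-recurrence ESLs
   most methylated at relapse form a signature; samples are clustered with
   Ward linkage on 1 − Pearson r over the union of signatures, and a
   diagnosis–relapse pair is *correct* when the two samples merge as
   immediate dendrogram siblings.  Significance comes from a permutation
   test (random k-locus signatures per patient,
   p = #{sims with ≥ observed correct}/n_sims).
6. **Lineage enrichment** — per-ESL two-sided Fisher's exact tests of
   perturbation counts between lineages with Bonferroni correction, then
   the prevalence/odds-ratio selection rules for lymphoid-enriched
   (OR > 1, prevalence ≥ 50%, top half by OR) and myeloid-enriched loci
   (two pairwise comparisons intersected, prevalence ≥ 10%).
7. **Outcomes** — median or extreme-quartile DMI stratification,
   Kaplan–Meier curves with log-log CIs, log-rank tests, covariate-adjusted
   Cox models, and a simulation-based power/sample-size search (with a
   Schoenfeld closed-form cross-check).
8. **Gene prioritization** — map recurrent ESLs to promoters (within
   1500 bp upstream of a TSS), then intersect three criteria: negative
   methylation–expression correlation, negative age–expression correlation
   (both Bonferroni-corrected), and mean promoter-ESL recurrence above 5%.

A first-class synthetic-cohort generator (`sim_config()`,
`simulate_cohort()`, `simulate_longitudinal_cohort()`,
`simulate_survival_cohort()`) plants ground truth — stable loci, clonal
signatures with E[β] = (1 − f)·μ_bg + f·μ_clone, age drift, and
proportional-hazards survival — so every stage is testable end to end.

## Worked example

```r
library(methstab)

# healthy discovery cohort with planted stable loci
sim <- simulate_cohort(sim_config(n_probes = 10000, n_samples = 500), seed = 42)
esl <- discover_esls(sim$beta, fraction = 0.10)
esl
#> esl_set: 1000 loci (800 unmethylated, 200 methylated)
#>   empty band: (0.029, 0.969)

# destabilization threshold from three control cohorts
um <- esl$probe_id[esl$esl_class == "unmethylated"]
controls <- lapply(1:3, function(k) {
  ctrl <- simulate_cohort(sim_config(n_probes = 10000, n_samples = 150),
                          seed = 100 + k, probe_model = sim$truth)
  beta_matrix(unclass(ctrl$beta)[um, , drop = FALSE])
})
thr <- calibrate_threshold(controls, percentile = 99.9)
#> destabilization threshold: 0.02874

# binarize a clonal cohort; recurrence and DMI
set.seed(6)
leuk <- simulate_cohort(sim_config(n_probes = 10000, n_samples = 200),
                        seed = 7, clone_fractions = runif(200, 0.2, 0.9),
                        probe_model = sim$truth)
prof <- destabilization_profile(
  beta_matrix(unclass(leuk$beta)[um, , drop = FALSE]), thr, "low")
prof
#> destab_profile: 800 ESLs x 200 samples (pole low, threshold 0.02874)
#>   recurrent (>= 5%): 78; low recurrence: 722
dmi <- compute_dmi(leuk$beta, um, subset_label = "unmethylated ESLs")
cor(dmi$dmi, leuk$truth$clone_fraction)
#> 0.999

# diagnosis-relapse epi-clone matching with a permutation null
lc <- simulate_longitudinal_cohort(sim_config(n_probes = 50000), 24, seed = 11,
                                   timepoints = c("diagnosis", "relapse"))
match_epiclones(lc$beta, lc$meta, lc$truth$stable_low, k = 15,
                n_sims = 200, seed = 12)
#> matching_result: 24/24 diagnosis-relapse pairs correct (sibling)
#>   permutation p = 0.005 (200 simulations)

# DMI survival stratification under a planted hazard ratio of 1.5
surv <- simulate_survival_cohort(
  sim_config(baseline_hazard = 0.1, log_hr = log(1.5)),
  rep(c("high", "low"), 1000), seed = 13)
km_analysis(surv, data.frame(sample_id = surv$sample_id,
                             group = surv$dmi_group))
#> km_result (mortality): n = 2000, events = 1649
#>   log-rank p = 1.332e-13; HR(high vs low) = 1.443 [1.309, 1.591]
```

The 1000 discovered loci are exactly the planted 10% stable decile; the
calibrated threshold sits just above the background pole, so the clonal
cohort's recurrence and DMI are driven by planted signatures (DMI tracks
clone fraction at r ≈ 1); the 24 diagnosis–relapse pairs cluster as
siblings and random signatures almost never reproduce that (p = 0.005 at
200 simulations); and the Cox hazard ratio recovers the planted 1.5 within
its confidence interval.

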