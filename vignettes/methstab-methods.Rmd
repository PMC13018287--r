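---
title: "Methods: stable-locus discovery, methylation instability and epi-clone tracking"
author: "methstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stable-locus discovery, methylation instability and epi-clone tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methstab)
```

## Scope and model

`methstab` analyses β-value matrices (CpG probes × samples, β ∈ [0, 1],
the methylated fraction of total signal at a CpG).  Its object of study is
the small class of CpGs that are *epigenetically stable* in healthy blood:
pinned to one methylation pole with near-zero cohort variance.  Stability
makes these loci sensitive detectors of somatic change — any methylation
appearing at a normally unmethylated stable locus must have been acquired,
and if a cell clone expands, its private methylation marks rise in bulk β
proportionally to the clone's share of the sample.  The pipeline exploits
this in five ways: a per-sample instability scalar (DMI), longitudinal
clone tracking, patient-specific epi-clone signatures that link diagnosis
and relapse samples, lineage-biased perturbation catalogues, and a
promoter-centred prioritization of genes plausibly silenced by the process.

The package starts at β values.  Raw array preprocessing (IDAT parsing,
normalisation, detection p-values) and cell-type deconvolution are out of
scope; deconvolved cell fractions enter only as ordinary Cox covariates.

## ESL discovery

Given a healthy discovery cohort:

1. **Blocklist filtering** (`filter_probes`): probes flagged as
   SNP-adjacent, cross-reactive, age-predictive, on sex chromosomes, or
   non-CpG are removed before any ranking.  Blocklists are user-supplied
   annotation columns; the package does not attempt to reconstruct
   platform-era manifests.
2. **Variance ranking** (`rank_variance`): per-probe variance over
   non-missing values with the unbiased n − 1 denominator.  The estimator
   choice is numerically immaterial at cohort scale but is fixed so that
   tie-breaking (by probe ID) is deterministic across platforms.
3. **Selection** (`select_stable`): the `floor(fraction × n)` least
   variable probes, default fraction 0.10.
4. **Purified-cell filter** (`filter_purified_outliers`): a locus that
   looks stable in whole blood can be methylated in one purified cell
   population and merely diluted in bulk.  "Outlier" is under-determined,
   so the rule is explicit and configurable: the default removes a
   low-pole candidate if *any* sample of *any* purified cell type exceeds
   β = 0.1 (mirrored at 0.9 for the high pole); an alternative
   1.5 × IQR Tukey-fence rule per cell type is selectable.  When no
   purified data are supplied the step is skipped with an explicit
   message.  Variance selection runs first and purification second; both
   counts are retained (`n_candidates` attribute).
5. **Bimodal classification** (`classify_bimodal`): stable loci are
   expected to be bimodal — means near 0 or near 1 with an empty middle.
   The split point is 0.5 and a forbidden band (default (0.2, 0.8)) must
   be empty; any candidate mean inside it is excluded with a warning, and
   the observed empty band (largest unmethylated mean, smallest
   methylated mean) is reported.

All subsequent analyses focus on the unmethylated ESL class, whose
destabilization behaves consistently across disease cohorts; the high-pole
class is supported symmetrically.

## Destabilization threshold and recurrence

`calibrate_threshold` computes, per control cohort, each ESL's mean β,
pools all cohort × ESL means, and returns a percentile of the pool
(default 99.9).  Percentiles of a finite pool are definition-sensitive, so
the definition is pinned: type-7 linear interpolation between order
statistics (the `stats::quantile` default), recorded alongside the pool
size.  Binarization (`binarize_calls`) is strict — a low-pole call is 1
iff β > threshold ("exceeding"), so values equal to the threshold are
unperturbed and ties are stable.  The mirrored high-pole rule calls
β < threshold with a low-percentile calibration (e.g. 0.1).

`call_recurrence` divides perturbed by non-missing calls per locus;
missing calls leave both numerator and denominator, avoiding bias from
cohort-specific missingness.  The class boundary is *inclusive*:
recurrence ≥ 5% is "recurrent", below is "low" — where the two
formulations "5% or more" and "over 5%" conflict, the inclusive Methods
formulation wins and the choice is documented here.  `conditional_mean_beta`
averages β only over perturbed samples, so for low-pole loci it always
exceeds the threshold where defined.  `recurrence_beta_correlation`
reports Pearson r with a two-sided t-test between recurrence and
conditional means; on cohorts where large clones preferentially perturb
widely shared loci this correlation is strongly positive.

## DMI

`compute_dmi` is deliberately simple: the per-sample standard deviation
(n − 1) of β over a designated ESL subset.  The default subset is the
recurrent class — loci perturbed often enough that a per-sample spread is
informative — with any subset (e.g. all unmethylated ESLs) available for
sensitivity analysis.  Whether a population or sample SD was intended is
unrecoverable from the definition alone; with equal locus counts across
samples the choice is a global scale factor, and n − 1 is fixed here.
DMI is invariant to locus and sample order, contracts when a locus equal
to the sample mean is added, and on mixture cohorts is monotone both in
clone fraction (fixed signature size) and in signature size (fixed
fraction) — all asserted by tests.

`dmi_age_trend` groups samples into 5-year, left-closed, right-open bins
anchored at the cohort minimum age floored to a bin-width multiple,
computes per-bin means with normal-approximation 95% CIs, and fits the
regression *on bin means* (as is conventional for this display), also
reporting Pearson r/p over the bin means.  Single-sample bins are flagged
(undefined CI); fewer than three non-empty bins is an error.

## Epi-clone matching

`select_signature` takes the k (default 15) low-recurrence loci with the
highest β in a designated sample (relapse by default; a
`signature_from = "diagnosis"` flag covers the converse analysis), ties
broken by probe ID.  `cluster_and_pair` builds the union of all patients'
signatures, computes sample–sample distance 1 − Pearson r, and
agglomerates with Ward's criterion (`hclust` "ward.D2").  Ward linkage on
a correlation dissimilarity is mathematically unorthodox — Ward's
derivation assumes squared Euclidean distances — but it is the procedure
this analysis is defined by, and the caveat stops here.

"Correctly paired" needs a definition the dendrogram itself supplies: a
diagnosis–relapse pair is correct iff the two samples are merged as
immediate siblings (each one's first merge partner is the other).  This is
the unique parameter-free reading of pairing from a tree; a
mutual-nearest-neighbour alternative is available behind
`pairing = "mnn"`.

`epiclone_permutation_test` draws, per simulation, k random low-recurrence
loci per patient (without replacement within a patient), rebuilds the
union, re-clusters, counts correct pairs, and reports
p = #{simulations with count ≥ observed}/n_sims — the exceedance
proportion exactly as defined, with no +1 correction by default (a
`plus_one` flag provides the (b + 1)/(m + 1) estimator).  The test is
sometimes labelled two-sided in the field; the quantity actually defined
is the one-tailed exceedance proportion and that is what is implemented.

Two properties of this statistic matter for interpretation.  First, the
pool must dwarf the planted signal: with N loci in the low-recurrence pool
and P patients, a random draw leaks a given patient's signature locus with
probability ≈ kP/N per locus, so for small pools random signatures still
carry the clonal signal and p is conservative — mirroring why the real
analysis runs on a pool of tens of thousands of loci.  Second, the
exceedance p on an integer count is discrete and super-uniform under the
null (P(p ≤ t) ≤ t, with an atom at p = 1 whenever the observed count is
0).  A continuous uniformity test applied to the raw p would reject for
any correctly implemented exceedance statistic; calibration is therefore
checked on the randomized rank of the observed count among its own
permutation replicates, which is exactly Uniform(0, 1) under
exchangeability, alongside a direct super-uniformity check of the plain p
at the 5% level.

## Lineage enrichment

`fisher_per_esl` tests each locus's 2 × 2 perturbation table between two
groups with the two-sided Fisher's exact test (minimum-likelihood rule for
the two-sided tail, the standard exact convention) and Bonferroni
correction over tested loci.  The odds ratio is the raw cross-product
ratio, oriented so OR > 1 means higher perturbation odds in the named
target group; the Haldane–Anscombe 0.5 correction is applied only when a
zero cell occurs, keeping ORs finite for ranking without perturbing exact
tables.  `select_lymphoid` keeps significant loci with OR > 1 and target
prevalence ≥ 50%, ranks by OR (ties by smaller p, then probe ID) and
designates the top half — `floor(n/2)` on odd counts.  `select_myeloid`
runs two pairwise comparisons, intersects the loci passing significance
and OR > 1 in both, and applies the 10% prevalence bar; an optional
top-fraction cut per comparison exists but is off by default, since the
adapted procedure is described only loosely and the conservative reading
is the plain intersection.

## Outcomes

`stratify_dmi` implements the median rule (strictly above the median is
high; ties at the median go low — the documented resolution of the
even-cohort ambiguity) and the extreme-quartile rule (≥ Q3 high, ≤ Q1
low, middle excluded; type-7 quantiles).  Exclusion of participants with
a prevalent endpoint belongs in data preparation, upstream of these
functions.  `km_analysis` and `cox_adjusted` delegate the estimators to
the `survival` package (product-limit curves with log-log 95% CIs,
log-rank test, proportional-hazards fits); the package's own content is
the stratification contract, input validation and degenerate-case
behaviour (zero events: curves are returned, HR and log-rank p are
declared undefined rather than guessed).

`power_sample_size` is simulation-based, like the analysis it supports:
patients are split 50/50 into high/low groups, event times drawn from an
exponential proportional-hazards model, censoring independent exponential
calibrated to the target censoring fraction, and power estimated as the
rejection rate of the log-rank test over `n_iterations` trials per
candidate n, with its Monte Carlo SE.  Pilot survival data may replace
the explicit event model (exponential rate = events / person-time,
censoring fraction from the data).  `schoenfeld_sample_size` provides the
closed-form events-based cross-check.

## Gene prioritization

`map_promoter_esls` assigns a locus to its nearest gene when
−1500 ≤ tss_distance ≤ 0 (upstream-only window, used for prioritization);
a symmetric ±1500 bp window is used for the promoter-proximity
enrichment report — two windows because the two analyses are defined on
different intervals.  `correlate_meth_expr` computes per-ESL Pearson
correlations between β and the gene's expression, log2(x + 1)-transformed
by default (a documented convention; raw TPM is available), averaging r
over a gene's ESLs.  "Significant negative correlation" at gene level is
made explicit: the gene's mean r must be negative and at least one of its
ESLs must carry a Bonferroni-significant negative correlation (correction
over all tested ESLs); the convention is configurable.
`correlate_age_expr` tests each gene's expression against donor age with
Bonferroni correction over genes.  `prioritize_genes` is the conjunction:
significant negative methylation–expression correlation, significant
negative age–expression correlation, and mean promoter-ESL recurrence
strictly above 5%.  `context_enrichment` reports the CpG-island 2 × 2
odds ratio (raw cross-product, Fisher p) of an ESL set against the
non-ESL background and the fraction of ESLs within 1500 bp of a TSS.
Bonferroni is used throughout the package for multiplicity, matching the
analysis family it implements.

## The synthetic cohort generator

`sim_config` defines a forward model chosen to make every pipeline claim
testable with planted truth, not to be a generative model of array data:

* **Background**: each probe draws β from a beta distribution.  Stable
  probes get means skewed hard against their pole (Beta(1, 5) profile
  within [0.005, 0.04], mirrored at the high pole) and concentration 1000
  (within-probe SD ≈ 0.004 at the low pole) — most stable loci sit at the
  pole with a thin tail inward, reproducing the bimodal mean profile of
  stable sites and leaving the calibrated threshold above almost all
  background variation.  Variable probes get uniform means in
  [0.05, 0.95] and concentrations 2–50, so their variance is at least an
  order of magnitude above the stable class.
* **Clones**: each affected sample carries a patient-specific signature of
  `signature_size` (default 15) loci sampled from the stable-unmethylated
  pool; at those loci β is the mixture (1 − f)·background + f·clone with
  clone level Beta-distributed around 0.8.  E[β] is affine in clone
  fraction f, which the tests verify by regression, and which makes DMI
  monotone in f.
* **Age**: a per-sample Poisson number of perturbed loci with mean
  0.1 × age (years), each at a small mixture fraction (0.05–0.2) —
  a linear accumulation hazard giving the DMI–age trend a planted
  analogue.
* **Survival**: exponential event times under proportional hazards
  (default log HR = log 1.5 for the high-DMI group), independent
  exponential censoring calibrated to the target censoring fraction —
  the simplest model satisfying the Cox assumptions downstream analyses
  make.

Default cohort dimensions are 10,000 probes with a 10% stable fraction
(8% unmethylated, 2% methylated — roughly the observed 5:1 class ratio)
and 500 samples.  A `probe_model` argument lets several cohorts
(discovery + controls + disease) share one planted locus structure, as a
real probe panel would.  All randomness is fixed by a single seed and the
generators restore the caller's RNG state.

What the generator does *not* emulate — batch effects, array chemistry,
cell-composition shifts, genotype effects, spatially correlated probes,
non-exponential hazards — bounds what green tests mean: they establish
that the algorithms are implemented correctly and behave as designed
under their stated assumptions, not that real cohorts will reproduce any
published effect size.  Quantities tied to specific external cohorts
(published locus counts, the β = 0.05932 threshold value, specific
hazard ratios, gene lists) are out of reach by construction and are not
claimed.

## Problem sizes and numerical conventions in the test suite

The package's validation suite fixes its own study sizes: discovery
recovery on 20 cohorts of 10,000 probes × 500 samples; DMI monotonicity
over clone fractions 0–0.9 with 50 replicates each (20-sample cohorts);
matching power on 100 cohorts of 24 diagnosis–relapse pairs (5,000-probe
panels) and null calibration over 500 cohorts of 8 pairs at 200
permutations each; Fisher agreement with exhaustive hypergeometric
enumeration over every 2 × 2 table of total size ≤ 30; 200 permuted-label
datasets for the false-positive control; 100 replicates of n = 2000
survival cohorts for Cox bias and coverage; and 100 fully-null
prioritization replicates of 300 genes × 60 samples.  Threshold
calibration is checked against an independent sort-and-interpolate oracle
to 10⁻¹² on 1000 random pools.

Other conventions, gathered in one place: probe-ID tie-breaks everywhere
a rank or top-k cut occurs; strict inequalities at the destabilization
threshold; inclusive 5% recurrence boundary; type-7 quantiles for
percentile, quartile and IQR computations; Bonferroni for multiplicity;
`ward.D2` for Ward agglomeration; Haldane–Anscombe only at zero cells;
write/read round-trips serialized at `%.17g` so doubles survive exactly.

## Known limitations

* The purified-cell outlier rule is a parameter-explicit stand-in for an
  under-specified step; results depend on its ceiling/floor (or fence)
  settings.
* Sibling-merge pairing is stricter than visual dendrogram reading; a
  pair separated by one intervening merge counts as incorrect.
* The permutation p is conservative when the low-recurrence pool is small
  relative to k × patients (signal leakage into random signatures).
* The power search assumes exponential baselines; with strongly
  non-exponential pilot hazards the closed-form cross-check is the better
  sanity bound.
* Expression/β correlations are Pearson on (log-transformed) values;
  heavy-tailed expression may warrant rank-based sensitivity analyses,
  which the package does not automate.
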