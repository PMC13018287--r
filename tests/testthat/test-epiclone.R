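test_that("signature selection is a top-k sort with lexicographic ties", {
  b <- c(a = 0.9, b = 0.5, c = 0.1)
  expect_identical(select_signature(b, 2), c("a", "b"))
  # all equal: first k by probe ID
  b2 <- c(z = 0.4, m = 0.4, a = 0.4)
  expect_identical(select_signature(b2, 2), c("a", "m"))
  # sorting oracle on random vectors
  set.seed(51)
  for (i in 1:10) {
    v <- setNames(runif(40), sprintf("cg%02d", sample(40)))
    k <- sample(1:20, 1)
    oracle <- names(sort(v, decreasing = TRUE))[seq_len(k)]
    expect_setequal(select_signature(v, k), oracle)
  }
  expect_error(select_signature(b, 4), "need k")
})

test_that("separable patients pair as dendrogram siblings", {
  cfg <- sim_config(n_probes = 1000, n_samples = 4)
  lc <- simulate_longitudinal_cohort(cfg, 2, seed = 61,
                                     diagnosis_fraction = 0.9,
                                     relapse_fraction = 0.9,
                                     timepoints = c("diagnosis", "relapse"))
  union_loci <- unique(unlist(lc$truth$signatures))
  res <- cluster_and_pair(lc$beta[union_loci, , drop = FALSE], lc$meta)
  expect_identical(res$n_correct, 2L)
  expect_identical(res$n_patients, 2L)
  # sibling-pair symmetry: at most n/2 sibling pairs, each counted once
  expect_lte(nrow(res$pairs), ncol(lc$beta) / 2)
  # mutual-nearest-neighbour criterion agrees on the separable case
  res_mnn <- cluster_and_pair(lc$beta[union_loci, , drop = FALSE], lc$meta,
                              pairing = "mnn")
  expect_identical(res_mnn$n_correct, 2L)
})

test_that("constant profiles and malformed designs are rejected", {
  x <- matrix(runif(20), 5, 4,
              dimnames = list(paste0("g", 1:5),
                              c("p1_diagnosis", "p1_relapse",
                                "p2_diagnosis", "p2_relapse")))
  meta <- data.frame(sample_id = colnames(x),
                     patient_id = rep(c("p1", "p2"), each = 2),
                     timepoint = rep(c("diagnosis", "relapse"), 2))
  x[, 2] <- 0.5
  expect_error(cluster_and_pair(x, meta), "p1_relapse")
  meta2 <- meta
  meta2$timepoint <- c("diagnosis", "diagnosis", "relapse", "relapse")
  expect_error(cluster_and_pair(matrix(runif(20), 5, 4,
                                       dimnames = dimnames(x)), meta2),
               "exactly one diagnosis")
})

test_that("permutation p-value boundary cases and determinism", {
  cfg <- sim_config(n_probes = 800, n_samples = 8)
  lc <- simulate_longitudinal_cohort(cfg, 4, seed = 71,
                                     diagnosis_fraction = 0,
                                     relapse_fraction = 0,
                                     timepoints = c("diagnosis", "relapse"))
  # observed = 0 is never beaten: p = 1
  p0 <- epiclone_permutation_test(lc$beta, lc$meta, lc$truth$stable_low,
                                  observed = 0, k = 10, n_sims = 20,
                                  seed = 5)
  expect_equal(p0$p, 1)
  # observed above n_patients is unattainable: p = 0
  p5 <- epiclone_permutation_test(lc$beta, lc$meta, lc$truth$stable_low,
                                  observed = 5, k = 10, n_sims = 20,
                                  seed = 5)
  expect_equal(p5$p, 0)
  # identical seed, identical p; plus-one estimator shifts as documented
  pa <- epiclone_permutation_test(lc$beta, lc$meta, lc$truth$stable_low,
                                  observed = 2, k = 10, n_sims = 30,
                                  seed = 9)
  pb <- epiclone_permutation_test(lc$beta, lc$meta, lc$truth$stable_low,
                                  observed = 2, k = 10, n_sims = 30,
                                  seed = 9)
  expect_identical(pa$sim_counts, pb$sim_counts)
  pc <- epiclone_permutation_test(lc$beta, lc$meta, lc$truth$stable_low,
                                  observed = 2, k = 10, n_sims = 30,
                                  seed = 9, plus_one = TRUE)
  expect_equal(pc$p, (sum(pa$sim_counts >= 2) + 1) / 31)
  expect_error(epiclone_permutation_test(lc$beta, lc$meta,
                                         lc$truth$stable_low[1:5],
                                         observed = 1, k = 10, n_sims = 5),
               "smaller than k")
})

test_that("p-value is invariant to patient order in the metadata", {
  cfg <- sim_config(n_probes = 800, n_samples = 8)
  lc <- simulate_longitudinal_cohort(cfg, 4, seed = 81,
                                     timepoints = c("diagnosis", "relapse"))
  meta_rev <- lc$meta[rev(seq_len(nrow(lc$meta))), ]
  r1 <- cluster_and_pair(lc$beta[lc$truth$stable_low[1:60], ], lc$meta)
  r2 <- cluster_and_pair(lc$beta[lc$truth$stable_low[1:60], ], meta_rev)
  expect_identical(r1$n_correct, r2$n_correct)
})

test_that("end-to-end matching recovers planted epi-clones with a significant p", {
  # the low-recurrence pool must dwarf the planted signatures, as in real
  # cohorts, so that random permutation draws rarely hit signature loci
  cfg <- sim_config(n_probes = 50000, n_samples = 16)
  lc <- simulate_longitudinal_cohort(cfg, 8, seed = 91,
                                     timepoints = c("diagnosis", "relapse"))
  res <- match_epiclones(lc$beta, lc$meta, lc$truth$stable_low, k = 15,
                         n_sims = 100, seed = 13)
  expect_identical(res$n_correct, 8L)
  expect_lt(res$p, 0.05)
  # signatures recover the planted loci (top-15 from relapse at high f)
  for (p in names(res$signatures)) {
    expect_gte(length(intersect(res$signatures[[p]],
                                lc$truth$signatures[[p]])), 13)
  }
})

test_that("destroying the signature linkage drops matching to chance levels", {
  cfg <- sim_config(n_probes = 2000, n_samples = 16)
  counts <- vapply(1:15, function(i) {
    lc <- simulate_longitudinal_cohort(cfg, 8, seed = 900 + i,
                                       diagnosis_fraction = 0,
                                       relapse_fraction = 0,
                                       timepoints = c("diagnosis", "relapse"))
    res <- match_epiclones(lc$beta, lc$meta, lc$truth$stable_low, k = 15,
                           n_sims = 0)
    res$n_correct
  }, integer(1))
  # with 16 interchangeable samples the chance of a correct sibling pair is
  # small; mean correct should sit well below half the patients
  expect_lt(mean(counts), 2.5)
})
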