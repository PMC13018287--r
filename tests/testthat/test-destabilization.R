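test_that("threshold calibration matches the sort-and-interpolate oracle", {
  # pooled vector 0.01..1.00: oracle by hand
  m <- make_beta(seq(0.01, 1, by = 0.01), n_probes = 100)
  thr <- calibrate_threshold(list(m), percentile = 99.9)
  expect_equal(as.numeric(thr),
               percentile_oracle(seq(0.01, 1, by = 0.01), 99.9),
               tolerance = 1e-15)

  # random pooled vectors across cohorts
  set.seed(5)
  for (i in 1:25) {
    cohorts <- lapply(seq_len(sample(1:4, 1)), function(k) {
      make_beta(runif(sample(5:50, 1) * 3), n_samples = 3)
    })
    pct <- runif(1, 1, 99.9)
    pooled <- unlist(lapply(cohorts, function(x) rowMeans(unclass(x))))
    expect_equal(as.numeric(calibrate_threshold(cohorts, pct)),
                 percentile_oracle(pooled, pct), tolerance = 1e-12)
  }

  # degenerate cases
  expect_equal(as.numeric(calibrate_threshold(
    list(make_beta(rep(0.3, 6), n_probes = 2)))), 0.3)
  expect_equal(as.numeric(calibrate_threshold(
    list(make_beta(c(0.1, 0.3), n_probes = 1)))), 0.2)  # one ESL, one mean
  expect_error(calibrate_threshold(list(), 99.9), "at least one")
  expect_error(calibrate_threshold(list(m), 0), "between 0 and 100")
})

test_that("calibration is invariant to cohort order and sample order", {
  set.seed(9)
  c1 <- make_beta(runif(60), n_probes = 20)
  c2 <- make_beta(runif(80), n_probes = 20)
  t1 <- calibrate_threshold(list(c1, c2))
  t2 <- calibrate_threshold(list(c2, c1))
  expect_equal(as.numeric(t1), as.numeric(t2))
  c1p <- make_beta(unclass(c1)[, sample(ncol(c1))])
  expect_equal(as.numeric(calibrate_threshold(list(c1p, c2))),
               as.numeric(t1))
})

test_that("binarization is strict and matches the elementwise oracle", {
  thr <- 0.05932
  m <- make_beta(c(0.05932, 0.06, 0.01, NA), n_probes = 2)
  calls <- binarize_calls(m, thr, "low")
  expect_identical(calls[1, 1], 0L)   # equal to threshold: not perturbed
  expect_identical(calls[2, 1], 1L)   # 0.06 exceeds 0.05932
  expect_identical(calls[1, 2], 0L)
  expect_true(is.na(calls[2, 2]))

  # high pole: perturbed means falling below the high-pole threshold
  mh <- make_beta(c(0.8321, 0.80, 0.95), n_probes = 3)
  ch <- binarize_calls(mh, 0.8321, "high")
  expect_identical(as.vector(ch), c(0L, 1L, 0L))

  set.seed(2)
  r <- make_beta(runif(200), n_probes = 20)
  rc <- binarize_calls(r, 0.4, "low")
  expect_identical(sum(rc), sum(unclass(r) > 0.4))

  expect_warning(binarize_calls(m, 0.6, "low"), "mismatch")
  expect_warning(binarize_calls(mh, 0.3, "high"), "mismatch")
})

test_that("recurrence fractions, class boundary and missing-call handling", {
  calls <- matrix(c(1L, 0L, 0L, 0L), 1, 4,
                  dimnames = list("e1", paste0("s", 1:4)))
  r <- call_recurrence(calls)
  expect_equal(r$recurrence, 0.25)
  expect_identical(r$recurrence_class, "recurrent")

  calls30 <- matrix(c(1L, rep(0L, 29)), 1, 30,
                    dimnames = list("e1", paste0("s", 1:30)))
  r30 <- call_recurrence(calls30)
  expect_equal(r30$recurrence, 1 / 30, tolerance = 1e-12)
  expect_identical(r30$recurrence_class, "low")

  # exactly 5% counts as recurrent ("5% or more")
  calls100 <- matrix(c(rep(1L, 5), rep(0L, 95)), 1, 100,
                     dimnames = list("e1", paste0("s", 1:100)))
  expect_identical(call_recurrence(calls100)$recurrence_class, "recurrent")

  # missing calls drop out of numerator and denominator
  cna <- matrix(c(1L, NA, 0L, NA), 1, 4,
                dimnames = list("e1", paste0("s", 1:4)))
  expect_equal(call_recurrence(cna)$recurrence, 0.5)

  # monotonicity: adding a perturbed sample never lowers recurrence
  set.seed(3)
  base <- matrix(rbinom(50, 1, 0.2), 5, 10,
                 dimnames = list(paste0("e", 1:5), paste0("s", 1:10)))
  extra <- cbind(base, s11 = rep(1L, 5))
  expect_true(all(call_recurrence(extra)$recurrence >=
                    call_recurrence(base)$recurrence))
})

test_that("conditional mean beta equals the masked-mean oracle", {
  m <- make_beta(c(0.3, 0.01), n_probes = 1, probe_ids = "e1")
  calls <- matrix(c(1L, 0L), 1, 2, dimnames = dimnames(m))
  expect_equal(unname(conditional_mean_beta(m, calls)), 0.3)

  none <- matrix(c(0L, 0L), 1, 2, dimnames = dimnames(m))
  expect_true(is.na(conditional_mean_beta(m, none)))

  set.seed(4)
  mm <- make_beta(runif(300), n_probes = 30)
  cc <- matrix(rbinom(300, 1, 0.3), 30, 10, dimnames = dimnames(mm))
  storage.mode(cc) <- "integer"
  got <- conditional_mean_beta(mm, cc)
  oracle <- sapply(1:30, function(i) {
    sel <- cc[i, ] == 1L
    if (!any(sel)) NA_real_ else mean(unclass(mm)[i, sel])
  })
  expect_equal(unname(got), oracle)
})

test_that("recurrence-conditional-mean correlation handles exact and degenerate cases", {
  rec <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(recurrence_beta_correlation(rec, 0.1 + 2 * rec)$r, 1)
  expect_equal(recurrence_beta_correlation(rec, 1 - rec)$r, -1)
  expect_error(recurrence_beta_correlation(rec, rep(0.5, 4)), "zero variance")
  expect_error(recurrence_beta_correlation(rec[1:2], rec[1:2]), "at least 3")
})

test_that("coupled penetrance and clone fraction yield a positive correlation", {
  # hot loci are preferentially perturbed by large clones: loci picked by
  # many patients should also show higher methylation among the affected
  set.seed(11)
  n_loci <- 120; n_samples <- 150
  ids <- sprintf("cg%03d", seq_len(n_loci))
  f <- sort(runif(n_samples, 0.05, 0.9))
  bg <- matrix(rbeta(n_loci * n_samples, 1, 60), n_loci, n_samples,
               dimnames = list(ids, sprintf("s%03d", 1:n_samples)))
  # popularity increases with locus index; high-f samples pick popular loci
  for (j in seq_len(n_samples)) {
    w <- seq_len(n_loci) ^ (3 * f[j])
    sig <- sample(n_loci, 10, prob = w)
    bg[sig, j] <- (1 - f[j]) * bg[sig, j] + f[j] * 0.85
  }
  prof <- destabilization_profile(beta_matrix(bg), 0.15, "low")
  res <- recurrence_beta_correlation(prof$recurrence, prof$conditional_mean)
  expect_gt(res$r, 0.5)
})

test_that("binarize-after-calibrate reproduces the percentile's exceedance rate", {
  cfg <- sim_config(n_probes = 3000, n_samples = 100)
  sim <- simulate_cohort(cfg, seed = 71)
  um <- sim$truth$stable_low
  ctrl <- lapply(1:3, function(s) {
    cs <- simulate_cohort(cfg, seed = 80 + s, probe_model = sim$truth)
    beta_matrix(unclass(cs$beta)[um, , drop = FALSE])
  })
  thr <- calibrate_threshold(ctrl, 99.9)
  pooled <- unlist(lapply(ctrl, function(m) rowMeans(unclass(m))))
  # defining property of the percentile on its own calibration pool
  expect_lte(mean(pooled > thr), 0.001 + 1 / length(pooled))
})

test_that("destabilization profile ties calls, recurrence and conditional means together", {
  set.seed(12)
  m <- make_beta(runif(200, 0, 0.2), n_probes = 20)
  prof <- destabilization_profile(m, 0.1, "low")
  expect_identical(dim(prof$calls), dim(m))
  # invariant: conditional mean exceeds threshold wherever defined
  def <- !is.na(prof$conditional_mean)
  expect_true(all(prof$conditional_mean[def] > prof$threshold))
  expect_equal(prof$recurrence$recurrence,
               unname(rowMeans(prof$calls)))
})
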