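# shared fixture builders and independent oracles

make_beta <- function(values, n_probes = NULL, n_samples = NULL,
                      probe_ids = NULL, sample_ids = NULL) {
  if (is.null(n_probes)) {
    n_probes <- if (!is.null(n_samples)) length(values) / n_samples
    else nrow(values)
  }
  m <- if (is.matrix(values)) values else matrix(values, nrow = n_probes)
  if (is.null(probe_ids)) {
    probe_ids <- if (!is.null(rownames(m))) rownames(m)
    else sprintf("cg%03d", seq_len(nrow(m)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(colnames(m))) colnames(m)
    else sprintf("s%02d", seq_len(ncol(m)))
  }
  dimnames(m) <- list(probe_ids, sample_ids)
  beta_matrix(m)
}

make_annotation <- function(probe_ids,
                            chromosome = "chr1",
                            position = seq_along(probe_ids) * 1000L,
                            cgi_relation = "island",
                            nearest_gene = "GENE1",
                            tss_distance = -200L,
                            near_snp = FALSE, cross_reactive = FALSE,
                            age_associated = FALSE, sex_chromosome = FALSE,
                            non_cpg = FALSE) {
  data.frame(probe_id = probe_ids, chromosome = chromosome,
             position = position, cgi_relation = cgi_relation,
             nearest_gene = nearest_gene, tss_distance = tss_distance,
             near_snp = near_snp, cross_reactive = cross_reactive,
             age_associated = age_associated,
             sex_chromosome = sex_chromosome, non_cpg = non_cpg,
             stringsAsFactors = FALSE)
}

# independent percentile oracle: sort, then linear interpolation between
# order statistics at h = (n - 1) p + 1
percentile_oracle <- function(x, percentile) {
  x <- unname(sort(x))
  n <- length(x)
  p <- percentile / 100
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# exhaustive two-sided Fisher p for table [[a, b], [c, d]] by hypergeometric
# enumeration (minimum-likelihood rule), written from the log-binomial
# formula rather than dhyper/fisher.test
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b     # target-group size
  m2 <- c + d
  k <- a + c      # total perturbed
  lp <- function(x) {
    lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k)
  }
  xs <- max(0, k - m2):min(k, m1)
  probs <- exp(lp(xs))
  p_obs <- exp(lp(a))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# simple survival-table builder
make_surv <- function(time, event, sample_ids = NULL, ...) {
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_along(time))
  data.frame(sample_id = sample_ids, time = time, event_mortality = event,
             ..., stringsAsFactors = FALSE)
}
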