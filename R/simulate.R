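#' Simulation configuration for synthetic methylation cohorts
#'
#' Defines the forward model used by the cohort generators: a bimodal,
#' pole-concentrated background (beta-distributed per probe), patient-specific
#' clonal perturbation signatures whose expected beta is affine in clone
#' fraction, a linear-in-age perturbation hazard, and a proportional-hazards
#' survival layer tied to DMI group.
#'
#' Probe classes: a fraction of probes is stably unmethylated (means drawn in
#' \code{stable_low_mean}), a fraction stably methylated (means in
#' \code{stable_high_mean}); the rest are variable, with per-probe means in
#' \code{variable_mean} and lower beta concentrations.  At a signature locus
#' of a sample with clone fraction f, beta is the mixture
#' \code{(1 - f) * background + f * clone}, so E[beta] is affine in f.
#'
#' @param n_probes number of probes.
#' @param n_samples default cohort size.
#' @param fraction_stable_unmeth,fraction_stable_meth planted stable-probe
#'   fractions (defaults 0.08 / 0.02: a 10\% stable decile, roughly 5:1
#'   unmethylated:methylated).
#' @param stable_low_mean,stable_high_mean ranges of per-probe means for the
#'   two stable poles; within each range, means are drawn skewed toward the
#'   pole so most loci sit near 0 (or 1) with a thin tail inward.
#' @param stable_concentration beta-distribution concentration (a + b) for
#'   stable probes; large values pin probes to their pole.
#' @param variable_mean,variable_concentration ranges for variable probes.
#' @param clone_fraction default range the per-patient clone fraction is
#'   drawn from (uniform), used when no explicit fractions are supplied.
#' @param signature_size loci per patient-specific clonal signature.
#' @param clone_level,clone_concentration beta parameters of the methylated
#'   clone component at signature loci.
#' @param age_range ages drawn uniformly from this range when requested.
#' @param age_hazard expected number of age-perturbed loci per year of age
#'   (Poisson); models gradual accumulation of clonal perturbation.
#' @param age_effect_fraction range of the (small) clone fraction attached to
#'   each age-perturbed locus.
#' @param baseline_hazard exponential baseline event hazard per time unit.
#' @param log_hr log hazard ratio of the high-DMI group (default log 1.5).
#' @param censoring_rate target fraction of censored observations.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_probes = 10000,
                       n_samples = 500,
                       fraction_stable_unmeth = 0.08,
                       fraction_stable_meth = 0.02,
                       stable_low_mean = c(0.005, 0.04),
                       stable_high_mean = c(0.96, 0.995),
                       stable_concentration = 1000,
                       variable_mean = c(0.05, 0.95),
                       variable_concentration = c(2, 50),
                       clone_fraction = c(0.3, 0.9),
                       signature_size = 15,
                       clone_level = 0.8,
                       clone_concentration = 50,
                       age_range = c(20, 90),
                       age_hazard = 0.1,
                       age_effect_fraction = c(0.05, 0.2),
                       baseline_hazard = 0.1,
                       log_hr = log(1.5),
                       censoring_rate = 0.2) {
  cfg <- as.list(environment())
  .check_scalar(cfg$n_probes, "n_probes", 1)
  .check_scalar(cfg$n_samples, "n_samples", 1)
  .check_scalar(cfg$fraction_stable_unmeth, "fraction_stable_unmeth", 0, 1)
  .check_scalar(cfg$fraction_stable_meth, "fraction_stable_meth", 0, 1)
  if (cfg$fraction_stable_unmeth + cfg$fraction_stable_meth >= 1) {
    stop("stable fractions must sum to less than 1", call. = FALSE)
  }
  .check_scalar(cfg$signature_size, "signature_size", 1)
  .check_scalar(cfg$clone_level, "clone_level", 0, 1)
  .check_scalar(cfg$age_hazard, "age_hazard", 0)
  .check_scalar(cfg$censoring_rate, "censoring_rate", 0, 1)
  if (cfg$baseline_hazard <= 0) {
    stop("baseline_hazard must be positive", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# per-probe class assignment and beta-distribution shapes; a probe model
# stored in a previous simulation's truth can be reused so several cohorts
# (e.g. discovery + controls) share one planted locus structure
.resolve_probe_model <- function(cfg, probe_model) {
  if (is.null(probe_model)) return(.probe_model(cfg))
  req <- c("probe_class", "probe_mean", "probe_concentration")
  if (!all(req %in% names(probe_model))) {
    stop("'probe_model' needs elements ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (length(probe_model$probe_class) != cfg$n_probes) {
    stop("'probe_model' size does not match config n_probes", call. = FALSE)
  }
  list(class = unname(probe_model$probe_class),
       mu = unname(probe_model$probe_mean),
       conc = unname(probe_model$probe_concentration),
       probe_ids = names(probe_model$probe_class))
}

.probe_model <- function(cfg) {
  np <- cfg$n_probes
  n_low <- round(np * cfg$fraction_stable_unmeth)
  n_high <- round(np * cfg$fraction_stable_meth)
  cls <- rep("variable", np)
  cls[seq_len(n_low)] <- "stable_low"
  if (n_high > 0) cls[n_low + seq_len(n_high)] <- "stable_high"
  cls <- sample(cls)   # scatter classes over probe indices
  mu <- numeric(np)
  conc <- numeric(np)
  # pole means are skewed toward the pole (Beta(1, 5) within the range):
  # most stable loci sit hard against 0 or 1 with a thin tail inward,
  # mirroring the observed bimodal mean-beta profile of stable sites
  i <- cls == "stable_low"
  mu[i] <- cfg$stable_low_mean[1] +
    diff(cfg$stable_low_mean) * stats::rbeta(sum(i), 1, 5)
  conc[i] <- cfg$stable_concentration
  i <- cls == "stable_high"
  mu[i] <- cfg$stable_high_mean[2] -
    diff(cfg$stable_high_mean) * stats::rbeta(sum(i), 1, 5)
  conc[i] <- cfg$stable_concentration
  i <- cls == "variable"
  mu[i] <- stats::runif(sum(i), cfg$variable_mean[1], cfg$variable_mean[2])
  conc[i] <- stats::runif(sum(i), cfg$variable_concentration[1],
                          cfg$variable_concentration[2])
  list(class = cls, mu = mu, conc = conc,
       probe_ids = sprintf("cg%07d", seq_len(np)))
}

.clone_draw <- function(n, cfg) {
  stats::rbeta(n, cfg$clone_level * cfg$clone_concentration,
               (1 - cfg$clone_level) * cfg$clone_concentration)
}

# overlay a clonal signature on one sample column
.apply_signature <- function(beta_col, sig_idx, f, cfg) {
  beta_col[sig_idx] <- (1 - f) * beta_col[sig_idx] +
    f * .clone_draw(length(sig_idx), cfg)
  beta_col
}

#' Simulate a methylation cohort with planted truth
#'
#' Draws a probes-by-samples beta matrix from the configured background
#' model, then overlays patient-specific clonal signatures (for samples with
#' a positive clone fraction) and, when ages are supplied, an age-dependent
#' accumulation of low-level perturbations at stable-unmethylated loci.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed; fixes all randomness.
#' @param clone_fractions optional numeric vector (length \code{n_samples},
#'   values in [0, 1]) of per-sample clone fractions; \code{NULL} means a
#'   fully healthy cohort (all zero).
#' @param ages optional numeric vector of ages, or \code{TRUE} to draw them
#'   from \code{config$age_range}; \code{NULL} disables the age model.
#' @param probe_model optional probe model to reuse (the \code{truth} of a
#'   previous simulation under the same config), so that several cohorts
#'   share one planted locus structure; \code{NULL} draws a fresh one.
#' @return list with elements \code{beta} (a \code{\link{beta_matrix}}),
#'   \code{meta} (sample metadata data.frame) and \code{truth} (planted
#'   stable sets, per-patient signatures, clone fractions, group labels).
#' @export
simulate_cohort <- function(config, seed, clone_fractions = NULL,
                            ages = NULL, probe_model = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ns <- config$n_samples
  if (config$n_probes < 1 || ns < 1) {
    stop("degenerate configuration: need at least one probe and one sample",
         call. = FALSE)
  }
  if (is.null(clone_fractions)) clone_fractions <- rep(0, ns)
  if (length(clone_fractions) != ns ||
      any(clone_fractions < 0 | clone_fractions > 1)) {
    stop("'clone_fractions' must have length n_samples with values in [0, 1]",
         call. = FALSE)
  }
  with_seed(seed, {
    pm <- .resolve_probe_model(config, probe_model)
    np <- config$n_probes
    vals <- matrix(stats::rbeta(np * ns, pm$mu * pm$conc,
                                (1 - pm$mu) * pm$conc),
                   nrow = np,
                   dimnames = list(pm$probe_ids, sprintf("S%04d", seq_len(ns))))
    if (isTRUE(ages)) {
      ages <- stats::runif(ns, config$age_range[1], config$age_range[2])
    }
    low_pool <- pm$probe_ids[pm$class == "stable_low"]
    signatures <- vector("list", ns)
    names(signatures) <- colnames(vals)
    for (j in seq_len(ns)) {
      f <- clone_fractions[j]
      if (f > 0) {
        sig <- sample(low_pool, config$signature_size)
        signatures[[j]] <- sig
        vals[, j] <- .apply_signature(vals[, j], match(sig, pm$probe_ids),
                                      f, config)
      }
      if (!is.null(ages)) {
        n_pert <- stats::rpois(1, config$age_hazard * ages[j])
        if (n_pert > 0) {
          pert <- sample(low_pool, min(n_pert, length(low_pool)))
          fa <- stats::runif(length(pert), config$age_effect_fraction[1],
                             config$age_effect_fraction[2])
          idx <- match(pert, pm$probe_ids)
          vals[idx, j] <- (1 - fa) * vals[idx, j] +
            fa * .clone_draw(length(idx), config)
        }
      }
    }
    meta <- data.frame(
      sample_id = colnames(vals),
      patient_id = sprintf("P%04d", seq_len(ns)),
      cohort = "sim",
      disease = ifelse(clone_fractions > 0, "clonal", "healthy"),
      tissue = "blood",
      age = if (is.null(ages)) NA_real_ else ages,
      timepoint = "none",
      clone_vaf = clone_fractions,
      stringsAsFactors = FALSE
    )
    truth <- list(
      stable_low = pm$probe_ids[pm$class == "stable_low"],
      stable_high = pm$probe_ids[pm$class == "stable_high"],
      variable = pm$probe_ids[pm$class == "variable"],
      probe_class = stats::setNames(pm$class, pm$probe_ids),
      probe_mean = stats::setNames(pm$mu, pm$probe_ids),
      probe_concentration = stats::setNames(pm$conc, pm$probe_ids),
      signatures = signatures,
      clone_fraction = stats::setNames(clone_fractions, colnames(vals)),
      group = stats::setNames(ifelse(clone_fractions > 0, "clonal", "healthy"),
                              colnames(vals))
    )
    list(beta = beta_matrix(vals), meta = meta, truth = truth)
  })
}

#' Simulate a longitudinal diagnosis/remission/relapse cohort
#'
#' Each patient carries one clonal signature shared by the diagnosis and
#' relapse samples (high clone fraction) while the remission sample has
#' clone fraction near zero, emulating epi-clone persistence through disease
#' progression.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n_patients number of patients.
#' @param seed integer seed.
#' @param diagnosis_fraction,relapse_fraction optional per-patient clone
#'   fractions; defaults draw both from \code{config$clone_fraction}.
#' @param remission_fraction clone fraction of remission samples (default 0).
#' @param timepoints which timepoints to emit per patient.
#' @param probe_model optional probe model to reuse, as in
#'   \code{\link{simulate_cohort}}.
#' @return list with \code{beta}, \code{meta} (sample/patient/timepoint and
#'   clone VAF) and \code{truth} (per-patient signatures and fractions).
#' @export
simulate_longitudinal_cohort <- function(config, n_patients, seed,
                                         diagnosis_fraction = NULL,
                                         relapse_fraction = NULL,
                                         remission_fraction = 0,
                                         timepoints = c("diagnosis",
                                                        "remission",
                                                        "relapse"),
                                         probe_model = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .check_scalar(n_patients, "n_patients", 1)
  timepoints <- match.arg(timepoints, several.ok = TRUE)
  with_seed(seed, {
    pm <- .resolve_probe_model(config, probe_model)
    np <- config$n_probes
    low_pool <- pm$probe_ids[pm$class == "stable_low"]
    if (length(low_pool) < config$signature_size) {
      stop("stable-low pool smaller than signature_size", call. = FALSE)
    }
    if (is.null(diagnosis_fraction)) {
      diagnosis_fraction <- stats::runif(n_patients, config$clone_fraction[1],
                                         config$clone_fraction[2])
    }
    if (is.null(relapse_fraction)) {
      relapse_fraction <- stats::runif(n_patients, config$clone_fraction[1],
                                       config$clone_fraction[2])
    }
    diagnosis_fraction <- rep_len(diagnosis_fraction, n_patients)
    relapse_fraction <- rep_len(relapse_fraction, n_patients)
    remission_fraction <- rep_len(remission_fraction, n_patients)
    signatures <- replicate(n_patients,
                            sample(low_pool, config$signature_size),
                            simplify = FALSE)
    names(signatures) <- sprintf("P%03d", seq_len(n_patients))
    ns <- n_patients * length(timepoints)
    vals <- matrix(stats::rbeta(np * ns, pm$mu * pm$conc,
                                (1 - pm$mu) * pm$conc),
                   nrow = np, dimnames = list(pm$probe_ids, NULL))
    meta <- expand.grid(timepoint = timepoints,
                        patient_id = names(signatures),
                        stringsAsFactors = FALSE)[, 2:1]
    meta$sample_id <- paste(meta$patient_id, meta$timepoint, sep = "_")
    colnames(vals) <- meta$sample_id
    frac_of <- function(tp, i) switch(tp,
      diagnosis = diagnosis_fraction[i],
      remission = remission_fraction[i],
      relapse = relapse_fraction[i])
    meta$clone_vaf <- NA_real_
    for (r in seq_len(nrow(meta))) {
      i <- match(meta$patient_id[r], names(signatures))
      f <- frac_of(meta$timepoint[r], i)
      meta$clone_vaf[r] <- f
      if (f > 0) {
        vals[, r] <- .apply_signature(vals[, r],
                                      match(signatures[[i]], pm$probe_ids),
                                      f, config)
      }
    }
    meta$cohort <- "sim"
    meta$disease <- "leukemia"
    meta$tissue <- "blood"
    truth <- list(
      stable_low = low_pool,
      stable_high = pm$probe_ids[pm$class == "stable_high"],
      probe_class = stats::setNames(pm$class, pm$probe_ids),
      probe_mean = stats::setNames(pm$mu, pm$probe_ids),
      probe_concentration = stats::setNames(pm$conc, pm$probe_ids),
      signatures = signatures,
      diagnosis_fraction = stats::setNames(diagnosis_fraction,
                                           names(signatures)),
      relapse_fraction = stats::setNames(relapse_fraction, names(signatures)),
      remission_fraction = stats::setNames(remission_fraction,
                                           names(signatures))
    )
    list(beta = beta_matrix(vals),
         meta = validate_sample_meta(meta),
         truth = truth)
  })
}

#' Simulate a proportional-hazards survival cohort
#'
#' Event times are exponential with hazard
#' \code{baseline_hazard * exp(log_hr)} for the high-DMI group and
#' \code{baseline_hazard} otherwise; censoring is independent exponential
#' calibrated so roughly \code{censoring_rate} of observations are censored.
#'
#' @param config a \code{\link{sim_config}} (uses \code{baseline_hazard},
#'   \code{log_hr}, \code{censoring_rate}).
#' @param dmi_groups character vector of group labels, \code{"high"} or
#'   \code{"low"}, one per sample.
#' @param seed integer seed.
#' @return survival-table data.frame with \code{sample_id}, \code{time},
#'   \code{event_mortality} and \code{dmi_group}.
#' @export
simulate_survival_cohort <- function(config, dmi_groups, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(dmi_groups %in% c("high", "low"))) {
    stop("'dmi_groups' must be 'high'/'low' labels", call. = FALSE)
  }
  n <- length(dmi_groups)
  with_seed(seed, {
    h <- config$baseline_hazard * ifelse(dmi_groups == "high",
                                         exp(config$log_hr), 1)
    t_event <- stats::rexp(n, h)
    p <- config$censoring_rate
    if (p >= 1) {
      time <- stats::rexp(n, config$baseline_hazard)
      event <- rep(0L, n)
    } else if (p <= 0) {
      time <- t_event
      event <- rep(1L, n)
    } else {
      c_rate <- config$baseline_hazard * p / (1 - p)
      t_cens <- stats::rexp(n, c_rate)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    }
    validate_survival_table(data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      time = time,
      event_mortality = event,
      dmi_group = dmi_groups,
      stringsAsFactors = FALSE
    ))
  })
}
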