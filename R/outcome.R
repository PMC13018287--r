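#' Stratify samples by DMI
#'
#' Median rule: DMI strictly above the cohort median is \code{"high"},
#' everything else (including ties at the median) \code{"low"}.  Quartile
#' rule: at or above the third quartile is \code{"high"}, at or below the
#' first quartile \code{"low"}, the middle half \code{"excluded"} —
#' comparing only the extreme quartiles accentuates outcome differences.
#'
#' @param dmi \code{dmi_scores} or data.frame with \code{sample_id},
#'   \code{dmi}.
#' @param rule \code{"median"} (default) or \code{"quartile"}.
#' @return data.frame of class \code{stratified_cohort}:
#'   \code{(sample_id, dmi, group)} with attribute \code{rule}.
#' @export
stratify_dmi <- function(dmi, rule = c("median", "quartile")) {
  rule <- match.arg(rule)
  df <- as.data.frame(dmi)[, c("sample_id", "dmi")]
  df <- df[!is.na(df$dmi), , drop = FALSE]
  if (nrow(df) < 2L || (rule == "quartile" && nrow(df) < 4L)) {
    stop("too few samples with DMI for the '", rule, "' rule", call. = FALSE)
  }
  if (stats::sd(df$dmi) == 0) {
    stop("all DMI values equal: no split possible", call. = FALSE)
  }
  if (rule == "median") {
    med <- stats::median(df$dmi)
    df$group <- ifelse(df$dmi > med, "high", "low")
  } else {
    q <- stats::quantile(df$dmi, probs = c(0.25, 0.75), type = 7,
                         names = FALSE)
    df$group <- ifelse(df$dmi >= q[2L], "high",
                       ifelse(df$dmi <= q[1L], "low", "excluded"))
  }
  rownames(df) <- NULL
  attr(df, "rule") <- rule
  class(df) <- c("stratified_cohort", class(df))
  df
}

.endpoint_col <- function(surv, endpoint) {
  col <- if (startsWith(endpoint, "event_")) endpoint
  else paste0("event_", endpoint)
  if (!col %in% names(surv)) {
    stop("survival table has no '", col, "' column", call. = FALSE)
  }
  col
}

#' Kaplan-Meier analysis of DMI groups
#'
#' Product-limit curves per group with log-log 95\% confidence intervals, a
#' log-rank test, and the hazard ratio of the high- versus low-DMI group
#' from a univariate proportional-hazards fit.  Samples stratified as
#' \code{"excluded"} are dropped; prevalent cases should be removed from the
#' table upstream.
#'
#' @param surv survival-table data.frame (see
#'   \code{\link{read_survival_table}}).
#' @param groups \code{stratified_cohort} or data.frame with
#'   \code{sample_id}, \code{group}.
#' @param endpoint endpoint name, e.g. \code{"mortality"}, \code{"cvd"}.
#' @return list of class \code{km_result}: \code{fit} (a
#'   \code{survival::survfit}), \code{logrank_p}, \code{hr}, \code{hr_ci},
#'   \code{hr_p}, \code{n}, \code{n_events}.
#' @export
km_analysis <- function(surv, groups, endpoint = "mortality") {
  col <- .endpoint_col(surv, endpoint)
  g <- as.data.frame(groups)[, c("sample_id", "group")]
  g <- g[g$group %in% c("high", "low"), , drop = FALSE]
  d <- merge(surv, g, by = "sample_id")
  d <- d[!is.na(d$time) & !is.na(d[[col]]), , drop = FALSE]
  if (nrow(d) == 0L) stop("no samples shared by survival table and groups",
                          call. = FALSE)
  d$group <- factor(d$group, levels = c("low", "high"))
  s <- survival::Surv(d$time, d[[col]])
  fit <- survival::survfit(s ~ group, data = d, conf.type = "log-log")
  if (sum(d[[col]]) == 0) {
    logrank_p <- NA_real_
    warning("no events observed: log-rank test undefined", call. = FALSE)
  } else {
    lr <- survival::survdiff(s ~ group, data = d)
    logrank_p <- stats::pchisq(lr$chisq, df = 1L, lower.tail = FALSE)
  }
  ev_by_group <- tapply(d[[col]], d$group, sum)
  hr <- hr_ci <- hr_p <- NA
  if (all(ev_by_group > 0, na.rm = TRUE)) {
    cox <- survival::coxph(s ~ group, data = d)
    sc <- summary(cox)
    hr <- unname(sc$conf.int[1L, "exp(coef)"])
    hr_ci <- unname(sc$conf.int[1L, c("lower .95", "upper .95")])
    hr_p <- unname(sc$coefficients[1L, "Pr(>|z|)"])
  } else {
    warning("a group has zero events: hazard ratio undefined", call. = FALSE)
  }
  out <- list(fit = fit, logrank_p = logrank_p, hr = hr, hr_ci = hr_ci,
              hr_p = hr_p, n = nrow(d),
              n_events = sum(d[[col]]), endpoint = endpoint)
  class(out) <- "km_result"
  out
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("km_result (%s): n = %d, events = %d\n",
              x$endpoint, x$n, x$n_events))
  cat(sprintf("  log-rank p = %.4g; HR(high vs low) = %.3f [%.3f, %.3f]\n",
              x$logrank_p, x$hr, x$hr_ci[1], x$hr_ci[2]))
  invisible(x)
}

#' @export
plot.km_result <- function(x, ...) {
  graphics::plot(x$fit, conf.int = TRUE, col = c("blue", "red"),
                 xlab = "time", ylab = "survival probability", ...)
  graphics::legend("bottomleft", legend = c("low DMI", "high DMI"),
                   col = c("blue", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Covariate-adjusted Cox proportional-hazards model
#'
#' Fits the endpoint against the DMI group indicator (high vs low) plus the
#' named covariates (e.g. age, sex, clonal-hematopoiesis status,
#' immune-cell fractions) and reports per-term hazard ratios.
#'
#' @param surv survival table; must contain the covariate columns.
#' @param groups \code{stratified_cohort} or data.frame with
#'   \code{sample_id}, \code{group}.
#' @param covariates character vector of covariate column names.
#' @param endpoint endpoint name.
#' @return data.frame \code{(term, hr, ci_lo, ci_hi, p)} with the fitted
#'   \code{coxph} model as attribute \code{fit}.
#' @export
cox_adjusted <- function(surv, groups, covariates = character(0),
                         endpoint = "mortality") {
  col <- .endpoint_col(surv, endpoint)
  g <- as.data.frame(groups)[, c("sample_id", "group")]
  g <- g[g$group %in% c("high", "low"), , drop = FALSE]
  d <- merge(surv, g, by = "sample_id")
  missing_cov <- setdiff(covariates, names(d))
  if (length(missing_cov)) {
    stop("covariate(s) absent from survival table: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  d$group <- factor(d$group, levels = c("low", "high"))
  rhs <- paste(c("group", covariates), collapse = " + ")
  fml <- stats::as.formula(paste0("survival::Surv(time, ", col, ") ~ ", rhs))
  fit <- survival::coxph(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("Cox fit failed (collinear or constant covariate?): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sc <- summary(fit)
  out <- data.frame(term = rownames(sc$coefficients),
                    hr = sc$conf.int[, "exp(coef)"],
                    ci_lo = sc$conf.int[, "lower .95"],
                    ci_hi = sc$conf.int[, "upper .95"],
                    p = sc$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fit") <- fit
  out
}

#' Simulation-based sample size for a DMI survival comparison
#'
#' Estimates, over a grid of candidate sample sizes, the power of the
#' two-group log-rank test under a proportional-hazards event model
#' (exponential baseline, configurable censoring) with patients split
#' equally into high- and low-DMI groups, and returns the smallest n whose
#' estimated power reaches the target.  Pilot survival data may be supplied
#' instead of an explicit event model, in which case the baseline hazard
#' and censoring rate are estimated from it.
#'
#' @param target_power target power (default 0.85).
#' @param hr hazard ratio of the high-DMI group (default 1.5).
#' @param alpha type I error rate (default 0.05).
#' @param n_grid candidate total sample sizes (even numbers; the split is
#'   50/50).
#' @param n_iterations simulated trials per grid point (default 1000).
#' @param seed integer seed.
#' @param event_model list with \code{baseline_hazard} and
#'   \code{censoring_rate}.
#' @param pilot optional data.frame with \code{time} and an event column
#'   (\code{event} or \code{event_*}); overrides \code{event_model}.
#' @return list of class \code{power_result}: \code{n_required} (NA when the
#'   target is unattainable on the grid), \code{grid} (n, power, Monte
#'   Carlo SE), plus the inputs.
#' @export
power_sample_size <- function(target_power = 0.85, hr = 1.5, alpha = 0.05,
                              n_grid = seq(20, 200, by = 10),
                              n_iterations = 1000, seed = NULL,
                              event_model = list(baseline_hazard = 0.1,
                                                 censoring_rate = 0.2),
                              pilot = NULL) {
  .check_scalar(target_power, "target_power", 0, 1)
  .check_scalar(alpha, "alpha", 0, 1)
  if (hr <= 0) stop("'hr' must be positive", call. = FALSE)
  if (!is.null(pilot)) {
    evc <- grep("^event", names(pilot), value = TRUE)[1L]
    if (is.na(evc) || !"time" %in% names(pilot)) {
      stop("pilot data needs 'time' and an event column", call. = FALSE)
    }
    event_model <- list(
      baseline_hazard = sum(pilot[[evc]]) / sum(pilot$time),
      censoring_rate = mean(pilot[[evc]] == 0)
    )
  }
  if (event_model$baseline_hazard <= 0) {
    stop("baseline hazard must be positive", call. = FALSE)
  }
  cfg <- sim_config(baseline_hazard = event_model$baseline_hazard,
                    log_hr = log(hr),
                    censoring_rate = event_model$censoring_rate)
  n_grid <- sort(unique(as.integer(n_grid)))
  with_seed(seed, {
    grid <- do.call(rbind, lapply(n_grid, function(n) {
      gl <- rep(c("high", "low"), length.out = n)
      hits <- vapply(seq_len(n_iterations), function(i) {
        st <- simulate_survival_cohort(cfg, gl, seed = NULL)
        if (sum(st$event_mortality) == 0) return(FALSE)
        lr <- survival::survdiff(
          survival::Surv(time, event_mortality) ~ dmi_group, data = st)
        stats::pchisq(lr$chisq, df = 1L, lower.tail = FALSE) < alpha
      }, logical(1))
      pw <- mean(hits)
      data.frame(n = n, power = pw,
                 mc_se = sqrt(pw * (1 - pw) / n_iterations))
    }))
    ok <- grid$n[grid$power >= target_power]
    if (length(ok) == 0L) {
      message("target power not reached on the candidate grid")
    }
    out <- list(n_required = if (length(ok)) min(ok) else NA_integer_,
                grid = grid, target_power = target_power, hr = hr,
                alpha = alpha, n_iterations = n_iterations,
                event_model = event_model)
    class(out) <- "power_result"
    out
  })
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "power_result: HR = %.2f, alpha = %.2f, target power = %.2f\n",
    x$hr, x$alpha, x$target_power))
  cat(if (is.na(x$n_required)) "  target not reached on grid\n"
      else sprintf("  required n = %d\n", x$n_required))
  invisible(x)
}

#' Closed-form (Schoenfeld) sample size cross-check
#'
#' The standard events-based approximation for a two-sided log-rank
#' comparison with equal allocation: required events
#' \eqn{d = (z_{1-\alpha/2} + z_{power})^2 / (p (1-p) \log(HR)^2)} scaled by
#' the expected event probability to a total sample size.
#'
#' @param hr hazard ratio.
#' @param target_power target power.
#' @param alpha two-sided type I error rate.
#' @param p_event expected fraction of subjects with an observed event.
#' @param allocation fraction allocated to the high group (default 0.5).
#' @return total sample size (rounded up to an even integer).
#' @export
schoenfeld_sample_size <- function(hr = 1.5, target_power = 0.85,
                                   alpha = 0.05, p_event = 0.8,
                                   allocation = 0.5) {
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(target_power)
  d <- (z_a + z_b)^2 / (allocation * (1 - allocation) * log(hr)^2)
  2 * ceiling(d / p_event / 2)
}
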