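#' Calibrate the ESL destabilization threshold from control cohorts
#'
#' For each control cohort the per-ESL mean beta is computed; all cohort x
#' ESL means are pooled and the threshold is the configured percentile of
#' the pooled vector (type-7 linear interpolation between order statistics).
#' Applied to normally unmethylated loci this yields the upper bound of
#' normal methylation; the mirrored calibration on methylated loci uses a
#' low percentile.
#'
#' @param control_cohorts list of \code{\link{beta_matrix}} objects, each
#'   restricted to one ESL class.
#' @param percentile percentile in (0, 100); default 99.9.
#' @return scalar threshold (beta units) with attribute \code{n_pooled}.
#' @export
calibrate_threshold <- function(control_cohorts, percentile = 99.9) {
  if (!is.list(control_cohorts) || length(control_cohorts) < 1L) {
    stop("need at least one control cohort", call. = FALSE)
  }
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      is.na(percentile) || percentile <= 0 || percentile >= 100) {
    stop("'percentile' must lie strictly between 0 and 100", call. = FALSE)
  }
  pooled <- unlist(lapply(control_cohorts, function(m) {
    rowMeans(unclass(m), na.rm = TRUE)
  }), use.names = FALSE)
  pooled <- pooled[!is.na(pooled)]
  if (length(pooled) == 0L) stop("pooled mean vector is empty", call. = FALSE)
  thr <- unname(stats::quantile(pooled, probs = percentile / 100,
                                type = 7, names = FALSE))
  attr(thr, "n_pooled") <- length(pooled)
  attr(thr, "percentile") <- percentile
  thr
}

#' Binarize ESL methylation against a destabilization threshold
#'
#' For normally unmethylated (low-pole) loci a call of 1 marks beta values
#' strictly exceeding the threshold; for normally methylated (high-pole)
#' loci, beta values strictly below the (high-pole) threshold.  Missing
#' beta values yield missing calls.
#'
#' @param matrix \code{\link{beta_matrix}} restricted to one ESL class (or
#'   any matrix; rows are taken as-is, optionally subset by \code{esl_ids}).
#' @param threshold calibrated threshold.
#' @param pole \code{"low"} (default) or \code{"high"}.
#' @param esl_ids optional probe subset.
#' @return integer matrix of 0/1/NA calls with the same dimnames.
#' @export
binarize_calls <- function(matrix, threshold, pole = c("low", "high"),
                           esl_ids = NULL) {
  pole <- match.arg(pole)
  x <- unclass(matrix)
  if (!is.null(esl_ids)) {
    missing <- setdiff(esl_ids, rownames(x))
    if (length(missing)) {
      stop("ESL(s) absent from matrix: ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    x <- x[esl_ids, , drop = FALSE]
  }
  if (pole == "low" && threshold >= 0.5) {
    warning("low-pole threshold >= 0.5 looks like a pole/threshold mismatch",
            call. = FALSE)
  }
  if (pole == "high" && threshold <= 0.5) {
    warning("high-pole threshold <= 0.5 looks like a pole/threshold mismatch",
            call. = FALSE)
  }
  calls <- if (pole == "low") x > threshold else x < threshold
  storage.mode(calls) <- "integer"
  calls
}

#' Per-ESL recurrence of destabilization
#'
#' Recurrence is the fraction of (non-missing) samples in which the locus is
#' perturbed.  Loci perturbed in less than 5\% of samples are classed
#' \code{"low"} recurrence; 5\% or more, \code{"recurrent"}.
#'
#' @param calls 0/1/NA call matrix from \code{\link{binarize_calls}}.
#' @param recurrent_cut class boundary (default 0.05, inclusive for
#'   \code{"recurrent"}).
#' @return data.frame \code{(probe_id, n_perturbed, n_called, recurrence,
#'   recurrence_class)}.
#' @export
call_recurrence <- function(calls, recurrent_cut = 0.05) {
  if (ncol(calls) < 1L) stop("need at least one sample", call. = FALSE)
  n_called <- rowSums(!is.na(calls))
  n_pert <- rowSums(calls == 1L, na.rm = TRUE)
  rec <- ifelse(n_called > 0, n_pert / n_called, NA_real_)
  data.frame(
    probe_id = rownames(calls),
    n_perturbed = n_pert,
    n_called = n_called,
    recurrence = rec,
    recurrence_class = ifelse(is.na(rec), NA_character_,
                              ifelse(rec >= recurrent_cut, "recurrent",
                                     "low")),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Conditional mean beta over perturbed samples
#'
#' For each ESL, the mean beta computed only over the samples in which the
#' locus is called perturbed; \code{NA} when no sample is perturbed.
#'
#' @param matrix beta matrix aligned with \code{calls}.
#' @param calls 0/1/NA call matrix with the same dimnames.
#' @return named numeric vector of conditional means.
#' @export
conditional_mean_beta <- function(matrix, calls) {
  x <- unclass(matrix)
  if (!identical(dim(x), dim(calls)) ||
      !identical(rownames(x), rownames(calls))) {
    stop("'matrix' and 'calls' must be aligned", call. = FALSE)
  }
  w <- !is.na(calls) & calls == 1L & !is.na(x)
  num <- rowSums(x * w, na.rm = TRUE)
  den <- rowSums(w)
  out <- ifelse(den > 0, num / den, NA_real_)
  names(out) <- rownames(x)
  out
}

#' Correlation between recurrence and conditional mean beta
#'
#' Pearson correlation (with a two-sided t-test) between per-ESL recurrence
#' and the conditional mean beta over perturbed samples; a positive r means
#' frequently destabilized loci reach higher methylation in affected
#' samples, consistent with a larger methylated-cell fraction.
#'
#' @param recurrence numeric vector (or the \code{recurrence} column of
#'   \code{\link{call_recurrence}} output).
#' @param conditional_means numeric vector aligned with \code{recurrence}.
#' @return list \code{(r, p, n)}.
#' @export
recurrence_beta_correlation <- function(recurrence, conditional_means) {
  if (is.data.frame(recurrence)) recurrence <- recurrence$recurrence
  ok <- !is.na(recurrence) & !is.na(conditional_means)
  if (sum(ok) < 3L) {
    stop("need at least 3 ESLs with defined conditional means", call. = FALSE)
  }
  x <- recurrence[ok]; y <- conditional_means[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in recurrence or conditional means", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Full destabilization profile of a cohort
#'
#' Binarizes the cohort against a calibrated threshold and assembles calls,
#' recurrence and conditional mean beta into one object.
#'
#' @param matrix beta matrix restricted to one ESL class.
#' @param threshold calibrated destabilization threshold.
#' @param pole \code{"low"} or \code{"high"}.
#' @param esl_ids optional probe subset.
#' @return list of class \code{destab_profile} with elements
#'   \code{threshold}, \code{pole}, \code{calls}, \code{recurrence},
#'   \code{conditional_mean}.
#' @export
destabilization_profile <- function(matrix, threshold,
                                    pole = c("low", "high"),
                                    esl_ids = NULL) {
  pole <- match.arg(pole)
  calls <- binarize_calls(matrix, threshold, pole, esl_ids)
  x <- unclass(matrix)[rownames(calls), , drop = FALSE]
  out <- list(threshold = as.numeric(threshold),
              pole = pole,
              calls = calls,
              recurrence = call_recurrence(calls),
              conditional_mean = conditional_mean_beta(x, calls))
  class(out) <- "destab_profile"
  out
}

#' @export
print.destab_profile <- function(x, ...) {
  rec <- x$recurrence
  cat(sprintf(
    "destab_profile: %d ESLs x %d samples (pole %s, threshold %.5f)\n",
    nrow(x$calls), ncol(x$calls), x$pole, x$threshold))
  cat(sprintf("  recurrent (>= 5%%): %d; low recurrence: %d\n",
              sum(rec$recurrence_class == "recurrent", na.rm = TRUE),
              sum(rec$recurrence_class == "low", na.rm = TRUE)))
  invisible(x)
}
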