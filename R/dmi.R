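#' Per-sample DNA methylation instability (DMI)
#'
#' DMI is the standard deviation (n - 1 denominator) of a sample's beta
#' values over a designated ESL subset — by convention the recurrently
#' perturbed, normally unmethylated loci, so that scattered clonal
#' methylation at these uniform-background sites raises the score.
#'
#' @param matrix \code{\link{beta_matrix}}.
#' @param esl_ids probe subset to score over (e.g. recurrent ESLs).
#' @param subset_label stored label describing the subset.
#' @return data.frame of class \code{dmi_scores} with columns
#'   \code{(sample_id, dmi, n_loci)}; samples with fewer than two usable
#'   loci get \code{NA} with a warning.
#' @export
compute_dmi <- function(matrix, esl_ids, subset_label = "recurrent") {
  if (length(esl_ids) == 0L) stop("'esl_ids' is empty", call. = FALSE)
  x <- unclass(matrix)
  missing <- setdiff(esl_ids, rownames(x))
  if (length(missing)) {
    stop("ESL(s) absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  x <- x[esl_ids, , drop = FALSE]
  n_loci <- colSums(!is.na(x))
  dmi <- apply(x, 2L, stats::sd, na.rm = TRUE)
  low <- n_loci < 2
  if (any(low)) {
    warning(sum(low), " sample(s) with <2 usable loci: DMI set to NA",
            call. = FALSE)
    dmi[low] <- NA_real_
  }
  out <- data.frame(sample_id = colnames(x), dmi = unname(dmi),
                    n_loci = as.integer(unname(n_loci)), stringsAsFactors = FALSE)
  attr(out, "subset") <- subset_label
  class(out) <- c("dmi_scores", class(out))
  out
}

#' @export
print.dmi_scores <- function(x, ...) {
  cat(sprintf("dmi_scores: %d samples over '%s' subset; median DMI %.4f\n",
              nrow(x), attr(x, "subset"),
              stats::median(x$dmi, na.rm = TRUE)))
  invisible(x)
}

#' Longitudinal DMI trajectories
#'
#' Joins per-sample DMI with patient/timepoint metadata into an ordered
#' per-patient trajectory table, carrying the clone VAF alongside when
#' available so epigenetic and genetic clone-size readouts can be overlaid.
#'
#' @param dmi \code{dmi_scores} (or data.frame with \code{sample_id},
#'   \code{dmi}).
#' @param meta sample metadata with \code{sample_id}, \code{patient_id},
#'   \code{timepoint} and optionally \code{clone_vaf}.
#' @return data.frame of class \code{dmi_trajectory}, one row per sample,
#'   ordered by patient then timepoint (diagnosis < remission < relapse <
#'   followup).
#' @export
dmi_trajectory <- function(dmi, meta) {
  tp_order <- c("diagnosis", "remission", "relapse", "followup", "none")
  m <- merge(meta, as.data.frame(dmi)[, c("sample_id", "dmi")],
             by = "sample_id")
  key <- paste(m$patient_id, m$timepoint)
  if (anyDuplicated(key)) {
    stop("duplicated timepoint for patient(s): ",
         paste(unique(m$patient_id[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  }
  m$timepoint <- factor(m$timepoint, levels = tp_order)
  m <- m[order(m$patient_id, m$timepoint), , drop = FALSE]
  cols <- c("patient_id", "timepoint", "sample_id", "dmi")
  if ("clone_vaf" %in% names(m) && any(!is.na(m$clone_vaf))) {
    cols <- c(cols, "clone_vaf")
  }
  out <- m[, cols, drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dmi_trajectory", class(out))
  out
}

#' DMI versus age trend on binned means
#'
#' Groups samples into fixed-width age bins (left-closed, right-open,
#' anchored at the cohort minimum floored to a bin-width multiple), computes
#' per-bin mean DMI with normal-approximation 95\% confidence intervals, and
#' fits a linear regression of bin means on bin midpoints, reporting the
#' slope and the Pearson correlation over bin means.
#'
#' @param dmi \code{dmi_scores} or numeric vector of DMI values.
#' @param ages numeric ages (years) aligned with \code{dmi}.
#' @param bin_width bin width in years (default 5).
#' @return list of class \code{dmi_age_trend}: \code{bins} (data.frame with
#'   bin bounds, midpoint, n, mean, ci_lo, ci_hi), \code{slope},
#'   \code{intercept}, \code{r}, \code{p}, \code{n_bins}.
#' @export
dmi_age_trend <- function(dmi, ages, bin_width = 5) {
  if (inherits(dmi, "dmi_scores") || is.data.frame(dmi)) dmi <- dmi$dmi
  ok <- !is.na(dmi) & !is.na(ages)
  dmi <- dmi[ok]; ages <- ages[ok]
  if (length(dmi) < 3L) stop("need at least 3 samples with age and DMI",
                             call. = FALSE)
  .check_scalar(bin_width, "bin_width", 1e-9)
  anchor <- floor(min(ages) / bin_width) * bin_width
  bin_lo <- anchor + bin_width * floor((ages - anchor) / bin_width)
  lo <- sort(unique(bin_lo))
  stats_by <- function(f) vapply(lo, function(b) f(dmi[bin_lo == b]),
                                 numeric(1))
  n <- stats_by(length)
  mu <- stats_by(mean)
  sdv <- stats_by(function(v) if (length(v) > 1) stats::sd(v) else NA_real_)
  se <- sdv / sqrt(n)
  bins <- data.frame(lower = lo, upper = lo + bin_width,
                     midpoint = lo + bin_width / 2,
                     n = n, mean = mu,
                     ci_lo = mu - 1.96 * se, ci_hi = mu + 1.96 * se)
  if (nrow(bins) < 2L) {
    stop("all samples fall in one age bin; cannot fit a trend",
         call. = FALSE)
  }
  if (nrow(bins) < 3L) {
    stop("need at least 3 non-empty age bins", call. = FALSE)
  }
  if (any(n == 1L)) {
    message(sum(n == 1L), " bin(s) with a single sample: CI undefined")
  }
  fit <- stats::lm(mean ~ midpoint, data = bins)
  ct <- stats::cor.test(bins$midpoint, bins$mean, method = "pearson")
  out <- list(bins = bins,
              slope = unname(stats::coef(fit)[2L]),
              intercept = unname(stats::coef(fit)[1L]),
              r = unname(ct$estimate),
              p = ct$p.value,
              n_bins = nrow(bins),
              bin_width = bin_width)
  class(out) <- "dmi_age_trend"
  out
}

#' @export
print.dmi_age_trend <- function(x, ...) {
  cat(sprintf(
    "dmi_age_trend: %d bins of %g y; slope %.3g DMI/year; r = %.3f (p = %.3g)\n",
    x$n_bins, x$bin_width, x$slope, x$r, x$p))
  invisible(x)
}

#' @export
plot.dmi_age_trend <- function(x, ...) {
  b <- x$bins
  graphics::plot(b$midpoint, b$mean, pch = 16,
                 ylim = range(c(b$ci_lo, b$ci_hi, b$mean), na.rm = TRUE),
                 xlab = "age (years)", ylab = "mean DMI", ...)
  graphics::arrows(b$midpoint, b$ci_lo, b$midpoint, b$ci_hi,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(x$intercept, x$slope, col = "red")
  invisible(x)
}
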