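#' Remove blocklisted probes
#'
#' Drops every probe carrying any of the named blocklist flags (SNP
#' proximity, cross-reactivity, age association, sex chromosomes, non-CpG
#' context) before stability ranking.
#'
#' @param annotation probe annotation data.frame
#'   (see \code{\link{read_probe_annotation}}).
#' @param exclude_flags flag columns to apply; default all five.
#' @param probe_ids optional probe universe (e.g. matrix rownames); every one
#'   must be covered by the annotation.
#' @return character vector of retained probe IDs.
#' @export
filter_probes <- function(annotation,
                          exclude_flags = c("near_snp", "cross_reactive",
                                            "age_associated",
                                            "sex_chromosome", "non_cpg"),
                          probe_ids = NULL) {
  bad_flags <- setdiff(exclude_flags, names(annotation))
  if (length(bad_flags)) {
    stop("annotation lacks flag column(s): ",
         paste(bad_flags, collapse = ", "), call. = FALSE)
  }
  if (!is.null(probe_ids)) {
    missing <- setdiff(probe_ids, annotation$probe_id)
    if (length(missing)) {
      stop("probe(s) in matrix absent from annotation, e.g. ",
           paste(utils::head(missing, 5L), collapse = ", "),
           " (", length(missing), " total)", call. = FALSE)
    }
    annotation <- annotation[annotation$probe_id %in% probe_ids, ,
                             drop = FALSE]
  }
  if (length(exclude_flags) == 0L) return(annotation$probe_id)
  flagged <- Reduce(`|`, lapply(exclude_flags, function(fl) {
    v <- annotation[[fl]]
    !is.na(v) & v
  }))
  annotation$probe_id[!flagged]
}

#' Rank probes by cohort beta-value variance
#'
#' Computes the unbiased (n - 1) sample variance per probe over non-missing
#' values and ranks probes from least to most variable; ties are ordered by
#' probe ID so the ranking is deterministic.
#'
#' @param matrix a \code{\link{beta_matrix}} (healthy discovery cohort).
#' @return data.frame \code{(probe_id, mean_beta, variance, rank)} sorted by
#'   rank; probes with fewer than two observations are dropped with a
#'   warning.
#' @export
rank_variance <- function(matrix) {
  x <- unclass(matrix)
  n_obs <- rowSums(!is.na(x))
  v <- .row_var(x)
  m <- rowMeans(x, na.rm = TRUE)
  drop <- n_obs < 2
  if (any(drop)) {
    warning(sum(drop), " probe(s) with <2 observations excluded from ",
            "variance ranking", call. = FALSE)
  }
  df <- data.frame(probe_id = rownames(x)[!drop],
                   mean_beta = m[!drop],
                   variance = v[!drop],
                   stringsAsFactors = FALSE)
  ord <- order(df$variance, df$probe_id)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Select the least-variable probe fraction
#'
#' Keeps the \code{floor(fraction * n)} lowest-variance probes (the
#' stability decile for \code{fraction = 0.1}); ties at the cut are broken
#' lexicographically by probe ID.
#'
#' @param variance_table output of \code{\link{rank_variance}}.
#' @param fraction fraction of probes to keep, in (0, 1).
#' @return the selected rows of \code{variance_table}.
#' @export
select_stable <- function(variance_table, fraction = 0.1) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction <= 0 || fraction >= 1) {
    stop("'fraction' must lie strictly between 0 and 1", call. = FALSE)
  }
  k <- floor(fraction * nrow(variance_table))
  ord <- order(variance_table$variance, variance_table$probe_id)
  out <- variance_table[ord, , drop = FALSE][seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop stability candidates that are outliers in purified cell types
#'
#' A residual cell-type signal can make a locus look stable in whole blood
#' while being methylated in one purified population.  A low-pole candidate
#' is removed if any purified-cell sample exceeds \code{low_ceiling}
#' (mirrored with \code{high_floor} for high-pole candidates); the
#' alternative \code{"tukey"} rule removes candidates with any value outside
#' the per-cell-type 1.5 x IQR fences.
#'
#' @param candidates data.frame from \code{\link{select_stable}} (needs
#'   \code{probe_id} and \code{mean_beta} to decide each candidate's pole).
#' @param purified named list of beta matrices, one per purified cell type;
#'   \code{NULL} or empty skips the filter with a message.
#' @param rule \code{"ceiling"} (default) or \code{"tukey"}.
#' @param low_ceiling,high_floor bounds for the ceiling rule.
#' @return \code{candidates} reduced to the retained rows.
#' @export
filter_purified_outliers <- function(candidates, purified,
                                     rule = c("ceiling", "tukey"),
                                     low_ceiling = 0.1, high_floor = 0.9) {
  rule <- match.arg(rule)
  if (is.null(purified) || length(purified) == 0L) {
    message("no purified-cell data supplied; outlier filter skipped")
    return(candidates)
  }
  low_pole <- candidates$mean_beta < 0.5
  remove <- rep(FALSE, nrow(candidates))
  for (ct in seq_along(purified)) {
    x <- unclass(purified[[ct]])
    idx <- match(candidates$probe_id, rownames(x))
    if (anyNA(idx)) {
      stop("purified matrix ", ct, " does not cover all candidates",
           call. = FALSE)
    }
    x <- x[idx, , drop = FALSE]
    if (rule == "ceiling") {
      hi <- apply(x, 1L, max, na.rm = TRUE)
      lo <- apply(x, 1L, min, na.rm = TRUE)
      remove <- remove | (low_pole & hi > low_ceiling) |
        (!low_pole & lo < high_floor)
    } else {
      q1 <- apply(x, 1L, stats::quantile, probs = 0.25, na.rm = TRUE)
      q3 <- apply(x, 1L, stats::quantile, probs = 0.75, na.rm = TRUE)
      iqr <- q3 - q1
      hi <- apply(x, 1L, max, na.rm = TRUE)
      lo <- apply(x, 1L, min, na.rm = TRUE)
      remove <- remove | hi > q3 + 1.5 * iqr | lo < q1 - 1.5 * iqr
    }
  }
  out <- candidates[!remove, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify stable loci as unmethylated or methylated
#'
#' Stable loci sit at one of two methylation poles; probes whose cohort mean
#' falls below \code{split} are stably unmethylated ESLs, above it stably
#' methylated.  Any probe mean inside the forbidden middle band violates the
#' expected bimodality and is excluded with a warning.
#'
#' @param stable data.frame of stable candidates with \code{probe_id},
#'   \code{mean_beta}, \code{variance}, \code{rank} (as produced by
#'   \code{\link{select_stable}}).
#' @param split class boundary (default 0.5).
#' @param forbidden_band numeric length-2; means strictly inside this open
#'   interval are excluded.
#' @return data.frame of class \code{esl_set}, columns
#'   \code{(probe_id, esl_class, mean_beta, variance, rank)}, with
#'   attributes \code{band} (observed empty band: max unmethylated mean,
#'   min methylated mean) and \code{n_excluded}.
#' @export
classify_bimodal <- function(stable, split = 0.5,
                             forbidden_band = c(0.2, 0.8)) {
  if (nrow(stable) == 0L) stop("empty stable set", call. = FALSE)
  mid <- stable$mean_beta > forbidden_band[1] &
    stable$mean_beta < forbidden_band[2]
  if (any(mid)) {
    warning(sum(mid), " probe(s) with intermediate mean beta excluded ",
            "from ESL classification", call. = FALSE)
  }
  out <- stable[!mid, , drop = FALSE]
  out$esl_class <- ifelse(out$mean_beta < split, "unmethylated", "methylated")
  out <- out[, c("probe_id", "esl_class", "mean_beta", "variance", "rank")]
  rownames(out) <- NULL
  um <- out$mean_beta[out$esl_class == "unmethylated"]
  me <- out$mean_beta[out$esl_class == "methylated"]
  attr(out, "band") <- c(
    max_unmethylated = if (length(um)) max(um) else NA_real_,
    min_methylated = if (length(me)) min(me) else NA_real_
  )
  attr(out, "n_excluded") <- sum(mid)
  class(out) <- c("esl_set", class(out))
  out
}

#' @export
print.esl_set <- function(x, ...) {
  cat(sprintf("esl_set: %d loci (%d unmethylated, %d methylated)\n",
              nrow(x), sum(x$esl_class == "unmethylated"),
              sum(x$esl_class == "methylated")))
  b <- attr(x, "band")
  if (!anyNA(b)) {
    cat(sprintf("  empty band: (%.3f, %.3f)\n", b[1], b[2]))
  }
  invisible(x)
}

#' Discover epigenetically stable loci from a healthy cohort
#'
#' Full discovery pipeline: blocklist filtering, variance ranking,
#' lowest-decile selection, optional purified-cell outlier exclusion, and
#' bimodal classification into stably unmethylated / methylated loci.
#'
#' @param matrix healthy-cohort \code{\link{beta_matrix}}.
#' @param annotation probe annotation covering the matrix probes; \code{NULL}
#'   skips blocklist filtering.
#' @param fraction stability fraction passed to \code{\link{select_stable}}.
#' @param purified optional purified-cell matrices for
#'   \code{\link{filter_purified_outliers}}.
#' @param exclude_flags blocklist flags to apply.
#' @param ... further arguments to \code{\link{classify_bimodal}}.
#' @return an \code{esl_set}; attribute \code{n_candidates} records the
#'   pre-purification count.
#' @export
discover_esls <- function(matrix, annotation = NULL, fraction = 0.1,
                          purified = NULL,
                          exclude_flags = c("near_snp", "cross_reactive",
                                            "age_associated",
                                            "sex_chromosome", "non_cpg"),
                          ...) {
  keep <- rownames(matrix)
  if (!is.null(annotation)) {
    keep <- filter_probes(annotation, exclude_flags, probe_ids = keep)
  }
  vt <- rank_variance(beta_matrix(unclass(matrix)[keep, , drop = FALSE]))
  cand <- select_stable(vt, fraction)
  n_candidates <- nrow(cand)
  if (!is.null(purified)) {
    cand <- filter_purified_outliers(cand, purified)
  }
  out <- classify_bimodal(cand, ...)
  attr(out, "n_candidates") <- n_candidates
  out
}
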