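# two-sided Fisher p and odds ratio for one 2x2 table
# a = perturbed in target, b = unperturbed in target,
# c = perturbed in other,  d = unperturbed in other.
# OR is the raw cross-product ratio, Haldane-Anscombe corrected (add 0.5 to
# every cell) only when a zero cell occurs, so ranking by OR stays finite.
.fisher_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, c, b, d), nrow = 2L)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  if (a == 0 || b == 0 || c == 0 || d == 0) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  c(p = p, or = or)
}

#' Per-ESL Fisher's exact test of lineage-biased destabilization
#'
#' For each locus, a two-sided Fisher's exact test (minimum-likelihood rule)
#' on the 2x2 table of perturbed/unperturbed calls in the target versus the
#' other group, with Bonferroni correction over tested loci.  The odds ratio
#' is oriented so OR > 1 means higher perturbation odds in the target group.
#'
#' @param calls 0/1/NA call matrix (loci x samples).
#' @param groups character vector of group labels aligned with the samples.
#' @param target_group label of the group the odds ratio points toward.
#' @return data.frame of class \code{enrichment_records}: per-locus counts,
#'   odds ratio, raw and Bonferroni p, and per-group prevalence.
#' @export
fisher_per_esl <- function(calls, groups, target_group) {
  if (length(groups) != ncol(calls)) {
    stop("'groups' must have one label per sample", call. = FALSE)
  }
  levs <- unique(groups)
  if (length(levs) != 2L) {
    stop("need exactly two nonempty groups, got: ",
         paste(levs, collapse = ", "), call. = FALSE)
  }
  if (!target_group %in% levs) {
    stop("'target_group' not among group labels", call. = FALSE)
  }
  in_t <- groups == target_group
  ct <- calls[, in_t, drop = FALSE]
  co <- calls[, !in_t, drop = FALSE]
  a <- unname(rowSums(ct == 1L, na.rm = TRUE))
  b <- unname(rowSums(ct == 0L, na.rm = TRUE))
  cc <- unname(rowSums(co == 1L, na.rm = TRUE))
  d <- unname(rowSums(co == 0L, na.rm = TRUE))
  m <- nrow(calls)
  res <- t(vapply(seq_len(m),
                  function(i) .fisher_2x2(a[i], b[i], cc[i], d[i]),
                  numeric(2)))
  out <- data.frame(
    probe_id = rownames(calls),
    n_perturbed_target = a,
    n_unperturbed_target = b,
    n_perturbed_other = cc,
    n_unperturbed_other = d,
    odds_ratio = res[, "or"],
    p = res[, "p"],
    p_bonferroni = pmin(1, res[, "p"] * m),
    prevalence_target = ifelse(a + b > 0, a / (a + b), NA_real_),
    prevalence_other = ifelse(cc + d > 0, cc / (cc + d), NA_real_),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "target_group") <- target_group
  class(out) <- c("enrichment_records", class(out))
  out
}

# rank records by decreasing OR, ties by smaller p then probe ID
.or_rank_order <- function(records) {
  order(-records$odds_ratio, records$p, records$probe_id)
}

#' Select lymphoid-enriched destabilized loci
#'
#' From Bonferroni-significant records oriented toward the lymphoid group:
#' keep loci with OR > 1 and lymphoid prevalence at or above the prevalence
#' bar, rank by OR, and designate the top half as lymphoid-enriched.
#'
#' @param records \code{enrichment_records} with the lymphoid group as
#'   target.
#' @param alpha significance level on the Bonferroni-adjusted p.
#' @param prevalence_threshold minimum target-group prevalence (default 0.5).
#' @param top_fraction fraction of ranked candidates kept
#'   (default 0.5; \code{floor} on odd counts).
#' @return character vector of selected probe IDs (empty, with a message,
#'   when no candidate passes).
#' @export
select_lymphoid <- function(records, alpha = 0.05,
                            prevalence_threshold = 0.5,
                            top_fraction = 0.5) {
  cand <- records[!is.na(records$p_bonferroni) &
                    records$p_bonferroni < alpha &
                    records$odds_ratio > 1 &
                    records$prevalence_target >= prevalence_threshold, ,
                  drop = FALSE]
  if (nrow(cand) == 0L) {
    message("no candidate loci pass the lymphoid-enrichment filters")
    return(character(0))
  }
  cand <- cand[.or_rank_order(cand), , drop = FALSE]
  cand$probe_id[seq_len(floor(nrow(cand) * top_fraction))]
}

#' Select myeloid-enriched destabilized loci
#'
#' Accounts for the lower perturbation frequency of the myeloid group by
#' running two pairwise comparisons (e.g. AML vs T-ALL and AML vs BCP-ALL,
#' both oriented toward the myeloid group), intersecting the loci passing
#' the significance and OR > 1 filters in both, and keeping those with
#' myeloid prevalence at or above the prevalence bar.
#'
#' @param records_a,records_b \code{enrichment_records} for the two pairwise
#'   comparisons, computed on the same probe universe, target = myeloid.
#' @param alpha significance level on the Bonferroni-adjusted p.
#' @param prevalence_threshold minimum myeloid prevalence (default 0.10).
#' @param top_fraction optional OR-rank cut applied to each comparison
#'   before intersecting; \code{NULL} (default) disables it.
#' @return character vector of selected probe IDs.
#' @export
select_myeloid <- function(records_a, records_b, alpha = 0.05,
                           prevalence_threshold = 0.10,
                           top_fraction = NULL) {
  if (!setequal(records_a$probe_id, records_b$probe_id)) {
    stop("the two comparisons cover different probe universes",
         call. = FALSE)
  }
  pass <- function(r) {
    cand <- r[!is.na(r$p_bonferroni) & r$p_bonferroni < alpha &
                r$odds_ratio > 1, , drop = FALSE]
    if (!is.null(top_fraction) && nrow(cand) > 0L) {
      cand <- cand[.or_rank_order(cand), , drop = FALSE]
      cand <- cand[seq_len(floor(nrow(cand) * top_fraction)), , drop = FALSE]
    }
    cand
  }
  ca <- pass(records_a)
  cb <- pass(records_b)
  sel <- intersect(ca$probe_id, cb$probe_id)
  if (length(sel) == 0L) {
    message("no candidate loci pass both myeloid comparisons")
    return(character(0))
  }
  prev <- ca$prevalence_target[match(sel, ca$probe_id)]
  sel[!is.na(prev) & prev >= prevalence_threshold]
}
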