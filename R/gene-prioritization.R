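#' Map ESLs to gene promoters
#'
#' Assigns each locus to its nearest gene when it falls in the promoter
#' window.  For prioritization the window is upstream-only
#' (\code{-upstream_bp <= tss_distance <= 0}); the symmetric window
#' (\code{|tss_distance| <= upstream_bp}) is the one used for
#' promoter-proximity enrichment reporting.
#'
#' @param esl_ids character vector of locus IDs.
#' @param annotation probe annotation with \code{probe_id},
#'   \code{nearest_gene}, \code{tss_distance} (negative upstream of TSS).
#' @param upstream_bp window size in bp (default 1500).
#' @param window \code{"upstream"} (default) or \code{"symmetric"}.
#' @return named list: gene -> character vector of its promoter ESLs.  Loci
#'   with missing \code{tss_distance} are skipped with a message.
#' @export
map_promoter_esls <- function(esl_ids, annotation, upstream_bp = 1500,
                              window = c("upstream", "symmetric")) {
  window <- match.arg(window)
  ann <- annotation[match(esl_ids, annotation$probe_id), , drop = FALSE]
  if (anyNA(ann$probe_id)) {
    stop("ESL(s) absent from annotation: ",
         paste(utils::head(setdiff(esl_ids, annotation$probe_id), 5L),
               collapse = ", "), call. = FALSE)
  }
  skip <- is.na(ann$tss_distance) | is.na(ann$nearest_gene)
  if (any(skip)) {
    message(sum(skip), " locus/loci without TSS annotation skipped")
    ann <- ann[!skip, , drop = FALSE]
  }
  inside <- if (window == "upstream") {
    ann$tss_distance >= -upstream_bp & ann$tss_distance <= 0
  } else {
    abs(ann$tss_distance) <= upstream_bp
  }
  ann <- ann[inside, , drop = FALSE]
  split(ann$probe_id, ann$nearest_gene)
}

#' Per-gene correlation between promoter-ESL methylation and expression
#'
#' For each ESL, the Pearson correlation between its beta values and the
#' (log2(x + 1)-transformed by default) expression of its gene over the
#' shared samples; genes with several promoter ESLs get the mean r.  A gene
#' counts as significantly negatively correlated when its mean r is
#' negative and at least one of its ESLs has a Bonferroni-significant
#' negative correlation (correction over all tested ESLs).
#'
#' @param beta beta matrix (loci x samples).
#' @param expr expression matrix (genes x samples), TPM-like.
#' @param gene_map named list gene -> ESL IDs from
#'   \code{\link{map_promoter_esls}}.
#' @param log_transform log2(x + 1)-transform expression first (default
#'   TRUE).
#' @param alpha significance level applied to Bonferroni-adjusted per-ESL p.
#' @return data.frame \code{(gene, n_esls, r_meth_expr, p_meth_expr,
#'   significant_negative)}; \code{p_meth_expr} is the gene's smallest
#'   Bonferroni-adjusted per-ESL p.
#' @export
correlate_meth_expr <- function(beta, expr, gene_map, log_transform = TRUE,
                                alpha = 0.05) {
  b <- unclass(beta)
  e <- as.matrix(expr)
  shared <- intersect(colnames(b), colnames(e))
  if (length(shared) < 3L) {
    stop("need at least 3 shared samples between beta and expression",
         call. = FALSE)
  }
  b <- b[, shared, drop = FALSE]
  e <- e[, shared, drop = FALSE]
  if (log_transform) e <- log2(e + 1)
  genes <- names(gene_map)
  n_tests <- sum(lengths(gene_map))
  rows <- lapply(genes, function(g) {
    loci <- intersect(gene_map[[g]], rownames(b))
    if (length(loci) == 0L || !g %in% rownames(e)) return(NULL)
    y <- e[g, ]
    if (stats::sd(y) == 0) return(NULL)
    res <- vapply(loci, function(l) {
      x <- b[l, ]
      if (stats::sd(x, na.rm = TRUE) == 0) return(c(NA_real_, NA_real_))
      ct <- stats::cor.test(x, y, method = "pearson")
      c(unname(ct$estimate), ct$p.value)
    }, numeric(2))
    r <- res[1L, ]; p_adj <- pmin(1, res[2L, ] * n_tests)
    data.frame(gene = g, n_esls = length(loci),
               r_meth_expr = mean(r, na.rm = TRUE),
               p_meth_expr = suppressWarnings(min(p_adj, na.rm = TRUE)),
               significant_negative = mean(r, na.rm = TRUE) < 0 &&
                 any(p_adj < alpha & r < 0, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), n_esls = integer(0),
                      r_meth_expr = numeric(0), p_meth_expr = numeric(0),
                      significant_negative = logical(0))
  }
  rownames(out) <- NULL
  out
}

#' Per-gene correlation between expression and donor age
#'
#' Pearson correlation of each gene's (optionally log-transformed)
#' expression with age, Bonferroni-corrected over the tested genes.
#' Constant-expression genes are skipped.
#'
#' @param expr expression matrix (genes x samples).
#' @param ages numeric ages aligned with the expression columns.
#' @param log_transform log2(x + 1)-transform expression first.
#' @param alpha significance level on the adjusted p.
#' @return data.frame \code{(gene, r_age_expr, p_age_expr,
#'   p_age_expr_adj, significant_negative)}.
#' @export
correlate_age_expr <- function(expr, ages, log_transform = TRUE,
                               alpha = 0.05) {
  e <- as.matrix(expr)
  ok <- !is.na(ages)
  if (sum(ok) < 3L) stop("need ages for at least 3 samples", call. = FALSE)
  e <- e[, ok, drop = FALSE]
  ages <- ages[ok]
  if (log_transform) e <- log2(e + 1)
  keep <- apply(e, 1L, function(v) stats::sd(v) > 0)
  if (any(!keep)) message(sum(!keep), " constant-expression gene(s) skipped")
  e <- e[keep, , drop = FALSE]
  m <- nrow(e)
  res <- t(apply(e, 1L, function(v) {
    ct <- stats::cor.test(v, ages, method = "pearson")
    c(unname(ct$estimate), ct$p.value)
  }))
  out <- data.frame(gene = rownames(e),
                    r_age_expr = res[, 1L],
                    p_age_expr = res[, 2L],
                    p_age_expr_adj = pmin(1, res[, 2L] * m),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant_negative <- out$r_age_expr < 0 & out$p_age_expr_adj < alpha
  out
}

#' Mean ESL recurrence per gene
#'
#' @param gene_map named list gene -> ESL IDs.
#' @param recurrence \code{\link{call_recurrence}} output.
#' @return named numeric vector: mean recurrence over each gene's ESLs.
#' @export
gene_mean_recurrence <- function(gene_map, recurrence) {
  vapply(gene_map, function(loci) {
    r <- recurrence$recurrence[match(loci, recurrence$probe_id)]
    mean(r, na.rm = TRUE)
  }, numeric(1))
}

#' Prioritize genes by the three promoter-instability criteria
#'
#' A gene is prioritized when (1) its expression declines significantly
#' with age, (2) promoter-ESL methylation correlates significantly
#' negatively with its expression, and (3) the mean recurrence of its
#' promoter ESLs exceeds the recurrence cut — together nominating genes
#' plausibly silenced by accumulating promoter methylation instability.
#'
#' @param meth_records output of \code{\link{correlate_meth_expr}}.
#' @param age_records output of \code{\link{correlate_age_expr}}.
#' @param mean_recurrence named vector from
#'   \code{\link{gene_mean_recurrence}}.
#' @param recurrence_cut minimum mean recurrence (default 0.05, strict).
#' @return data.frame of class \code{gene_records}, one row per gene in
#'   \code{meth_records}, with the three criteria and a \code{prioritized}
#'   flag.
#' @export
prioritize_genes <- function(meth_records, age_records, mean_recurrence,
                             recurrence_cut = 0.05) {
  if (nrow(meth_records) == 0L) {
    out <- cbind(meth_records[, c("gene", "n_esls", "r_meth_expr",
                                  "p_meth_expr")],
                 data.frame(r_age_expr = numeric(0),
                            p_age_expr_adj = numeric(0),
                            mean_recurrence = numeric(0),
                            prioritized = logical(0)))
    class(out) <- c("gene_records", class(out))
    return(out)
  }
  i <- match(meth_records$gene, age_records$gene)
  out <- data.frame(
    gene = meth_records$gene,
    n_esls = meth_records$n_esls,
    r_meth_expr = meth_records$r_meth_expr,
    p_meth_expr = meth_records$p_meth_expr,
    sig_meth = meth_records$significant_negative,
    r_age_expr = age_records$r_age_expr[i],
    p_age_expr_adj = age_records$p_age_expr_adj[i],
    sig_age = age_records$significant_negative[i],
    mean_recurrence = unname(mean_recurrence[meth_records$gene]),
    stringsAsFactors = FALSE
  )
  out$prioritized <- !is.na(out$sig_meth) & out$sig_meth &
    !is.na(out$sig_age) & out$sig_age &
    !is.na(out$mean_recurrence) & out$mean_recurrence > recurrence_cut
  class(out) <- c("gene_records", class(out))
  out
}

#' Genomic-context enrichment of an ESL set
#'
#' Two summaries of where stable loci sit: the CpG-island enrichment odds
#' ratio of ESLs versus the non-ESL background (raw cross-product ratio,
#' two-sided Fisher p) and the fraction of ESLs within 1500 bp of a TSS.
#'
#' @param esl_ids character vector of ESL probe IDs.
#' @param annotation probe annotation covering ESLs and background.
#' @param tss_window bp window for the TSS-proximity fraction.
#' @return list \code{(odds_ratio, p, table, tss_fraction)}.
#' @export
context_enrichment <- function(esl_ids, annotation, tss_window = 1500) {
  is_esl <- annotation$probe_id %in% esl_ids
  if (!any(is_esl)) stop("no ESL found in annotation", call. = FALSE)
  if (all(is_esl)) stop("background (non-ESL) set is empty", call. = FALSE)
  island <- annotation$cgi_relation == "island"
  a <- sum(is_esl & island); b <- sum(is_esl & !island)
  c <- sum(!is_esl & island); d <- sum(!is_esl & !island)
  or <- if (a == 0 || b == 0 || c == 0 || d == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  p <- stats::fisher.test(matrix(c(a, c, b, d), 2L))$p.value
  td <- annotation$tss_distance[is_esl]
  tss_fraction <- mean(abs(td) <= tss_window, na.rm = TRUE)
  list(odds_ratio = or, p = p,
       table = matrix(c(a, b, c, d), 2L,
                      dimnames = list(c("island", "not_island"),
                                      c("ESL", "non_ESL"))),
       tss_fraction = tss_fraction)
}
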