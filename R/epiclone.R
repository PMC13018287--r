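#' Select a sample's epi-clone signature loci
#'
#' The k low-recurrence loci with the highest beta values in the given
#' sample; because these loci are rarely methylated across the cohort, high
#' methylation in one sample marks a patient-specific clonal event.  Ties
#' are broken lexicographically by probe ID.
#'
#' @param beta named numeric vector: the sample's beta values over the
#'   low-recurrence locus pool.
#' @param k signature size (default 15).
#' @return character vector of k probe IDs.
#' @export
select_signature <- function(beta, k = 15) {
  beta <- beta[!is.na(beta)]
  if (length(beta) < k) {
    stop("only ", length(beta), " usable loci; need k = ", k, call. = FALSE)
  }
  names(beta)[order(-beta, names(beta))][seq_len(k)]
}

# sibling pairs of a dendrogram: merge rows joining two singletons
.sibling_pairs <- function(hc) {
  both <- hc$merge[, 1L] < 0 & hc$merge[, 2L] < 0
  cbind(-hc$merge[both, 1L], -hc$merge[both, 2L])
}

#' Cluster diagnosis/relapse samples and count correct pairings
#'
#' Samples are clustered with Ward's linkage on the correlation distance
#' (1 - Pearson r between sample profiles over the union of signature
#' loci).  A diagnosis-relapse pair is "correct" when the two samples are
#' merged as immediate siblings in the dendrogram, i.e. each one's first
#' merge partner is the other.  The alternative \code{"mnn"} criterion
#' instead requires the two samples to be mutual nearest neighbours in the
#' distance matrix.
#'
#' @param matrix beta matrix restricted to the union of signature loci,
#'   samples in columns.
#' @param meta data.frame with \code{sample_id}, \code{patient_id},
#'   \code{timepoint} (\code{"diagnosis"}/\code{"relapse"}); each patient
#'   must contribute exactly one of each.
#' @param pairing \code{"sibling"} (default) or \code{"mnn"}.
#' @return list of class \code{matching_result}: \code{pairs} (per patient:
#'   both sample IDs and whether correctly paired), \code{n_correct},
#'   \code{n_patients}, \code{tree} (the \code{hclust} object).
#' @export
cluster_and_pair <- function(matrix, meta, pairing = c("sibling", "mnn")) {
  pairing <- match.arg(pairing)
  x <- unclass(matrix)
  meta <- meta[match(colnames(x), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) {
    stop("metadata does not cover all matrix samples", call. = FALSE)
  }
  if (ncol(x) %% 2L != 0L) stop("odd sample count", call. = FALSE)
  tab <- table(meta$patient_id, meta$timepoint)
  if (!all(colnames(tab) %in% c("diagnosis", "relapse")) ||
      !all(c("diagnosis", "relapse") %in% colnames(tab)) ||
      !all(tab[, "diagnosis"] == 1L) || !all(tab[, "relapse"] == 1L)) {
    stop("each patient needs exactly one diagnosis and one relapse sample",
         call. = FALSE)
  }
  sds <- apply(x, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0)) {
    stop("constant profile (undefined correlation) for sample(s): ",
         paste(colnames(x)[!is.finite(sds) | sds == 0], collapse = ", "),
         call. = FALSE)
  }
  d <- 1 - stats::cor(x, use = "pairwise.complete.obs")
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  patients <- unique(meta$patient_id)
  di <- match(meta$sample_id[meta$timepoint == "diagnosis"][
    match(patients, meta$patient_id[meta$timepoint == "diagnosis"])],
    colnames(x))
  ri <- match(meta$sample_id[meta$timepoint == "relapse"][
    match(patients, meta$patient_id[meta$timepoint == "relapse"])],
    colnames(x))
  if (pairing == "sibling") {
    sib <- .sibling_pairs(hc)
    sib_key <- paste(pmin(sib[, 1L], sib[, 2L]), pmax(sib[, 1L], sib[, 2L]))
    correct <- paste(pmin(di, ri), pmax(di, ri)) %in% sib_key
  } else {
    diag(d) <- Inf
    nn <- apply(d, 1L, which.min)
    correct <- nn[di] == ri & nn[ri] == di
  }
  pairs <- data.frame(patient_id = patients,
                      diagnosis = colnames(x)[di],
                      relapse = colnames(x)[ri],
                      correct = correct,
                      stringsAsFactors = FALSE)
  out <- list(pairs = pairs,
              n_correct = sum(correct),
              n_patients = length(patients),
              pairing = pairing,
              tree = hc)
  class(out) <- "matching_result"
  out
}

#' Permutation test for diagnosis-relapse matching
#'
#' In each simulation, k random low-recurrence loci are drawn (without
#' replacement, independently per patient) from the pool, the union matrix
#' is rebuilt, samples are re-clustered, and correct pairs are counted.
#' The p-value is the proportion of simulations whose count equals or
#' exceeds the observed count.
#'
#' @param matrix full beta matrix (loci x diagnosis/relapse samples).
#' @param meta metadata as in \code{\link{cluster_and_pair}}.
#' @param pool character vector of low-recurrence locus IDs present in the
#'   matrix.
#' @param observed observed number of correct pairs.
#' @param k signature size per patient.
#' @param n_sims number of simulations (default 1000).
#' @param seed integer seed.
#' @param plus_one use the (b + 1) / (m + 1) permutation p estimator instead
#'   of the plain exceedance proportion.
#' @param pairing pairing criterion, as in \code{\link{cluster_and_pair}}.
#' @return list \code{(p, sim_counts, n_sims, observed)}.
#' @export
epiclone_permutation_test <- function(matrix, meta, pool, observed, k = 15,
                                      n_sims = 1000, seed = NULL,
                                      plus_one = FALSE,
                                      pairing = "sibling") {
  if (n_sims < 1L) stop("'n_sims' must be at least 1", call. = FALSE)
  pool <- intersect(pool, rownames(matrix))
  if (length(pool) < k) {
    stop("low-recurrence pool (", length(pool), ") smaller than k = ", k,
         call. = FALSE)
  }
  x <- unclass(matrix)
  patients <- unique(meta$patient_id)
  n_pat <- length(patients)
  with_seed(seed, {
    sim_counts <- vapply(seq_len(n_sims), function(s) {
      loci <- unique(unlist(
        replicate(n_pat, sample(pool, k), simplify = FALSE)))
      res <- cluster_and_pair(x[loci, , drop = FALSE], meta,
                              pairing = pairing)
      res$n_correct
    }, numeric(1))
    b <- sum(sim_counts >= observed)
    p <- if (plus_one) (b + 1) / (n_sims + 1) else b / n_sims
    list(p = p, sim_counts = sim_counts, n_sims = n_sims,
         observed = observed)
  })
}

#' Match diagnosis and relapse samples by epi-clone signatures
#'
#' End-to-end matching: for each patient, select the k low-recurrence loci
#' most methylated in the designated sample (relapse by default), cluster
#' all samples over the union of signatures, count correctly paired
#' patients, and assess significance with the permutation test.
#'
#' @param matrix beta matrix over (at least) the low-recurrence loci.
#' @param meta metadata as in \code{\link{cluster_and_pair}}.
#' @param recurrence \code{\link{call_recurrence}} output (its
#'   \code{"low"}-class loci form the pool) or a character vector of pool
#'   locus IDs.
#' @param k signature size per patient (default 15).
#' @param signature_from select signatures from \code{"relapse"} (default)
#'   or \code{"diagnosis"} samples.
#' @param n_sims permutation simulations (0 skips the test).
#' @param seed integer seed for the permutation test.
#' @param pairing pairing criterion, as in \code{\link{cluster_and_pair}}.
#' @return \code{matching_result} with added \code{signatures},
#'   \code{p}, \code{n_sims}, \code{seed}, \code{k}.
#' @export
match_epiclones <- function(matrix, meta, recurrence, k = 15,
                            signature_from = c("relapse", "diagnosis"),
                            n_sims = 1000, seed = NULL,
                            pairing = "sibling") {
  signature_from <- match.arg(signature_from)
  pool <- if (is.data.frame(recurrence)) {
    recurrence$probe_id[recurrence$recurrence_class == "low"]
  } else {
    as.character(recurrence)
  }
  pool <- intersect(pool, rownames(matrix))
  if (length(pool) < k) {
    stop("low-recurrence pool smaller than k", call. = FALSE)
  }
  x <- unclass(matrix)
  meta <- meta[meta$timepoint %in% c("diagnosis", "relapse"), , drop = FALSE]
  meta <- meta[meta$sample_id %in% colnames(x), , drop = FALSE]
  src <- meta[meta$timepoint == signature_from, , drop = FALSE]
  signatures <- lapply(seq_len(nrow(src)), function(i) {
    select_signature(x[pool, src$sample_id[i]], k)
  })
  names(signatures) <- src$patient_id
  union_loci <- unique(unlist(signatures))
  res <- cluster_and_pair(x[union_loci, meta$sample_id, drop = FALSE],
                          meta, pairing = pairing)
  res$signatures <- signatures
  res$k <- k
  if (n_sims > 0) {
    pt <- epiclone_permutation_test(x[, meta$sample_id, drop = FALSE], meta,
                                    pool, res$n_correct, k = k,
                                    n_sims = n_sims, seed = seed,
                                    pairing = pairing)
    res$p <- pt$p
    res$sim_counts <- pt$sim_counts
    res$n_sims <- n_sims
    res$seed <- seed
  }
  res
}

#' @export
print.matching_result <- function(x, ...) {
  cat(sprintf("matching_result: %d/%d diagnosis-relapse pairs correct (%s)\n",
              x$n_correct, x$n_patients, x$pairing))
  if (!is.null(x$p)) {
    cat(sprintf("  permutation p = %.4g (%d simulations)\n", x$p, x$n_sims))
  }
  invisible(x)
}

#' @export
plot.matching_result <- function(x, ...) {
  graphics::plot(x$tree, xlab = "", sub = "",
                 main = sprintf("%d/%d correctly paired",
                                x$n_correct, x$n_patients), ...)
  invisible(x)
}
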