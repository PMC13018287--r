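#' Construct a validated beta-value matrix
#'
#' A beta matrix holds methylation fractions (beta values, the methylated
#' share of total signal at a CpG) with probes in rows and samples in
#' columns.  All non-missing values must lie in [0, 1] and row/column
#' identifiers must be unique.
#'
#' @param values numeric matrix, probes in rows, samples in columns, with
#'   rownames (probe IDs) and colnames (sample IDs).
#' @return The matrix with class \code{beta_matrix} prepended.
#' @export
beta_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("beta matrix needs probe rownames and sample colnames", call. = FALSE)
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    stop("duplicate probe identifier(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) {
    stop("duplicate sample identifier(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "beta value out of [0, 1] at probe '%s', sample '%s' (value %g)%s",
      rownames(values)[i], colnames(values)[j], values[i, j],
      if (nrow(bad) > 1L) sprintf(" and %d more", nrow(bad) - 1L) else ""),
      call. = FALSE)
  }
  class(values) <- c("beta_matrix", class(values))
  values
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples, %d missing values\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Read a beta-value matrix from delimited text
#'
#' Expects one header row and one leading label column.  Empty cells and
#' \code{"NA"} are read as missing.  Values outside [0, 1] and duplicate
#' identifiers are hard errors.
#'
#' @param path file path (tab-delimited by default).
#' @param orientation \code{"probes_in_rows"} (default) or
#'   \code{"samples_in_rows"}; the returned matrix always has probes in rows.
#' @param sep field separator; use \code{","} for CSV.
#' @return A \code{\link{beta_matrix}}.
#' @export
read_beta_matrix <- function(path,
                             orientation = c("probes_in_rows",
                                             "samples_in_rows"),
                             sep = "\t") {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), comment.char = "",
                          quote = "\"")
  if (ncol(df) < 2L) stop("matrix file needs a label column plus data columns",
                          call. = FALSE)
  labels <- as.character(df[[1L]])
  dup <- labels[duplicated(labels)]
  if (length(dup)) {
    stop("duplicate row identifier(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    storage.mode(vals) <- "double"
  }
  rownames(vals) <- labels
  bad <- which(!is.na(vals) & (vals < 0 | vals > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("value out of [0, 1] in %s at row '%s', column '%s' (%g)",
                 path, rownames(vals)[i], colnames(vals)[j], vals[i, j]),
         call. = FALSE)
  }
  if (orientation == "samples_in_rows") vals <- t(vals)
  beta_matrix(vals)
}

#' Write a beta-value matrix to delimited text
#'
#' Values are serialized with \code{\%.17g} so a write/read round trip
#' reproduces the doubles exactly.
#'
#' @param x a \code{\link{beta_matrix}} (or plain named matrix).
#' @param path output path.
#' @param sep field separator.
#' @param label header name of the leading probe-ID column.
#' @return \code{path}, invisibly.
#' @export
write_beta_matrix <- function(x, path, sep = "\t", label = "probe_id") {
  chr <- matrix(sprintf("%.17g", x), nrow = nrow(x))
  chr[is.na(x)] <- "NA"
  out <- cbind(rownames(x), chr)
  colnames(out) <- c(label, colnames(x))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.cgi_levels <- c("island", "shore", "shelf", "open_sea")
.flag_cols <- c("near_snp", "cross_reactive", "age_associated",
                "sex_chromosome", "non_cpg")
.sex_chroms <- c("chrX", "chrY", "X", "Y")

#' Read a probe annotation manifest
#'
#' Required columns: \code{probe_id}, \code{chromosome}, \code{position},
#' \code{cgi_relation} (island/shore/shelf/open_sea), \code{nearest_gene},
#' \code{tss_distance} (signed bp, negative upstream of the TSS) and the
#' logical blocklist flags \code{near_snp}, \code{cross_reactive},
#' \code{age_associated}, \code{sex_chromosome}, \code{non_cpg}.
#'
#' @param path delimited text file.
#' @param sep field separator.
#' @return data.frame with one row per probe and parsed logical flags.
#' @export
read_probe_annotation <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), quote = "\"")
  required <- c("probe_id", "chromosome", "position", "cgi_relation",
                "nearest_gene", "tss_distance", .flag_cols)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("annotation is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$cgi_relation[!is.na(df$cgi_relation)]),
                 .cgi_levels)
  if (length(bad)) {
    stop("unknown cgi_relation label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(.cgi_levels, collapse = "/"),
         call. = FALSE)
  }
  for (fl in .flag_cols) {
    v <- df[[fl]]
    if (is.character(v)) v <- toupper(v) %in% c("TRUE", "T", "1", "YES")
    df[[fl]] <- as.logical(v)
  }
  is_sex <- df$chromosome %in% .sex_chroms
  if (any(df$sex_chromosome != is_sex, na.rm = TRUE)) {
    stop("sex_chromosome flag inconsistent with chromosome label for probe(s): ",
         paste(utils::head(df$probe_id[which(df$sex_chromosome != is_sex)], 5L),
               collapse = ", "), call. = FALSE)
  }
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup)) {
    stop("duplicate probe_id in annotation: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  df
}

#' Read sample metadata
#'
#' Required columns: \code{sample_id}, \code{patient_id}, \code{cohort},
#' \code{disease}, \code{tissue}, \code{timepoint}.  Optional: \code{age},
#' \code{sex}, \code{clone_vaf}.  Within a longitudinal set the
#' (patient, timepoint) pairs must be unique and clone VAFs lie in [0, 1].
#'
#' @param path delimited text file.
#' @param sep field separator.
#' @return data.frame of sample metadata.
#' @export
read_sample_meta <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), quote = "\"")
  required <- c("sample_id", "patient_id", "cohort", "disease", "tissue",
                "timepoint")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("sample metadata missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_sample_meta(df)
}

#' Validate a sample-metadata data.frame
#'
#' @param meta data.frame with at least \code{sample_id}, \code{patient_id},
#'   \code{timepoint}.
#' @return \code{meta}, invisibly unchanged, after validation.
#' @export
validate_sample_meta <- function(meta) {
  tp_levels <- c("diagnosis", "remission", "relapse", "followup", "none")
  bad <- setdiff(unique(meta$timepoint[!is.na(meta$timepoint)]), tp_levels)
  if (length(bad)) {
    stop("unknown timepoint label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  key <- paste(meta$patient_id, meta$timepoint)
  longi <- meta$timepoint != "none"
  if (anyDuplicated(key[longi])) {
    stop("duplicated (patient_id, timepoint) pair in longitudinal metadata",
         call. = FALSE)
  }
  if (!is.null(meta$clone_vaf)) {
    v <- meta$clone_vaf
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("clone_vaf outside [0, 1]", call. = FALSE)
    }
  }
  meta
}

#' Read a survival table
#'
#' Expects \code{sample_id}, a \code{time} column (strictly positive, one
#' unit throughout) and one 0/1 event-indicator column per endpoint
#' (e.g. \code{event_mortality}, \code{event_cvd}); any further columns are
#' carried as covariates.
#'
#' @param path delimited text file.
#' @param sep field separator.
#' @return data.frame validated for positive times and binary indicators.
#' @export
read_survival_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), quote = "\"")
  if (!all(c("sample_id", "time") %in% names(df))) {
    stop("survival table needs 'sample_id' and 'time' columns", call. = FALSE)
  }
  validate_survival_table(df)
}

#' Validate a survival table
#' @param surv data.frame with \code{time} and \code{event_*} columns.
#' @return \code{surv} after validation.
#' @export
validate_survival_table <- function(surv) {
  if (any(!is.na(surv$time) & surv$time <= 0)) {
    stop("survival times must be strictly positive", call. = FALSE)
  }
  ev <- grep("^event_", names(surv), value = TRUE)
  for (e in ev) {
    v <- surv[[e]]
    if (any(!is.na(v) & !(v %in% c(0, 1)))) {
      stop("event indicator '", e, "' must be 0/1", call. = FALSE)
    }
  }
  surv
}

#' Restrict beta matrices to their common probe set
#'
#' Mirrors cross-platform harmonization (e.g. keeping only probes shared
#' between 450K and EPIC arrays): every returned matrix is restricted to the
#' intersection of all input probe sets, in the same order.
#'
#' @param matrices list of two or more beta matrices.
#' @return list of beta matrices sharing an identical probe order (the first
#'   matrix's order restricted to the intersection).
#' @export
harmonize_probe_sets <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2L) {
    stop("need a list of at least two matrices", call. = FALSE)
  }
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) == 0L) {
    stop("no probes shared by all matrices", call. = FALSE)
  }
  keep <- rownames(matrices[[1L]])[rownames(matrices[[1L]]) %in% common]
  lapply(matrices, function(m) beta_matrix(unclass(m)[keep, , drop = FALSE]))
}
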