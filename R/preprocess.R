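# Quantification processing chain: high-confidence filter -> detection
# filter -> minimum-value imputation -> quantile normalization -> log2 /
# per-treatment Z-scores. Each step records itself on the table's stage
# ledger; running a step after a later one errors, so the order cannot be
# violated silently.

#' Keep high-confidence proteins
#'
#' A protein is high-confidence if it has at least one unique peptide and
#' two strict peptides, or more than two strict peptides. Row order is
#' preserved; every protein in the table must have an evidence record.
#'
#' @param x a [quant_table()]
#' @param evidence data.frame from [read_peptide_evidence()]
#' @return the filtered [quant_table()]
#' @export
filter_high_confidence <- function(x, evidence) {
  stopifnot(inherits(x, "quant_table"))
  ids <- rownames(x$abundance)
  idx <- match(ids, evidence$protein_id)
  if (anyNA(idx))
    stop("no peptide evidence for protein(s): ",
         paste(ids[is.na(idx)], collapse = ", "))
  u <- evidence$unique_peptides[idx]
  s <- evidence$strict_peptides[idx]
  keep <- (u >= 1 & s >= 2) | s > 2
  x <- advance_stage(x, "high_confidence")
  x$abundance <- x$abundance[keep, , drop = FALSE]
  x
}

#' Keep proteins detected in enough samples
#'
#' @param x a [quant_table()]
#' @param min_samples minimum number of non-missing abundances required
#'   (default 1: detected in at least one sample)
#' @return the filtered [quant_table()]
#' @export
filter_detected <- function(x, min_samples = 1L) {
  stopifnot(inherits(x, "quant_table"), min_samples >= 1)
  keep <- rowSums(!is.na(x$abundance)) >= min_samples
  x <- advance_stage(x, "detected")
  x$abundance <- x$abundance[keep, , drop = FALSE]
  x
}

#' Impute missing abundances with observed minima
#'
#' Replaces each missing cell by the minimum observed value of its sample
#' column (default) or of the whole matrix. Per-column scope respects
#' sample-specific detection sensitivity. Cell provenance
#' (observed/imputed) is recorded on the table.
#'
#' @param x a [quant_table()]
#' @param scope `"column"` or `"global"`
#' @return the imputed [quant_table()] with a `provenance` matrix
#' @export
impute_min <- function(x, scope = c("column", "global")) {
  stopifnot(inherits(x, "quant_table"))
  scope <- match.arg(scope)
  x <- advance_stage(x, "imputed")
  miss <- is.na(x$abundance)
  all_missing <- colSums(!miss) == 0
  if (any(all_missing))
    stop("cannot impute: sample(s) with no observed values: ",
         paste(colnames(x$abundance)[all_missing], collapse = ", "))
  fill <- if (scope == "column") {
    apply(x$abundance, 2, min, na.rm = TRUE)[col(x$abundance)]
  } else {
    rep(min(x$abundance, na.rm = TRUE), length(x$abundance))
  }
  x$abundance[miss] <- fill[miss]
  prov <- matrix("observed", nrow(miss), ncol(miss), dimnames = dimnames(miss))
  prov[miss] <- "imputed"
  x$provenance <- prov
  x
}

#' Quantile-normalize a complete abundance matrix
#'
#' Standard quantile normalization: each column's ranks are mapped onto
#' the across-column mean of the order statistics, so every column ends
#' with an identical sorted value vector. Ties within a column receive
#' the mean of the reference quantiles of their tied ranks. Missing
#' values must have been imputed first.
#'
#' @param x a [quant_table()] with no missing values
#' @return the normalized [quant_table()]
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "quant_table"))
  if (anyNA(x$abundance))
    stop("quantile_normalize requires a complete matrix; run impute_min first")
  x <- advance_stage(x, "quantile_normalized")
  norm <- limma::normalizeQuantiles(x$abundance, ties = TRUE)
  dimnames(norm) <- dimnames(x$abundance)
  x$abundance <- norm
  x
}

#' Per-treatment Z-scores of log2 abundance
#'
#' Averages a group's replicate columns on the raw scale, takes log2,
#' and standardizes across proteins: z = (log2(a) - mean) / sd with the
#' sample (n-1) standard deviation.
#'
#' @param x a [quant_table()] with strictly positive abundances in the
#'   group's columns (run after imputation/normalization)
#' @param group one of `r toString(HD_GROUPS)`
#' @return named numeric vector of Z-scores, one per protein
#' @export
log2_zscore_by_group <- function(x, group) {
  stopifnot(inherits(x, "quant_table"))
  group <- match.arg(group, HD_GROUPS)
  cols <- group_columns(x, group)
  a <- rowMeans(x$abundance[, cols, drop = FALSE])
  if (anyNA(a) || any(a <= 0))
    stop("log2_zscore_by_group needs positive, non-missing abundances in group ",
         group, "; run imputation first")
  lg <- log2(a)
  if (length(lg) < 2 || stats::sd(lg) == 0)
    stop("zero or undefined abundance spread in group ", group,
         "; Z-scores are not defined")
  z <- (lg - mean(lg)) / stats::sd(lg)
  stats::setNames(z, rownames(x$abundance))
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper applying, in order: [filter_high_confidence()],
#' [filter_detected()], [impute_min()], [quantile_normalize()].
#'
#' @param x a [quant_table()]
#' @param evidence peptide-evidence data.frame
#' @param min_samples detection-filter threshold
#' @param impute_scope `"column"` or `"global"`
#' @return the processed [quant_table()]
#' @export
preprocess <- function(x, evidence, min_samples = 1L,
                       impute_scope = c("column", "global")) {
  x <- filter_high_confidence(x, evidence)
  x <- filter_detected(x, min_samples)
  x <- impute_min(x, match.arg(impute_scope))
  quantile_normalize(x)
}

#' Extract the normalized log2 table with provenance
#'
#' @param x a fully preprocessed [quant_table()] (no missing values)
#' @return list with `log2_abundance` (matrix), `provenance` (matrix of
#'   "observed"/"imputed"), and `samples`
#' @export
as_normalized <- function(x) {
  stopifnot(inherits(x, "quant_table"))
  if (anyNA(x$abundance)) stop("table still contains missing values")
  prov <- x$provenance
  if (is.null(prov))
    prov <- matrix("observed", nrow(x$abundance), ncol(x$abundance),
                   dimnames = dimnames(x$abundance))
  list(log2_abundance = log2(x$abundance), provenance = prov, samples = x$samples)
}
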