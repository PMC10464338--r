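#' @keywords internal
"_PACKAGE"

#' Treatment groups of a gradient hexanediol elution experiment
#'
#' The four treatment groups, in elution order: isotonic-buffer control
#' (IB) followed by 2%, 5% and 10% 1,6-hexanediol fractions.
#' @export
HD_GROUPS <- c("IB", "HD2", "HD5", "HD10")

# ordered preprocessing stages; a table may not revisit an earlier stage
# once a later one has been applied
.STAGES <- c("high_confidence", "detected", "imputed", "quantile_normalized")

#' Construct a protein x sample quantification table
#'
#' The pipeline's central object: a matrix of label-free peak-area
#' abundances (rows = proteins, columns = samples) with sample metadata
#' assigning each column to a treatment group and replicate. Missing
#' values are `NA`; observed values must be non-negative.
#'
#' @param abundance numeric matrix with protein ids as rownames and
#'   sample ids as colnames; `NA` encodes a missing (undetected) cell.
#' @param samples data.frame with columns `sample_id`, `group`
#'   (one of `r toString(HD_GROUPS)`) and `replicate` (positive integer),
#'   one row per abundance column, in column order.
#' @return an object of class `quant_table`: a list with elements
#'   `abundance`, `samples`, `stages` (preprocessing stages applied so
#'   far) and `provenance` (set by [impute_min()]).
#' @export
quant_table <- function(abundance, samples) {
  stopifnot(is.matrix(abundance), is.numeric(abundance))
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix must have protein rownames and sample colnames")
  dup <- rownames(abundance)[duplicated(rownames(abundance))]
  if (length(dup))
    stop("duplicate protein_id: ", paste(unique(dup), collapse = ", "))
  if (any(abundance < 0, na.rm = TRUE))
    stop("negative abundance values are not allowed")
  samples <- validate_sample_sheet(samples)
  if (nrow(samples) != ncol(abundance) ||
      !identical(samples$sample_id, colnames(abundance)))
    stop("sample sheet rows must match abundance columns (same ids, same order)")
  structure(
    list(abundance = abundance, samples = samples,
         stages = character(), provenance = NULL),
    class = "quant_table"
  )
}

validate_sample_sheet <- function(samples) {
  samples <- as.data.frame(samples)
  need <- c("sample_id", "group", "replicate")
  if (!all(need %in% names(samples)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup))
    stop("duplicate sample_id in sample sheet: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(samples$group), HD_GROUPS)
  if (length(bad))
    stop("unknown treatment group(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(HD_GROUPS, collapse = "/"), ")")
  samples$group <- factor(as.character(samples$group), levels = HD_GROUPS)
  samples$replicate <- as.integer(samples$replicate)
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1))
    stop("replicate must be a positive integer")
  samples
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d proteins x %d samples\n",
              nrow(x$abundance), ncol(x$abundance)))
  cat("groups:", paste(sprintf("%s=%d", levels(x$samples$group),
                               table(x$samples$group)), collapse = " "), "\n")
  cat(sprintf("missing cells: %d\n", sum(is.na(x$abundance))))
  if (length(x$stages)) cat("stages applied:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$abundance)

# refuse to (re-)apply `stage` if a stage later in the pipeline order has
# already been recorded; returns the table with `stage` appended
advance_stage <- function(x, stage) {
  idx <- match(stage, .STAGES)
  done <- match(x$stages, .STAGES)
  if (any(done >= idx))
    stop(sprintf("pipeline order violation: '%s' cannot run after '%s'",
                 stage, .STAGES[max(done)]))
  x$stages <- c(x$stages, stage)
  x
}

# columns of the abundance matrix belonging to one treatment group
group_columns <- function(x, group) {
  group <- match.arg(group, HD_GROUPS)
  which(x$samples$group == group)
}

#' Replicate-mean raw abundance per treatment group
#'
#' Averages the replicate columns of each treatment group on the raw
#' (pre-log) scale, ignoring missing cells. A protein with no observed
#' value in a group gets 0 there: after the detection filter, absence
#' from a group is read as "not eluted in this fraction", not imputed.
#'
#' @param x a [quant_table()]
#' @return numeric matrix, proteins x 4 groups (IB, HD2, HD5, HD10)
#' @export
group_means <- function(x) {
  stopifnot(inherits(x, "quant_table"))
  cols <- lapply(HD_GROUPS, function(g) {
    idx <- group_columns(x, g)
    if (!length(idx)) stop("no samples for group ", g)
    m <- rowMeans(x$abundance[, idx, drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- 0
    m
  })
  out <- do.call(cbind, cols)
  dimnames(out) <- list(rownames(x$abundance), HD_GROUPS)
  out
}
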