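# Readers and writers for the plain-text formats the pipeline touches:
# quantification TSV + sample sheet, peptide-evidence TSV, FASTA, GMT
# annotation sets, and BED-like disorder intervals. All readers validate;
# none silently drops rows.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

read_tsv_checked <- function(path, col_names) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  miss <- setdiff(col_names, names(df))
  if (length(miss))
    stop(basename(path), ": missing required column(s): ",
         paste(miss, collapse = ", "))
  df
}

# empty cell or "NA" (any case) is missing; zeros are observed values
parse_abundance <- function(x, where) {
  x <- trimws(x)
  is_missing <- x == "" | toupper(x) == "NA"
  v <- suppressWarnings(as.numeric(x))
  bad <- !is_missing & is.na(v)
  if (any(bad))
    stop(where, ": non-numeric abundance value(s): ",
         paste(unique(x[bad]), collapse = ", "))
  v[is_missing] <- NA_real_
  if (any(v < 0, na.rm = TRUE))
    stop(where, ": negative abundance value(s)")
  v
}

#' Read a protein quantification table with its sample sheet
#'
#' The quantification file is a TSV whose first column is `protein_id`
#' and whose remaining columns are samples (header = sample ids); cell
#' values are peak-area abundances, with empty cells or `NA`
#' (case-insensitive) meaning missing. The sample sheet is a TSV with
#' columns `sample_id`, `group`, `replicate` assigning each sample to a
#' treatment group; keeping it a separate, validated file (rather than
#' encoding metadata in the header) makes group membership explicit.
#'
#' @param path quantification TSV
#' @param sample_sheet sample-sheet TSV
#' @return a [quant_table()]
#' @export
read_quant_table <- function(path, sample_sheet) {
  sheet <- read_tsv_checked(sample_sheet, c("sample_id", "group", "replicate"))
  sheet$replicate <- suppressWarnings(as.integer(sheet$replicate))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  if (ncol(df) < 2) stop(basename(path), ": expected protein_id plus sample columns")
  sample_ids <- names(df)[-1]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop(basename(path), ": duplicate sample_id in header: ",
         paste(unique(dup), collapse = ", "))
  unknown <- setdiff(sample_ids, sheet$sample_id)
  if (length(unknown))
    stop(basename(path), ": sample(s) absent from sample sheet: ",
         paste(unknown, collapse = ", "))
  ids <- trimws(df[[1]])
  mat <- sapply(sample_ids, function(s)
    parse_abundance(df[[s]], sprintf("%s, sample %s", basename(path), s)))
  mat <- matrix(mat, nrow = length(ids),
                dimnames = list(ids, sample_ids))
  quant_table(mat, sheet[match(sample_ids, sheet$sample_id), , drop = FALSE])
}

#' Read per-protein peptide evidence
#'
#' TSV with columns `protein_id`, `unique_peptides`, `strict_peptides`
#' (strict = peptides at or above the search engine's ion-score cutoff).
#' Counts must be non-negative integers; one row per protein.
#'
#' @param path evidence TSV
#' @return data.frame with the three columns, integer counts
#' @export
read_peptide_evidence <- function(path) {
  df <- read_tsv_checked(path, c("protein_id", "unique_peptides", "strict_peptides"))
  for (col in c("unique_peptides", "strict_peptides")) {
    raw <- trimws(df[[col]])
    v <- suppressWarnings(as.numeric(raw))
    if (any(is.na(v)) || any(v != floor(v)) || any(v < 0))
      stop(basename(path), ": ", col, " must be non-negative integers")
    df[[col]] <- as.integer(v)
  }
  df$protein_id <- trimws(df$protein_id)
  dup <- df$protein_id[duplicated(df$protein_id)]
  if (length(dup))
    stop(basename(path), ": duplicate protein_id: ", paste(unique(dup), collapse = ", "))
  df
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file
#' @return named character vector of uppercase amino-acid sequences
#'   (20-letter alphabet plus X)
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(seqs))) stop(basename(path), ": empty sequence(s)")
  ok <- paste0("^[", paste(c(AA20, "X"), collapse = ""), "]+$")
  bad <- names(seqs)[!grepl(ok, seqs)]
  if (length(bad))
    stop(basename(path), ": non-standard residue letters in: ",
         paste(bad, collapse = ", "))
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup))
    stop(basename(path), ": duplicate sequence id: ", paste(unique(dup), collapse = ", "))
  seqs
}

#' Write protein sequences to FASTA
#' @param seqs named character vector of sequences
#' @param path output file
#' @param width line-wrap width
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read annotation sets in GMT format
#'
#' One set per line: name, description, then member protein ids,
#' tab-separated. Stands in for externally curated lists (condensate
#' components, transcription factors, RNA-binding proteins, known
#' phase-separating proteins, ...).
#'
#' @param path GMT file
#' @return named list of character vectors of member ids; descriptions
#'   kept in the `"description"` attribute
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 0L) < 3
  if (any(short))
    stop(basename(path), ": GMT line(s) with fewer than 3 fields (line ",
         paste(which(short), collapse = ", "), ")")
  nm <- vapply(fields, `[[`, "", 1L)
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop(basename(path), ": duplicate set name: ", paste(unique(dup), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nm
  empty <- nm[vapply(sets, length, 0L) == 0]
  if (length(empty))
    stop(basename(path), ": set(s) with no members: ", paste(empty, collapse = ", "))
  attr(sets, "description") <- stats::setNames(vapply(fields, `[[`, "", 2L), nm)
  sets
}

#' Write annotation sets in GMT format
#' @param sets named list of character vectors
#' @param path output file
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read per-protein disorder intervals
#'
#' BED-like 3-column TSV (`protein_id`, `start`, `end`) of predicted
#' intrinsically disordered regions in 0-based half-open residue
#' coordinates. Disorder prediction happens upstream; this package only
#' consumes the intervals.
#'
#' @param path interval TSV (no header)
#' @param sequences optional named character vector; when supplied,
#'   every interval is cross-checked against its sequence length
#' @return data.frame with columns `protein_id`, `start`, `end`
#' @export
read_disorder <- function(path, sequences = NULL) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "")
  if (ncol(df) < 3) stop(basename(path), ": expected 3 columns (id, start, end)")
  out <- data.frame(protein_id = trimws(df[[1]]),
                    start = suppressWarnings(as.integer(df[[2]])),
                    end   = suppressWarnings(as.integer(df[[3]])))
  if (any(is.na(out$start)) || any(is.na(out$end)))
    stop(basename(path), ": non-integer interval bound(s)")
  bad <- out$start < 0 | out$start >= out$end
  if (any(bad))
    stop(basename(path), ": invalid interval(s) (need 0 <= start < end) for ",
         paste(unique(out$protein_id[bad]), collapse = ", "))
  if (!is.null(sequences)) {
    known <- out$protein_id %in% names(sequences)
    over <- known & out$end > nchar(sequences)[out$protein_id]
    if (any(over))
      stop(basename(path), ": interval end beyond sequence length for ",
           paste(unique(out$protein_id[over]), collapse = ", "))
  }
  out
}

#' Write a data frame as TSV at full precision
#'
#' Emits a header row, missing values as empty strings, and numeric
#' values with 17 significant digits so that a write/read round trip
#' reproduces doubles bit-identically.
#'
#' @param rows data.frame
#' @param path output file
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  fmt <- lapply(rows, function(col) {
    out <- if (is.double(col)) sprintf("%.17g", col) else as.character(col)
    out[is.na(col)] <- ""
    out
  })
  m <- do.call(cbind, fmt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(rows), collapse = "\t"), con)
  writeLines(apply(m, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a quantification table and its sample sheet
#' @param x a [quant_table()]
#' @param path quantification TSV to write
#' @param sample_sheet optional sample-sheet TSV to write alongside
#' @export
write_quant_table <- function(x, path, sample_sheet = NULL) {
  stopifnot(inherits(x, "quant_table"))
  df <- data.frame(protein_id = rownames(x$abundance), check.names = FALSE)
  for (j in seq_len(ncol(x$abundance))) df[[colnames(x$abundance)[j]]] <- x$abundance[, j]
  write_table(df, path)
  if (!is.null(sample_sheet)) write_table(x$samples, sample_sheet)
  invisible(path)
}
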