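# Sequence features relevant to liquid-liquid phase separation:
# low-complexity fraction from an entropy two-threshold sliding-window
# detector, disorder fraction from externally predicted intervals,
# fraction of charged residues, and Kyte-Doolittle hydropathy rescaled to
# [0, 1] (Uversky convention).

# Kyte-Doolittle hydropathy index
KD_SCALE <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
              Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
              L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
              S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

CHARGED_AA <- c("D", "E", "K", "R")

check_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1, nzchar(seq))
  toupper(seq)
}

#' Shannon compositional complexity of a residue window
#'
#' Entropy in bits per residue of the window's amino-acid composition,
#' `-sum (n_a/L) log2(n_a/L)` over observed residues. `X` residues are
#' excluded from the counts (the counted length shrinks accordingly); a
#' window of only `X` has no defined complexity and yields `NA`.
#'
#' @param window amino-acid string
#' @return complexity in bits, or `NA` for an all-`X` window
#' @export
window_complexity <- function(window) {
  window <- check_seq(window)
  chars <- strsplit(window, "")[[1]]
  chars <- chars[chars != "X"]
  if (!length(chars)) {
    message("window of only X residues: complexity undefined")
    return(NA_real_)
  }
  p <- table(chars) / length(chars)
  -sum(p * log2(p))
}

# complexity of every length-W window of `chars` (character vector),
# vectorized via cumulative residue counts; X excluded per window
sliding_complexity <- function(chars, W) {
  L <- length(chars)
  n_win <- L - W + 1
  letters20 <- AA20
  counts <- vapply(letters20, function(a) cumsum(chars == a),
                   numeric(L))
  counts <- rbind(0, counts)                      # (L+1) x 20 cumulative
  win <- counts[(W + 1):(L + 1), , drop = FALSE] -
         counts[1:n_win, , drop = FALSE]          # n_win x 20
  len <- rowSums(win)                             # counted length (X excluded)
  p <- win / ifelse(len > 0, len, NA_real_)
  h <- -rowSums(ifelse(win > 0, p * log2(p), 0))
  h[len == 0] <- NA_real_                         # all-X window
  h
}

#' Detect low-complexity segments (entropy two-threshold scan)
#'
#' SEG-style detection of low-complexity domains: every length-`W`
#' window with complexity at or below `locut` triggers a segment; each
#' trigger is extended left and right over contiguous windows with
#' complexity at or below `hicut`; overlapping extended regions are
#' merged. Returned segments carry the compositional complexity of their
#' merged subsequence. The boundary-refinement stage of the original
#' detector (optimal-subsegment minimization) is deliberately omitted:
#' the per-protein low-complexity length fraction this package reports is
#' insensitive to second-order boundary adjustments, and the
#' trigger/extend/merge scan is what the tests verify against a
#' brute-force oracle.
#'
#' All-`X` windows have undefined complexity and never trigger or extend
#' a segment. Sequences shorter than `W` return no segments.
#'
#' @param seq amino-acid string
#' @param W window length (default 12)
#' @param locut trigger threshold in bits (default 2.2)
#' @param hicut extension threshold in bits (default 2.5)
#' @return data.frame with columns `start`, `end` (0-based half-open
#'   residue coordinates) and `complexity`, sorted by `start`
#' @export
seg_low_complexity <- function(seq, W = 12, locut = 2.2, hicut = 2.5) {
  seq <- check_seq(seq)
  if (W < 2 || locut <= 0 || locut > hicut)
    stop("need W >= 2 and 0 < locut <= hicut")
  empty <- data.frame(start = integer(), end = integer(), complexity = numeric())
  L <- nchar(seq)
  if (L < W) return(empty)
  chars <- strsplit(seq, "")[[1]]
  h <- sliding_complexity(chars, W)
  trigger <- !is.na(h) & h <= locut
  if (!any(trigger)) return(empty)
  extend <- !is.na(h) & h <= hicut
  # maximal runs of extendable windows that contain at least one trigger
  r <- rle(extend)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  spans <- NULL
  for (k in which(r$values)) {
    if (any(trigger[run_start[k]:run_end[k]]))
      spans <- rbind(spans, c(run_start[k] - 1L, run_end[k] - 1L + W))
  }
  if (is.null(spans)) return(empty)
  # merge overlapping residue spans (runs are window-disjoint but their
  # residue spans can still overlap when the gap is shorter than W)
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  merged <- spans[1, , drop = FALSE]
  for (i in seq_len(nrow(spans))[-1]) {
    last <- nrow(merged)
    if (spans[i, 1] < merged[last, 2]) {
      merged[last, 2] <- max(merged[last, 2], spans[i, 2])
    } else {
      merged <- rbind(merged, spans[i, ])
    }
  }
  data.frame(
    start = as.integer(merged[, 1]),
    end = as.integer(merged[, 2]),
    complexity = vapply(seq_len(nrow(merged)), function(i)
      suppressMessages(window_complexity(
        substr(seq, merged[i, 1] + 1, merged[i, 2]))), 0)
  )
}

# total length covered by a set of [start, end) intervals
union_length <- function(start, end) {
  if (!length(start)) return(0L)
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0L; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e) cur_e <- max(cur_e, end[i])
    else { tot <- tot + (cur_e - cur_s); cur_s <- start[i]; cur_e <- end[i] }
  }
  tot + (cur_e - cur_s)
}

#' Low-complexity length fraction
#'
#' Union length of low-complexity segments divided by sequence length.
#'
#' @param seq amino-acid string
#' @param segments data.frame from [seg_low_complexity()]
#' @return fraction in \[0, 1\]
#' @export
lcd_fraction <- function(seq, segments) {
  seq <- check_seq(seq)
  if (nrow(segments) && any(segments$start < 0 | segments$end > nchar(seq)))
    stop("segment outside sequence bounds")
  union_length(segments$start, segments$end) / nchar(seq)
}

#' Disorder length fraction
#'
#' Union length of externally predicted disordered intervals divided by
#' sequence length.
#'
#' @param seq amino-acid string
#' @param intervals data.frame with `start`, `end` (0-based half-open)
#' @return fraction in \[0, 1\]
#' @export
idr_fraction <- function(seq, intervals) {
  seq <- check_seq(seq)
  if (nrow(intervals) &&
      any(intervals$start < 0 | intervals$start >= intervals$end |
            intervals$end > nchar(seq)))
    stop("disorder interval outside sequence bounds")
  union_length(intervals$start, intervals$end) / nchar(seq)
}

#' Fraction of charged residues
#'
#' Proportion of D, E, K, R over the full sequence length (histidine is
#' not counted as charged, following the usual convention of sequence
#' parameter calculators).
#'
#' @param seq amino-acid string
#' @return fraction in \[0, 1\]
#' @export
fcr <- function(seq) {
  seq <- check_seq(seq)
  chars <- strsplit(seq, "")[[1]]
  sum(chars %in% CHARGED_AA) / length(chars)
}

#' Normalized (Uversky) hydropathy
#'
#' Mean Kyte-Doolittle hydropathy rescaled residue-wise to \[0, 1\] via
#' `(KD + 4.5) / 9`. `X` residues are skipped (the averaged length
#' shrinks); any other non-standard letter is an error.
#'
#' @param seq amino-acid string
#' @return mean rescaled hydropathy in \[0, 1\]
#' @export
uversky_hydropathy <- function(seq) {
  seq <- check_seq(seq)
  chars <- strsplit(seq, "")[[1]]
  chars <- chars[chars != "X"]
  if (!length(chars)) stop("sequence has no scorable residues")
  kd <- KD_SCALE[chars]
  if (anyNA(kd))
    stop("unknown residue(s): ",
         paste(unique(chars[is.na(kd)]), collapse = ", "))
  mean((kd + 4.5) / 9)
}

#' Per-protein feature vectors
#'
#' Computes, for every sequence, the low-complexity fraction (via
#' [seg_low_complexity()]), disorder fraction (from supplied intervals;
#' 0 when a protein has none), fraction of charged residues, and
#' normalized hydropathy. Optional externally computed predictor scores
#' (e.g. pi-contact or granule-propensity scores) are joined by protein
#' id.
#'
#' @param sequences named character vector of sequences
#' @param disorder optional data.frame from [read_disorder()]
#' @param scores optional data.frame with a `protein_id` column plus
#'   numeric score columns, joined as-is
#' @param W,locut,hicut low-complexity detector parameters
#' @return data.frame with columns `protein_id`, `lcd_fraction`,
#'   `idr_fraction`, `fcr`, `hydropathy`, plus any score columns
#' @export
feature_vectors <- function(sequences, disorder = NULL, scores = NULL,
                            W = 12, locut = 2.2, hicut = 2.5) {
  stopifnot(length(sequences) > 0, !is.null(names(sequences)))
  out <- data.frame(
    protein_id = names(sequences),
    lcd_fraction = vapply(sequences, function(s)
      lcd_fraction(s, seg_low_complexity(s, W, locut, hicut)), 0),
    idr_fraction = 0,
    fcr = vapply(sequences, fcr, 0),
    hydropathy = vapply(sequences, uversky_hydropathy, 0),
    row.names = NULL
  )
  if (!is.null(disorder)) {
    known <- disorder$protein_id %in% names(sequences)
    d <- disorder[known, , drop = FALSE]
    out$idr_fraction <- vapply(names(sequences), function(id)
      idr_fraction(sequences[[id]], d[d$protein_id == id, , drop = FALSE]), 0)
  }
  if (!is.null(scores)) {
    stopifnot("protein_id" %in% names(scores))
    out <- merge(out, scores, by = "protein_id", all.x = TRUE, sort = FALSE)
    out <- out[match(names(sequences), out$protein_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
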