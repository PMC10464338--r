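# Elution statistics: per-protein hexanediol-vs-buffer abundance ratio,
# per-concentration abundance shares, representative/common/minor
# classification, and set-wise abundance ratios. Ratio statistics work on
# raw replicate means (undetected groups contribute 0), never on imputed
# values, so absent fractions cannot be inflated by imputation.

HD_CONC <- c("HD2", "HD5", "HD10")

REP_CLASSES <- c("representative_HD2", "representative_HD5",
                 "representative_HD10", "common", "minor", "undefined")

#' Hexanediol-vs-buffer abundance ratio
#'
#' Fraction of a protein's abundance eluted by 1,6-hexanediol:
#' `hd_total / (ib + hd_total)`. A protein absent from every group
#' (both inputs 0) has no defined ratio and yields `NA`.
#'
#' @param a_ib abundance in the isotonic-buffer control (vectorized)
#' @param a_hd_total summed abundance across the hexanediol fractions
#' @return numeric in \[0, 1\], or `NA` where both inputs are 0
#' @export
hd_vs_ib_ratio <- function(a_ib, a_hd_total) {
  stopifnot(all(a_ib >= 0, na.rm = TRUE), all(a_hd_total >= 0, na.rm = TRUE))
  tot <- a_ib + a_hd_total
  out <- ifelse(tot > 0, a_hd_total / tot, NA_real_)
  if (anyNA(out))
    message(sum(is.na(out)), " protein(s) with zero total abundance: ratio undefined, excluded")
  out
}

#' Per-concentration abundance shares
#'
#' Shares of a protein's hexanediol-eluted abundance across the 2%, 5%
#' and 10% fractions; each row sums to 1. Proteins never eluted by
#' hexanediol (all three 0) get `NA` shares.
#'
#' @param a_hd2,a_hd5,a_hd10 per-fraction abundances (vectorized)
#' @return numeric matrix with columns `s2`, `s5`, `s10`
#' @export
concentration_shares <- function(a_hd2, a_hd5, a_hd10) {
  stopifnot(all(a_hd2 >= 0), all(a_hd5 >= 0), all(a_hd10 >= 0))
  tot <- a_hd2 + a_hd5 + a_hd10
  n_undef <- sum(tot == 0)
  if (n_undef > 0)
    message(n_undef, " protein(s) with no hexanediol-eluted abundance: shares undefined, excluded")
  denom <- ifelse(tot > 0, tot, NA_real_)
  cbind(s2 = a_hd2 / denom, s5 = a_hd5 / denom, s10 = a_hd10 / denom)
}

#' Classify proteins by their dominant elution fraction
#'
#' A protein is *representative* of a hexanediol concentration when that
#' fraction holds strictly more than `rep_threshold` of its summed
#' hexanediol-eluted abundance (at most one fraction can). Otherwise it
#' is *common* when its largest share lies in
#' `[common_low, rep_threshold]`, and *minor* below that. Undefined
#' shares give `undefined`.
#'
#' @param shares matrix with columns `s2`, `s5`, `s10` (rows sum to 1),
#'   or a single length-3 share vector
#' @param rep_threshold representative cutoff (default 0.5)
#' @param common_low lower bound of the common band (default 0.2)
#' @return factor with levels `r toString(REP_CLASSES)`
#' @export
classify_representative <- function(shares, rep_threshold = 0.5, common_low = 0.2) {
  if (is.null(dim(shares))) shares <- matrix(shares, nrow = 1,
                                             dimnames = list(NULL, c("s2", "s5", "s10")))
  stopifnot(ncol(shares) == 3)
  if (rep_threshold <= 0 || rep_threshold >= 1 ||
      common_low <= 0 || common_low >= 1 || common_low >= rep_threshold)
    stop("need 0 < common_low < rep_threshold < 1")
  ok <- stats::complete.cases(shares)
  if (any(abs(rowSums(shares[ok, , drop = FALSE]) - 1) > 1e-9))
    stop("defined share rows must sum to 1")
  cls <- rep("undefined", nrow(shares))
  top <- apply(shares, 1, which.max)
  mx <- apply(shares, 1, max)
  cls[ok & mx > rep_threshold] <-
    paste0("representative_", HD_CONC)[top[ok & mx > rep_threshold]]
  cls[ok & mx <= rep_threshold & mx >= common_low] <- "common"
  cls[ok & mx < common_low] <- "minor"
  factor(cls, levels = REP_CLASSES)
}

#' Build per-protein elution profiles
#'
#' Computes, for every protein, the replicate-mean raw abundance per
#' treatment group, the hexanediol-vs-buffer abundance ratio, the
#' per-concentration shares, and the representative/common class.
#'
#' @param x a [quant_table()] (ratios use raw replicate means; apply the
#'   detection filter first, not imputation)
#' @param rep_threshold,common_low classification cutoffs, see
#'   [classify_representative()]
#' @param hd_pooling how the three hexanediol fractions are pooled into a
#'   single hexanediol abundance for the ratio: `"sum"` (sequential
#'   elution: each fraction is distinct material) or `"max"`
#' @return data.frame with columns `protein_id`, `a_IB`, `a_HD2`,
#'   `a_HD5`, `a_HD10`, `hd_ratio`, `s2`, `s5`, `s10`, `rep_class`
#' @export
elution_profiles <- function(x, rep_threshold = 0.5, common_low = 0.2,
                             hd_pooling = c("sum", "max")) {
  stopifnot(inherits(x, "quant_table"))
  hd_pooling <- match.arg(hd_pooling)
  gm <- group_means(x)
  hd_total <- switch(hd_pooling,
                     sum = rowSums(gm[, HD_CONC, drop = FALSE]),
                     max = apply(gm[, HD_CONC, drop = FALSE], 1, max))
  ratio <- suppressMessages(hd_vs_ib_ratio(gm[, "IB"], hd_total))
  shares <- suppressMessages(
    concentration_shares(gm[, "HD2"], gm[, "HD5"], gm[, "HD10"]))
  data.frame(
    protein_id = rownames(gm),
    a_IB = gm[, "IB"], a_HD2 = gm[, "HD2"],
    a_HD5 = gm[, "HD5"], a_HD10 = gm[, "HD10"],
    hd_ratio = ratio,
    s2 = shares[, "s2"], s5 = shares[, "s5"], s10 = shares[, "s10"],
    rep_class = classify_representative(shares, rep_threshold, common_low),
    row.names = NULL
  )
}

#' Set-wise abundance ratio for one treatment group
#'
#' Summed abundance of a protein set in one treatment group divided by
#' the set's summed abundance across groups — the set-level analogue of
#' the per-protein shares. With `include_ib = FALSE` (default) the
#' denominator covers the three hexanediol fractions only, so the three
#' hexanediol ratios of a set sum to 1; with `include_ib = TRUE` the
#' buffer control joins the denominator (and `group = "IB"` is allowed),
#' giving the set-level hexanediol-vs-buffer decomposition.
#'
#' @param profiles data.frame from [elution_profiles()]
#' @param members character vector of protein ids in the set
#' @param group treatment group whose share is returned
#' @param include_ib include the buffer control in the denominator
#' @param set_name label used in error messages
#' @return a single ratio in \[0, 1\]
#' @export
setwise_abundance_ratio <- function(profiles, members, group,
                                    include_ib = FALSE, set_name = "set") {
  allowed <- if (include_ib) HD_GROUPS else HD_CONC
  group <- match.arg(group, allowed)
  rows <- profiles$protein_id %in% members
  if (!any(rows))
    stop("no profiled proteins in set '", set_name, "'")
  p <- profiles[rows, , drop = FALSE]
  num <- sum(p[[paste0("a_", group)]])
  den <- sum(p$a_HD2 + p$a_HD5 + p$a_HD10 + if (include_ib) p$a_IB else 0)
  if (den == 0) stop("set '", set_name, "' has zero total abundance")
  num / den
}

#' Count quantified proteins per treatment group
#'
#' Number of proteins with at least one observed (non-missing, positive)
#' abundance in each treatment group, plus the total over all groups.
#'
#' @param x a [quant_table()] (typically after the high-confidence and
#'   detection filters)
#' @return named integer vector over `r toString(HD_GROUPS)` plus `total`
#' @export
count_quantified_per_group <- function(x) {
  stopifnot(inherits(x, "quant_table"))
  counts <- vapply(HD_GROUPS, function(g) {
    cols <- group_columns(x, g)
    sum(rowSums(!is.na(x$abundance[, cols, drop = FALSE]) &
                  x$abundance[, cols, drop = FALSE] > 0, na.rm = TRUE) > 0)
  }, 0L)
  c(counts, total = nrow(x$abundance))
}
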