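# Comparison statistics used by the analysis: Pearson chi-square on type
# composition, independent-samples t test (Welch by default),
# Mann-Whitney rank-sum test, upper-tail hypergeometric set enrichment
# with Benjamini-Hochberg correction, and the rank-based quartile split
# used to contrast high- vs low-abundance proteins.

#' Pearson chi-square test of independence on a 2 x k count table
#'
#' No continuity correction; all expected counts must be positive.
#'
#' @param counts 2 x k matrix of non-negative counts
#' @return list with `chi2`, `df`, `p`
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2, ncol(counts) >= 2, all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal: expected counts are not all positive")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Independent-samples t test
#'
#' Welch's unequal-variance t test by default; set `equal_var = TRUE`
#' for the pooled-variance form. When both samples are constant with the
#' same mean there is no evidence of a difference and `t = 0, p = 1` by
#' convention; any other zero-variance situation is an error.
#'
#' @param x,y numeric samples, each of length >= 2
#' @param equal_var pool the variances
#' @return list with `t`, `df`, `p` (two-sided)
#' @export
t_test_independent <- function(x, y, equal_var = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    stop("both samples constant with different means: t undefined")
  }
  if (vx == 0 || vy == 0)
    stop("zero variance in one sample: t test not applicable")
  res <- stats::t.test(x, y, var.equal = equal_var)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Mann-Whitney rank-sum test
#'
#' Returns the U statistic for `x` and a two-sided p-value: exact by
#' enumeration when the combined sample size is at most `exact_max` and
#' there are no ties, otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric samples
#' @param exact_max combined-size cutoff for the exact distribution
#' @return list with `U`, `p`, `exact` (logical)
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= exact_max && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(U = unname(res$statistic), p = unname(res$p.value), exact = use_exact)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p_values numeric vector of p-values in \[0, 1\]
#' @return adjusted values, same order as the input
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric set enrichment over annotation sets
#'
#' For each annotation set (intersected with the universe first), tests
#' whether the query over-represents the set: upper-tail hypergeometric
#' `P(X >= overlap)` given the universe size, set size and query size.
#' Benjamini-Hochberg q-values are computed across all tested sets. Sets
#' empty after intersection with the universe are skipped with a message.
#'
#' @param query character vector of protein ids (must lie in `universe`)
#' @param sets named list of character vectors (e.g. [read_gmt()])
#' @param universe character vector of all quantified protein ids
#' @return data.frame with columns `set_name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, `q_value`
#' @export
hypergeometric_enrichment <- function(query, sets, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query protein(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    if (!length(s)) {
      message("set '", nm, "' empty after intersection with universe: skipped")
      return(NULL)
    }
    k <- length(intersect(query, s))
    data.frame(set_name = nm, overlap = k, set_size = length(s),
               query_size = length(query), universe_size = length(universe),
               p_value = stats::phyper(k - 1, length(s),
                                       length(universe) - length(s),
                                       length(query), lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable sets after intersection with universe")
  out$q_value <- bh_fdr(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}

#' Quartile split of a named value vector
#'
#' Assigns each protein to an abundance quartile by rank, `Q4` highest.
#' Ties are broken by protein id (lexicographic) so the assignment is
#' deterministic and independent of input order.
#'
#' @param values named numeric vector with at least 8 entries
#' @return named factor with levels `Q1`..`Q4`
#' @export
quartile_split <- function(values) {
  stopifnot(!is.null(names(values)))
  n <- length(values)
  if (n < 8) stop("quartile split needs at least 8 values")
  o <- order(values, names(values))
  bin <- integer(n)
  bin[o] <- ceiling(4 * seq_len(n) / n)
  stats::setNames(factor(paste0("Q", bin), levels = paste0("Q", 1:4)),
                  names(values))
}
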