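# Synthetic gradient-elution experiments with known ground truth. The
# generator plants three protein classes that differ both in their
# elution behaviour (how much of each protein the buffer control vs the
# three hexanediol fractions recover) and in their sequence makeup
# (low-complexity block content, disorder coverage), so every pipeline
# stage - filters, imputation, normalization, elution classification,
# sequence features, statistics - can be exercised against a known
# answer.

SIM_CLASSES <- c("llps_like", "structured", "background")

#' Default elution-share profiles of the planted classes
#'
#' Mean share of a protein's total material recovered in each treatment
#' group (rows sum to 1). The phase-separation-prone class elutes mostly
#' at 2% hexanediol; the structured class mostly resists hexanediol and
#' washes out with the buffer control; the background class sits in
#' between.
#' @export
default_elution_profiles <- function() {
  m <- rbind(
    llps_like  = c(0.10, 0.60, 0.20, 0.10),
    structured = c(0.70, 0.15, 0.10, 0.05),
    background = c(0.40, 0.25, 0.20, 0.15)
  )
  colnames(m) <- HD_GROUPS
  m
}

#' Simulation configuration
#'
#' @param n_proteins number of proteins to simulate
#' @param replicates named integer vector: replicate count per treatment
#'   group
#' @param class_fractions named proportions of the three planted classes
#'   (must sum to 1)
#' @param elution_profiles class x group matrix of mean elution shares
#'   (rows sum to 1); see [default_elution_profiles()]
#' @param abundance_lognormal `c(meanlog, sdlog)` of each protein's total
#'   abundance on the peak-area scale
#' @param replicate_sdlog standard deviation (log scale) of the
#'   multiplicative replicate noise
#' @param missing_rate overall fraction of cells masked missing
#'   (abundance-dependent: low-abundance cells are masked
#'   preferentially, mimicking left-censored label-free data); must be
#'   below 0.5 so the rank weighting stays a valid probability
#' @param seed integer seed; all outputs are deterministic given it
#' @return a `sim_config` list
#' @export
sim_config <- function(n_proteins = 2000,
                       replicates = c(IB = 2, HD2 = 2, HD5 = 2, HD10 = 2),
                       class_fractions = c(llps_like = 0.3, structured = 0.4,
                                           background = 0.3),
                       elution_profiles = default_elution_profiles(),
                       abundance_lognormal = c(meanlog = log(1e7), sdlog = 1.5),
                       replicate_sdlog = 0.2,
                       missing_rate = 0.15,
                       seed = 1L) {
  stopifnot(n_proteins >= 1,
            identical(sort(names(replicates)), sort(HD_GROUPS)),
            all(replicates >= 1),
            identical(sort(names(class_fractions)), sort(SIM_CLASSES)),
            identical(sort(rownames(elution_profiles)), sort(SIM_CLASSES)),
            identical(colnames(elution_profiles), HD_GROUPS),
            replicate_sdlog >= 0,
            missing_rate >= 0, missing_rate < 0.5,
            abs(seed) < 2^31 - 10)
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9)
    stop("degenerate class fractions: must be non-negative and sum to 1")
  if (any(abs(rowSums(elution_profiles) - 1) > 1e-9))
    stop("each elution profile must sum to 1")
  structure(list(
    n_proteins = as.integer(n_proteins),
    replicates = replicates[HD_GROUPS],
    class_fractions = class_fractions[SIM_CLASSES],
    elution_profiles = elution_profiles[SIM_CLASSES, , drop = FALSE],
    abundance_lognormal = abundance_lognormal,
    replicate_sdlog = replicate_sdlog,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# largest-remainder apportionment of n among fractions
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# one simulated sequence: low-complexity blocks (biased S/G/Q/P alphabet)
# embedded in near-uniform background; returns sequence, the block
# intervals, and the realized block coverage
sim_sequence <- function(len, lc_target) {
  lc_probs <- c(S = 0.45, G = 0.30, Q = 0.15, P = 0.10)
  n_lc <- round(len * lc_target)
  blocks <- NULL
  if (n_lc >= 12) {
    n_blocks <- sample(1:3, 1)
    sizes <- apportion(n_lc, rep(1 / n_blocks, n_blocks))
    sizes <- sizes[sizes >= 12]
    if (length(sizes)) {
      # place blocks left-to-right with random gaps
      free <- len - sum(sizes)
      cuts <- sort(sample(0:free, length(sizes)))
      starts <- cuts + cumsum(c(0, utils::head(sizes, -1)))
      blocks <- cbind(start = starts, end = starts + sizes)
    }
  }
  chars <- sample(AA20, len, replace = TRUE)
  if (!is.null(blocks)) {
    for (i in seq_len(nrow(blocks))) {
      idx <- (blocks[i, "start"] + 1):blocks[i, "end"]
      chars[idx] <- sample(names(lc_probs), length(idx),
                           replace = TRUE, prob = lc_probs)
    }
  }
  list(seq = paste(chars, collapse = ""),
       blocks = blocks,
       lc_realized = if (is.null(blocks)) 0 else sum(blocks[, 2] - blocks[, 1]) / len)
}

#' Simulate a proteome with planted sequence classes
#'
#' Generates sequences, disorder intervals and a ground-truth table for
#' the three planted classes. Phase-separation-prone proteins (length
#' 300-800) carry contiguous low-complexity blocks covering 30-60% of
#' their residues, drawn from a serine/glycine/glutamine/proline-biased
#' alphabet, with disorder intervals over those blocks; structured
#' proteins use the 20-letter alphabet near-uniformly with under 10%
#' disorder; background proteins sit between. Deterministic given the
#' config seed.
#'
#' @param config a [sim_config()]
#' @return list with `sequences` (named character), `disorder`
#'   (data.frame: protein_id, start, end) and `truth` (data.frame: class,
#'   true shares, target low-complexity/disorder fractions, hydropathy
#'   band)
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  counts <- apportion(n, config$class_fractions)
  classes <- rep(SIM_CLASSES, counts)
  ids <- sprintf("SYN%04d", seq_len(n))
  lc_target <- numeric(n); idr_target <- numeric(n)
  lc_target[classes == "llps_like"] <- stats::runif(counts[1], 0.30, 0.60)
  lc_target[classes == "structured"] <- 0
  lc_target[classes == "background"] <- stats::runif(counts[3], 0.10, 0.25)
  idr_target[classes == "llps_like"] <- lc_target[classes == "llps_like"]
  idr_target[classes == "structured"] <- stats::runif(counts[2], 0.02, 0.08)
  idr_target[classes == "background"] <- stats::runif(counts[3], 0.10, 0.30)

  seqs <- character(n)
  disorder <- vector("list", n)
  lc_real <- numeric(n)
  for (i in seq_len(n)) {
    len <- sample(300:800, 1)
    s <- sim_sequence(len, lc_target[i])
    seqs[i] <- s$seq
    lc_real[i] <- s$lc_realized
    if (classes[i] == "llps_like" && !is.null(s$blocks)) {
      # disorder tracks the low-complexity blocks
      disorder[[i]] <- data.frame(protein_id = ids[i],
                                  start = s$blocks[, "start"],
                                  end = s$blocks[, "end"])
    } else {
      # one interval of the target coverage at a random position
      w <- max(1L, round(len * idr_target[i]))
      st <- sample(0:(len - w), 1)
      disorder[[i]] <- data.frame(protein_id = ids[i], start = st, end = st + w)
    }
  }
  names(seqs) <- ids
  shares <- config$elution_profiles[classes, , drop = FALSE]
  truth <- data.frame(
    protein_id = ids, class = classes,
    share_IB = shares[, "IB"], share_HD2 = shares[, "HD2"],
    share_HD5 = shares[, "HD5"], share_HD10 = shares[, "HD10"],
    target_lcd_fraction = lc_real,
    target_idr_fraction = idr_target,
    hydropathy_band = ifelse(classes == "llps_like", "low",
                             ifelse(classes == "structured", "mid", "mid_low")),
    row.names = NULL
  )
  list(sequences = seqs, disorder = do.call(rbind, disorder), truth = truth)
}

#' Simulate a gradient-elution quantification experiment
#'
#' Draws each protein's total abundance from the configured log-normal,
#' splits it over the treatment groups by the protein's true elution
#' shares, applies multiplicative log-normal replicate noise, masks
#' cells missing with a left-censored-like, rank-weighted mechanism
#' (low-abundance cells are masked preferentially), and samples peptide
#' evidence such that about 97% of proteins pass the high-confidence
#' filter. Deterministic given the config seed.
#'
#' @param config a [sim_config()]
#' @param truth ground-truth data.frame from [simulate_proteome()]
#' @return list with `table` (a [quant_table()]) and `evidence`
#'   (data.frame)
#' @export
simulate_elution <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"),
            nrow(truth) == config$n_proteins)
  set.seed(config$seed + 1L)
  n <- config$n_proteins
  total <- stats::rlnorm(n, config$abundance_lognormal[["meanlog"]],
                         config$abundance_lognormal[["sdlog"]])
  reps <- config$replicates
  sample_ids <- unlist(lapply(HD_GROUPS, function(g)
    paste0(g, "_r", seq_len(reps[[g]]))))
  groups <- rep(HD_GROUPS, reps[HD_GROUPS])
  share_cols <- paste0("share_", groups)
  mat <- matrix(NA_real_, n, length(sample_ids),
                dimnames = list(truth$protein_id, sample_ids))
  for (j in seq_along(sample_ids)) {
    mu <- total * truth[[share_cols[j]]]
    mat[, j] <- mu * stats::rlnorm(n, 0, config$replicate_sdlog)
  }
  if (config$missing_rate > 0) {
    # mask probability decreases linearly with abundance rank
    r <- rank(mat, ties.method = "first")
    prob <- config$missing_rate * 2 * (1 - (r - 0.5) / length(mat))
    mask <- stats::runif(length(mat)) < prob
    mat[mask] <- NA_real_
  }
  fail <- stats::runif(n) < 0.03
  evidence <- data.frame(
    protein_id = truth$protein_id,
    unique_peptides = ifelse(fail, 0L, 1L + stats::rpois(n, 2)),
    strict_peptides = ifelse(fail, sample(0:2, n, replace = TRUE),
                             2L + stats::rpois(n, 3))
  )
  sheet <- data.frame(sample_id = sample_ids, group = groups,
                      replicate = unlist(lapply(reps[HD_GROUPS], seq_len)))
  list(table = quant_table(mat, sheet), evidence = evidence)
}

#' Simulate a complete study
#'
#' Proteome plus elution experiment in one call.
#'
#' @param config a [sim_config()]
#' @return list with `sequences`, `disorder`, `truth`, `table`,
#'   `evidence`
#' @export
simulate_study <- function(config = sim_config()) {
  prot <- simulate_proteome(config)
  elu <- simulate_elution(config, prot$truth)
  c(prot, elu)
}

#' Write a simulated study to disk
#'
#' Emits the FASTA, disorder TSV, quantification TSV, sample sheet,
#' evidence TSV and ground-truth TSV for a simulated study.
#'
#' @param study list from [simulate_study()]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(study$sequences, file.path(dir, "proteome.fasta"))
  utils::write.table(study$disorder, file.path(dir, "disorder.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_quant_table(study$table, file.path(dir, "quant.tsv"),
                    file.path(dir, "samples.tsv"))
  write_table(study$evidence, file.path(dir, "evidence.tsv"))
  write_table(study$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
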