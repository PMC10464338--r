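# End-to-end orchestration: read inputs, preprocess, profile the
# elution, compute sequence features, run the comparison statistics, and
# write a bundle of tabular reports plus a run log. Stages never mutate
# each other's outputs; the master table is assembled by protein_id
# joins only.

#' Default pipeline options
#'
#' Every analysis choice that the method leaves open is an explicit key
#' here, so a replication attempt can toggle each one.
#'
#' @return named list of option defaults
#' @export
default_run_options <- function() {
  list(
    impute_scope = "column",       # minimum per sample column, or "global"
    min_detected_samples = 1,      # detection filter
    hd_pooling = "sum",            # pooling of the three hexanediol fractions
    rep_threshold = 0.5,           # representative share cutoff (strict >)
    common_low = 0.2,              # lower bound of the common band
    seg_window = 12,               # low-complexity detector window
    seg_locut = 2.2,               # trigger threshold (bits)
    seg_hicut = 2.5,               # extension threshold (bits)
    abundance_split = "quartile",  # high/low abundance contrast: quartile|median
    hd_enriched_cutoff = 0.5,      # hd_ratio above this = hexanediol-enriched
    seed = 1
  )
}

read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  opts <- utils::modifyList(default_run_options(),
                            config[intersect(names(config),
                                             names(default_run_options()))])
  paths <- config[setdiff(names(config), names(opts))]
  for (key in c("quant", "sample_sheet", "evidence")) {
    if (is.null(paths[[key]])) stop("config is missing required path: ", key)
  }
  for (key in intersect(names(paths), c("quant", "sample_sheet", "evidence",
                                        "fasta", "disorder", "scores", "sets"))) {
    if (!file.exists(paths[[key]]))
      stop("config path does not exist: ", key, " = ", paths[[key]])
  }
  if (is.null(paths$out_dir)) stop("config is missing out_dir")
  c(paths, list(options = opts))
}

log_line <- function(log, ...) c(log, paste0(...))

#' Run the full analysis pipeline
#'
#' Executes reading, preprocessing, elution profiling, sequence-feature
#' computation and statistics in order, and writes the report bundle to
#' `out_dir`:
#' \describe{
#'   \item{master_table.tsv}{per-protein elution profile, Z-scores and
#'     sequence features, joined on protein_id}
#'   \item{group_comparison.tsv}{annotation-class composition of
#'     hexanediol- vs buffer-enriched proteins with a chi-square test}
#'   \item{setwise_ratios.tsv}{per annotation set, abundance share of
#'     each treatment group}
#'   \item{class_features.tsv}{sequence-feature medians per elution
#'     class with Mann-Whitney contrasts between representative classes}
#'   \item{enrichment_<class>.tsv}{hypergeometric set enrichment of each
#'     representative class}
#'   \item{run_log.txt}{package version, seed, config echo, stage log}
#' }
#' Sequence-dependent outputs are skipped (and logged) when no FASTA is
#' configured; set-dependent outputs likewise without a GMT.
#'
#' @param config path to a YAML config file, or an equivalent list. Keys:
#'   `quant`, `sample_sheet`, `evidence` (required paths), `fasta`,
#'   `disorder`, `scores`, `sets` (optional paths), `out_dir`, plus any
#'   option in [default_run_options()].
#' @return invisibly, a list with the computed tables and the log
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  opts <- cfg$options
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  log <- log_line(log, "chsms ", as.character(utils::packageVersion("chsms")),
                  " | seed ", opts$seed)
  log <- log_line(log, "config: ", paste(names(opts), unlist(opts),
                                         sep = "=", collapse = " "))
  set.seed(opts$seed)

  stage <- "quant_io"
  result <- tryCatch({
    raw <- read_quant_table(cfg$quant, cfg$sample_sheet)
    evidence <- read_peptide_evidence(cfg$evidence)
    log <- log_line(log, "quant_io: ", nrow(raw$abundance), " proteins, ",
                    ncol(raw$abundance), " samples")

    stage <- "preprocess"
    filtered <- filter_detected(
      filter_high_confidence(raw, evidence), opts$min_detected_samples)
    log <- log_line(log, "preprocess: ", nrow(filtered$abundance),
                    " high-confidence proteins detected in >= ",
                    opts$min_detected_samples, " sample(s)")
    norm <- quantile_normalize(impute_min(filtered, opts$impute_scope))
    zsc <- sapply(HD_GROUPS, function(g) log2_zscore_by_group(norm, g))

    stage <- "elution_profile"
    profiles <- elution_profiles(filtered, opts$rep_threshold,
                                 opts$common_low, opts$hd_pooling)
    log <- log_line(log, "elution_profile: ",
                    paste(levels(profiles$rep_class),
                          table(profiles$rep_class), sep = "=", collapse = " "))

    stage <- "seqfeatures"
    features <- NULL
    if (!is.null(cfg$fasta)) {
      seqs <- read_fasta(cfg$fasta)
      disorder <- if (!is.null(cfg$disorder)) read_disorder(cfg$disorder, seqs)
      scores <- if (!is.null(cfg$scores))
        utils::read.delim(cfg$scores, check.names = FALSE)
      seqs <- seqs[intersect(profiles$protein_id, names(seqs))]
      features <- feature_vectors(seqs, disorder, scores,
                                  opts$seg_window, opts$seg_locut, opts$seg_hicut)
      log <- log_line(log, "seqfeatures: ", nrow(features), " proteins scored")
    } else {
      log <- log_line(log, "seqfeatures: skipped (no fasta configured)")
    }

    stage <- "stats"
    sets <- if (!is.null(cfg$sets)) read_gmt(cfg$sets)
    master <- merge(profiles,
                    data.frame(protein_id = rownames(zsc),
                               z_IB = zsc[, "IB"], z_HD2 = zsc[, "HD2"],
                               z_HD5 = zsc[, "HD5"], z_HD10 = zsc[, "HD10"]),
                    by = "protein_id", all.x = TRUE)
    if (!is.null(features))
      master <- merge(master, features, by = "protein_id", all.x = TRUE)
    write_table(master, file.path(cfg$out_dir, "master_table.tsv"))

    group_comparison <- NULL
    setwise <- NULL
    enrichment <- list()
    if (!is.null(sets)) {
      group_comparison <- compare_group_composition(
        profiles, sets, opts$hd_enriched_cutoff)
      write_table(group_comparison$table,
                  file.path(cfg$out_dir, "group_comparison.tsv"))
      setwise <- setwise_ratio_table(profiles, sets)
      write_table(setwise, file.path(cfg$out_dir, "setwise_ratios.tsv"))
      universe <- profiles$protein_id
      for (cls in paste0("representative_", HD_CONC)) {
        query <- profiles$protein_id[profiles$rep_class == cls]
        if (!length(query)) {
          log <- log_line(log, "enrichment: no proteins in ", cls, "; skipped")
          next
        }
        enr <- suppressMessages(
          hypergeometric_enrichment(query, sets, universe))
        enrichment[[cls]] <- enr
        write_table(enr, file.path(cfg$out_dir,
                                   paste0("enrichment_", cls, ".tsv")))
      }
      log <- log_line(log, "stats: chi2=",
                      format(group_comparison$chi2, digits = 6),
                      " df=", group_comparison$df,
                      " p=", format(group_comparison$p, digits = 6))
    } else {
      log <- log_line(log, "stats: set-wise outputs skipped (no sets configured)")
      # still emit placeholder-free bundle: write empty group comparison
      write_table(data.frame(), file.path(cfg$out_dir, "group_comparison.tsv"))
      write_table(data.frame(), file.path(cfg$out_dir, "setwise_ratios.tsv"))
    }

    class_features <- NULL
    if (!is.null(features)) {
      class_features <- class_feature_comparison(profiles, features)
      write_table(class_features, file.path(cfg$out_dir, "class_features.tsv"))
    }

    list(table = norm, profiles = profiles, features = features,
         zscores = zsc, master = master,
         group_comparison = group_comparison, setwise = setwise,
         enrichment = enrichment, class_features = class_features)
  }, error = function(e) {
    stop(sprintf("pipeline failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
  result$log <- log
  invisible(result)
}

#' Annotation-class composition of hexanediol- vs buffer-enriched proteins
#'
#' Splits profiled proteins into hexanediol-enriched (ratio above
#' `cutoff`) and buffer-enriched, counts members of each annotation set
#' on both sides, and tests composition independence with a chi-square
#' test over the 2 x k table.
#'
#' @param profiles data.frame from [elution_profiles()]
#' @param sets named list of protein-id sets
#' @param cutoff hexanediol-vs-buffer ratio above which a protein counts
#'   as hexanediol-enriched
#' @return list with `table` (long-format counts), `chi2`, `df`, `p`
#' @export
compare_group_composition <- function(profiles, sets, cutoff = 0.5) {
  ok <- !is.na(profiles$hd_ratio)
  hd <- profiles$protein_id[ok & profiles$hd_ratio > cutoff]
  ib <- profiles$protein_id[ok & profiles$hd_ratio <= cutoff]
  counts <- sapply(sets, function(m)
    c(HD = sum(hd %in% m), IB = sum(ib %in% m)))
  tested <- counts[, colSums(counts) > 0, drop = FALSE]
  if (ncol(tested) < 2)
    stop("need at least two annotation sets with members among profiled proteins")
  chi <- chi_square_independence(tested)
  long <- data.frame(
    set_name = rep(colnames(counts), each = 2),
    side = rep(c("HD", "IB"), ncol(counts)),
    count = as.vector(counts))
  long$chi2 <- chi$chi2; long$df <- chi$df; long$p <- chi$p
  c(list(table = long), chi)
}

#' Set-wise abundance shares per treatment group
#'
#' For every annotation set with profiled members: the
#' hexanediol-vs-buffer decomposition (shares of IB and of each
#' hexanediol fraction over the full denominator) and the
#' hexanediol-only concentration shares.
#'
#' @param profiles data.frame from [elution_profiles()]
#' @param sets named list of protein-id sets
#' @return data.frame, one row per set
#' @export
setwise_ratio_table <- function(profiles, sets) {
  rows <- lapply(names(sets), function(nm) {
    members <- sets[[nm]]
    if (!any(profiles$protein_id %in% members)) return(NULL)
    with_ib <- vapply(HD_GROUPS, function(g)
      setwise_abundance_ratio(profiles, members, g, include_ib = TRUE,
                              set_name = nm), 0)
    hd_only <- vapply(HD_CONC, function(g)
      setwise_abundance_ratio(profiles, members, g, include_ib = FALSE,
                              set_name = nm), 0)
    data.frame(set_name = nm,
               n_profiled = sum(profiles$protein_id %in% members),
               hd_ratio = sum(with_ib[HD_CONC]),
               ratio_IB = with_ib[["IB"]], ratio_HD2 = with_ib[["HD2"]],
               ratio_HD5 = with_ib[["HD5"]], ratio_HD10 = with_ib[["HD10"]],
               share_HD2 = hd_only[["HD2"]], share_HD5 = hd_only[["HD5"]],
               share_HD10 = hd_only[["HD10"]])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no annotation set overlaps the profiled proteins")
  out
}

#' Sequence-feature comparison across elution classes
#'
#' Feature medians per elution class, with two-sided Mann-Whitney tests
#' between every pair of representative classes for each feature.
#'
#' @param profiles data.frame from [elution_profiles()]
#' @param features data.frame from [feature_vectors()]
#' @return data.frame in long format: one row per (feature, class) with
#'   the median, and one row per (feature, class pair) with the p-value
#' @export
class_feature_comparison <- function(profiles, features) {
  df <- merge(profiles[, c("protein_id", "rep_class")], features,
              by = "protein_id")
  feat_cols <- setdiff(names(features), "protein_id")
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, TRUE)]
  med_rows <- do.call(rbind, lapply(feat_cols, function(f) {
    ag <- stats::aggregate(df[[f]], list(class = df$rep_class), stats::median,
                           na.rm = TRUE, drop = FALSE)
    data.frame(feature = f, class_a = as.character(ag$class), class_b = NA,
               statistic = "median", value = ag$x)
  }))
  rep_levels <- paste0("representative_", HD_CONC)
  pairs <- utils::combn(rep_levels, 2)
  test_rows <- do.call(rbind, lapply(feat_cols, function(f) {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- df[[f]][df$rep_class == pairs[1, j]]
      b <- df[[f]][df$rep_class == pairs[2, j]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      p <- if (length(a) && length(b)) mann_whitney_u(a, b)$p else NA_real_
      data.frame(feature = f, class_a = pairs[1, j], class_b = pairs[2, j],
                 statistic = "mann_whitney_p", value = p)
    }))
  }))
  rbind(med_rows, test_rows)
}

#' High- vs low-abundance feature contrast within one treatment group
#'
#' Splits proteins by their per-treatment Z-scored abundance (top vs
#' bottom quartile by default, or above/below the median) and tests each
#' sequence feature between the two strata with a Mann-Whitney test.
#'
#' @param zscores named numeric vector for one treatment group (from
#'   [log2_zscore_by_group()])
#' @param features data.frame from [feature_vectors()]
#' @param split `"quartile"` (Q4 vs Q1) or `"median"`
#' @return data.frame: one row per feature with group medians and p
#' @export
abundance_feature_contrast <- function(zscores, features,
                                       split = c("quartile", "median")) {
  split <- match.arg(split)
  common <- intersect(names(zscores), features$protein_id)
  z <- zscores[common]
  if (split == "quartile") {
    q <- quartile_split(z)
    hi <- names(q)[q == "Q4"]; lo <- names(q)[q == "Q1"]
  } else {
    hi <- names(z)[z > stats::median(z)]; lo <- names(z)[z <= stats::median(z)]
  }
  feat_cols <- setdiff(names(features), "protein_id")
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, TRUE)]
  fx <- features[match(common, features$protein_id), , drop = FALSE]
  rownames(fx) <- common
  do.call(rbind, lapply(feat_cols, function(f) {
    a <- fx[hi, f]; b <- fx[lo, f]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    data.frame(feature = f,
               median_high = stats::median(a), median_low = stats::median(b),
               p = mann_whitney_u(a, b)$p)
  }))
}
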