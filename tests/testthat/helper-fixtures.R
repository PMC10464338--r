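# In-code fixtures shared across test files.

# tiny quant table: 2 replicates per group, optionally with missing cells
tiny_table <- function(values, n_prot = nrow(values)) {
  groups <- rep(c("IB", "HD2", "HD5", "HD10"), each = 2)
  ids <- paste0(groups, "_r", rep(1:2, 4))
  stopifnot(ncol(values) == 8)
  dimnames(values) <- list(paste0("P", seq_len(n_prot)), ids)
  quant_table(values, data.frame(sample_id = ids, group = groups,
                                 replicate = rep(1:2, 4)))
}

# deterministic abundance matrix with a known missing pattern
tiny_matrix <- function(n_prot = 6, seed = 11, missing = TRUE) {
  set.seed(seed)
  m <- matrix(rlnorm(n_prot * 8, log(1e6), 1), n_prot, 8)
  if (missing) m[cbind(c(1, 3, 5), c(2, 7, 4))] <- NA
  m
}

full_evidence <- function(ids) {
  data.frame(protein_id = ids, unique_peptides = 2L, strict_peptides = 4L)
}

# random test sequences of varied compositional complexity: concatenated
# blocks drawn from alphabets of random size, so the low-complexity
# detector sees triggers, extensions and clean regions
varied_sequence <- function(len) {
  out <- character(0)
  while (length(out) < len) {
    k <- sample(c(1, 2, 3, 6, 20), 1)
    alpha <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], k)
    out <- c(out, sample(alpha, sample(8:20, 1), replace = TRUE))
  }
  paste(out[seq_len(len)], collapse = "")
}
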