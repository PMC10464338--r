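test_that("window complexity is Shannon entropy over counted residues", {
  expect_equal(window_complexity("AAAAAAAAAAAA"), 0)
  expect_equal(window_complexity("AAAAAACCCCCC"), 1)
  expect_equal(window_complexity("ACDEFGHIKLMN"), log2(12))
  # X residues are excluded with the counted length reduced
  expect_equal(window_complexity("AAXXAA"), 0)
  expect_equal(window_complexity("ACXX"), 1)
  expect_message(h <- window_complexity("XXXX"), "undefined")
  expect_true(is.na(h))
  expect_equal(window_complexity("aaaaaacccccc"), 1)  # case-insensitive
})

test_that("low-complexity detection handles homopolymers and clean sequences", {
  seg <- seg_low_complexity(strrep("A", 30))
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end), c(0L, 30L))
  expect_equal(seg$complexity, 0)

  # every window above locut: nothing detected
  set.seed(3)
  clean <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60,
                        replace = TRUE), collapse = "")
  stopifnot(min(sapply(1:49, function(i)
    window_complexity(substr(clean, i, i + 11)))) > 2.2)
  expect_equal(nrow(seg_low_complexity(clean)), 0)

  expect_error(seg_low_complexity(strrep("A", 30), W = 1), "W >= 2")
  expect_error(seg_low_complexity(strrep("A", 30), locut = 3, hicut = 2.5),
               "locut")
  # shorter than one window: no segments
  expect_equal(nrow(seg_low_complexity("ACDEF")), 0)
})

test_that("low-complexity detection matches the brute-force oracle", {
  set.seed(2024)
  for (i in 1:200) {
    s <- varied_sequence(60)
    got <- seg_low_complexity(s)
    want <- oracle_seg(s)
    expect_equal(nrow(got), nrow(want), info = s)
    if (nrow(want)) {
      expect_equal(got$start, unname(want[, "start"]), info = s)
      expect_equal(got$end, unname(want[, "end"]), info = s)
    }
    h <- sapply(1:49, function(j)
      suppressMessages(window_complexity(substr(s, j, j + 11))))
    # reported complexity is the entropy of the merged subsequence, and
    # each segment's boundary windows respect the extension threshold
    for (k in seq_len(nrow(got))) {
      expect_equal(got$complexity[k], suppressMessages(
        window_complexity(substr(s, got$start[k] + 1, got$end[k]))))
      expect_lte(h[got$start[k] + 1], 2.5)
      expect_lte(h[got$end[k] - 11], 2.5)
    }
    # every trigger window lies inside a segment
    for (j in which(!is.na(h) & h <= 2.2)) {
      expect_true(any(got$start <= j - 1 & got$end >= j + 11), info = s)
    }
  }
})

test_that("length-fraction features are union-based and bounded", {
  seqs <- strrep("A", 20)
  expect_equal(lcd_fraction(seqs, data.frame(start = integer(),
                                             end = integer())), 0)
  expect_equal(lcd_fraction(seqs, data.frame(start = 0, end = 20)), 1)
  expect_equal(lcd_fraction(seqs, data.frame(start = c(0, 5),
                                             end = c(10, 15))), 0.75)
  expect_error(lcd_fraction(seqs, data.frame(start = 0, end = 25)), "bounds")

  s10 <- strrep("A", 10)
  expect_equal(idr_fraction(s10, data.frame(start = integer(),
                                            end = integer())), 0)
  expect_equal(idr_fraction(s10, data.frame(start = 0, end = 10)), 1)
  expect_equal(idr_fraction(s10, data.frame(start = 0, end = 5)), 0.5)
  expect_error(idr_fraction(s10, data.frame(start = 3, end = 12)), "bounds")
})

test_that("charged-residue fraction counts D/E/K/R only", {
  expect_equal(fcr("EKEKEK"), 1)
  expect_equal(fcr("GGGGGG"), 0)
  expect_equal(fcr("DEKRGGGGGG"), 0.4)
  expect_equal(fcr("HHHH"), 0)      # histidine is not counted
  expect_equal(fcr("dekrgggggg"), 0.4)
})

test_that("Uversky hydropathy rescales the Kyte-Doolittle index to [0,1]", {
  expect_equal(uversky_hydropathy("IIII"), 1)
  expect_equal(uversky_hydropathy("RRRR"), 0)
  expect_equal(uversky_hydropathy("IR"), 0.5)
  expect_equal(uversky_hydropathy("IXR"), 0.5)  # X skipped
  expect_error(uversky_hydropathy("AB"), "unknown residue")
})

test_that("composition features are invariant under self-concatenation", {
  set.seed(8)
  for (i in 1:10) {
    s <- varied_sequence(40)
    expect_equal(fcr(paste0(s, s)), fcr(s))
    expect_equal(uversky_hydropathy(paste0(s, s)), uversky_hydropathy(s))
  }
})

test_that("feature vectors join disorder and external scores by protein id", {
  seqs <- c(P1 = strrep("A", 30), P2 = paste0(strrep("EK", 15)))
  disorder <- data.frame(protein_id = "P2", start = 0L, end = 15L)
  scores <- data.frame(protein_id = c("P2", "P1"), pscore = c(2.5, -1))
  fv <- feature_vectors(seqs, disorder, scores)
  expect_equal(fv$protein_id, c("P1", "P2"))
  expect_equal(fv$lcd_fraction[1], 1)          # homopolymer
  expect_equal(fv$idr_fraction, c(0, 0.5))
  expect_equal(fv$fcr[2], 1)
  expect_equal(fv$pscore, c(-1, 2.5))
  expect_true(all(fv$lcd_fraction >= 0 & fv$lcd_fraction <= 1))
})
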