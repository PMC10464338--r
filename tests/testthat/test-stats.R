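test_that("chi-square independence matches closed form and scale property", {
  res <- chi_square_independence(rbind(c(10, 20), c(20, 10)))
  # all expected counts are 15: chi2 = 4 * 25/15
  expect_equal(res$chi2, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p, pchisq(20 / 3, 1, lower.tail = FALSE))

  same <- chi_square_independence(rbind(c(3, 7, 5), c(3, 7, 5)))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_equal(same$df, 2)

  a <- rbind(c(4, 9, 2), c(7, 3, 8))
  expect_equal(chi_square_independence(2 * a)$chi2,
               2 * chi_square_independence(a)$chi2)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))),
               "zero marginal")
})

test_that("t test handles identity, antisymmetry and degenerate variance", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  same <- t_test_independent(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  y <- c(0.5, 1.5, 4.4, 2.0)
  ab <- t_test_independent(x, y)
  ba <- t_test_independent(y, x)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)

  expect_equal(t_test_independent(c(2, 2, 2), c(2, 2))$p, 1)
  expect_error(t_test_independent(c(2, 2), c(3, 3)), "constant")
  expect_error(t_test_independent(c(2, 2), c(1, 3)), "zero variance")

  # pooled-variance variant reduces df to n1 + n2 - 2
  pooled <- t_test_independent(x, y, equal_var = TRUE)
  expect_equal(pooled$df, 6)
})

test_that("t test p agrees with a permutation oracle on seeded samples", {
  set.seed(55)
  x <- rnorm(8, 0.8, 1)
  y <- rnorm(9, 0, 1)
  p_analytic <- t_test_independent(x, y)$p
  p_perm <- oracle_t_perm(x, y)
  se <- sqrt(p_perm * (1 - p_perm) / 1e4)
  expect_lt(abs(p_analytic - p_perm), 3 * se + 1e-4)
})

test_that("Mann-Whitney U has exact small-sample p and conservation", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)   # 2/20 arrangements as extreme
  expect_true(res$exact)

  x <- c(1, 3, 5, 7); y <- c(2, 4, 6, 8)
  expect_equal(mann_whitney_u(x, y)$U + mann_whitney_u(y, x)$U,
               length(x) * length(y))

  # identical samples: U at the center of its range, |x||y|/2
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$U, 4.5)
})

test_that("exact Mann-Whitney p matches full enumeration on seeded samples", {
  set.seed(91)
  for (i in 1:15) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    v <- sample(1000, m + n)   # distinct -> no ties
    x <- v[1:m]; y <- v[-(1:m)]
    res <- mann_whitney_u(x, y)
    expect_true(res$exact)
    expect_equal(res$p, oracle_mw_exact(x, y), tolerance = 1e-12)
  }
  # above the cutoff or with ties the approximation is used
  expect_false(mann_whitney_u(rnorm(8), rnorm(8))$exact)
  expect_false(mann_whitney_u(c(1, 2, 2), c(3, 4))$exact)
})

test_that("hypergeometric enrichment matches combinatorial enumeration", {
  universe <- paste0("P", 1:20)
  sets <- list(hit = paste0("P", 1:5))
  res <- hypergeometric_enrichment(paste0("P", 1:5), sets, universe)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$overlap, 5)

  # all overlaps on a 10-universe / 4-set / 3-query toy
  uni10 <- paste0("U", 1:10)
  for (k in 0:3) {
    q <- c(head(paste0("U", 1:4), k), head(paste0("U", 5:10), 3 - k))
    r <- hypergeometric_enrichment(q, list(s = paste0("U", 1:4)), uni10)
    expect_equal(r$p_value, oracle_hyper_upper(k, 4, 10, 3), tolerance = 1e-12)
  }

  # sets outside the universe are skipped with a message
  expect_message(
    r2 <- hypergeometric_enrichment(c("U1"), list(s = paste0("U", 1:4),
                                                  gone = "ZZZ"), uni10),
    "skipped")
  expect_equal(nrow(r2), 1)
  expect_error(hypergeometric_enrichment(character(), list(s = "U1"), uni10),
               "empty query")
  expect_error(hypergeometric_enrichment("ZZ", list(s = "U1"), uni10),
               "outside the universe")
})

test_that("BH adjustment matches step-up minimization and preserves ranking", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(12)
  p <- runif(50)^2
  q <- bh_fdr(p)
  expect_equal(q, oracle_bh(p))
  expect_true(all(q >= p - 1e-12))
  expect_equal(order(q[order(p)]), seq_along(p))  # ranking preserved
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("quartile split is rank-based, deterministic and tie-stable", {
  v <- setNames(1:8, paste0("P", 1:8))
  q <- quartile_split(v)
  expect_equal(unname(table(q)), rep(2L, 4), ignore_attr = TRUE)
  expect_equal(as.character(q[c("P1", "P8")]), c("Q1", "Q4"))

  # all-equal values: lexicographic tie rule, still two per bin
  tied <- setNames(rep(5, 8), paste0("P", 8:1))
  qt <- quartile_split(tied)
  expect_equal(unname(table(qt)), rep(2L, 4), ignore_attr = TRUE)
  expect_equal(as.character(qt[c("P1", "P2")]), c("Q1", "Q1"))

  # permuting insertion order leaves the assignment unchanged
  perm <- sample(v)
  expect_equal(quartile_split(perm)[names(v)], q)
  expect_error(quartile_split(setNames(1:7, paste0("P", 1:7))), "at least 8")
})
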