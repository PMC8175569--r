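test_that("pearson reports r, R2 and the t-distribution p", {
  x <- 1:10
  perfect <- pearson(x, 2 * x + 1)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$R2, 1)
  expect_equal(pearson(x, -x)$r, -1)

  # fixed series against an independent evaluation of the closed formulas
  a <- c(2.1, 3.9, 4.2, 6.8, 7.0, 9.3)
  b <- c(1.0, 2.2, 2.0, 4.1, 3.9, 6.0)
  got <- pearson(a, b)
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  tstat <- r * sqrt((6 - 2) / (1 - r^2))
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$p, 2 * stats::pt(-abs(tstat), 4), tolerance = 1e-12)

  flat <- pearson(rep(1, 5), 1:5)
  expect_false(flat$defined)
  expect_true(is.na(flat$r))
  expect_error(pearson(1:3, 1:4), "equal length")
})

test_that("pearson p matches the closed form on an (r, n) grid to 1e-10", {
  for (n in c(5L, 10L, 30L)) {
    for (target_r in c(-0.9, -0.3, 0.2, 0.7, 0.95)) {
      set.seed(n + round(100 * target_r))
      x <- rnorm(n)
      y <- target_r * x + sqrt(1 - target_r^2) * rnorm(n)
      got <- pearson(x, y)
      tstat <- got$r * sqrt((n - 2) / (1 - got$r^2))
      expect_equal(got$p, 2 * stats::pt(-abs(tstat), n - 2),
                   tolerance = 1e-10)
    }
  }
})

test_that("equal-variance t test follows the pooled formula", {
  same <- ttest_equal_var(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  a <- c(1.2, 2.4, 3.1, 4.0); b <- c(2.2, 3.1, 4.4)
  got <- ttest_equal_var(a, b)
  sp2 <- (3 * var(a) + 2 * var(b)) / 5
  tman <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  expect_equal(got$t, tman, tolerance = 1e-12)
  expect_equal(got$df, 5)

  # p shrinks monotonically with the shift between groups
  ps <- vapply(c(1, 3, 9), function(s) ttest_equal_var(a, a + s)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(ttest_equal_var(1, c(1, 2)), "n >= 2")
})

test_that("fold changes reproduce the reported molecule-count contrasts", {
  # cytoplasmic TUG1 under splice-blocking: 29 -> 12 molecules
  fc <- fold_change(29, 12)
  expect_equal(fc$fold_rounded, 2.4)
  expect_equal(fc$direction, "decrease")
  # nuclear TUG1: 21 -> 38 molecules
  fc <- fold_change(21, 38)
  expect_equal(fc$fold_rounded, 1.8)
  expect_equal(fc$direction, "increase")
  # second cell line, nucleus: 29 -> 48
  expect_equal(fold_change(29, 48)$fold_rounded, 1.7)

  eq <- fold_change(7, 7)
  expect_equal(eq$fold, 1.0)
  expect_equal(eq$direction, "none")
  # symmetric magnitude, opposite direction
  expect_equal(fold_change(12, 29)$fold, fold_change(29, 12)$fold)
  expect_false(fold_change(0, 5)$defined)
})

test_that("nuclear enrichment is the nuclear percentage of molecules", {
  expect_equal(nuclear_enrichment(86, 14), 86.0)
  expect_equal(nuclear_enrichment(0, 7), 0.0)
  set.seed(8)
  nuc <- rpois(20, 30); cyt <- rpois(20, 10) + 1
  expect_equal(mean(nuclear_enrichment(nuc, cyt)),
               mean(100 * nuc / (nuc + cyt)))
  expect_error(nuclear_enrichment(0, 0), "> 0")
})

test_that("2^-ddCt series is 1 at the calibrator and halves per cycle", {
  r <- relative_expression_series(time = c(0, 1, 2),
                                  ct_target = c(20, 22, 24),
                                  ct_ref = c(15, 16, 17))
  expect_equal(r$rel_expr[1], 1.0)
  expect_equal(r$rel_expr[2], 0.5)     # ddCt of exactly one cycle
  expect_equal(r$rel_expr[3], 0.25)

  # four-timepoint fixture against hand-computed values
  tt <- c(0, 0.67, 2.5, 4.5)
  ctt <- c(24.1, 24.9, 26.0, 27.2); ctr <- c(16.0, 16.2, 16.1, 16.4)
  got <- relative_expression_series(tt, ctt, ctr)
  dct <- ctt - ctr
  expect_equal(got$rel_expr, 2^(-(dct - dct[1])))

  # invariance under a constant Ct shift applied to both genes
  shifted <- relative_expression_series(tt, ctt + 3, ctr + 3)
  expect_equal(shifted$rel_expr, got$rel_expr)

  # technical replicates average before differencing
  reps <- relative_expression_series(c(0, 1),
                                     ct_target = rbind(c(20, 21), c(22, 23)),
                                     ct_ref = c(15, 16.5))
  expect_equal(reps$rel_expr[2], 2^(-((22.5 - 16.5) - (20.5 - 15))))
  expect_error(relative_expression_series(c(0, 1), c(1, 2), c(1, 2),
                                          calibrator = 5), "calibrator")
})

test_that("compartment fractions are TPM shares summing to one", {
  even <- compartment_fraction(matrix(c(10, 10, 10), 1))
  expect_equal(as.vector(even), rep(1 / 3, 3))
  expect_equal(as.vector(compartment_fraction(matrix(c(100, 0, 0), 1))),
               c(1, 0, 0))

  # counts + lengths route: fractions match brute-force TPM computation
  counts <- cbind(chromatin = c(100, 40, 5), nucleoplasm = c(50, 60, 5),
                  cytoplasm = c(10, 200, 5))
  len <- c(1000, 2500, 600)
  fr <- compartment_fraction(counts, lengths = len)
  man <- apply(counts, 2, function(cl) (cl / len) / sum(cl / len) * 1e6)
  man <- man / rowSums(man)
  expect_equal(fr, man, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(rowSums(fr), rep(1, 3), ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(sum(tpm(counts[, 1], len)), 1e6)
})
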