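cts1 <- function(EI, IE, EE) data.frame(intron_id = "i1", EI = EI, IE = IE,
                                        EE = EE)

test_that("balance test reproduces exact two-sided binomial p-values", {
  expect_equal(balance_test(5, 5), 1.0)
  expect_equal(balance_test(10, 0), 2 * 0.5^10)        # 0.001953125
  expect_equal(balance_test(7, 3), 0.34375)            # 2 * sum_{k>=7} C(10,k)/2^10
  expect_equal(balance_test(0, 0), 1.0)
  expect_equal(balance_test(3, 7), balance_test(7, 3))
  expect_error(balance_test(-1, 2), "non-negative")
})

test_that("two-junction PIR follows the mean-retention-read formula", {
  e <- estimate_pir(cts1(30, 30, 70))
  expect_equal(e$pir, 30.0)
  expect_equal(e$status, "ok")
  expect_equal(e$n_total, 130)

  expect_equal(estimate_pir(cts1(0, 0, 50))$pir, 0.0)
  expect_equal(estimate_pir(cts1(50, 50, 0))$pir, 100.0)
})

test_that("coverage and balance filters leave PIR undefined, never 0 or 100", {
  low <- estimate_pir(cts1(3, 4, 5))          # 12 < 15 total reads
  expect_equal(low$status, "low_coverage")
  expect_true(is.na(low$pir))

  imb <- estimate_pir(cts1(20, 2, 30))
  expect_equal(imb$status, "imbalanced")
  expect_true(is.na(imb$pir))
  expect_equal(imb$balance_p, 1.211166e-4, tolerance = 1e-6)

  # the same counts pass at a stricter alpha
  ok <- estimate_pir(cts1(20, 2, 30), alpha = 1e-5)
  expect_equal(ok$status, "ok")
})

test_that("single-junction recalculation uses one boundary's evidence", {
  dn <- recalc_single_junction(cts1(99, 30, 70), side = "downstream")
  expect_equal(dn$pir, 30.0)
  expect_equal(dn$status, "single_junction_downstream")
  expect_equal(dn$n_total, 100)   # EI excluded from the evidence total

  up <- recalc_single_junction(cts1(10, 99, 90), side = "upstream")
  expect_equal(up$pir, 10.0)
  expect_equal(up$status, "single_junction_upstream")

  # the coverage filter applies to the reduced evidence
  empty <- recalc_single_junction(cts1(99, 0, 0), side = "downstream")
  expect_equal(empty$status, "low_coverage")
  expect_true(is.na(empty$pir))
})

test_that("PIR is symmetric in EI/IE and strictly decreasing in EE", {
  expect_equal(estimate_pir(cts1(17, 31, 40))$pir,
               estimate_pir(cts1(31, 17, 40))$pir)
  pirs <- vapply(c(10, 20, 40, 80, 160),
                 function(ee) estimate_pir(cts1(25, 25, ee))$pir, numeric(1))
  expect_true(all(diff(pirs) < 0))
})

test_that("per-gene extremes and percentile ranks summarize defined PIRs", {
  est <- data.frame(
    gene_id = c("TERT", "TERT", "TERT", "TUG1"),
    biotype = c("coding", "coding", "coding", "lncRNA"),
    pir = c(30.2, 31.4, NA, 55))
  s <- gene_pir_extremes(est)
  tert <- s[s$gene_id == "TERT", ]
  expect_equal(tert$max_pir, 31.4)
  expect_equal(tert$min_pir, 30.2)
  expect_equal(tert$n_evaluable_introns, 2L)
  tug <- s[s$gene_id == "TUG1", ]
  expect_equal(tug$max_pir, tug$min_pir)   # single defined intron

  # genes with no defined PIR are dropped
  s2 <- gene_pir_extremes(data.frame(gene_id = c("a", "b"), biotype = "coding",
                                     pir = c(NA, 10)))
  expect_equal(s2$gene_id, "b")

  ec <- pir_ecdf_table(s)
  expect_equal(max(ec$ecdf_max[ec$biotype == "coding"]), 1.0)

  expect_equal(percentile_rank(31.4, c(1, 5, 10, 20, 31.4)), 100)
  expect_equal(percentile_rank(0.5, c(1, 5, 10, 20, 31.4)), 0)
  expect_equal(percentile_rank(10, c(1, 5, 10, 20, 31.4)), 60)
})

test_that("pir_fit carries counts to estimates with model methods", {
  m <- tiny_model()
  aln <- simulate_junction_reads(m, c(0.2, 0.6), depth = 20000, seed = 3)
  fit <- pir_fit(aln, m)
  expect_s3_class(fit, "pir_fit")
  co <- coef(fit)
  expect_named(co, c("g.I1", "g.I2"))
  expect_equal(unname(co), fit$estimates$pir)
  expect_output(print(fit), "PIR fit")
  s <- summary(fit)
  expect_equal(s$max_pir, max(fit$estimates$pir, na.rm = TRUE))

  # simulate() regenerates counts whose re-estimate is near the fit
  sim <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sim, 2)
  refit <- pir_fit(sim[[1]])
  expect_equal(refit$estimates$pir, fit$estimates$pir, tolerance = 0.15)

  # single-junction routing by intron id
  fit2 <- pir_fit(aln, m, single_junction = c(g.I1 = "downstream"))
  expect_equal(fit2$estimates$status[fit2$estimates$intron_id == "g.I1"],
               "single_junction_downstream")
})

test_that("simulated retention fractions are recovered within sampling error", {
  m <- tiny_model()
  for (rho in c(0.1, 0.5)) {
    hits <- 0L; n <- 0L
    for (s in 1:10) {
      fit <- pir_fit(simulate_junction_reads(m, rho, 20000, seed = 100 + s), m)
      p <- fit$estimates$pir[!is.na(fit$estimates$pir)]
      hits <- hits + sum(abs(p - 100 * rho) <= 2); n <- n + length(p)
    }
    expect_gte(hits / n, 0.9)
  }
})
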