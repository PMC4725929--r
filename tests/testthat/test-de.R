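test_that("FPKM normalises by kilobase of transcript and million mapped reads", {
  expect_equal(compute_fpkm(1000, 1000, 1e6), 1000)
  expect_equal(compute_fpkm(0, 2000, 5e7), 0)
  expect_equal(compute_fpkm(250, 500, 1e7), 50)
  expect_error(compute_fpkm(10, 0, 1e6), "length")
  expect_error(compute_fpkm(10, 1000, 0), "total")
  expect_error(compute_fpkm(-1, 1000, 1e6), "non-negative")
})

test_that("log2 fold change applies the 0.01 zero substitution and is antisymmetric", {
  expect_equal(log2_fold_change(1, 4), 2)
  expect_equal(log2_fold_change(0, 1), log2(1 / 0.01))
  expect_equal(log2_fold_change(0, 0), 0)
  expect_error(log2_fold_change(-1, 2), ">= 0")
  set.seed(11)
  a <- c(0, rlnorm(50)); b <- c(rlnorm(50), 0)
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
})

test_that("conditional pmf matches closed-form and exact-rational values", {
  expect_equal(ac_pmf(0, 0, 1e6, 1e6), 0.5)
  expect_equal(ac_pmf(1, 0, 1e6, 1e6), 0.25)
  # 969/131072, computed with exact rational arithmetic
  expect_equal(ac_pmf(15, 5, 1e6, 1e6), 0.00739288330078125, tolerance = 1e-12)
  expect_error(ac_pmf(-1, 0, 1e6, 1e6), "non-negative")
})

test_that("conditional pmf is a probability distribution", {
  for (x in c(0L, 1L, 5L, 20L)) {
    for (ratio in c(0.5, 1, 2)) {
      total <- sum(ac_pmf(0:2000, x, 1e6, ratio * 1e6))
      expect_equal(total, 1, tolerance = 1e-9,
                   label = sprintf("sum pmf (x=%d, r=%.1f)", x, ratio))
    }
  }
})

test_that("cumulative conditional probability matches oracles and is monotone", {
  expect_equal(ac_cumulative(0, 0, 1e6, 1e6), 0.5)
  expect_equal(ac_cumulative(500, 5, 1e6, 1e6), 1, tolerance = 1e-9)
  # exact-rational frozen value, N1 = 2 N2
  expect_equal(ac_cumulative(10, 5, 2e6, 1e6), 0.995960458869794,
               tolerance = 1e-12)
  for (x in c(0L, 3L, 17L)) {
    cdf <- ac_cumulative(0:40, rep(x, 41L), 1.5e6, 0.7e6)
    expect_true(all(diff(cdf) >= 0))
    expect_equal(cdf, oracle_ac_cdf(0:40, x, 1.5e6, 0.7e6), tolerance = 1e-10)
  }
})

test_that("two-sided p-value is exact, symmetric and matches frozen oracle values", {
  expect_equal(ac_two_sided_p(0, 0, 7e5, 7e5), 1)
  expect_equal(ac_two_sided_p(10, 10, 1e6, 1e6), 1)
  # exact-rational frozen value for (x=5, y=20, N1=N2)
  expect_equal(ac_two_sided_p(5, 20, 1e6, 1e6), 0.002493917942047119,
               tolerance = 1e-12)
  set.seed(21)
  for (i in 1:50) {
    x <- rpois(1, 30); y <- rpois(1, 30)
    N1 <- runif(1, 5e5, 5e6); N2 <- runif(1, 5e5, 5e6)
    expect_equal(ac_two_sided_p(x, y, N1, N2),
                 ac_two_sided_p(y, x, N2, N1), tolerance = 1e-12)
  }
})

test_that("two-sided p-value agrees with the negative-binomial oracle at large counts", {
  # counts up to 1e6 must run through log-gamma, not factorials
  cases <- rbind(c(1e6, 999000), c(5e5, 5e5), c(1200, 900), c(0, 50))
  for (i in seq_len(nrow(cases))) {
    x <- cases[i, 1]; y <- cases[i, 2]
    expect_equal(ac_two_sided_p(x, y, 5e7, 5e7),
                 max(oracle_ac_two_sided(x, y, 5e7, 5e7), .Machine$double.xmin),
                 tolerance = 1e-8)
  }
})

test_that("BH q-values reproduce the step-up construction", {
  expect_equal(bh_qvalues(0.04), 0.04)
  # hand step-up, m = 3: min over the tail of {3*0.01/1, 3*0.02/2, 3*0.03/3}
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(5)
  p <- runif(200)^2
  expect_equal(bh_qvalues(p), oracle_bh(p))
  perm <- sample(length(p))
  expect_equal(bh_qvalues(p[perm]), bh_qvalues(p)[perm])
  # monotone in p
  o <- order(p)
  expect_true(all(diff(bh_qvalues(p)[o]) >= 0))
  expect_error(bh_qvalues(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_qvalues(numeric(0)), "empty")
})

test_that("DE calling combines the FDR and fold-change thresholds", {
  rec <- data.frame(q = c(0.0005, 0.0005, 0.002), log2fc = c(1.5, 0.5, 3))
  expect_equal(call_de(rec)$is_de, c(TRUE, FALSE, FALSE))
  expect_equal(call_de(rec, fdr = 0.01)$is_de, c(TRUE, FALSE, TRUE))
})

test_that("de_test builds a complete per-transcript record", {
  ct <- tiny_count_table()
  de <- de_test(ct, "A", "B")
  expect_s3_class(de, "de_result")
  expect_equal(de$fpkm_a, compute_fpkm(ct$counts$A, ct$counts$length, 1e6))
  expect_equal(de$fpkm_b, compute_fpkm(ct$counts$B, ct$counts$length, 2e6))
  expect_true(all(de$p > 0 & de$p <= 1))
  expect_equal(de$q, bh_qvalues(de$p))
  expect_error(de_test(ct, "A", "nope"), "unknown sample")

  # zero-count pairs are retained, not filtered
  ct0 <- count_table(data.frame(transcript_id = c("z", "t"),
                                length = c(500L, 500L),
                                A = c(0L, 10L), B = c(0L, 30L)),
                     c(A = 1e6, B = 1e6))
  de0 <- de_test(ct0, "A", "B")
  expect_equal(de0$p[1], 1)
  expect_equal(de0$log2fc[1], 0)
})

test_that("DE result tables round-trip through their writer and reader", {
  de <- de_test(tiny_count_table(), "A", "C")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_de_result(de, path)
  back <- read_de_result(path)
  expect_equal(attr(back, "sample_a"), "A")
  expect_equal(attr(back, "sample_b"), "C")
  expect_equal(back$p, de$p, tolerance = 1e-12)
  expect_equal(back$is_de, de$is_de)
})
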