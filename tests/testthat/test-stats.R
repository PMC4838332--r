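test_that("contingency tables pool captures and refuse empty input", {
  meta <- data.frame(
    treatment = rep(c("T+", "T-"), c(50, 25)),
    outcome = c(rep("non_capture", 25), rep("capture_drop", 15),
                rep("consume", 10), rep("non_capture", 3),
                rep("capture_drop", 14), rep("consume", 8)))
  ct <- buildContingency(meta, groups = c("T+", "T-"))
  expect_equal(unname(tableCounts(ct)),
               matrix(c(25L, 25L, 3L, 22L), 2, byrow = TRUE))
  empty <- meta[0, ]
  ct0 <- buildContingency(empty, groups = c("T+", "T-"))
  expect_equal(sum(tableCounts(ct0)), 0L)
  expect_error(fisherExact(ct0), "degenerate")
  expect_error(buildContingency(meta, groups = c("T+", "bogus")), "bogus")
})

test_that("relative risk of capture matches the published group ratios", {
  expect_equal(round(relativeRiskCapture(contingencyTable2x2(25, 25, 3, 22)), 2),
               1.76)
  expect_equal(round(relativeRiskCapture(contingencyTable2x2(14, 19, 1, 16)), 1),
               1.6)
  expect_equal(relativeRiskCapture(contingencyTable2x2(10, 10, 5, 5)), 1)
  # swapping the groups gives the reciprocal
  rr <- relativeRiskCapture(contingencyTable2x2(25, 25, 3, 22))
  rrT <- relativeRiskCapture(contingencyTable2x2(3, 22, 25, 25))
  expect_equal(rr * rrT, 1, tolerance = 1e-12)
  expect_warning(relativeRiskCapture(contingencyTable2x2(5, 0, 3, 2)),
                 "undefined")
})

test_that("Fisher exact inference reproduces the published odds ratios and CIs", {
  f1 <- fisherExact(contingencyTable2x2(25, 25, 3, 22))
  expect_equal(f1@orCmle, 7.15, tolerance = 0.005)
  expect_equal(f1@ci95, c(1.8, 42.0), tolerance = 0.01)
  f2 <- fisherExact(contingencyTable2x2(14, 19, 1, 16))
  expect_equal(f2@orCmle, 11.32, tolerance = 0.005)
  expect_equal(f2@ci95, c(1.4, 527.6), tolerance = 0.01)
  fb <- fisherExact(contingencyTable2x2(5, 5, 5, 5))
  expect_equal(fb@orCmle, 1)
  expect_equal(fb@pTwoSided, 1)
  # boundary table: infinite upper bound, estimate above 0
  fz <- fisherExact(matrix(c(8, 0, 2, 6), 2, byrow = TRUE))
  expect_true(is.infinite(fz@orCmle) || fz@ci95[2] == Inf)
})

test_that("Fisher exact agrees with stats::fisher.test on random tables", {
  set.seed(23)
  for (rep in 1:25) {
    m <- matrix(rpois(4, 8), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    f <- fisherExact(m)
    ref <- fisher.test(m)
    expect_equal(f@pTwoSided, ref$p.value, tolerance = 1e-7)
    # fisher.test's own root-finding is looser than ours; compare at its scale
    expect_equal(f@orCmle, unname(ref$estimate), tolerance = 1e-3)
    expect_equal(f@ci95, as.numeric(ref$conf.int), tolerance = 2e-3)
  }
})

test_that("CMLE odds ratio lies inside its CI and the CI shrinks with sample size", {
  f <- fisherExact(contingencyTable2x2(12, 8, 5, 15))
  expect_true(f@ci95[1] <= f@orCmle && f@orCmle <= f@ci95[2])
  f2 <- fisherExact(contingencyTable2x2(48, 32, 20, 60))   # all cells x 4
  expect_lt(diff(log(f2@ci95)), diff(log(f@ci95)))
})

test_that("exact binomial palatability bounds match the published values", {
  e1 <- exactBinomialRejection(14, 22)
  expect_equal(round(e1@proportion, 2), 0.64)
  expect_equal(e1@ci95[1], 0.44, tolerance = 0.005)
  expect_equal(e1@pValue, 0)             # degenerate null p0 = 0, x > 0
  expect_true(e1@degenerateNull)
  e2 <- exactBinomialRejection(15, 16)
  expect_equal(round(e2@proportion, 2), 0.94)
  expect_equal(round(e2@ci95[1], 2), 0.74)

  e0 <- exactBinomialRejection(0, 10, p0 = 0.3)
  expect_equal(e0@ci95[1], 0)
  expect_equal(e0@pValue, 1)
  expect_error(exactBinomialRejection(5, 3))

  # lower bound is monotone in x and matches binom.test's one-sided CI
  lows <- vapply(0:16, function(x) exactBinomialRejection(x, 16)@ci95[1],
                 numeric(1))
  expect_true(all(diff(lows) > 0))
  bt <- binom.test(14, 22, p = 0.5, alternative = "greater")
  expect_equal(exactBinomialRejection(14, 22)@ci95[1], bt$conf.int[1],
               tolerance = 1e-9)
})

test_that("Welch t matches a direct formula evaluation and is null on identical samples", {
  a <- c(12.1, 9.8, 14.2, 11.5, 10.9, 13.3)
  b <- c(8.2, 9.9, 7.4, 10.1, 8.8)
  w <- welchT(a, b)
  se2a <- var(a) / length(a); se2b <- var(b) / length(b)
  tRef <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  dfRef <- (se2a + se2b)^2 /
    (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
  expect_equal(w$t, tRef, tolerance = 1e-10)
  expect_equal(w$df, dfRef, tolerance = 1e-10)
  same <- c(1, 2, 3, 4, 2.5)
  w0 <- welchT(same, same)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  expect_error(welchT(c(1), c(1, 2)))
})

test_that("Welch CI covers the true species IPI difference at nominal rate", {
  set.seed(91)
  hits <- mean(replicate(1000, {
    a <- rnorm(9, 44, 9); b <- rnorm(6, 21, 9)
    ci <- welchT(a, b)$ci95
    ci[1] <= 23 && 23 <= ci[2]
  }))
  expect_gte(hits, 0.93)
})

test_that("rank and distribution tests behave on identity and match a CDF oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(ksTest(x, x)$D, 0)
  expect_gt(mwwTest(x, x)$p, 0.9)
  set.seed(8)
  for (rep in 1:5) {
    a <- rnorm(sample(5:20, 1)); b <- rnorm(sample(5:20, 1), 1)
    Dref <- max(vapply(sort(c(a, b)), function(q)
      abs(mean(a <= q) - mean(b <= q)), numeric(1)))
    expect_equal(ksTest(a, b)$D, Dref, tolerance = 1e-12)
  }
})

test_that("Levene preprocessing removes exactly the upper log-scale outliers", {
  set.seed(14)
  v <- c(rlnorm(20, 0, 0.1), 1e6)   # one huge value
  g <- rep(c("A", "B"), length.out = 21)
  r <- leveneAfterOutlierRemoval(v, g)
  expect_equal(r$nRemoved, 1L)
  expect_false(r$kept[21])
  expect_true(is.finite(r$p))
  expect_error(leveneAfterOutlierRemoval(c(1, -2, 3), c("A", "B", "A")),
               "record 2")
})

test_that("Bonferroni caps at 1, is monotone, and is the identity at m = 1", {
  expect_equal(bonferroni(0.5, m = 3), 1)
  expect_equal(bonferroni(0.01, m = 2), 0.02)
  expect_equal(bonferroni(c(0.2, 0.7)), c(0.4, 1))
  p <- sort(runif(5))
  expect_true(all(diff(bonferroni(p, m = 5)) >= 0))
  expect_equal(bonferroni(0.37, m = 1), 0.37)
  expect_error(bonferroni(1.2, m = 1))
  expect_error(bonferroni(c(0.1, 0.2), m = 1))
})

test_that("first-interaction filter keeps the earliest record per moth, order-invariant", {
  meta <- data.frame(
    interaction_id = c("i1", "i2", "i3", "i4"),
    moth_id = c("m1", "m1", "m2", "m3"),
    timestamp = c(2, 1, 5, 3))
  kept <- firstInteractionFilter(meta)
  expect_setequal(kept$interaction_id, c("i2", "i3", "i4"))
  shuffled <- meta[c(3, 1, 4, 2), ]
  expect_setequal(firstInteractionFilter(shuffled)$interaction_id,
                  kept$interaction_id)
  allUnique <- data.frame(interaction_id = c("a", "b"),
                          moth_id = c("x", "y"), timestamp = 1:2)
  expect_equal(nrow(firstInteractionFilter(allUnique)), 2L)
  expect_error(firstInteractionFilter(data.frame(moth_id = "m")))
})

test_that("species evasion comparison recovers the configured odds ratio", {
  set.seed(33)
  n <- 300
  meta <- data.frame(
    species = rep(c("P_roseicapitis", "C_martini"), each = n),
    evasion = c(ifelse(runif(n) < 0.43, "dive", "no_evasion"),
                ifelse(runif(n) < 0.17, "dive", "no_evasion")))
  ec <- evasionComparison(meta)
  truthOR <- (0.43 / 0.57) / (0.17 / 0.83)
  expect_true(ec$fisher@ci95[1] <= truthOR && truthOR <= ec$fisher@ci95[2])
  # equal rates: CI contains 1
  meta2 <- data.frame(
    species = rep(c("P_roseicapitis", "C_martini"), each = 100),
    evasion = rep(rep(c("dive", "no_evasion"), 50), 2))
  ec2 <- evasionComparison(meta2)
  expect_true(ec2$fisher@ci95[1] <= 1 && 1 <= ec2$fisher@ci95[2])
  # an empty cell yields a one-sided infinite bound, not an error
  meta3 <- data.frame(
    species = rep(c("P_roseicapitis", "C_martini"), each = 10),
    evasion = c(rep("dive", 10), rep(c("dive", "no_evasion"), 5)))
  ec3 <- evasionComparison(meta3)
  expect_true(is.infinite(ec3$fisher@ci95[2]))
  # turn-away records are dropped before tabulation
  meta4 <- rbind(meta2, data.frame(species = "P_roseicapitis",
                                   evasion = "turn_away"))
  expect_equal(sum(evasionComparison(meta4)$table), sum(ec2$table))
})
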