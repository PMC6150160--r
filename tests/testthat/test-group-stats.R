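# Independent p-value oracle: numerically integrate the t density rather
# than use the closed-form distribution function.
pOracle <- function(tStat, df) {
  2 * integrate(function(x) dt(x, df), abs(tStat), Inf,
                rel.tol = 1e-10)$value
}

test_that("group summaries use the n-1 SD and SE = SD/sqrt(n)", {
  s <- summarizeGroup(GroupMeasurements("flat", c(1, 1, 1, 1)))
  expect_equal(c(s@mean, s@sd, s@se), c(1, 0, 0))

  s2 <- summarizeGroup(GroupMeasurements("pair", c(0, 2)))
  expect_equal(s2@mean, 1)
  expect_equal(s2@sd, sqrt(2))
  expect_equal(s2@se, 1)

  # SD 20.63 at n = 7 prints as SE 7.80
  g <- simulateGroup("cox2 cream", mean = 106.86, sd = 20.63, n = 7, seed = 3)
  expect_equal(round(summarizeGroup(g)@se, 2), 7.80)

  expect_error(summarizeGroup(GroupMeasurements("one", 5)),
               class = "invalidArgumentError")
})

test_that("Welch test from summaries matches the printed comparisons", {
  expect_equal(pValue(welchFromSummary(10, 2, 5, 10, 2, 5)), 1)
  expect_equal(significanceCategory(welchFromSummary(10, 2, 5, 10, 2, 5)),
               "NS")

  # bcl-2: C_BCNU@HCLI vs Cream BCNU
  w <- welchFromSummary(75.63, 23.59, 7, 106.33, 15.12, 7)
  expect_equal(significanceCategory(w), "p<0.05")
  expect_equal(pValue(w), pOracle(w@tStatistic, w@df), tolerance = 1e-6)
  expect_equal(pValue(w), 0.016, tolerance = 0.05)

  # cox-2: C_BCNU@HCLI vs Cream BCNU
  w2 <- welchFromSummary(67.41, 18.70, 7, 106.86, 20.63, 7)
  expect_equal(significanceCategory(w2), "p<0.01")
  expect_equal(pValue(w2), pOracle(w2@tStatistic, w2@df), tolerance = 1e-6)
  expect_equal(pValue(w2), 0.003, tolerance = 0.1)
})

test_that("degenerate zero-variance comparisons are handled explicitly", {
  same <- welchFromSummary(5, 0, 4, 5, 0, 4)
  expect_equal(pValue(same), 1)
  expect_equal(significanceCategory(same), "NS")

  diff <- welchFromSummary(5, 0, 4, 6, 0, 4)
  expect_equal(pValue(diff), 0)
  expect_equal(significanceCategory(diff), "p<0.001")
  expect_true(diff@degenerate)

  expect_error(welchFromSummary(1, 1, 1, 2, 1, 5),
               class = "invalidArgumentError")
})

test_that("welchTest agrees with stats::t.test and is symmetric", {
  for (seed in 1:6) {
    set.seed(seed)
    a <- GroupMeasurements("a", rnorm(sample(3:9, 1), 10, 2))
    b <- GroupMeasurements("b", rnorm(sample(3:9, 1), 11, 3))
    w <- welchTest(a, b)
    ref <- t.test(groupValues(a), groupValues(b), var.equal = FALSE)
    expect_equal(pValue(w), ref$p.value, tolerance = 1e-12)
    expect_equal(w@df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(w@tStatistic, unname(ref$statistic), tolerance = 1e-12)

    rev <- welchTest(b, a)
    expect_equal(pValue(rev), pValue(w))
    expect_equal(rev@tStatistic, -w@tStatistic)
    expect_equal(rev@df, w@df)

    # category consistent with the strict thresholds
    expected <- if (pValue(w) < 0.001) "p<0.001"
                else if (pValue(w) < 0.01) "p<0.01"
                else if (pValue(w) < 0.05) "p<0.05" else "NS"
    expect_equal(significanceCategory(w), expected)
  }
})

test_that("welchTest on exact-moment data equals the summary path", {
  for (i in 1:3) {
    g1 <- simulateGroup("g1", bcl2Summaries$mean[i], bcl2Summaries$sd[i],
                        n = 7, seed = i)
    g2 <- simulateGroup("g2", bcl2Summaries$mean[i + 1],
                        bcl2Summaries$sd[i + 1], n = 7, seed = i + 50)
    w <- welchTest(g1, g2)
    ws <- welchFromSummary(bcl2Summaries$mean[i], bcl2Summaries$sd[i], 7,
                           bcl2Summaries$mean[i + 1],
                           bcl2Summaries$sd[i + 1], 7)
    expect_equal(pValue(w), pValue(ws), tolerance = 1e-9)
    expect_equal(significanceCategory(w), significanceCategory(ws))
  }
})

test_that("the comparison matrix is symmetric with an NS diagonal", {
  g <- list(GroupMeasurements("x", c(1, 2, 3)),
            GroupMeasurements("y", c(1, 2, 3)))
  cm <- comparisonMatrix(g)
  expect_true(all(cm@categories == "NS"))

  for (seed in 1:4) {
    set.seed(seed)
    gs <- lapply(1:4, function(i)
      GroupMeasurements(paste0("g", i), rnorm(5, i * 2, 2)))
    cm <- comparisonMatrix(gs)
    expect_identical(cm@categories, t(cm@categories))
    expect_true(all(diag(cm@categories) == "NS"))
    expect_equal(cm@pValues, t(cm@pValues))
  }

  expect_error(comparisonMatrix(g[1]), class = "invalidArgumentError")
  expect_error(comparisonMatrix(list(GroupMeasurements("x", 1:3),
                                     GroupMeasurements("x", 2:4))),
               class = "invalidArgumentError")
})

test_that("the treated-vs-cream cells reproduce with exact-moment groups", {
  mk <- function(df, seed0) {
    lapply(seq_len(nrow(df)), function(i)
      simulateGroup(df$label[i], df$mean[i], df$sd[i], n = 7,
                    seed = seed0 + i))
  }
  cmB <- comparisonMatrix(mk(bcl2Summaries, 10))
  expect_equal(cmB@categories["C_BCNU@HCLI", "Cream BCNU"], "p<0.05")
  cmC <- comparisonMatrix(mk(cox2Summaries, 20))
  expect_equal(cmC@categories["C_BCNU@HCLI", "Cream BCNU"], "p<0.01")
})

test_that("optional multiplicity adjustment weakens categories only", {
  set.seed(9)
  gs <- lapply(1:4, function(i)
    GroupMeasurements(paste0("g", i), rnorm(6, i * 3, 2)))
  raw <- comparisonMatrix(gs, adjust = "none")
  adj <- comparisonMatrix(gs, adjust = "bonferroni")
  expect_true(all(adj@pValues >= raw@pValues))
})
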