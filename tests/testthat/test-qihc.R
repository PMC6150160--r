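# Forward-render an image from per-pixel hematoxylin/DAB optical-density
# amounts through the stain matrix (independent of the package simulator).
renderHDAB <- function(hAmount, dAmount) {
  m <- hdabStainMatrix()
  n <- length(dAmount)
  od <- outer(hAmount, m["hematoxylin", ]) + outer(dAmount, m["dab", ])
  RgbImage(array(pmin(pmax(round(255 * 10^(-od)), 0), 255),
                 dim = c(n, 1, 3)))
}

test_that("a white image carries no chromogen in any channel", {
  img <- RgbImage(array(255, dim = c(4, 5, 3)))
  st <- deconvolveHDAB(img)
  expect_true(all(dabChannel(st) == 255))
  expect_true(all(hematoxylinChannel(st) == 255))
})

test_that("deconvolution inverts forward synthesis within one grey level", {
  d <- seq(0, 1.5, by = 0.05)
  img <- renderHDAB(rep(0.3, length(d)), d)
  st <- deconvolveHDAB(img)
  expect_true(all(abs(dabChannel(st) - round(255 * 10^(-d))) <= 1))
  # same guarantee for the counterstain on pure-hematoxylin pixels; in mixed
  # very dark pixels 8-bit quantization is too coarse for a 1-level bound on
  # the secondary channel
  h <- seq(0, 1.5, by = 0.05)
  imgH <- renderHDAB(h, rep(0, length(h)))
  expect_true(all(abs(hematoxylinChannel(deconvolveHDAB(imgH)) -
                        round(255 * 10^(-h))) <= 1))
})

test_that("a pure-hematoxylin pixel shows essentially no DAB", {
  img <- renderHDAB(1, 0)
  st <- deconvolveHDAB(img)
  recovered <- -log10(dabChannel(st)[1, 1] / 255)
  expect_lt(abs(recovered), 0.02)
})

test_that("zone binning follows the stated intensity ranges", {
  h <- zoneHistogram(dabMatrix(rep(30, 10), 2, 5))
  expect_equal(unname(zoneCounts(h)[["high_positive"]]), 10)

  h2 <- zoneHistogram(dabMatrix(c(60, 61), 1, 2))
  expect_equal(unname(zoneCounts(h2)[["high_positive"]]), 1)
  expect_equal(unname(zoneCounts(h2)[["positive"]]), 1)

  h3 <- zoneHistogram(dabMatrix(rep(240, 4), 2, 2))
  expect_equal(unname(zoneCounts(h3)[["excluded"]]), 4)

  # 235 belongs to the stated negative range, 236 starts the exclusion
  h4 <- zoneHistogram(dabMatrix(c(235, 236), 1, 2))
  expect_equal(unname(zoneCounts(h4)[["negative"]]), 1)
  expect_equal(unname(zoneCounts(h4)[["excluded"]]), 1)

  expect_error(zoneHistogram(dabMatrix(1:4, 2, 2),
                             PixelMask(matrix(FALSE, 2, 2))),
               class = "invalidArgumentError")
})

test_that("zone counts always sum to the masked-pixel total", {
  for (seed in 1:8) {
    img <- randomRgbImage(15, 17, seed)
    set.seed(seed + 100)
    mask <- PixelMask(matrix(runif(15 * 17) > 0.3, 15, 17))
    if (!any(mask@.Data)) next
    h <- zoneHistogram(deconvolveHDAB(img), mask)
    expect_identical(sum(zoneCounts(h)), sum(mask@.Data))
  }
})

test_that("the weighted score follows its formula and stays in [1, 4]", {
  mkHist <- function(counts) {
    new("ZoneHistogram",
        counts = setNames(as.integer(counts),
                          c("high_positive", "positive", "low_positive",
                            "negative", "excluded")),
        total = as.integer(sum(counts)))
  }
  expect_equal(globalScore(ihcScore(mkHist(c(50, 0, 0, 0, 0)))), 4)
  expect_equal(globalScore(ihcScore(mkHist(c(25, 25, 25, 25, 0)))), 2.5)
  expect_equal(globalScore(ihcScore(mkHist(c(0, 100, 0, 100, 0)))), 2.0)
  # excluded pixels do not dilute the score
  expect_equal(globalScore(ihcScore(mkHist(c(50, 0, 0, 0, 70)))), 4)
  expect_error(ihcScore(mkHist(c(0, 0, 0, 0, 12))), class = "noScoreError")

  for (seed in 1:10) {
    set.seed(seed)
    counts <- rmultinom(1, 500, runif(5))[, 1]
    if (sum(counts[1:4]) == 0) next
    sc <- ihcScore(mkHist(counts))
    expect_gte(globalScore(sc), 1)
    expect_lte(globalScore(sc), 4)
    expect_equal(globalScore(sc), sum(partialScores(sc)))
  }
})

test_that("score and energy are invariant under pixel permutation", {
  img <- randomRgbImage(12, 12, 7)
  st <- deconvolveHDAB(img)
  dab <- dabChannel(st)
  set.seed(8)
  perm <- matrix(sample(as.vector(dab)), 12, 12)
  expect_equal(globalScore(ihcScore(zoneHistogram(dab))),
               globalScore(ihcScore(zoneHistogram(perm))))
  expect_equal(chromogenEnergy(dab), chromogenEnergy(perm))
})

test_that("darkening a pixel never decreases score and always raises energy", {
  dab <- dabMatrix(c(200, 150, 90, 40, 240, 130), 2, 3)
  s0 <- globalScore(ihcScore(zoneHistogram(dab)))
  e0 <- chromogenEnergy(dab)
  dab2 <- dab
  dab2[1, 1] <- 100   # negative zone -> positive zone
  expect_gte(globalScore(ihcScore(zoneHistogram(dab2))), s0)
  expect_gt(chromogenEnergy(dab2), e0)
})

test_that("chromogen energy is the RMS DAB amplitude", {
  expect_equal(chromogenEnergy(dabMatrix(rep(255, 6), 2, 3)), 0)
  expect_equal(chromogenEnergy(dabMatrix(rep(155, 6), 2, 3)), 100)
  half <- dabMatrix(c(255, 255, 55, 55), 2, 2)
  expect_equal(chromogenEnergy(half), sqrt(mean(c(0, 0, 200, 200)^2)))
  expect_equal(round(chromogenEnergy(half), 2), 141.42)
  expect_equal(chromogenEnergy(half, mode = "mean_square"), 20000)
})

test_that("control subtraction floors at zero with a warning", {
  expect_equal(correctedEU(correctedEnergy(100, 30)), 70)
  expect_equal(correctedEU(correctedEnergy(30, 30)), 0)
  expect_warning(res <- correctedEnergy(20, 30), "clamped")
  expect_equal(correctedEU(res), 0)
  expect_true(res@clamped)
})

test_that("synthetic images score exactly their analytic expectation", {
  cases <- list(
    c(high_positive = 1),
    c(positive = 0.5, negative = 0.5),
    c(high_positive = 0.25, positive = 0.25, low_positive = 0.25,
      negative = 0.25),
    c(high_positive = 0.1, positive = 0.2, low_positive = 0.3,
      negative = 0.3))   # 10% excluded remainder
  for (i in seq_along(cases)) {
    sim <- simulateIhcImage(25, 31, cases[[i]], seed = i)
    sc <- ihcScore(zoneHistogram(deconvolveHDAB(sim$image), sim$mask))
    expect_equal(globalScore(sc), globalScore(sim$expected), info = i)
    expect_equal(partialScores(sc), partialScores(sim$expected), info = i)
  }
})

test_that("an all-excluded synthetic image yields no score", {
  sim <- simulateIhcImage(10, 10, c(), seed = 1)
  expect_null(sim$expected)
  expect_error(ihcScore(zoneHistogram(deconvolveHDAB(sim$image), sim$mask)),
               class = "noScoreError")
})
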