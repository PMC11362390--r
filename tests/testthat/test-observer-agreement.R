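straightMidline <- function(pixelSize = 0.01, len = 500,
                            dir = "end") {
  midlinePath(cbind(50, seq_len(len)), pixelSize = pixelSize,
              ischemicDirection = dir)
}

test_that("along-midline distances carry the ischemic-ward sign", {
  ml <- straightMidline()
  expect_equal(signedMidlineDistance(ml, c(50, 300), c(50, 300)), 0)
  expect_equal(signedMidlineDistance(ml, c(50, 300), c(50, 420)), 1.2)
  mlRev <- straightMidline(dir = "start")
  expect_equal(signedMidlineDistance(mlRev, c(50, 300), c(50, 420)),
               -1.2)
})

test_that("off-axis points project onto the nearest midline point", {
  ml <- straightMidline()
  ## 10 px above the line: same arclength foot
  expect_equal(signedMidlineDistance(ml, c(40, 300), c(60, 420)), 1.2)
  ## bent polyline: projection picks the closer segment
  bent <- midlinePath(rbind(c(0, 0), c(0, 100), c(100, 100)),
                      pixelSize = 0.01)
  d <- signedMidlineDistance(bent, c(0, 0), c(40, 90))
  expect_equal(d, (100 + 40 - 0) * 0.01, tolerance = 1e-6)
})

test_that("placements beyond the snap radius are data errors", {
  ml <- straightMidline()
  expect_error(signedMidlineDistance(ml, c(50, 300), c(150, 300)),
               "snap")
  expect_silent(signedMidlineDistance(ml, c(50, 300), c(90, 300),
                                      snapRadius = 60))
})

test_that("fractions within a limit count non-missing placements", {
  d <- c(0.5, -0.8, 1.2, 2.5)
  expect_equal(fractionWithin(d, 1)$fraction, 0.5)
  expect_equal(fractionWithin(d, 2)$fraction, 0.75)
  expect_equal(fractionWithin(rep(0, 5), 1)$fraction, 1)
  withNA <- fractionWithin(c(d, NA, NA), 1)
  expect_equal(withNA$fraction, 0.5)
  expect_equal(withNA$n, 4)
  expect_equal(withNA$nMissing, 2)
  expect_error(fractionWithin(numeric(0), 1), "non-empty")
  expect_error(fractionWithin(d, 0), "positive")
})

test_that("fractionWithin is monotone in the limit", {
  set.seed(3)
  d <- rnorm(60, 0.4, 1.1)
  fr <- vapply(c(0.5, 1, 1.5, 2, 3),
               function(l) fractionWithin(d, l)$fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("distance categories use right-closed 1 cm bins", {
  d <- c(0, -1.5, 1.0, -1.0, 1.0001, NA)
  cats <- placementCategories(d)
  expect_equal(as.character(cats),
               c("within", "toward_well", "within", "toward_well",
                 "toward_ischemic", "missing"))
  expect_error(placementCategories(d, binEdges = c(-Inf, 1, 1, Inf)),
               "increasing")
})

test_that("kappa reproduces hand-computed agreement tables", {
  ## confusion table [[20, 5], [10, 15]]: po 0.7, pe 0.5, kappa 0.4
  a <- rep(c("x", "x", "y", "y"), c(20, 5, 10, 15))
  b <- rep(c("x", "y", "x", "y"), c(20, 5, 10, 15))
  k <- cohensKappa(a, b, nBoot = 0)
  expect_equal(k@po, 0.7)
  expect_equal(k@pe, 0.5)
  expect_equal(kappaValue(k), 0.4)
  ## identity and chance level
  ident <- cohensKappa(c("a", "b", "a", "c"), c("a", "b", "a", "c"),
                       nBoot = 0)
  expect_equal(kappaValue(ident), 1)
  chance <- cohensKappa(c(1, 1, 2, 2), c(1, 2, 1, 2), nBoot = 0)
  expect_equal(kappaValue(chance), 0)
})

test_that("kappa is symmetric and invariant to relabeling", {
  set.seed(15)
  a <- sample(letters[1:3], 40, replace = TRUE)
  b <- sample(letters[1:3], 40, replace = TRUE)
  expect_equal(kappaValue(cohensKappa(a, b, nBoot = 0)),
               kappaValue(cohensKappa(b, a, nBoot = 0)))
  relab <- c(a = "z1", b = "z2", c = "z3")
  expect_equal(kappaValue(cohensKappa(relab[a], relab[b], nBoot = 0)),
               kappaValue(cohensKappa(a, b, nBoot = 0)))
})

test_that("kappa matches independent computations on random vectors", {
  set.seed(8)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    a <- sample(c("p", "q", "r"), n, replace = TRUE)
    b <- sample(c("p", "q", "r"), n, replace = TRUE)
    po <- mean(a == b)
    if (po == 1 && length(unique(a)) == 1) next  # undefined case
    k <- cohensKappa(a, b, nBoot = 0)
    expect_equal(kappaValue(k), bruteKappa(a, b), tolerance = 1e-12)
    if (requireNamespace("e1071", quietly = TRUE)) {
      tab <- table(factor(a, levels = c("p", "q", "r")),
                   factor(b, levels = c("p", "q", "r")))
      expect_equal(kappaValue(k),
                   e1071::classAgreement(tab)$kappa,
                   tolerance = 1e-12)
    }
  }
})

test_that("degenerate and mismatched rating vectors are handled", {
  expect_warning(k <- cohensKappa(rep("a", 5), rep("a", 5), nBoot = 0),
                 "undefined")
  expect_true(is.na(kappaValue(k)))
  expect_error(cohensKappa(1:3, 1:4), "length")
})

test_that("the bootstrap CI brackets kappa and is seeded", {
  set.seed(2)
  a <- sample(c("u", "v"), 60, replace = TRUE)
  b <- ifelse(runif(60) < 0.8, a, sample(c("u", "v"), 60, TRUE))
  k1 <- cohensKappa(a, b, nBoot = 400, seed = 5)
  k2 <- cohensKappa(a, b, nBoot = 400, seed = 5)
  expect_identical(kappaCI(k1), kappaCI(k2))
  ci <- kappaCI(k1)
  expect_lte(ci["low"], ci["high"])
  expect_true(ci["low"] <= kappaValue(k1) + 1e-9 &&
                kappaValue(k1) <= ci["high"] + 1e-9)
})

test_that("synthetic observers drift toward the ischemic side as configured", {
  ml <- midlinePath(cbind(50, seq_len(800)), pixelSize = 0.04)
  obs <- data.frame(observer_id = paste0("O", 1:10),
                    expertise = rep(c("expert", "physician"), 5))
  refArc <- seq(150, 650, length.out = 12)
  pl <- simulateObserverPlacements(ml, refArc, obs, driftMean = 0.6,
                                   driftSD = 0.8, missingRate = 0.03,
                                   seed = 6)
  expect_equal(nrow(pl), 120)
  d <- pl$distance_cm
  pHat <- mean(d > 0, na.rm = TRUE)
  p0 <- pnorm(0.6 / 0.8)             # configured drift fraction
  n <- sum(!is.na(d))
  expect_lt(abs(pHat - p0), 3 * sqrt(p0 * (1 - p0) / n))
  ## distances recomputed through the projection match the drift scale
  expect_lt(abs(mean(d, na.rm = TRUE) - 0.6), 3 * 0.8 / sqrt(n))
})
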