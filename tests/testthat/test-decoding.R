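test_that("within-class scores follow the constant-block structure", {
  sm <- blockSimilarityMatrix(c(A = 4, B = 4), rWithin = 0.8,
                              rBetween = 0.2)
  s <- withinClassScore(sm, "A")
  # target images: own row over the A block minus the diagonal -> 0.8
  expect_equal(unname(s[1:4]), rep(0.8, 4))
  expect_equal(unname(s[5:8]), rep(0.2, 4))
})

test_that("within-class scores match a brute-force loop oracle", {
  sm <- randomSimilarityMatrix(nPerRace = 4, nRaces = 3, seed = 11)
  for (r in levels(raceLabels(sm))) {
    expect_equal(unname(withinClassScore(sm, r)),
                 withinScoreOracle(similarityValues(sm),
                                   as.character(raceLabels(sm)), r),
                 tolerance = 1e-12)
  }
  expect_error(withinClassScore(sm, "absent"), "not present")
})

test_that("AUC handles separation, ties and the enumerated example", {
  expect_equal(aucFromScores(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(aucFromScores(rep(2, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(aucFromScores(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)
  expect_error(aucFromScores(1:3, c(TRUE, TRUE, TRUE)), "negative")
})

test_that("AUC equals the exhaustive comparison oracle on random inputs", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    scores <- sample(0:4, n, replace = TRUE) + # many ties
      sample(c(0, 0.5), n, replace = TRUE)
    pos <- logical(n)
    pos[sample(n, sample(seq_len(n - 1), 1))] <- TRUE
    expect_equal(aucFromScores(scores, pos), aucOracle(scores, pos))
  }
})

test_that("d-prime transform matches the normal-quantile oracle", {
  expect_equal(aucToDprime(0.5), 0)
  expect_equal(aucToDprime(0.75), 0.9539, tolerance = 1e-4)
  expect_equal(aucToDprime(0.9), 1.8124, tolerance = 1e-4)
  # strictly increasing and antisymmetric about 0.5
  grid <- seq(0.01, 0.99, by = 0.01)
  d <- aucToDprime(grid)
  expect_true(all(diff(d) > 0))
  expect_equal(aucToDprime(1 - grid), -d)
  # extreme AUC stays finite through clipping
  expect_true(is.finite(aucToDprime(1, nPositive = 10, nNegative = 20)))
})

test_that("race decoding composes scores, AUC and d-prime", {
  sm <- blockSimilarityMatrix(c(A = 5, B = 10))
  rd <- raceDecoding(sm, "A")
  expect_equal(rd$auc, 1)
  expect_equal(rd$dprime, aucToDprime(1, 5, 10))  # clipped maximum
  # random matrix equals brute-force recomputation
  sm2 <- randomSimilarityMatrix(seed = 5)
  rd2 <- raceDecoding(sm2, "race2")
  s <- withinScoreOracle(similarityValues(sm2),
                         as.character(raceLabels(sm2)), "race2")
  expect_equal(rd2$auc, aucOracle(s, raceLabels(sm2) == "race2"))
})

test_that("label shuffling destroys decodability", {
  # on an unstructured (exchangeable) matrix shuffled labels average to
  # chance AUC
  smNoise <- randomSimilarityMatrix(nPerRace = 9, nRaces = 2,
                                    nFeatures = 25, seed = 66)
  set.seed(123)
  aucsNoise <- replicate(1000, {
    shuffled <- smNoise
    shuffled@raceLabels <- sample(raceLabels(smNoise))
    raceDecoding(shuffled, "race1")$auc
  })
  expect_lt(abs(mean(aucsNoise) - 0.5), 0.02)
  # on a planted block matrix shuffling collapses the perfect decoding
  # (AUC 1) to chance or below: the self-excluded score statistic is
  # conservatively biased under permuted labels, never inflated
  sm <- blockSimilarityMatrix(c(A = 9, B = 9))
  expect_equal(raceDecoding(sm, "A")$auc, 1)
  set.seed(321)
  aucs <- replicate(1000, {
    shuffled <- sm
    shuffled@raceLabels <- sample(raceLabels(sm))
    raceDecoding(shuffled, "A")$auc
  })
  expect_lte(mean(aucs), 0.5 + 0.02)
})

test_that("identity decoding separates same from different pairs", {
  r <- c(rep(0.9, 4), rep(0.1, 4))
  flags <- rep(c(TRUE, FALSE), each = 4)
  id <- identityDecoding(r, flags)
  expect_equal(id$auc, 1)
  set.seed(8)
  rr <- rnorm(12)
  ff <- rep(c(TRUE, FALSE), 6)
  expect_equal(identityDecoding(rr, ff)$auc, aucOracle(rr, ff))
  expect_error(identityDecoding(rr, rep(TRUE, 12)), "both")
})

test_that("within-between difference matches blocks and the loop oracle", {
  sm <- blockSimilarityMatrix(c(A = 4, B = 4, C = 4))
  wb <- withinBetweenDifference(sm)
  expect_equal(wb$difference, rep(0.6, 12))
  # all-equal correlations give zero difference
  smEq <- blockSimilarityMatrix(c(A = 4, B = 4), rWithin = 0.3,
                                rBetween = 0.3)
  expect_equal(withinBetweenDifference(smEq)$difference, rep(0, 8))
  # random case against explicit loops
  smR <- randomSimilarityMatrix(seed = 21)
  wbR <- withinBetweenDifference(smR)
  v <- similarityValues(smR)
  lab <- as.character(raceLabels(smR))
  for (i in seq_along(lab)) {
    own <- which(lab == lab[i] & seq_along(lab) != i)
    oth <- which(lab != lab[i])
    expect_equal(wbR$within_mean[i], mean(v[i, own]), tolerance = 1e-12)
    expect_equal(wbR$between_mean[i], mean(v[i, oth]), tolerance = 1e-12)
  }
})

test_that("Holm-corrected contrasts follow the step-down rule", {
  set.seed(31)
  cells <- list(
    c1 = list(a = rnorm(8, 1), b = rnorm(8)),
    c2 = list(a = rnorm(8, 0.5), b = rnorm(8)),
    c3 = list(a = rnorm(8), b = rnorm(8)))
  res <- contrastTHolm(cells, paired = TRUE)
  expect_equal(res$p_holm, holmOracle(res$p_raw))
  expect_true(all(res$p_holm >= res$p_raw))
  expect_true(all(res$p_holm <= 1))
  # a single cell is unadjusted
  one <- contrastTHolm(cells[1], paired = TRUE)
  expect_equal(one$p_holm, one$p_raw)
  # the documented worked example
  expect_equal(holmOracle(c(0.01, 0.03, 0.04)), c(0.03, 0.06, 0.06))
  expect_equal(stats::p.adjust(c(0.01, 0.03, 0.04), "holm"),
               c(0.03, 0.06, 0.06))
})

test_that("degenerate contrast cells raise errors", {
  expect_error(contrastTHolm(list(x = list(a = 1:2, b = 2:3))), "n < 3")
  expect_error(
    contrastTHolm(list(x = list(a = c(2, 3, 4), b = c(1, 2, 3)))),
    "constant")
})

test_that("Cohen's d matches hand computation and rejects zero spread", {
  expect_equal(cohensD(c(2, 3, 4), c(1, 1, 1), paired = TRUE), 2)
  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3), paired = FALSE), 0)
  expect_error(cohensD(c(2, 3, 4), c(1, 2, 3), paired = TRUE), "zero")
})
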