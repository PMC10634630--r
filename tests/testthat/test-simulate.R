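test_that("feature generator emulates the full stimulus-set structure", {
  cfg <- featureGenConfig()  # 3 races x 90 identities x 2 images, 16 layers
  gen <- simulateLayerFeatures(cfg, seed = 1)
  expect_length(gen$layers, 16)
  fs <- gen$layers[[1]]
  expect_equal(nrow(activations(fs)), 540L)
  expect_equal(as.vector(table(raceLabels(fs))), rep(180L, 3))
  # 45 same + 45 different identity pairs per race
  tab <- table(gen$pairs$race, gen$pairs$same_identity)
  expect_equal(as.vector(tab), rep(45L, 6))
  # different-identity pairs really join two identities
  diffPairs <- gen$pairs[!gen$pairs$same_identity, ]
  idOf <- function(x) sub("_im[0-9]+$", "", x)
  expect_true(all(idOf(diffPairs$image_id_a) != idOf(diffPairs$image_id_b)))
  samePairs <- gen$pairs[gen$pairs$same_identity, ]
  expect_true(all(idOf(samePairs$image_id_a) == idOf(samePairs$image_id_b)))
})

test_that("generators are pure functions of config and seed", {
  cfg <- featureGenConfig(identitiesPerRace = 6L, nLayers = 3L,
                          nFeatures = 20L)
  g1 <- simulateLayerFeatures(cfg, seed = 42)
  g2 <- simulateLayerFeatures(cfg, seed = 42)
  expect_identical(lapply(g1$layers, activations),
                   lapply(g2$layers, activations))
  g3 <- simulateLayerFeatures(cfg, seed = 43)
  expect_false(identical(activations(g1$layers[[1]]),
                         activations(g3$layers[[1]])))

  p1 <- simulateVoxelPatterns(patternGenConfig(nPerGroup = 3), seed = 7)
  p2 <- simulateVoxelPatterns(patternGenConfig(nPerGroup = 3), seed = 7)
  expect_identical(responses(p1), responses(p2))

  m1 <- simulateStatMap(c(10, 10, 10), noiseSd = 0.5, seed = 9)
  m2 <- simulateStatMap(c(10, 10, 10), noiseSd = 0.5, seed = 9)
  expect_identical(statValues(m1), statValues(m2))

  b1 <- simulateBehaviour(seq(0, 1, length.out = 10), seed = 5)
  b2 <- simulateBehaviour(seq(0, 1, length.out = 10), seed = 5)
  expect_identical(b1, b2)
})

test_that("signal-off features drive decoding to chance", {
  cfg <- featureGenConfig(identitiesPerRace = 10L, nLayers = 4L,
                          nFeatures = 40L,
                          raceSignalProfile = rep(0, 4),
                          identitySignalProfile = rep(0, 4))
  d <- vapply(1:20, function(s) {
    gen <- simulateLayerFeatures(cfg, seed = s)
    sm <- buildSimilarityMatrix(gen$layers[[4]])
    raceDecoding(sm, "Asian")$dprime
  }, numeric(1))
  expect_lt(abs(mean(d)), 0.2)
})

test_that("an increasing race-signal profile yields increasing d-prime", {
  rho <- vapply(1:10, function(s) {
    cfg <- featureGenConfig(identitiesPerRace = 10L, nFeatures = 100L)
    gen <- simulateLayerFeatures(cfg, seed = s)
    d <- vapply(gen$layers, function(fs)
      raceDecoding(buildSimilarityMatrix(fs), "Asian")$dprime, numeric(1))
    cor(d, seq_along(d), method = "spearman")
  }, numeric(1))
  expect_gt(mean(rho), 0.9)
})

test_that("behaviour generator is guess-limited and slope-sensitive", {
  pairR <- seq(-0.5, 0.9, length.out = 30)
  flat <- simulateBehaviour(pairR, slope = 0, guessRate = 0.1,
                            nParticipants = 400, seed = 3)
  expect_lt(max(abs(colMeans(flat) - 0.5)), 0.1)
  steep <- simulateBehaviour(pairR, slope = 20, guessRate = 0.05,
                             nParticipants = 400, seed = 4)
  expect_gt(cor(colMeans(steep), pairR), 0.9)
})

test_that("pattern generator plants the advertised structure", {
  # noiseless, no boost: all participants identical, LOPO diagonal r = 1
  cfg <- patternGenConfig(nPerGroup = 3, noiseSd = 0, ownRaceBoost = 0)
  vps <- simulateVoxelPatterns(cfg, seed = 2)
  ps <- lopoSimilarity(vps)
  diag <- ps$condition_a == ps$condition_b
  expect_equal(ps$r[diag], rep(1, sum(diag)), tolerance = 1e-12)
  # templates of different races correlate near rhoBetween, object near 0
  info <- conditionInfo(vps)
  dc <- which(info$arrangement == "different")
  tm <- responses(vps)[1, dc, ]
  cc <- cor(t(tm))
  faceIdx <- which(info$race[dc] != "Object")
  objIdx <- which(info$race[dc] == "Object")
  offFace <- cc[faceIdx, faceIdx][upper.tri(diag(length(faceIdx)))]
  expect_lt(max(abs(offFace - cfg$rhoBetween)), 0.2)
  expect_lt(max(abs(cc[faceIdx, objIdx])), 0.2)
})

test_that("stat-map generator places blobs where asked", {
  map <- simulateStatMap(c(20, 20, 20), matrix(c(5, 10, 15), 1),
                         amplitudes = 4, widths = 2, noiseSd = 0)
  pk <- findPeak(map)
  expect_equal(pk$index, c(5L, 10L, 15L))
  expect_equal(pk$z, 4)
  expect_error(simulateStatMap(c(10, 10, 10), matrix(c(50, 5, 5), 1)),
               "inside the grid")
})

test_that("config validation rejects inconsistent settings", {
  expect_error(featureGenConfig(nLayers = 4, raceSignalProfile = c(0, 1)),
               "one entry per layer")
  expect_error(featureGenConfig(imagesPerIdentity = 1L), "same-identity")
  expect_error(patternGenConfig(rhoWithin = 0.1, rhoBetween = 0.5),
               "rhoBetween")
  expect_error(patternGenConfig(nPerGroup = 1L), "at least 2")
})
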