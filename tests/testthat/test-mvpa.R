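toyPatterns <- function() {
  # 3 participants in one group, 2 conditions, 4 voxels, hand-set values
  r <- array(NA_real_, c(3, 2, 4),
             dimnames = list(c("p1", "p2", "p3"), c("c1", "c2"), NULL))
  r["p1", "c1", ] <- c(1, 2, 3, 4);  r["p1", "c2", ] <- c(4, 3, 2, 1)
  r["p2", "c1", ] <- c(2, 2, 3, 5);  r["p2", "c2", ] <- c(5, 3, 2, 0)
  r["p3", "c1", ] <- c(1, 1, 4, 4);  r["p3", "c2", ] <- c(4, 4, 1, 1)
  voxelPatternSet(r, rep("G", 3),
                  data.frame(condition = c("c1", "c2"),
                             race = c("A", "B"),
                             arrangement = "different"))
}

test_that("normalization zeroes the per-voxel condition mean", {
  set.seed(3)
  r <- array(rnorm(5 * 4 * 10), c(5, 4, 10))
  vps <- voxelPatternSet(r, rep(c("G1", "G2"), c(3, 2)))
  norm <- normalizePatterns(vps)
  m <- apply(responses(norm), c(1, 3), mean)
  expect_lt(max(abs(m)), 1e-12)
  # constant-across-conditions voxels become exactly zero
  r2 <- array(rep(7, 2 * 3 * 4), c(2, 3, 4))
  n2 <- normalizePatterns(voxelPatternSet(r2, c("G", "G")))
  expect_equal(as.vector(responses(n2)), rep(0, 24))
  # two conditions become an antisymmetric half-difference pattern
  r3 <- array(0, c(2, 2, 3))
  r3[1, 1, ] <- c(2, 4, 6); r3[1, 2, ] <- c(0, 0, 0)
  r3[2, 1, ] <- 1; r3[2, 2, ] <- 1
  n3 <- normalizePatterns(voxelPatternSet(r3, c("G", "G")))
  expect_equal(responses(n3)[1, 1, ], c(1, 2, 3))
  expect_equal(responses(n3)[1, 2, ], -c(1, 2, 3))
})

test_that("LOPO similarity matches a hand-computed toy case", {
  vps <- toyPatterns()
  ps <- lopoSimilarity(vps)
  # p1's c1 pattern against the mean c1 pattern of p2 and p3
  tmpl11 <- (c(2, 2, 3, 5) + c(1, 1, 4, 4)) / 2
  expect_equal(ps$r[ps$participant == "p1" & ps$condition_a == "c1" &
                    ps$condition_b == "c1"],
               pearsonOracle(c(1, 2, 3, 4), tmpl11), tolerance = 1e-12)
  tmpl12 <- (c(5, 3, 2, 0) + c(4, 4, 1, 1)) / 2
  expect_equal(ps$r[ps$participant == "p1" & ps$condition_a == "c1" &
                    ps$condition_b == "c2"],
               pearsonOracle(c(1, 2, 3, 4), tmpl12), tolerance = 1e-12)
  # n participants x ordered condition pairs rows
  expect_equal(nrow(ps), 3 * 4)
  expect_equal(ps$z, fisherZ(ps$r))
})

test_that("identical templates give clamped r = 1 on the diagonal pairs", {
  tpl <- rbind(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1))
  r <- array(NA_real_, c(4, 2, 5))
  for (p in 1:4) for (j in 1:2) r[p, j, ] <- tpl[j, ]
  vps <- voxelPatternSet(r, rep("G", 4))
  ps <- lopoSimilarity(vps)
  same <- ps$condition_a == ps$condition_b
  expect_equal(ps$r[same], rep(1, sum(same)), tolerance = 1e-12)
  expect_true(all(is.finite(ps$z)))
  cross <- ps$r[!same]
  expect_equal(cross, rep(pearsonOracle(tpl[1, ], tpl[2, ]), length(cross)),
               tolerance = 1e-12)
})

test_that("the left-out participant never contributes to its own template", {
  vps <- toyPatterns()
  ps <- lopoSimilarity(vps)
  # perturb p1 wildly; rows for p2 and p3 involve templates that include
  # p1, so they move, but p1's own rows change only via p1's pattern
  r2 <- responses(vps)
  r2["p1", , ] <- r2["p1", , ] * 100 + 5
  ps2 <- lopoSimilarity(voxelPatternSet(r2, rep("G", 3),
                                        conditionInfo(vps)))
  # p1's correlations are unchanged: its pattern was only rescaled
  # (Pearson-invariant) and its template excludes p1
  expect_equal(ps2$r[ps2$participant == "p1"],
               ps$r[ps$participant == "p1"], tolerance = 1e-12)
  expect_error(lopoSimilarity(voxelPatternSet(responses(vps),
                                              c("G", "H", "H"))),
               "fewer than 2")
})

test_that("pure-noise patterns give near-zero mean LOPO correlation", {
  set.seed(55)
  rs <- replicate(100, {
    r <- array(rnorm(6 * 3 * 40), c(6, 3, 40))
    mean(lopoSimilarity(voxelPatternSet(r, rep("G", 6)))$r)
  })
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("race contrast averages the right pair types", {
  # hand-built records: 1 participant, 3 face conditions + object
  info <- data.frame(condition = c("A_d", "B_d", "W_d", "O_d"),
                     race = c("Asian", "Black", "White", "Object"),
                     arrangement = "different")
  r <- array(rnorm(2 * 4 * 6, sd = 0.01), c(2, 4, 6))
  for (j in 1:4) r[, j, ] <- r[, j, ] + matrix(rnorm(6), 2, 6, byrow = TRUE)
  vps <- voxelPatternSet(r, c("Asian", "Asian"), info)
  ps <- lopoSimilarity(vps)
  rc <- raceSimilarityContrast(ps)
  sameMean <- sapply(split(ps, ps$participant), function(d)
    mean(d$z[d$race_a == d$race_b & d$race_a != "Object"]))
  expect_equal(rc$same_race, unname(sameMean[rc$participant]),
               tolerance = 1e-12)
  # constructed constant case
  ps2 <- ps
  ps2$z <- ifelse(ps2$race_a == ps2$race_b, 1.0, 0.4)
  rc2 <- raceSimilarityContrast(ps2)
  expect_equal(rc2$same_race, rep(1.0, 2))
  expect_equal(rc2$different_race, rep(0.4, 2))
  # a missing pair type is detected
  expect_error(raceSimilarityContrast(ps[ps$race_a != "Black", ]),
               "missing condition pair")
})

test_that("planted template structure is recovered by the race contrast", {
  hits <- vapply(1:50, function(s) {
    vps <- simulateVoxelPatterns(patternGenConfig(nPerGroup = 6), seed = s)
    dc <- conditionInfo(vps)$condition[
      conditionInfo(vps)$arrangement == "different"]
    ps <- lopoSimilarity(normalizePatterns(vps, dc), dc)
    mean(raceSimilarityContrast(ps)$difference) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("own-race bias contrast reproduces hand arithmetic", {
  info <- data.frame(condition = c("A_d", "W_d"),
                     race = c("Asian", "White"),
                     arrangement = "different")
  ps <- expand.grid(participant = c("p1", "p2", "q1", "q2"),
                    condition_a = c("A_d", "W_d"),
                    stringsAsFactors = FALSE)
  ps$condition_b <- ps$condition_a
  ps$group <- ifelse(grepl("^p", ps$participant), "Asian", "White")
  ps$race_a <- ifelse(ps$condition_a == "A_d", "Asian", "White")
  ps$race_b <- ps$race_a
  # Asian participants: own (Asian faces) 1.2, other 0.8
  # White participants: own (White faces) 1.0, other 0.9
  ps$z <- ifelse(ps$group == "Asian",
                 ifelse(ps$race_a == "Asian", 1.2, 0.8),
                 ifelse(ps$race_a == "White", 1.0, 0.9))
  # zero-mean participant jitter, varying within group so the planned
  # paired t-tests have non-zero spread
  ps$z <- ps$z + c(0.01, -0.01, 0.02, -0.02, -0.01, 0.01, -0.02, 0.02)
  orb <- ownRaceBiasContrast(ps)
  expect_equal(orb$interaction, ((1.2 - 0.8) + (1.0 - 0.9)) / 2,
               tolerance = 1e-12)
  expect_equal(unname(orb$cells["Asian", "Asian"]), 1.2, tolerance = 0.011)
  expect_equal(nrow(orb$planned), 2)
})

test_that("own-race boost is recovered and the null is centred", {
  res <- vapply(1:40, function(s) {
    vps <- simulateVoxelPatterns(
      patternGenConfig(nPerGroup = 6, ownRaceBoost = 1), seed = s)
    dc <- conditionInfo(vps)$condition[
      conditionInfo(vps)$arrangement == "different"]
    ps <- lopoSimilarity(normalizePatterns(vps, dc), dc)
    ownRaceBiasContrast(ps)$interaction
  }, numeric(1))
  expect_gte(mean(res > 0), 0.9)
  null <- vapply(1:40, function(s) {
    vps <- simulateVoxelPatterns(
      patternGenConfig(nPerGroup = 6, ownRaceBoost = 0), seed = 500 + s)
    dc <- conditionInfo(vps)$condition[
      conditionInfo(vps)$arrangement == "different"]
    ps <- lopoSimilarity(normalizePatterns(vps, dc), dc)
    ownRaceBiasContrast(ps)$interaction
  }, numeric(1))
  expect_lt(abs(mean(null)), 0.05)
})

test_that("category contrast separates faces from an orthogonal object", {
  vps <- simulateVoxelPatterns(patternGenConfig(nPerGroup = 6,
                                                noiseSd = 0.2), seed = 3)
  dc <- conditionInfo(vps)$condition[
    conditionInfo(vps)$arrangement == "different"]
  ps <- lopoSimilarity(normalizePatterns(vps, dc), dc)
  cc <- categoryContrast(ps)
  expect_true(all(c("face_face", "face_object") %in% names(cc)))
  expect_gt(mean(cc$difference), 0)
  # direct averaging oracle
  tagged <- ps
  tagged$ff <- tagged$race_a != "Object" & tagged$race_b != "Object" &
    tagged$race_a != tagged$race_b
  tagged$fo <- xor(tagged$race_a == "Object", tagged$race_b == "Object")
  p1 <- tagged[tagged$participant == tagged$participant[1], ]
  expect_equal(cc$face_face[1], mean(p1$z[p1$ff]), tolerance = 1e-12)
  expect_equal(cc$face_object[1], mean(p1$z[p1$fo]), tolerance = 1e-12)
  # without an object condition the contrast is an error
  expect_error(categoryContrast(ps[ps$race_a != "Object" &
                                   ps$race_b != "Object", ]),
               "no object condition")
})

test_that("adaptation index is the different-minus-same ROI response", {
  info <- data.frame(condition = c("A_s", "A_d"), race = "Asian",
                     arrangement = c("same", "different"))
  r <- array(NA_real_, c(2, 2, 4))
  r[, 1, ] <- 1.5   # same
  r[, 2, ] <- 2.0   # different
  vps <- voxelPatternSet(r, c("G", "G"), info)
  ad <- adaptationIndex(vps, roi = "ffa")
  expect_equal(ad$adaptation, c(0.5, 0.5))
  expect_equal(ad$roi, c("ffa", "ffa"))
  r[, 1, ] <- 2.0
  expect_equal(adaptationIndex(voxelPatternSet(r, c("G", "G"),
                                               info))$adaptation,
               c(0, 0))
  infoSameOnly <- data.frame(condition = c("A_s", "A_s2"), race = "Asian",
                             arrangement = "same")
  expect_error(adaptationIndex(voxelPatternSet(r, c("G", "G"),
                                               infoSameOnly)),
               "lacks")
})

test_that("planted repetition suppression is recovered at scale", {
  est <- vapply(1:20, function(s) {
    vps <- simulateVoxelPatterns(
      patternGenConfig(nPerGroup = 28L, noiseSd = 0.3,
                       adaptationEffect = 0.4), seed = s)
    mean(adaptationIndex(vps)$adaptation)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.4), 0.05)
})
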