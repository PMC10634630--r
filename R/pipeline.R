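#' Default end-to-end pipeline configuration
#'
#' Collects every tunable of the synthetic end-to-end run: generator
#' configurations, permutation count, significance level and ROI
#' parameters. Every stochastic stage draws its seed deterministically
#' from the single top-level `seed`.
#'
#' @param seed master seed for the run.
#' @param featureCfg a [featureGenConfig()].
#' @param patternCfg a [patternGenConfig()].
#' @param nPerm permutations for the decoding tests.
#' @param alpha significance level for critical-r / rejection decisions.
#' @param behaviourSlope,behaviourGuess,behaviourN behaviour-generator
#'   settings (see [simulateBehaviour()]); behaviour is driven by the last
#'   layer's pair similarities.
#' @param roiTargetSize,roiZMin,roiConnectivity ROI growth settings.
#' @param statMapDims,statMapAmplitude,statMapWidth synthetic z-map blob
#'   settings.
#' @return A config list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L,
                           featureCfg = featureGenConfig(
                             identitiesPerRace = 20L, nFeatures = 100L,
                             raceMultipliers = c(1, 1, 1.5)),
                           patternCfg = patternGenConfig(
                             ownRaceBoost = 0.5, adaptationEffect = 0.4),
                           nPerm = 500L, alpha = 0.05,
                           behaviourSlope = 8, behaviourGuess = 0.1,
                           behaviourN = 70L,
                           roiTargetSize = 500L, roiZMin = 2.3,
                           roiConnectivity = 6L,
                           statMapDims = c(40L, 40L, 40L),
                           statMapAmplitude = 6, statMapWidth = 4) {
  stopIfNot(is.numeric(seed) && length(seed) == 1L,
            "an explicit scalar seed is required for the stochastic stages")
  structure(as.list(environment()), class = "pipelineConfig")
}

#' Run the full synthetic analysis pipeline
#'
#' Generates layered features and the matching-task pair table, builds the
#' per-layer similarity matrices, decodes race (per race, one-versus-rest)
#' and identity with maximum-statistic permutation tests, simulates and
#' correlates behaviour layer by layer, grows an ROI on a synthetic z-map,
#' and runs the LOPO MVPA contrasts and the adaptation analysis on
#' synthetic voxel patterns. All result tables are written as CSV (plus
#' NIfTI volumes for the map and mask) under `outDir`, together with a
#' `manifest.json` recording the configuration; outputs are a
#' deterministic function of the configuration.
#'
#' @param cfg a [pipelineConfig()].
#' @param outDir output directory (created if absent).
#' @return Invisibly, a list with all result tables and objects.
#' @export
runPipeline <- function(cfg = pipelineConfig(), outDir) {
  stopIfNot(inherits(cfg, "pipelineConfig"),
            "cfg must come from pipelineConfig()")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)

  # --- features, similarity, decoding -------------------------------------
  gen <- simulateLayerFeatures(cfg$featureCfg, seed = seed)
  smList <- lapply(gen$layers, buildSimilarityMatrix)
  races <- cfg$featureCfg$raceNames
  raceDec <- do.call(rbind, lapply(seq_along(races), function(i) {
    decodeRace(smList, races[i], nPerm = cfg$nPerm, seed = seed + i,
               nRacesTested = length(races))
  }))
  utils::write.csv(raceDec, file.path(outDir, "race_decoding.csv"),
                   row.names = FALSE)

  pairRByLayer <- vapply(smList, pairSimilarity, numeric(nrow(gen$pairs)),
                         pairs = gen$pairs)
  idDec <- do.call(rbind, lapply(seq_along(races), function(i) {
    sel <- gen$pairs$race == races[i]
    decodeIdentity(pairRByLayer[sel, , drop = FALSE],
                   gen$pairs$same_identity[sel], nPerm = cfg$nPerm,
                   seed = seed + 10L + i, nRacesTested = length(races),
                   race = races[i])
  }))
  utils::write.csv(idDec, file.path(outDir, "identity_decoding.csv"),
                   row.names = FALSE)

  wb <- withinBetweenDifference(smList[[length(smList)]])
  utils::write.csv(wb, file.path(outDir, "within_between_last_layer.csv"),
                   row.names = FALSE)

  # --- behaviour RSA ------------------------------------------------------
  lastLayer <- length(smList)
  judgements <- simulateBehaviour(pairRByLayer[, lastLayer],
                                  slope = cfg$behaviourSlope,
                                  guessRate = cfg$behaviourGuess,
                                  nParticipants = cfg$behaviourN,
                                  seed = seed + 100L)
  behPairs <- behaviourSimilarity(judgements, gen$pairs)
  writePairTable(behPairs, file.path(outDir, "behaviour_pairs.csv"))
  behRsa <- do.call(rbind, lapply(smList, layerBehaviourCorrelation,
                                  pairs = behPairs, alpha = cfg$alpha))
  utils::write.csv(behRsa, file.path(outDir, "behaviour_rsa.csv"),
                   row.names = FALSE)

  # --- ROI ---------------------------------------------------------------
  map <- simulateStatMap(cfg$statMapDims,
                         centres = matrix(cfg$statMapDims / 2, 1),
                         amplitudes = cfg$statMapAmplitude,
                         widths = cfg$statMapWidth,
                         noiseSd = 0.2, seed = seed + 200L)
  writeStatMap(map, file.path(outDir, "zmap.nii.gz"))
  roi <- floodFillROI(map, targetSize = cfg$roiTargetSize,
                      zMin = cfg$roiZMin,
                      connectivity = cfg$roiConnectivity)
  writeROIMask(roi, file.path(outDir, "roi.nii.gz"), map = map)
  utils::write.csv(roiPeakTable(list(blob = roi)),
                   file.path(outDir, "roi_peaks.csv"), row.names = FALSE)

  # --- MVPA + adaptation --------------------------------------------------
  vps <- simulateVoxelPatterns(cfg$patternCfg, seed = seed + 300L)
  writeVoxelPatterns(vps, file.path(outDir, "voxel_patterns.csv"))
  diffConds <- vps@conditionInfo$condition[
    vps@conditionInfo$arrangement == "different"]
  mv <- normalizePatterns(vps, diffConds)
  ps <- lopoSimilarity(mv, diffConds)
  utils::write.csv(ps, file.path(outDir, "lopo_similarity.csv"),
                   row.names = FALSE)
  raceContrast <- raceSimilarityContrast(ps)
  utils::write.csv(raceContrast, file.path(outDir, "race_contrast.csv"),
                   row.names = FALSE)
  orb <- ownRaceBiasContrast(ps)
  utils::write.csv(orb$perParticipant,
                   file.path(outDir, "own_race_bias.csv"), row.names = FALSE)
  utils::write.csv(orb$planned,
                   file.path(outDir, "own_race_bias_planned.csv"),
                   row.names = FALSE)
  catContrast <- categoryContrast(ps)
  utils::write.csv(catContrast, file.path(outDir, "category_contrast.csv"),
                   row.names = FALSE)
  adapt <- adaptationIndex(vps, roi = "blob")
  utils::write.csv(adapt, file.path(outDir, "adaptation.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "faceRSA",
    version = as.character(utils::packageVersion("faceRSA")),
    seed = seed,
    nPerm = cfg$nPerm,
    alpha = cfg$alpha,
    featureCfg = unclass(cfg$featureCfg),
    patternCfg = unclass(cfg$patternCfg),
    stageSeeds = list(features = seed,
                      racePerm = seed + seq_along(races),
                      identityPerm = seed + 10L + seq_along(races),
                      behaviour = seed + 100L, statMap = seed + 200L,
                      patterns = seed + 300L))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(pairs = gen$pairs, similarity = smList,
                 raceDecoding = raceDec, identityDecoding = idDec,
                 withinBetween = wb, behaviourPairs = behPairs,
                 behaviourRsa = behRsa, map = map, roi = roi,
                 patterns = vps, lopo = ps, raceContrast = raceContrast,
                 ownRaceBias = orb, categoryContrast = catContrast,
                 adaptation = adapt))
}
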