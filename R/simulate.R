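#' Configuration for the layered feature generator
#'
#' Describes a synthetic stimulus set and the layer-dependent signal
#' structure planted in its feature vectors. The defaults emulate the
#' study conditions the analyses target: 3 races x 90 identities x 2
#' images = 540 images over 16 layers, with race and identity signal
#' ramping up across layers (the pattern expected of a deep face network,
#' where category and identity information concentrate in later layers).
#'
#' @param nRaces number of race categories.
#' @param identitiesPerRace identities per race (2 images each).
#' @param imagesPerIdentity images per identity (>= 2 so that
#'   same-identity pairs exist).
#' @param nLayers number of layers to simulate.
#' @param nFeatures features per layer (scalar or per-layer vector).
#' @param raceSignalProfile per-layer race-signal strength in `[0, 1]`.
#' @param identitySignalProfile per-layer identity-signal strength.
#' @param noiseSd standard deviation of the isotropic feature noise.
#' @param raceMultipliers per-race signal multipliers (e.g. a larger value
#'   for White faces emulates a network trained predominantly on White
#'   faces).
#' @param raceNames race labels.
#' @return A validated config list of class `featureGenConfig`.
#' @export
featureGenConfig <- function(nRaces = 3L, identitiesPerRace = 90L,
                             imagesPerIdentity = 2L, nLayers = 16L,
                             nFeatures = 200L,
                             raceSignalProfile = seq(0, 1, length.out = nLayers),
                             identitySignalProfile = seq(0, 1, length.out = nLayers),
                             noiseSd = 1,
                             raceMultipliers = rep(1, nRaces),
                             raceNames = c("Asian", "Black", "White")[seq_len(nRaces)]) {
  stopIfNot(length(raceSignalProfile) == nLayers &&
            length(identitySignalProfile) == nLayers,
            "signal profiles must have one entry per layer")
  stopIfNot(all(raceSignalProfile >= 0) && all(identitySignalProfile >= 0),
            "signal profiles must be non-negative")
  stopIfNot(imagesPerIdentity >= 2L,
            "imagesPerIdentity must be >= 2 to define same-identity pairs")
  stopIfNot(identitiesPerRace >= 2L, "need at least 2 identities per race")
  stopIfNot(length(raceMultipliers) == nRaces,
            "one multiplier per race required")
  stopIfNot(length(raceNames) == nRaces, "one name per race required")
  if (length(nFeatures) == 1L) nFeatures <- rep(nFeatures, nLayers)
  stopIfNot(length(nFeatures) == nLayers && all(nFeatures >= 2),
            "nFeatures must give >= 2 features for every layer")
  structure(list(nRaces = as.integer(nRaces),
                 identitiesPerRace = as.integer(identitiesPerRace),
                 imagesPerIdentity = as.integer(imagesPerIdentity),
                 nLayers = as.integer(nLayers),
                 nFeatures = as.integer(nFeatures),
                 raceSignalProfile = raceSignalProfile,
                 identitySignalProfile = identitySignalProfile,
                 noiseSd = noiseSd,
                 raceMultipliers = raceMultipliers,
                 raceNames = raceNames),
            class = "featureGenConfig")
}

#' Simulate layered feature sets and the matching-task pair table
#'
#' Every image's feature vector in layer l is
#' `raceSignal[l] * m_race * mu_race + identitySignal[l] * mu_identity +
#' noise`, where the race and identity prototype vectors are drawn once
#' per layer from a standard normal. Alongside the features, a pair table
#' is emitted with half same-identity and half different-identity trials
#' per race (45 + 45 at the default 90 identities per race): the first
#' half of each race's identities supply the same-identity pairs (their
#' two images), the second half supply different-identity pairs (images of
#' neighbouring identities).
#'
#' @param cfg a [featureGenConfig()].
#' @param seed RNG seed; the output is a pure function of (cfg, seed).
#' @return List with `layers` (named list of [FeatureSet-class]) and
#'   `pairs` (a pair table, see [pairTable()]).
#' @export
simulateLayerFeatures <- function(cfg = featureGenConfig(), seed = 1L) {
  stopIfNot(inherits(cfg, "featureGenConfig"),
            "cfg must come from featureGenConfig()")
  nImg <- cfg$nRaces * cfg$identitiesPerRace * cfg$imagesPerIdentity
  race <- rep(cfg$raceNames, each = cfg$identitiesPerRace * cfg$imagesPerIdentity)
  identity <- rep(paste0(rep(cfg$raceNames, each = cfg$identitiesPerRace),
                         "_id", seq_len(cfg$identitiesPerRace)),
                  each = cfg$imagesPerIdentity)
  ids <- paste0(identity, "_im", seq_len(cfg$imagesPerIdentity))
  raceIdx <- match(race, cfg$raceNames)
  idIdx <- match(identity, unique(identity))
  nId <- length(unique(identity))

  layers <- withSeed(seed, {
    lapply(seq_len(cfg$nLayers), function(l) {
      f <- cfg$nFeatures[l]
      muRace <- matrix(stats::rnorm(cfg$nRaces * f), cfg$nRaces, f)
      muId <- matrix(stats::rnorm(nId * f), nId, f)
      a <- cfg$raceSignalProfile[l] * cfg$raceMultipliers[raceIdx] *
        muRace[raceIdx, , drop = FALSE] +
        cfg$identitySignalProfile[l] * muId[idIdx, , drop = FALSE] +
        cfg$noiseSd * matrix(stats::rnorm(nImg * f), nImg, f)
      featureSet(a, race, identity, ids, sprintf("layer%02d", l))
    })
  })
  names(layers) <- vapply(layers, layerName, character(1))

  # matching-task pairs: per race, floor(nIdentities/2) same-identity
  # trials from the first half of identities and as many different-identity
  # trials from the second half
  half <- cfg$identitiesPerRace %/% 2L
  pairs <- do.call(rbind, lapply(cfg$raceNames, function(rc) {
    idsOfRace <- paste0(rc, "_id", seq_len(cfg$identitiesPerRace))
    sameIds <- idsOfRace[seq_len(half)]
    diffIds <- idsOfRace[(half + 1):(2 * half)]
    nd <- length(diffIds)
    rbind(
      data.frame(image_id_a = paste0(sameIds, "_im1"),
                 image_id_b = paste0(sameIds, "_im2"),
                 race = rc, same_identity = TRUE, stringsAsFactors = FALSE),
      data.frame(image_id_a = paste0(diffIds, "_im1"),
                 image_id_b = paste0(diffIds[c(2:nd, 1)], "_im2"),
                 race = rc, same_identity = FALSE, stringsAsFactors = FALSE))
  }))
  pairs$trial_id <- seq_len(nrow(pairs))
  list(layers = layers, pairs = pairTable(pairs))
}

#' Simulate same/different judgements from pair similarities
#'
#' Each simulated participant judges every trial "same" with probability
#' `guessRate + (1 - 2 * guessRate) * plogis(slope * (r - mean(r)))`,
#' independently across participants and trials, so that behaviour tracks
#' the supplied pair similarities when `slope > 0` and is at guess level
#' when `slope = 0`.
#'
#' @param pairR pair similarities driving the judgements (typically from
#'   [pairSimilarity()] on a late layer).
#' @param slope sensitivity of the judgement to pair similarity (>= 0).
#' @param guessRate lapse/guessing floor in `[0, 0.5)`.
#' @param nParticipants number of simulated participants.
#' @param seed RNG seed.
#' @return Binary matrix, participants x trials (1 = judged "same").
#' @export
simulateBehaviour <- function(pairR, slope = 8, guessRate = 0.1,
                              nParticipants = 70L, seed = 1L) {
  stopIfNot(slope >= 0, "slope must be non-negative")
  stopIfNot(guessRate >= 0 && guessRate < 0.5, "guessRate must be in [0, 0.5)")
  p <- guessRate + (1 - 2 * guessRate) *
    stats::plogis(slope * (pairR - mean(pairR)))
  withSeed(seed, {
    matrix(stats::rbinom(nParticipants * length(pairR), 1L,
                         rep(p, each = nParticipants)),
           nParticipants, length(pairR))
  })
}

#' Configuration for the voxel-pattern generator
#'
#' Describes group-shared condition templates and the effects planted on
#' top of them. Each face condition's template mixes a global face
#' component, a race component and a condition-unique component so that
#' templates of the same race correlate at about `rhoWithin` and templates
#' of different races at about `rhoBetween`; the object template is
#' independent of the face templates. A participant's pattern for
#' condition c is `baseline + (1 + ownRaceBoost * own(p, c)) * T_c -
#' adaptationEffect * same(c) + noise`, where `own(p, c)` flags conditions
#' whose face race matches the participant's group and `same(c)` flags
#' Same-Identity arrangements (so `adaptationEffect` is the planted
#' repetition-suppression magnitude in response units).
#'
#' @param nPerGroup participants per group.
#' @param groups participant-group labels.
#' @param nVoxels voxels per pattern.
#' @param races face-race condition labels.
#' @param rhoWithin,rhoBetween within- and between-race template
#'   correlations (`rhoWithin >= rhoBetween >= 0`).
#' @param ownRaceBoost extra template weight for own-race conditions
#'   (the own-race consistency advantage; 0 = none).
#' @param adaptationEffect planted Same-vs-Different response attenuation.
#' @param noiseSd per-voxel response noise SD.
#' @param baseline mean response level added to every condition.
#' @param includeObject include a pareidolic-object condition.
#' @param includeAdaptation include Same-Identity arrangements (otherwise
#'   only Different-Identity conditions are generated).
#' @return A validated config list of class `patternGenConfig`.
#' @export
patternGenConfig <- function(nPerGroup = 12L, groups = c("Asian", "White"),
                             nVoxels = 300L,
                             races = c("Asian", "Black", "White"),
                             rhoWithin = 0.6, rhoBetween = 0.2,
                             ownRaceBoost = 0, adaptationEffect = 0,
                             noiseSd = 0.5, baseline = 1,
                             includeObject = TRUE,
                             includeAdaptation = TRUE) {
  stopIfNot(nPerGroup >= 2L, "need at least 2 participants per group")
  stopIfNot(rhoWithin >= rhoBetween && rhoBetween >= 0 && rhoWithin <= 1,
            "need 0 <= rhoBetween <= rhoWithin <= 1")
  stopIfNot(is.finite(ownRaceBoost) && is.finite(adaptationEffect),
            "effects must be finite")
  stopIfNot(all(groups %in% races),
            "every participant group must have a matching face race")
  structure(list(nPerGroup = as.integer(nPerGroup), groups = groups,
                 nVoxels = as.integer(nVoxels), races = races,
                 rhoWithin = rhoWithin, rhoBetween = rhoBetween,
                 ownRaceBoost = ownRaceBoost,
                 adaptationEffect = adaptationEffect,
                 noiseSd = noiseSd, baseline = baseline,
                 includeObject = includeObject,
                 includeAdaptation = includeAdaptation),
            class = "patternGenConfig")
}

#' Simulate a voxel-pattern set with planted group structure
#'
#' @param cfg a [patternGenConfig()].
#' @param seed RNG seed; output is a pure function of (cfg, seed).
#' @return A [VoxelPatternSet-class].
#' @export
simulateVoxelPatterns <- function(cfg = patternGenConfig(), seed = 1L) {
  stopIfNot(inherits(cfg, "patternGenConfig"),
            "cfg must come from patternGenConfig()")
  arrangements <- if (cfg$includeAdaptation) c("different", "same")
                  else "different"
  info <- expand.grid(race = cfg$races, arrangement = arrangements,
                      stringsAsFactors = FALSE)
  if (cfg$includeObject)
    info <- rbind(info, data.frame(race = "Object",
                                   arrangement = arrangements))
  info$condition <- paste(info$race, info$arrangement, sep = "_")
  info <- info[, c("condition", "race", "arrangement")]
  nC <- nrow(info)
  nP <- cfg$nPerGroup * length(cfg$groups)
  grp <- rep(cfg$groups, each = cfg$nPerGroup)
  V <- cfg$nVoxels

  withSeed(seed, {
    g <- stats::rnorm(V)                      # global face component
    raceComp <- lapply(unique(info$race), function(r) stats::rnorm(V))
    names(raceComp) <- unique(info$race)
    # templates shared between the two arrangements of a race: the same
    # faces are shown, only their identity pairing differs
    uniqComp <- lapply(unique(info$race), function(r) stats::rnorm(V))
    names(uniqComp) <- unique(info$race)
    tmpl <- lapply(seq_len(nC), function(j) {
      r <- info$race[j]
      if (r == "Object")
        uniqComp[[r]]  # object template independent of the face templates
      else
        sqrt(cfg$rhoBetween) * g +
          sqrt(cfg$rhoWithin - cfg$rhoBetween) * raceComp[[r]] +
          sqrt(1 - cfg$rhoWithin) * uniqComp[[r]]
    })
    resp <- array(NA_real_, c(nP, nC, V),
                  dimnames = list(paste0(rep(cfg$groups, each = cfg$nPerGroup),
                                         "_p",
                                         rep(seq_len(cfg$nPerGroup),
                                             length(cfg$groups))),
                                  info$condition, NULL))
    for (p in seq_len(nP)) {
      for (j in seq_len(nC)) {
        own <- !is.na(info$race[j]) && info$race[j] == grp[p]
        amp <- 1 + cfg$ownRaceBoost * own
        shift <- cfg$baseline -
          cfg$adaptationEffect * (info$arrangement[j] == "same")
        resp[p, j, ] <- shift + amp * tmpl[[j]] +
          cfg$noiseSd * stats::rnorm(V)
      }
    }
    voxelPatternSet(resp, grp, info)
  })
}

#' Simulate a statistical map as Gaussian blobs plus noise
#'
#' The map is a sum of isotropic Gaussian bumps
#' `amplitude * exp(-d^2 / (2 * width^2))` centred at the given voxels,
#' plus optional white noise — a stand-in for a z-statistic contrast map
#' with focal activations, used to exercise peak finding and flood-fill
#' ROI growth.
#'
#' @param dims grid dimensions (length 3).
#' @param centres matrix of blob centres (one row per blob, 1-based voxel
#'   indices).
#' @param amplitudes,widths per-blob peak height and Gaussian width (in
#'   voxels).
#' @param noiseSd SD of additive Gaussian noise (0 = noiseless).
#' @param seed RNG seed (used only when `noiseSd > 0`).
#' @param affine optional voxel-to-world affine (see [statMap()]).
#' @return A [StatMap-class].
#' @export
simulateStatMap <- function(dims = c(40L, 40L, 40L),
                            centres = matrix(dims / 2, nrow = 1),
                            amplitudes = 6, widths = 3,
                            noiseSd = 0, seed = 1L, affine = NULL) {
  stopIfNot(length(dims) == 3L, "dims must have length 3")
  centres <- matrix(centres, ncol = 3)
  stopIfNot(all(centres >= 1 & centres <= matrix(dims, nrow(centres), 3,
                                                 byrow = TRUE)),
            "blob centres must lie inside the grid")
  amplitudes <- rep_len(amplitudes, nrow(centres))
  widths <- rep_len(widths, nrow(centres))
  ix <- arrayInd(seq_len(prod(dims)), dims)
  v <- numeric(prod(dims))
  for (b in seq_len(nrow(centres))) {
    d2 <- (ix[, 1] - centres[b, 1])^2 + (ix[, 2] - centres[b, 2])^2 +
      (ix[, 3] - centres[b, 3])^2
    v <- v + amplitudes[b] * exp(-d2 / (2 * widths[b]^2))
  }
  if (noiseSd > 0)
    v <- v + withSeed(seed, stats::rnorm(length(v), sd = noiseSd))
  statMap(array(v, dims), affine)
}
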