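#' Per-image average correlation to a target race
#'
#' For every image in the matrix (whatever its own race), computes the mean
#' Pearson correlation to the images of the target race, excluding any
#' comparison of an image with itself. These scores are the decision
#' variable for one-versus-rest race decoding.
#'
#' @param sm a [SimilarityMatrix-class].
#' @param targetRace race label defining the target class.
#' @return Named numeric vector, one score per image.
#' @export
withinClassScore <- function(sm, targetRace) {
  stopIfNot(is(sm, "SimilarityMatrix"), "sm must be a SimilarityMatrix")
  m <- sm@raceLabels == targetRace
  stopIfNot(any(m), "target race '%s' not present among labels", targetRace)
  stopIfNot(sum(m) >= 2L,
            "target race '%s' has a single image; scores undefined", targetRace)
  v <- sm@values
  k <- sum(m)
  # self-exclusion: subtract the unit diagonal for target-race images
  scores <- as.vector(v %*% m - m) / (k - m)
  names(scores) <- sm@imageIds
  scores
}

#' ROC area under the curve from scores and class labels
#'
#' The AUC is computed as the Mann-Whitney probability that a randomly
#' chosen positive score exceeds a randomly chosen negative score, with
#' ties counted as 1/2. Scores are rounded to 12 decimal places before
#' ranking so that algebraically equal scores (which can differ by a few
#' ulps depending on the order of floating-point accumulation) tie
#' exactly.
#'
#' @param scores numeric decision-variable scores.
#' @param positive logical vector marking the positive class.
#' @return AUC in `[0, 1]`.
#' @examples
#' aucFromScores(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
#' @export
aucFromScores <- function(scores, positive) {
  stopIfNot(length(scores) == length(positive),
            "scores and positive must have equal length")
  positive <- as.logical(positive)
  p <- sum(positive)
  n <- sum(!positive)
  stopIfNot(p >= 1L && n >= 1L,
            "need at least one positive and one negative score")
  r <- rank(round(scores, 12), ties.method = "average")
  (sum(r[positive]) - p * (p + 1) / 2) / (p * n)
}

#' Convert ROC AUC to d-prime
#'
#' Uses the signal-detection relation `d' = sqrt(2) * qnorm(AUC)`. An AUC
#' of exactly 0 or 1 maps to an infinite d', so the AUC is first clipped
#' into `[eps, 1 - eps]`; when the class sizes are supplied the clip is
#' `eps = 1 / (2 * nPositive * nNegative)`, half the smallest AUC step the
#' data can resolve. The clip is symmetric, so the antisymmetry
#' `d'(1 - a) = -d'(a)` is preserved.
#'
#' @param auc AUC value(s) in `[0, 1]`.
#' @param nPositive,nNegative optional class sizes used to set the clip.
#' @param eps clip width when class sizes are not given.
#' @return d-prime value(s).
#' @examples
#' aucToDprime(0.5)   # 0
#' aucToDprime(0.75)  # ~0.954
#' @export
aucToDprime <- function(auc, nPositive = NULL, nNegative = NULL, eps = 1e-6) {
  if (!is.null(nPositive) && !is.null(nNegative))
    eps <- 1 / (2 * nPositive * nNegative)
  sqrt(2) * stats::qnorm(pmin(pmax(auc, eps), 1 - eps))
}

#' One-versus-rest race decoding from a similarity matrix
#'
#' Scores every image by its average correlation to the target race
#' ([withinClassScore()]), treats target-race images as the positive class,
#' and summarises separability as ROC AUC and d-prime.
#'
#' @param sm a [SimilarityMatrix-class].
#' @param targetRace the race decoded against the rest.
#' @return One-row data.frame: `layer`, `target`, `auc`, `dprime`.
#' @seealso [decodeRace()] for the multi-layer permutation test.
#' @export
raceDecoding <- function(sm, targetRace) {
  scores <- withinClassScore(sm, targetRace)
  pos <- sm@raceLabels == targetRace
  auc <- aucFromScores(scores, pos)
  data.frame(layer = sm@layerName, target = as.character(targetRace),
             auc = auc,
             dprime = aucToDprime(auc, sum(pos), sum(!pos)),
             stringsAsFactors = FALSE)
}

#' Same- versus different-identity decoding from pair correlations
#'
#' Same-identity pairs form the positive class; separability of the pair
#' correlations is summarised as ROC AUC and d-prime.
#'
#' @param pairR numeric vector of pair correlations (one per trial).
#' @param sameIdentity logical vector marking same-identity trials.
#' @param layer,race labels carried into the result.
#' @return One-row data.frame: `layer`, `target`, `auc`, `dprime`.
#' @export
identityDecoding <- function(pairR, sameIdentity, layer = "layer",
                             race = "all") {
  sameIdentity <- as.logical(sameIdentity)
  stopIfNot(any(sameIdentity) && any(!sameIdentity),
            "need both same- and different-identity pairs")
  auc <- aucFromScores(pairR, sameIdentity)
  data.frame(layer = layer, target = as.character(race), auc = auc,
             dprime = aucToDprime(auc, sum(sameIdentity), sum(!sameIdentity)),
             stringsAsFactors = FALSE)
}

# Shared maximum-statistic machinery: given observed per-layer d' and the
# permutation null maxima, return the one-tailed FWER-corrected p-values
# using the add-one estimator with ">=" exceedance.
maxStatP <- function(observed, nullMax) {
  vapply(observed, function(o) (1 + sum(nullMax >= o)) / (length(nullMax) + 1),
         numeric(1))
}

# AUC for every column of a score matrix, each column with its own positive
# mask (columns of posMask). Rank-based Mann-Whitney with midrank ties.
aucColumns <- function(scoreMat, posMask) {
  p <- colSums(posMask)
  n <- nrow(scoreMat) - p
  ranks <- apply(round(scoreMat, 12), 2L, rank, ties.method = "average")
  (colSums(ranks * posMask) - p * (p + 1) / 2) / (p * n)
}

#' Race decoding across layers with maximum-statistic permutation test
#'
#' Runs one-versus-rest race decoding on every layer's similarity matrix
#' and controls the familywise error rate over layers with a
#' maximum-statistic permutation test: on each permutation the race labels
#' are permuted once and applied identically to every layer, the d' is
#' recomputed per layer (scores and class membership both refreshed under
#' the permuted labels), and the maximum d' over layers is recorded. The
#' one-tailed FWER p-value for a layer is `(1 + #{max >= observed}) /
#' (nPerm + 1)`; `p_bonferroni` further multiplies by the number of races
#' tested (capped at 1).
#'
#' @param smList list of [SimilarityMatrix-class] objects (the layers), all
#'   over the same images in the same order.
#' @param targetRace race decoded one-versus-rest.
#' @param nPerm number of permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @param nRacesTested Bonferroni factor for testing each race in turn
#'   (default 3).
#' @return data.frame with one row per layer: `layer`, `target`, `auc`,
#'   `dprime`, `p_fwer`, `p_bonferroni`.
#' @export
decodeRace <- function(smList, targetRace, nPerm = 10000L, seed = NULL,
                       nRacesTested = 3L) {
  stopIfNot(length(smList) >= 1L, "smList must contain at least one layer")
  stopIfNot(nPerm >= 1L, "nPerm must be >= 1")
  ids <- smList[[1]]@imageIds
  labels <- smList[[1]]@raceLabels
  for (sm in smList) {
    stopIfNot(identical(sm@imageIds, ids) && identical(sm@raceLabels, labels),
              "all layers must share the same images and labels")
  }
  pos <- labels == targetRace
  stopIfNot(sum(pos) >= 2L && sum(!pos) >= 1L,
            "degenerate labels for target race '%s'", targetRace)
  nImg <- length(labels)
  k <- sum(pos)
  eps <- 1 / (2 * k * (nImg - k))

  # permuted positive-class masks, shared across layers
  permMask <- withSeed(seed, {
    vapply(seq_len(nPerm), function(b) as.numeric(sample(pos)),
           numeric(nImg))
  })

  obs <- numeric(length(smList))
  nullMat <- matrix(NA_real_, nPerm, length(smList))
  for (l in seq_along(smList)) {
    v <- smList[[l]]@values
    # scores_i = (sum_j v_ij m_j - m_i) / (k - m_i), unit diagonal assumed
    scores <- (v %*% permMask - permMask) / (k - permMask)
    nullMat[, l] <- sqrt(2) * stats::qnorm(
      pmin(pmax(aucColumns(scores, permMask), eps), 1 - eps))
    obsScores <- as.vector(v %*% pos - pos) / (k - pos)
    obs[l] <- sqrt(2) * stats::qnorm(
      pmin(pmax(aucFromScores(obsScores, pos), eps), 1 - eps))
  }
  nullMax <- apply(nullMat, 1L, max)
  pF <- maxStatP(obs, nullMax)
  data.frame(
    layer = vapply(smList, slot, character(1), "layerName"),
    target = as.character(targetRace),
    auc = vapply(seq_along(smList), function(l) {
      v <- smList[[l]]@values
      s <- as.vector(v %*% pos - pos) / (k - pos)
      aucFromScores(s, pos)
    }, numeric(1)),
    dprime = obs,
    p_fwer = pF,
    p_bonferroni = pmin(1, nRacesTested * pF),
    stringsAsFactors = FALSE)
}

#' Identity decoding across layers with maximum-statistic permutation test
#'
#' Decodes same- versus different-identity pairs from their correlations in
#' every layer, and controls the familywise error rate over layers by
#' permuting the same/different class labels identically across layers and
#' recording the maximum d' per permutation.
#'
#' @param pairRByLayer numeric matrix of pair correlations, layers in
#'   columns (one row per trial), or a list of per-layer vectors.
#' @param sameIdentity logical vector, one flag per trial.
#' @param nPerm,seed,nRacesTested as in [decodeRace()].
#' @param layerNames optional layer names (default from column names).
#' @param race label carried into the result.
#' @return data.frame with one row per layer: `layer`, `target`, `auc`,
#'   `dprime`, `p_fwer`, `p_bonferroni`.
#' @export
decodeIdentity <- function(pairRByLayer, sameIdentity, nPerm = 10000L,
                           seed = NULL, nRacesTested = 3L,
                           layerNames = NULL, race = "all") {
  if (is.list(pairRByLayer) && !is.matrix(pairRByLayer))
    pairRByLayer <- do.call(cbind, pairRByLayer)
  pairRByLayer <- as.matrix(pairRByLayer)
  sameIdentity <- as.logical(sameIdentity)
  stopIfNot(nrow(pairRByLayer) == length(sameIdentity),
            "one same/different flag per trial is required")
  p <- sum(sameIdentity)
  n <- sum(!sameIdentity)
  stopIfNot(p >= 1L && n >= 1L, "degenerate labels: both classes required")
  if (is.null(layerNames)) {
    layerNames <- colnames(pairRByLayer)
    if (is.null(layerNames))
      layerNames <- paste0("layer", seq_len(ncol(pairRByLayer)))
  }
  eps <- 1 / (2 * p * n)
  nTrial <- length(sameIdentity)

  permMask <- withSeed(seed, {
    vapply(seq_len(nPerm), function(b) as.numeric(sample(sameIdentity)),
           numeric(nTrial))
  })
  # pair correlations are fixed; only the class labels move, so the ranks
  # can be computed once per layer
  nullMat <- matrix(NA_real_, nPerm, ncol(pairRByLayer))
  obs <- numeric(ncol(pairRByLayer))
  for (l in seq_len(ncol(pairRByLayer))) {
    rk <- rank(pairRByLayer[, l], ties.method = "average")
    aucNull <- (colSums(rk * permMask) - p * (p + 1) / 2) / (p * n)
    nullMat[, l] <- sqrt(2) * stats::qnorm(pmin(pmax(aucNull, eps), 1 - eps))
    aucObs <- (sum(rk[sameIdentity]) - p * (p + 1) / 2) / (p * n)
    obs[l] <- sqrt(2) * stats::qnorm(pmin(pmax(aucObs, eps), 1 - eps))
  }
  nullMax <- apply(nullMat, 1L, max)
  pF <- maxStatP(obs, nullMax)
  aucObsAll <- vapply(seq_len(ncol(pairRByLayer)), function(l)
    aucFromScores(pairRByLayer[, l], sameIdentity), numeric(1))
  data.frame(layer = layerNames, target = as.character(race),
             auc = aucObsAll, dprime = obs, p_fwer = pF,
             p_bonferroni = pmin(1, nRacesTested * pF),
             stringsAsFactors = FALSE)
}

#' Per-image within-race minus between-race correlation
#'
#' For each image: the mean correlation to other images of its own race
#' (self excluded) minus the mean correlation to all images of the other
#' races.
#'
#' @param sm a [SimilarityMatrix-class].
#' @return data.frame with columns `image_id`, `race`, `within_mean`,
#'   `between_mean`, `difference`.
#' @export
withinBetweenDifference <- function(sm) {
  stopIfNot(is(sm, "SimilarityMatrix"), "sm must be a SimilarityMatrix")
  races <- levels(droplevels(sm@raceLabels))
  counts <- table(sm@raceLabels)[races]
  single <- names(counts)[counts < 2]
  if (length(single))
    stop(sprintf("race(s) with a single image: %s",
                 paste(single, collapse = ", ")), call. = FALSE)
  v <- sm@values
  n <- nrow(v)
  within <- between <- numeric(n)
  for (r in races) {
    own <- sm@raceLabels == r
    idx <- which(own)
    kw <- sum(own)
    within[idx] <- (v[idx, own, drop = FALSE] %*% rep(1, kw) - 1) / (kw - 1)
    between[idx] <- v[idx, !own, drop = FALSE] %*% rep(1, n - kw) / (n - kw)
  }
  data.frame(image_id = sm@imageIds, race = as.character(sm@raceLabels),
             within_mean = within, between_mean = between,
             difference = within - between, stringsAsFactors = FALSE)
}

#' One-tailed t contrasts per cell with Holm correction
#'
#' Runs a one-tailed t-test in each cell (for instance each layer-by-race
#' combination) and applies the Holm step-down correction across cells.
#' Cells are paired (e.g. within-race vs between-race values on the same
#' images) or independent (e.g. same- vs different-identity pairs).
#'
#' @param cells named list; each element a list with numeric vectors `a`
#'   and `b`. The alternative is `a > b`.
#' @param paired logical: paired or independent-samples t-tests.
#' @return data.frame with `cell`, `t`, `df`, `p_raw`, `p_holm`,
#'   `cohens_d`.
#' @export
contrastTHolm <- function(cells, paired = TRUE) {
  stopIfNot(is.list(cells) && length(cells) >= 1L,
            "cells must be a non-empty list")
  nm <- names(cells)
  if (is.null(nm)) nm <- paste0("cell", seq_along(cells))
  res <- lapply(seq_along(cells), function(i) {
    a <- cells[[i]]$a; b <- cells[[i]]$b
    stopIfNot(!is.null(a) && !is.null(b),
              "cell '%s' must contain vectors a and b", nm[i])
    nmin <- if (paired) length(a) else min(length(a), length(b))
    stopIfNot(nmin >= 3L, "cell '%s' has n < 3", nm[i])
    tt <- tryCatch(
      stats::t.test(a, b, paired = paired, alternative = "greater",
                    var.equal = !paired),
      error = function(e)
        stop(sprintf("cell '%s': %s", nm[i], conditionMessage(e)),
             call. = FALSE))
    c(t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, d = cohensD(a, b, paired = paired))
  })
  res <- do.call(rbind, res)
  data.frame(cell = nm, t = res[, "t"], df = res[, "df"],
             p_raw = res[, "p"],
             p_holm = stats::p.adjust(res[, "p"], method = "holm"),
             cohens_d = res[, "d"], stringsAsFactors = FALSE)
}

#' Cohen's d effect size
#'
#' Paired: mean of the differences divided by their standard deviation.
#' Independent: difference in means divided by the pooled standard
#' deviation.
#'
#' @param a,b numeric vectors.
#' @param paired logical.
#' @return Cohen's d.
#' @examples
#' cohensD(c(2, 3, 4), c(1, 1, 1), paired = TRUE)  # 2
#' @export
cohensD <- function(a, b, paired = FALSE) {
  if (paired) {
    stopIfNot(length(a) == length(b), "paired vectors must match in length")
    stopIfNot(length(a) >= 2L, "need n >= 2")
    d <- a - b
    s <- stats::sd(d)
    stopIfNot(s > 0, "zero standard deviation of the paired differences")
    mean(d) / s
  } else {
    stopIfNot(length(a) >= 2L && length(b) >= 2L, "need n >= 2 per group")
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
    stopIfNot(sp > 0, "zero pooled standard deviation")
    (mean(a) - mean(b)) / sp
  }
}
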