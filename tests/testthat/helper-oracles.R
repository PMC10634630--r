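# Independent oracles used across the test files. Each is a deliberately
# naive implementation kept separate from the package's code paths.

# Two-pass Pearson correlation from first principles.
pearsonOracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Exhaustive pairwise-comparison AUC with explicit 1/2 tie credit.
aucOracle <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  total <- 0
  for (a in sp) for (b in sn)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(sp) * length(sn))
}

# Per-image mean correlation to a target class, written as explicit loops.
withinScoreOracle <- function(values, labels, target) {
  n <- nrow(values)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0; k <- 0
    for (j in seq_len(n)) {
      if (j != i && labels[j] == target) {
        acc <- acc + values[i, j]; k <- k + 1
      }
    }
    out[i] <- acc / k
  }
  out
}

# Holm step-down adjustment by direct enumeration of the step-down rule.
holmOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (k in seq_len(m)) {
    running <- max(running, (m - k + 1) * p[o[k]])
    adj[o[k]] <- min(1, running)
  }
  adj
}

# Breadth-first connected component of a logical 3-D mask from a start
# voxel, under face (6) connectivity.
connectedComponentOracle <- function(mask, start) {
  dims <- dim(mask)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  seen <- array(FALSE, dims)
  queue <- list(start)
  seen[start[1], start[2], start[3]] <- TRUE
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (k in seq_len(nrow(offs))) {
      nb <- cur + offs[k, ]
      if (all(nb >= 1) && all(nb <= dims) &&
          mask[nb[1], nb[2], nb[3]] && !seen[nb[1], nb[2], nb[3]]) {
        seen[nb[1], nb[2], nb[3]] <- TRUE
        queue[[length(queue) + 1]] <- nb
      }
    }
  }
  seen
}

# A block-structured similarity matrix: within-class r = rWithin,
# between-class r = rBetween, unit diagonal.
blockSimilarityMatrix <- function(classSizes, rWithin = 0.8, rBetween = 0.2,
                                  layer = "block") {
  labels <- rep(names(classSizes), classSizes)
  n <- length(labels)
  v <- matrix(rBetween, n, n)
  for (cl in names(classSizes)) {
    idx <- which(labels == cl)
    v[idx, idx] <- rWithin
  }
  diag(v) <- 1
  ids <- paste0("img", seq_len(n))
  dimnames(v) <- list(ids, ids)
  new("SimilarityMatrix", layerName = layer, values = v,
      raceLabels = factor(labels), identityLabels = factor(ids),
      imageIds = ids)
}

# A random valid similarity matrix built from random features.
randomSimilarityMatrix <- function(nPerRace = 4, nRaces = 3, nFeatures = 20,
                                   seed = 1) {
  set.seed(seed)
  n <- nPerRace * nRaces
  fs <- featureSet(matrix(rnorm(n * nFeatures), n, nFeatures),
                   raceLabels = rep(paste0("race", seq_len(nRaces)),
                                    each = nPerRace),
                   identityLabels = paste0("id", seq_len(n)))
  buildSimilarityMatrix(fs)
}
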