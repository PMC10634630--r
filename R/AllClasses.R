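#' @import methods
NULL

#' FeatureSet: labelled feature vectors for a set of face images
#'
#' A `FeatureSet` holds one layer's activations as an images-by-features
#' matrix together with the race and identity label of every image. It is
#' the unit of input for similarity-matrix construction: a deep network
#' yields one `FeatureSet` per layer, each row the flattened activation
#' tensor of one image.
#'
#' @slot layerName single string naming the layer (e.g. `"fc6"`).
#' @slot activations numeric matrix, one row per image, one column per
#'   feature. At least 2 images and 2 features (Pearson correlation is
#'   undefined for constant or length-1 vectors).
#' @slot raceLabels factor of length `nrow(activations)`.
#' @slot identityLabels factor of length `nrow(activations)`.
#' @slot imageIds character vector of unique image identifiers.
#'
#' @seealso [featureSet()], [flattenFeatures()], [buildSimilarityMatrix()]
#' @exportClass FeatureSet
setClass("FeatureSet",
  representation(
    layerName = "character",
    activations = "matrix",
    raceLabels = "factor",
    identityLabels = "factor",
    imageIds = "character"
  )
)

setValidity("FeatureSet", function(object) {
  n <- nrow(object@activations)
  msgs <- character()
  if (length(object@layerName) != 1L)
    msgs <- c(msgs, "layerName must be a single string")
  if (n < 2L)
    msgs <- c(msgs, "at least 2 images are required")
  if (ncol(object@activations) < 2L)
    msgs <- c(msgs, "at least 2 features per image are required")
  if (!is.numeric(object@activations))
    msgs <- c(msgs, "activations must be numeric")
  if (length(object@raceLabels) != n)
    msgs <- c(msgs, "raceLabels length must equal the number of images")
  if (length(object@identityLabels) != n)
    msgs <- c(msgs, "identityLabels length must equal the number of images")
  if (length(object@imageIds) != n)
    msgs <- c(msgs, "imageIds length must equal the number of images")
  if (anyDuplicated(object@imageIds))
    msgs <- c(msgs, "imageIds must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureSet
#'
#' @param activations numeric matrix (images x features).
#' @param raceLabels,identityLabels per-image labels (coerced to factor).
#' @param imageIds unique per-image identifiers; defaults to the matrix
#'   rownames, or `img1, img2, ...` if absent.
#' @param layerName name of the layer the activations come from.
#' @return A [FeatureSet-class] object.
#' @examples
#' fs <- featureSet(matrix(rnorm(12), 3, 4),
#'                  raceLabels = c("A", "A", "B"),
#'                  identityLabels = c("i1", "i2", "i3"))
#' @export
featureSet <- function(activations, raceLabels, identityLabels,
                       imageIds = NULL, layerName = "layer") {
  activations <- as.matrix(activations)
  if (is.null(imageIds)) {
    imageIds <- rownames(activations)
    if (is.null(imageIds))
      imageIds <- paste0("img", seq_len(nrow(activations)))
  }
  rownames(activations) <- imageIds
  new("FeatureSet",
      layerName = as.character(layerName),
      activations = activations,
      raceLabels = as.factor(raceLabels),
      identityLabels = as.factor(identityLabels),
      imageIds = as.character(imageIds))
}

#' SimilarityMatrix: pairwise Pearson correlations between image features
#'
#' Symmetric image-by-image matrix of Pearson correlations between feature
#' vectors, with the image labels carried along. The diagonal is exactly 1.
#'
#' @slot layerName layer the matrix was computed from.
#' @slot values numeric `n x n` correlation matrix.
#' @slot raceLabels,identityLabels per-image factors.
#' @slot imageIds unique image identifiers (also the dimnames of `values`).
#' @seealso [buildSimilarityMatrix()], [pairSimilarity()]
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(
    layerName = "character",
    values = "matrix",
    raceLabels = "factor",
    identityLabels = "factor",
    imageIds = "character"
  )
)

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  n <- nrow(v)
  msgs <- character()
  if (n != ncol(v)) msgs <- c(msgs, "values must be square")
  if (length(object@imageIds) != n)
    msgs <- c(msgs, "imageIds length must match matrix dimension")
  if (length(object@raceLabels) != n || length(object@identityLabels) != n)
    msgs <- c(msgs, "label lengths must match matrix dimension")
  if (n > 0) {
    if (max(abs(v - t(v))) > 1e-8)
      msgs <- c(msgs, "values must be symmetric")
    if (any(diag(v) != 1))
      msgs <- c(msgs, "diagonal must be exactly 1")
    off <- v[row(v) != col(v)]
    if (length(off) && (min(off) < -1 - 1e-12 || max(off) > 1 + 1e-12))
      msgs <- c(msgs, "off-diagonal entries must lie in [-1, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' VoxelPatternSet: per-participant, per-condition voxel response patterns
#'
#' Holds an array of GLM parameter estimates (participants x conditions x
#' voxels), the participant group (e.g. participant race) and a condition
#' table describing each condition's face race and same/different-identity
#' arrangement. This is the input to the leave-one-participant-out MVPA and
#' the adaptation analysis.
#'
#' @slot responses numeric 3-D array `[participants, conditions, voxels]`.
#' @slot participantGroup factor of length `nParticipants`.
#' @slot conditionInfo data.frame with one row per condition and columns
#'   `condition` (matching `dimnames(responses)[[2]]`), `race` and
#'   `arrangement` (`"same"`, `"different"`, or `NA`).
#' @seealso [voxelPatternSet()], [lopoSimilarity()], [adaptationIndex()]
#' @exportClass VoxelPatternSet
setClass("VoxelPatternSet",
  representation(
    responses = "array",
    participantGroup = "factor",
    conditionInfo = "data.frame"
  )
)

setValidity("VoxelPatternSet", function(object) {
  d <- dim(object@responses)
  msgs <- character()
  if (length(d) != 3L)
    msgs <- c(msgs, "responses must be a 3-D array [participants, conditions, voxels]")
  else {
    if (length(object@participantGroup) != d[1])
      msgs <- c(msgs, "participantGroup length must equal the number of participants")
    if (d[2] < 2L)
      msgs <- c(msgs, "at least 2 conditions are required")
    if (nrow(object@conditionInfo) != d[2])
      msgs <- c(msgs, "conditionInfo must have one row per condition")
  }
  req <- c("condition", "race", "arrangement")
  if (!all(req %in% names(object@conditionInfo)))
    msgs <- c(msgs, sprintf("conditionInfo must have columns %s",
                            paste(req, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a VoxelPatternSet
#'
#' @param responses 3-D numeric array `[participants, conditions, voxels]`.
#' @param participantGroup per-participant group labels (coerced to factor).
#' @param conditionInfo data.frame with columns `condition`, `race`,
#'   `arrangement`; defaults to conditions named from the array dimnames
#'   with unknown race/arrangement.
#' @return A [VoxelPatternSet-class] object.
#' @export
voxelPatternSet <- function(responses, participantGroup, conditionInfo = NULL) {
  if (is.null(dimnames(responses)[[2]])) {
    dn <- dimnames(responses)
    if (is.null(dn)) dn <- vector("list", 3)
    dn[[2]] <- paste0("cond", seq_len(dim(responses)[2]))
    dimnames(responses) <- dn
  }
  if (is.null(conditionInfo)) {
    conditionInfo <- data.frame(condition = dimnames(responses)[[2]],
                                race = NA_character_,
                                arrangement = NA_character_,
                                stringsAsFactors = FALSE)
  }
  new("VoxelPatternSet",
      responses = responses,
      participantGroup = as.factor(participantGroup),
      conditionInfo = conditionInfo)
}

#' StatMap: a 3-D statistical volume with a voxel-to-world affine
#'
#' A z-statistic volume (for instance a faces-greater-than-scenes contrast)
#' on a regular voxel grid, with a 4x4 affine mapping 0-based voxel indices
#' to world millimetre coordinates.
#'
#' @slot values numeric 3-D array of statistics.
#' @slot affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @seealso [statMap()], [findPeak()], [floodFillROI()]
#' @exportClass StatMap
setClass("StatMap",
  representation(values = "array", affine = "matrix")
)

setValidity("StatMap", function(object) {
  msgs <- character()
  if (length(dim(object@values)) != 3L)
    msgs <- c(msgs, "values must be a 3-D array")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msgs <- c(msgs, "affine must be a 4x4 matrix")
  else if (abs(det(object@affine)) < .Machine$double.eps)
    msgs <- c(msgs, "affine must be invertible")
  if (length(msgs)) msgs else TRUE
})

#' Construct a StatMap
#'
#' @param values 3-D numeric array.
#' @param affine 4x4 voxel-to-world affine; default identity orientation
#'   with the world origin at the array centre.
#' @return A [StatMap-class] object.
#' @export
statMap <- function(values, affine = NULL) {
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1:3, 4] <- -(dim(values) - 1) / 2
  }
  new("StatMap", values = values, affine = affine)
}

#' ROIMask: a connected boolean region of interest on a StatMap grid
#'
#' @slot mask logical 3-D array on the source map's grid.
#' @slot peakIndex integer length-3 voxel index (1-based, R convention) of
#'   the peak the region was grown from.
#' @slot peakWorldMm world millimetre coordinates of the peak voxel.
#' @slot peakZ statistic value at the peak.
#' @slot nVoxels number of voxels in the mask.
#' @slot zMin inclusion threshold used during growth.
#' @slot connectivity neighbourhood used (6, 18 or 26).
#' @seealso [floodFillROI()]
#' @exportClass ROIMask
setClass("ROIMask",
  representation(
    mask = "array",
    peakIndex = "integer",
    peakWorldMm = "numeric",
    peakZ = "numeric",
    nVoxels = "integer",
    zMin = "numeric",
    connectivity = "integer"
  )
)

setValidity("ROIMask", function(object) {
  msgs <- character()
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    msgs <- c(msgs, "mask must be a logical 3-D array")
  if (length(object@peakIndex) != 3L)
    msgs <- c(msgs, "peakIndex must have length 3")
  if (sum(object@mask) != object@nVoxels)
    msgs <- c(msgs, "nVoxels must equal the number of TRUE voxels")
  if (length(msgs)) msgs else TRUE
})
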