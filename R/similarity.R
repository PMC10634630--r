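#' Flatten per-image activation tensors into a FeatureSet
#'
#' Each image's raw activation array (of any shape, e.g. a convolutional
#' layer's height x width x channels tensor) is flattened row-major into a
#' single feature vector, giving one row per image in input order. All
#' images must share the same shape.
#'
#' @param raw list of numeric arrays, one per image, identical dimensions.
#' @param raceLabels,identityLabels per-image labels.
#' @param imageIds unique per-image identifiers; default from `names(raw)`
#'   or `img1, img2, ...`.
#' @param layerName layer name to record.
#' @return A [FeatureSet-class] with an images x features activation matrix.
#' @examples
#' raw <- list(array(1:4, c(2, 2)), array(5:8, c(2, 2)))
#' fs <- flattenFeatures(raw, raceLabels = c("A", "B"),
#'                       identityLabels = c("i1", "i2"))
#' dim(activations(fs))  # 2 x 4
#' @export
flattenFeatures <- function(raw, raceLabels, identityLabels,
                            imageIds = NULL, layerName = "layer") {
  stopIfNot(is.list(raw) && length(raw) >= 2L,
            "raw must be a list of at least 2 per-image arrays")
  if (is.null(imageIds)) {
    imageIds <- names(raw)
    if (is.null(imageIds)) imageIds <- paste0("img", seq_along(raw))
  }
  ref <- dim(as.array(raw[[1]]))
  for (i in seq_along(raw)) {
    d <- dim(as.array(raw[[i]]))
    if (!identical(d, ref))
      stop(sprintf(
        "image '%s' has shape [%s], expected [%s]",
        imageIds[i], paste(d, collapse = "x"), paste(ref, collapse = "x")),
        call. = FALSE)
  }
  # row-major flattening: last array index varies fastest
  flat <- t(vapply(raw, function(a) as.vector(aperm(as.array(a))),
                   numeric(prod(ref))))
  featureSet(flat, raceLabels, identityLabels, imageIds, layerName)
}

#' Build an image-by-image Pearson similarity matrix
#'
#' Correlates every pair of feature vectors in a [FeatureSet-class] to
#' produce the layer's representational similarity matrix. The diagonal is
#' forced to exactly 1.
#'
#' @param fs a [FeatureSet-class].
#' @return A [SimilarityMatrix-class].
#' @examples
#' fs <- featureSet(rbind(c(1, 2, 3), c(1, 2, 4)),
#'                  raceLabels = c("A", "B"),
#'                  identityLabels = c("i1", "i2"))
#' similarityValues(buildSimilarityMatrix(fs))[1, 2]  # ~0.98198
#' @export
buildSimilarityMatrix <- function(fs) {
  stopIfNot(is(fs, "FeatureSet"), "fs must be a FeatureSet")
  a <- fs@activations
  sds <- apply(a, 1L, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad))
    stop(sprintf("zero-variance feature row(s): %s",
                 paste(fs@imageIds[bad], collapse = ", ")), call. = FALSE)
  v <- stats::cor(t(a))
  v <- (v + t(v)) / 2
  diag(v) <- 1
  dimnames(v) <- list(fs@imageIds, fs@imageIds)
  new("SimilarityMatrix",
      layerName = fs@layerName, values = v,
      raceLabels = fs@raceLabels, identityLabels = fs@identityLabels,
      imageIds = fs@imageIds)
}

#' Validate a pair table
#'
#' A pair table records the trials of a same/different face-matching task:
#' one row per trial with the two image ids, the face race of the trial and
#' whether the two images show the same identity. Behavioural data attach a
#' `prop_same` column (proportion of participants judging "same").
#'
#' @param pairs data.frame with columns `image_id_a`, `image_id_b`,
#'   `same_identity` (logical) and optionally `trial_id`, `race`,
#'   `prop_same`.
#' @return The validated data.frame (with `trial_id` filled in if absent).
#' @export
pairTable <- function(pairs) {
  req <- c("image_id_a", "image_id_b", "same_identity")
  miss <- setdiff(req, names(pairs))
  stopIfNot(length(miss) == 0L,
            "pair table is missing column(s): %s", paste(miss, collapse = ", "))
  stopIfNot(is.logical(pairs$same_identity) || all(pairs$same_identity %in% c(0, 1)),
            "same_identity must be logical")
  pairs$same_identity <- as.logical(pairs$same_identity)
  if (is.null(pairs$trial_id)) pairs$trial_id <- seq_len(nrow(pairs))
  if (!is.null(pairs$prop_same))
    stopIfNot(all(pairs$prop_same >= 0 & pairs$prop_same <= 1, na.rm = TRUE),
              "prop_same must lie in [0, 1]")
  pairs
}

#' Look up the similarity of each trial's image pair
#'
#' Returns one Pearson r per trial, in trial order, taken from the
#' similarity matrix.
#'
#' @param sm a [SimilarityMatrix-class].
#' @param pairs a pair table (see [pairTable()]).
#' @return Numeric vector of correlations, one per row of `pairs`.
#' @export
pairSimilarity <- function(sm, pairs) {
  stopIfNot(is(sm, "SimilarityMatrix"), "sm must be a SimilarityMatrix")
  pairs <- pairTable(pairs)
  ia <- match(pairs$image_id_a, sm@imageIds)
  ib <- match(pairs$image_id_b, sm@imageIds)
  bad <- unique(c(pairs$image_id_a[is.na(ia)], pairs$image_id_b[is.na(ib)]))
  if (length(bad))
    stop(sprintf("image id(s) not in similarity matrix: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  sm@values[cbind(ia, ib)]
}
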