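# Accessor generics shared across the package's classes.

#' @rdname FeatureSet-class
#' @param object a package object
#' @export
setGeneric("activations", function(object) standardGeneric("activations"))
#' @rdname FeatureSet-class
#' @export
setGeneric("raceLabels", function(object) standardGeneric("raceLabels"))
#' @rdname FeatureSet-class
#' @export
setGeneric("identityLabels", function(object) standardGeneric("identityLabels"))
#' @rdname FeatureSet-class
#' @export
setGeneric("imageIds", function(object) standardGeneric("imageIds"))
#' @rdname FeatureSet-class
#' @export
setGeneric("layerName", function(object) standardGeneric("layerName"))
#' @rdname SimilarityMatrix-class
#' @export
setGeneric("similarityValues", function(object) standardGeneric("similarityValues"))
#' @rdname VoxelPatternSet-class
#' @export
setGeneric("responses", function(object) standardGeneric("responses"))
#' @rdname VoxelPatternSet-class
#' @export
setGeneric("participantGroup", function(object) standardGeneric("participantGroup"))
#' @rdname VoxelPatternSet-class
#' @export
setGeneric("conditionInfo", function(object) standardGeneric("conditionInfo"))
#' @rdname StatMap-class
#' @export
setGeneric("statValues", function(object) standardGeneric("statValues"))
#' @rdname StatMap-class
#' @export
setGeneric("voxelAffine", function(object) standardGeneric("voxelAffine"))
#' @rdname ROIMask-class
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname ROIMask-class
#' @export
setGeneric("nVoxels", function(object) standardGeneric("nVoxels"))
#' @rdname ROIMask-class
#' @export
setGeneric("peakIndex", function(object) standardGeneric("peakIndex"))
#' @rdname ROIMask-class
#' @export
setGeneric("peakWorldMm", function(object) standardGeneric("peakWorldMm"))

#' @rdname FeatureSet-class
setMethod("activations", "FeatureSet", function(object) object@activations)
#' @rdname FeatureSet-class
setMethod("raceLabels", "FeatureSet", function(object) object@raceLabels)
#' @rdname FeatureSet-class
setMethod("identityLabels", "FeatureSet", function(object) object@identityLabels)
#' @rdname FeatureSet-class
setMethod("imageIds", "FeatureSet", function(object) object@imageIds)
#' @rdname FeatureSet-class
setMethod("layerName", "FeatureSet", function(object) object@layerName)

#' @rdname SimilarityMatrix-class
setMethod("similarityValues", "SimilarityMatrix", function(object) object@values)
#' @rdname SimilarityMatrix-class
setMethod("raceLabels", "SimilarityMatrix", function(object) object@raceLabels)
#' @rdname SimilarityMatrix-class
setMethod("identityLabels", "SimilarityMatrix", function(object) object@identityLabels)
#' @rdname SimilarityMatrix-class
setMethod("imageIds", "SimilarityMatrix", function(object) object@imageIds)
#' @rdname SimilarityMatrix-class
setMethod("layerName", "SimilarityMatrix", function(object) object@layerName)

#' @rdname VoxelPatternSet-class
setMethod("responses", "VoxelPatternSet", function(object) object@responses)
#' @rdname VoxelPatternSet-class
setMethod("participantGroup", "VoxelPatternSet", function(object) object@participantGroup)
#' @rdname VoxelPatternSet-class
setMethod("conditionInfo", "VoxelPatternSet", function(object) object@conditionInfo)

#' @rdname StatMap-class
setMethod("statValues", "StatMap", function(object) object@values)
#' @rdname StatMap-class
setMethod("voxelAffine", "StatMap", function(object) object@affine)

#' @rdname ROIMask-class
setMethod("maskArray", "ROIMask", function(object) object@mask)
#' @rdname ROIMask-class
setMethod("nVoxels", "ROIMask", function(object) object@nVoxels)
#' @rdname ROIMask-class
setMethod("peakIndex", "ROIMask", function(object) object@peakIndex)
#' @rdname ROIMask-class
setMethod("peakWorldMm", "ROIMask", function(object) object@peakWorldMm)

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet '%s': %d images x %d features\n",
              object@layerName, nrow(object@activations),
              ncol(object@activations)))
  cat("  races:", paste(levels(object@raceLabels), collapse = ", "), "\n")
  cat(sprintf("  identities: %d\n", nlevels(object@identityLabels)))
})

setMethod("show", "SimilarityMatrix", function(object) {
  n <- nrow(object@values)
  off <- object@values[row(object@values) != col(object@values)]
  cat(sprintf("SimilarityMatrix '%s': %d x %d images\n",
              object@layerName, n, n))
  if (length(off))
    cat(sprintf("  off-diagonal r: mean %.3f, range [%.3f, %.3f]\n",
                mean(off), min(off), max(off)))
})

setMethod("show", "VoxelPatternSet", function(object) {
  d <- dim(object@responses)
  cat(sprintf("VoxelPatternSet: %d participants x %d conditions x %d voxels\n",
              d[1], d[2], d[3]))
  cat("  groups:", paste(sprintf("%s (%d)", levels(object@participantGroup),
                                 table(object@participantGroup)),
                         collapse = ", "), "\n")
  cat("  conditions:", paste(object@conditionInfo$condition, collapse = ", "),
      "\n")
})

setMethod("show", "StatMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("StatMap: %d x %d x %d voxels, z in [%.2f, %.2f]\n",
              d[1], d[2], d[3],
              min(object@values, na.rm = TRUE),
              max(object@values, na.rm = TRUE)))
})

setMethod("show", "ROIMask", function(object) {
  cat(sprintf("ROIMask: %d voxels (z > %.2f, %d-connectivity)\n",
              object@nVoxels, object@zMin, object@connectivity))
  cat(sprintf("  peak z = %.2f at voxel [%s], world [%s] mm\n",
              object@peakZ, paste(object@peakIndex, collapse = ", "),
              paste(sprintf("%.1f", object@peakWorldMm), collapse = ", ")))
})
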