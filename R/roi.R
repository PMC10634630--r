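# Neighbour offsets for 6-, 18- and 26-connectivity on a 3-D grid.
neighbourOffsets <- function(connectivity = 6L) {
  stopIfNot(connectivity %in% c(6L, 18L, 26L),
            "connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d >= 1 & d <= 2, "26" = d >= 1)
  g[keep, , drop = FALSE]
}

#' Find the peak voxel of a statistical map
#'
#' Returns the voxel with the highest statistic, optionally restricted to
#' a search mask. Ties are broken deterministically by the lowest linear
#' (column-major) index.
#'
#' @param map a [StatMap-class].
#' @param searchMask optional [ROIMask-class] or logical array restricting
#'   the search.
#' @return List with `index` (1-based voxel triplet), `linear` (linear
#'   index), `z` (peak value) and `worldMm` (world coordinates of the
#'   peak).
#' @export
findPeak <- function(map, searchMask = NULL) {
  stopIfNot(is(map, "StatMap"), "map must be a StatMap")
  v <- map@values
  keep <- is.finite(v)
  if (!is.null(searchMask)) {
    m <- if (is(searchMask, "ROIMask")) searchMask@mask else searchMask
    stopIfNot(identical(dim(m), dim(v)),
              "search mask must match the map grid")
    keep <- keep & m
  }
  stopIfNot(any(keep), "no finite voxels in the search region")
  vv <- ifelse(keep, v, -Inf)
  lin <- which.max(vv)  # which.max returns the first (lowest) index on ties
  idx <- arrayInd(lin, dim(v))[1, ]
  list(index = as.integer(idx), linear = as.integer(lin),
       z = v[lin], worldMm = voxelToWorld(map@affine, idx))
}

# 1-based R voxel index -> world mm via a 0-based NIfTI-style affine.
voxelToWorld <- function(affine, index) {
  as.vector(affine %*% c(index - 1, 1))[1:3]
}

#' Grow a region of interest by thresholded flood fill
#'
#' Grows a connected cluster from a peak voxel over the statistical map:
#' starting at the peak, the suprathreshold neighbour of the current
#' region with the highest statistic is added repeatedly (ties broken by
#' lowest linear index) until the target size is reached or no
#' suprathreshold neighbour remains. If fewer than `targetSize` voxels are
#' reachable, the region is cut back to the largest multiple of
#' `fallbackRounding` by removing the most recently added (lowest-z)
#' voxels, which preserves connectivity; if fewer than `fallbackRounding`
#' voxels are reachable an error is raised.
#'
#' @param map a [StatMap-class].
#' @param peak peak voxel as returned by [findPeak()], a 1-based index
#'   triplet, or `NULL` to use the global peak.
#' @param targetSize desired cluster size in voxels (default 500).
#' @param zMin lower statistic threshold for inclusion (default 2.3,
#'   exclusive: included voxels satisfy `z > zMin`).
#' @param fallbackRounding granularity of the fallback size (default 100).
#' @param connectivity 6 (face), 18 (face+edge) or 26 (face+edge+corner)
#'   neighbourhood; default 6.
#' @return An [ROIMask-class].
#' @export
floodFillROI <- function(map, peak = NULL, targetSize = 500L, zMin = 2.3,
                         fallbackRounding = 100L, connectivity = 6L) {
  stopIfNot(is(map, "StatMap"), "map must be a StatMap")
  stopIfNot(targetSize > 0L, "targetSize must be positive")
  stopIfNot(fallbackRounding > 0L, "fallbackRounding must be positive")
  if (is.null(peak)) peak <- findPeak(map)
  idx <- if (is.list(peak)) peak$index else as.integer(peak)
  stopIfNot(length(idx) == 3L, "peak must be a voxel index triplet")
  v <- map@values
  dims <- dim(v)
  stopIfNot(all(idx >= 1L & idx <= dims), "peak outside the map grid")
  peakZ <- v[idx[1], idx[2], idx[3]]
  stopIfNot(is.finite(peakZ) && peakZ > zMin,
            "peak statistic (%.3f) does not exceed the threshold (%.3f)",
            peakZ, zMin)

  offs <- neighbourOffsets(as.integer(connectivity))
  linOf <- function(ix) ix[, 1] + dims[1] * (ix[, 2] - 1) +
    dims[1] * dims[2] * (ix[, 3] - 1)
  inROI <- logical(prod(dims))
  inFrontier <- logical(prod(dims))
  peakLin <- linOf(matrix(idx, 1))
  inROI[peakLin] <- TRUE
  order <- integer(targetSize)
  order[1] <- peakLin
  nIn <- 1L
  frontier <- integer(0)

  pushNeighbours <- function(lin3, frontier) {
    nb <- matrix(lin3, nrow(offs), 3, byrow = TRUE) + offs
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nl <- linOf(nb[ok, , drop = FALSE])
    nl <- nl[!inROI[nl] & !inFrontier[nl] & is.finite(v[nl]) & v[nl] > zMin]
    inFrontier[nl] <<- TRUE
    c(frontier, nl)
  }
  frontier <- pushNeighbours(idx, frontier)

  while (nIn < targetSize && length(frontier)) {
    # highest z wins; ties by lowest linear index (frontier kept sorted-in
    # insertion order, which.max picks the first maximal element, so sort
    # candidates by linear index before scanning)
    frontier <- sort(frontier)
    best <- frontier[which.max(v[frontier])]
    frontier <- frontier[frontier != best]
    inFrontier[best] <- FALSE
    inROI[best] <- TRUE
    nIn <- nIn + 1L
    order[nIn] <- best
    bi <- arrayInd(best, dims)[1, ]
    frontier <- pushNeighbours(bi, frontier)
  }

  if (nIn < targetSize) {
    finalSize <- (nIn %/% fallbackRounding) * fallbackRounding
    stopIfNot(finalSize > 0L,
              "only %d voxels reachable, fewer than the rounding unit (%d)",
              nIn, fallbackRounding)
    if (finalSize < nIn) {
      drop <- order[(finalSize + 1):nIn]
      inROI[drop] <- FALSE
    }
    nIn <- as.integer(finalSize)
  }

  mask <- array(inROI, dims)
  new("ROIMask", mask = mask, peakIndex = as.integer(idx),
      peakWorldMm = voxelToWorld(map@affine, idx), peakZ = peakZ,
      nVoxels = as.integer(nIn), zMin = zMin,
      connectivity = as.integer(connectivity))
}

#' Summarise a set of ROI masks as a peak table
#'
#' One row per ROI with its peak world coordinates, size and peak
#' statistic — the layout conventionally reported for face-selective
#' regions.
#'
#' @param rois named list of [ROIMask-class] objects.
#' @return data.frame with `roi`, `x`, `y`, `z`, `voxels`, `peak_z`.
#' @export
roiPeakTable <- function(rois) {
  stopIfNot(is.list(rois) && length(rois) >= 1L,
            "rois must be a non-empty list of ROIMask objects")
  nm <- names(rois)
  if (is.null(nm)) nm <- paste0("roi", seq_along(rois))
  do.call(rbind, lapply(seq_along(rois), function(i) {
    r <- rois[[i]]
    data.frame(roi = nm[i], x = r@peakWorldMm[1], y = r@peakWorldMm[2],
               z = r@peakWorldMm[3], voxels = r@nVoxels, peak_z = r@peakZ,
               stringsAsFactors = FALSE)
  }))
}

#' Extract ROI voxel patterns from full-volume data
#'
#' Subsets a participants x conditions x voxels array whose voxel axis is
#' the flattened (column-major) volume down to the voxels of an ROI mask.
#'
#' @param vps a [VoxelPatternSet-class] whose voxel axis matches the mask
#'   volume (`prod(dim(mask))` voxels).
#' @param roi an [ROIMask-class].
#' @return A [VoxelPatternSet-class] restricted to the ROI voxels.
#' @export
applyROIMask <- function(vps, roi) {
  stopIfNot(is(vps, "VoxelPatternSet"), "vps must be a VoxelPatternSet")
  stopIfNot(is(roi, "ROIMask"), "roi must be an ROIMask")
  nVox <- dim(vps@responses)[3]
  stopIfNot(nVox == length(roi@mask),
            "voxel axis (%d) does not match the mask volume (%d voxels)",
            nVox, length(roi@mask))
  keep <- which(as.vector(roi@mask))
  voxelPatternSet(vps@responses[, , keep, drop = FALSE],
                  vps@participantGroup, vps@conditionInfo)
}
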