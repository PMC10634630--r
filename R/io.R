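#' Read and write similarity matrices as CSV
#'
#' A single CSV holds both the labels and the matrix: columns `image_id`,
#' `race`, `identity`, then one correlation column per image id (so the
#' matrix block is square with the image ids as header).
#'
#' @param sm a [SimilarityMatrix-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeSimilarityMatrix <- function(sm, file) {
  stopIfNot(is(sm, "SimilarityMatrix"), "sm must be a SimilarityMatrix")
  df <- data.frame(image_id = sm@imageIds,
                   race = as.character(sm@raceLabels),
                   identity = as.character(sm@identityLabels),
                   sm@values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[-(1:3)] <- sm@imageIds
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeSimilarityMatrix
#' @param layerName layer name to record on reading.
#' @export
readSimilarityMatrix <- function(file, layerName = "layer") {
  df <- utils::read.csv(file, check.names = FALSE,
                        stringsAsFactors = FALSE)
  req <- c("image_id", "race", "identity")
  stopIfNot(all(req %in% names(df)),
            "malformed similarity CSV '%s': missing %s", file,
            paste(setdiff(req, names(df)), collapse = ", "))
  ids <- df$image_id
  v <- as.matrix(df[, ids, drop = FALSE])
  stopIfNot(nrow(v) == ncol(v),
            "malformed similarity CSV '%s': matrix block not square", file)
  storage.mode(v) <- "double"
  dimnames(v) <- list(ids, ids)
  diag(v) <- 1
  v <- (v + t(v)) / 2
  diag(v) <- 1
  new("SimilarityMatrix", layerName = layerName, values = v,
      raceLabels = as.factor(df$race), identityLabels = as.factor(df$identity),
      imageIds = ids)
}

#' Read and write pair tables as CSV
#'
#' @param pairs a pair table (see [pairTable()]).
#' @param file path.
#' @return `file` invisibly (write); the validated table (read).
#' @export
writePairTable <- function(pairs, file) {
  utils::write.csv(pairTable(pairs), file, row.names = FALSE)
  invisible(file)
}

#' @rdname writePairTable
#' @export
readPairTable <- function(file) {
  pairTable(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' Read and write voxel-pattern sets as long-format CSV
#'
#' Long format: one row per (participant, condition, voxel) with columns
#' `participant`, `group`, `condition`, `race`, `arrangement`, `voxel`,
#' `value`.
#'
#' @param vps a [VoxelPatternSet-class].
#' @param file path.
#' @return `file` invisibly (write); a [VoxelPatternSet-class] (read).
#' @export
writeVoxelPatterns <- function(vps, file) {
  stopIfNot(is(vps, "VoxelPatternSet"), "vps must be a VoxelPatternSet")
  r <- vps@responses
  d <- dim(r)
  pid <- dimnames(r)[[1]]
  if (is.null(pid)) pid <- paste0("p", seq_len(d[1]))
  info <- vps@conditionInfo
  long <- data.frame(
    participant = rep(pid, times = d[2] * d[3]),
    group = rep(as.character(vps@participantGroup), times = d[2] * d[3]),
    condition = rep(rep(info$condition, each = d[1]), times = d[3]),
    race = rep(rep(info$race, each = d[1]), times = d[3]),
    arrangement = rep(rep(info$arrangement, each = d[1]), times = d[3]),
    voxel = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(r), stringsAsFactors = FALSE)
  utils::write.csv(long, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeVoxelPatterns
#' @export
readVoxelPatterns <- function(file) {
  long <- utils::read.csv(file, stringsAsFactors = FALSE)
  req <- c("participant", "group", "condition", "voxel", "value")
  stopIfNot(all(req %in% names(long)),
            "malformed pattern CSV '%s': missing %s", file,
            paste(setdiff(req, names(long)), collapse = ", "))
  pid <- unique(long$participant)
  cond <- unique(long$condition)
  vox <- sort(unique(long$voxel))
  stopIfNot(nrow(long) == length(pid) * length(cond) * length(vox),
            "malformed pattern CSV '%s': incomplete participant x condition x voxel grid",
            file)
  r <- array(NA_real_, c(length(pid), length(cond), length(vox)),
             dimnames = list(pid, cond, NULL))
  r[cbind(match(long$participant, pid), match(long$condition, cond),
          match(long$voxel, vox))] <- long$value
  grp <- long$group[match(pid, long$participant)]
  info <- unique(long[, intersect(c("condition", "race", "arrangement"),
                                  names(long))])
  if (is.null(info$race)) info$race <- NA_character_
  if (is.null(info$arrangement)) info$arrangement <- NA_character_
  info <- info[match(cond, info$condition), ]
  rownames(info) <- NULL
  voxelPatternSet(r, grp, info)
}

#' Read and write statistical maps and ROI masks as NIfTI
#'
#' Volumes are written as NIfTI-1 with the map's affine stored in the
#' sform; masks are written as 0/1 volumes.
#'
#' @param map a [StatMap-class].
#' @param file a `.nii` or `.nii.gz` path.
#' @return `file` invisibly (write); a [StatMap-class] (read).
#' @export
writeStatMap <- function(map, file) {
  stopIfNot(is(map, "StatMap"), "map must be a StatMap")
  img <- RNifti::asNifti(map@values)
  img <- RNifti::`sform<-`(img, structure(map@affine, code = 2L))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname writeStatMap
#' @export
readStatMap <- function(file) {
  img <- RNifti::readNifti(file)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  statMap(array(as.vector(img), dim(img)[1:3]), aff)
}

#' @rdname writeStatMap
#' @param roi an [ROIMask-class].
#' @export
writeROIMask <- function(roi, file, map = NULL) {
  stopIfNot(is(roi, "ROIMask"), "roi must be an ROIMask")
  affine <- if (!is.null(map)) map@affine else {
    a <- diag(4); a[1:3, 4] <- -(dim(roi@mask) - 1) / 2; a
  }
  img <- RNifti::asNifti(array(as.integer(roi@mask), dim(roi@mask)))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname writeStatMap
#' @export
readROIMaskArray <- function(file) {
  img <- RNifti::readNifti(file)
  array(as.vector(img) != 0, dim(img)[1:3])
}
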