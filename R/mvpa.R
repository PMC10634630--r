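#' Normalize voxel patterns by the per-voxel condition mean
#'
#' For every participant and voxel, the mean response across the selected
#' conditions is subtracted from those conditions, so each voxel's mean
#' over the subset is zero afterwards. This removes the shared univariate
#' response before pattern correlation.
#'
#' @param vps a [VoxelPatternSet-class].
#' @param conditions conditions to normalize over (names or indices);
#'   default all conditions.
#' @return A [VoxelPatternSet-class] with the selected conditions centred.
#' @export
normalizePatterns <- function(vps, conditions = NULL) {
  stopIfNot(is(vps, "VoxelPatternSet"), "vps must be a VoxelPatternSet")
  condNames <- vps@conditionInfo$condition
  if (is.null(conditions)) conditions <- condNames
  idx <- if (is.numeric(conditions)) as.integer(conditions)
         else match(conditions, condNames)
  stopIfNot(length(idx) >= 1L && !anyNA(idx),
            "condition subset is empty or contains unknown conditions")
  r <- vps@responses
  m <- apply(r[, idx, , drop = FALSE], c(1, 3), mean)   # participants x voxels
  for (j in idx) r[, j, ] <- r[, j, ] - m
  voxelPatternSet(r, vps@participantGroup, vps@conditionInfo)
}

#' Leave-one-participant-out pattern similarity
#'
#' For each participant and each ordered condition pair (i, j), correlates
#' the participant's voxel pattern for condition i with the group template
#' for condition j — the voxelwise mean pattern of the remaining
#' participants of the same group. A Fisher z (atanh of the clamped r) is
#' attached for downstream averaging.
#'
#' @param vps a [VoxelPatternSet-class]; normalize first with
#'   [normalizePatterns()] if pattern (rather than amplitude) similarity
#'   is wanted.
#' @param conditions optional subset of conditions (default all).
#' @return data.frame with one row per participant and ordered condition
#'   pair: `participant`, `group`, `condition_a` (left-out participant's
#'   condition), `condition_b` (group-template condition), their races and
#'   arrangements, `r` and `z`.
#' @export
lopoSimilarity <- function(vps, conditions = NULL) {
  stopIfNot(is(vps, "VoxelPatternSet"), "vps must be a VoxelPatternSet")
  info <- vps@conditionInfo
  if (is.null(conditions)) conditions <- info$condition
  idx <- if (is.numeric(conditions)) as.integer(conditions)
         else match(conditions, info$condition)
  stopIfNot(!anyNA(idx) && length(idx) >= 2L,
            "need at least 2 known conditions")
  r <- vps@responses
  grp <- vps@participantGroup
  small <- names(which(table(grp) < 2))
  if (length(small))
    stop(sprintf("group(s) with fewer than 2 participants: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  nP <- dim(r)[1]
  pid <- dimnames(r)[[1]]
  if (is.null(pid)) pid <- paste0("p", seq_len(nP))

  out <- vector("list", nP)
  for (p in seq_len(nP)) {
    others <- which(grp == grp[p] & seq_len(nP) != p)
    # group template per condition: unweighted voxelwise mean over the
    # remaining same-group participants
    tmpl <- apply(r[others, idx, , drop = FALSE], c(2, 3), mean)
    own <- r[p, idx, , drop = FALSE][1, , ]
    cc <- stats::cor(t(own), t(tmpl))  # [condition_a, condition_b]
    grid <- expand.grid(a = seq_along(idx), b = seq_along(idx))
    out[[p]] <- data.frame(
      participant = pid[p], group = as.character(grp[p]),
      condition_a = info$condition[idx][grid$a],
      condition_b = info$condition[idx][grid$b],
      race_a = info$race[idx][grid$a], race_b = info$race[idx][grid$b],
      arrangement_a = info$arrangement[idx][grid$a],
      arrangement_b = info$arrangement[idx][grid$b],
      r = cc[cbind(grid$a, grid$b)],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$z <- fisherZ(res$r)
  res
}

# Tag each LOPO record's condition pair: same_race / different_race for
# face-face pairs, face_object for mixed pairs, object_object otherwise.
faceRaceTag <- function(ps, objectLabel = "Object") {
  aObj <- is.na(ps$race_a) | ps$race_a == objectLabel
  bObj <- is.na(ps$race_b) | ps$race_b == objectLabel
  ps$pair_type <- ifelse(aObj & bObj, "object_object",
                         ifelse(aObj | bObj, "face_object",
                                ifelse(ps$race_a == ps$race_b, "same_race",
                                       "different_race")))
  ps
}

#' Same-race versus different-race pattern similarity per participant
#'
#' Averages LOPO Fisher z values over same-race condition pairs (e.g.
#' Asian-Asian, Black-Black, White-White) and over different-race pairs
#' (Asian-Black, Asian-White, Black-White) for each participant.
#'
#' @param ps LOPO records from [lopoSimilarity()].
#' @param objectLabel race label marking non-face (object) conditions,
#'   excluded here.
#' @return data.frame per participant: `participant`, `group`,
#'   `same_race`, `different_race`, `difference`.
#' @export
raceSimilarityContrast <- function(ps, objectLabel = "Object") {
  ps <- faceRaceTag(ps, objectLabel)
  faces <- ps[ps$pair_type %in% c("same_race", "different_race"), ,
              drop = FALSE]
  pairKey <- function(d) paste(pmin(d$race_a, d$race_b),
                               pmax(d$race_a, d$race_b))
  types <- unique(pairKey(faces))
  races <- sort(unique(c(faces$race_a, faces$race_b)))
  wanted <- c(paste(races, races),
              utils::combn(races, 2, FUN = paste, collapse = " "))
  miss <- setdiff(wanted, types)
  if (length(miss))
    stop(sprintf("missing condition pair type(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  agg <- stats::aggregate(z ~ participant + group + pair_type, data = faces,
                          FUN = mean)
  same <- agg[agg$pair_type == "same_race", ]
  diff <- agg[agg$pair_type == "different_race", ]
  m <- merge(same[, c("participant", "group", "z")],
             diff[, c("participant", "group", "z")],
             by = c("participant", "group"), suffixes = c("_same", "_diff"))
  data.frame(participant = m$participant, group = m$group,
             same_race = m$z_same, different_race = m$z_diff,
             difference = m$z_same - m$z_diff, stringsAsFactors = FALSE)
}

#' Own-race consistency contrast (Face x Participant-group)
#'
#' Restricts the LOPO records to the same-race condition pairs of two face
#' races that match the two participant groups (e.g. Asian-Asian and
#' White-White patterns in Asian and White participants) and forms the
#' 2 x 2 table of mean Fisher z by Face and Participant group. The
#' interaction contrast is the own-race minus other-race difference
#' averaged over groups; per group a planned one-tailed paired t-test
#' (own > other) and Cohen's d are reported.
#'
#' @param ps LOPO records from [lopoSimilarity()].
#' @param faces the two face races to cross with the participant groups;
#'   default the two group labels present in `ps`.
#' @return List with `cells` (2 x 2 matrix of mean z, faces x groups),
#'   `perParticipant` (own/other means), `interaction` (scalar contrast)
#'   and `planned` (per-group t, p, Cohen's d).
#' @export
ownRaceBiasContrast <- function(ps, faces = NULL) {
  groups <- sort(unique(ps$group))
  stopIfNot(length(groups) == 2L, "exactly two participant groups required")
  if (is.null(faces)) faces <- groups
  stopIfNot(length(faces) == 2L, "exactly two face races required")
  sel <- ps$race_a %in% faces & ps$race_a == ps$race_b
  d <- ps[sel, , drop = FALSE]
  stopIfNot(nrow(d) > 0, "no same-race records for the requested faces")
  cells <- tapply(d$z, list(factor(d$race_a, faces),
                            factor(d$group, groups)), mean)
  if (anyNA(cells))
    stop("missing Face x Participant-group cell(s)", call. = FALSE)
  per <- stats::aggregate(z ~ participant + group + race_a, data = d,
                          FUN = mean)
  per$role <- ifelse(per$race_a == per$group, "own", "other")
  wide <- merge(per[per$role == "own", c("participant", "group", "z")],
                per[per$role == "other", c("participant", "group", "z")],
                by = c("participant", "group"),
                suffixes = c("_own", "_other"))
  wide$difference <- wide$z_own - wide$z_other
  groupDiff <- tapply(wide$difference, factor(wide$group, groups), mean)
  planned <- do.call(rbind, lapply(groups, function(g) {
    w <- wide[wide$group == g, ]
    tt <- stats::t.test(w$z_own, w$z_other, paired = TRUE,
                        alternative = "greater")
    data.frame(group = g, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               cohens_d = cohensD(w$z_own, w$z_other, paired = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(cells = cells,
       perParticipant = wide,
       interaction = unname(mean(groupDiff)),
       planned = planned)
}

#' Face-face versus face-object pattern similarity per participant
#'
#' Averages LOPO Fisher z values over different-race face pairs
#' (face-face) and over face-object pairs for each participant.
#'
#' @param ps LOPO records from [lopoSimilarity()].
#' @param objectLabel race label of the object condition.
#' @return data.frame per participant: `participant`, `group`,
#'   `face_face`, `face_object`, `difference`.
#' @export
categoryContrast <- function(ps, objectLabel = "Object") {
  stopIfNot(any(ps$race_a == objectLabel | ps$race_b == objectLabel,
                na.rm = TRUE),
            "no object condition ('%s') present", objectLabel)
  ps <- faceRaceTag(ps, objectLabel)
  d <- ps[ps$pair_type %in% c("different_race", "face_object"), ,
          drop = FALSE]
  agg <- stats::aggregate(z ~ participant + group + pair_type, data = d,
                          FUN = mean)
  ff <- agg[agg$pair_type == "different_race", ]
  fo <- agg[agg$pair_type == "face_object", ]
  stopIfNot(nrow(ff) > 0 && nrow(fo) > 0,
            "both face-face and face-object pairs are required")
  m <- merge(ff[, c("participant", "group", "z")],
             fo[, c("participant", "group", "z")],
             by = c("participant", "group"), suffixes = c("_ff", "_fo"))
  data.frame(participant = m$participant, group = m$group,
             face_face = m$z_ff, face_object = m$z_fo,
             difference = m$z_ff - m$z_fo, stringsAsFactors = FALSE)
}

#' fMR-adaptation index per participant and face race
#'
#' Compares the mean (unnormalized) ROI response to the Different-Identity
#' and Same-Identity arrangements of each face race:
#' `adaptation = response_different - response_same`. Positive values
#' indicate repetition suppression (a reduced response to repeated
#' identity). Responses are averaged over the ROI voxels.
#'
#' @param vps a [VoxelPatternSet-class] (ROI-restricted, unnormalized)
#'   whose `conditionInfo` marks each condition's `race` and `arrangement`
#'   (`"same"` / `"different"`).
#' @param roi label recorded in the output (default "roi").
#' @return data.frame per participant x face race: `participant`, `group`,
#'   `roi`, `face_race`, `response_same`, `response_different`,
#'   `adaptation`.
#' @export
adaptationIndex <- function(vps, roi = "roi") {
  stopIfNot(is(vps, "VoxelPatternSet"), "vps must be a VoxelPatternSet")
  info <- vps@conditionInfo
  races <- unique(info$race[!is.na(info$arrangement)])
  stopIfNot(length(races) >= 1L,
            "conditionInfo carries no same/different arrangements")
  r <- vps@responses
  nP <- dim(r)[1]
  pid <- dimnames(r)[[1]]
  if (is.null(pid)) pid <- paste0("p", seq_len(nP))
  out <- list()
  for (rc in races) {
    iSame <- which(info$race == rc & info$arrangement == "same")
    iDiff <- which(info$race == rc & info$arrangement == "different")
    if (!length(iSame) || !length(iDiff))
      stop(sprintf("race '%s' lacks a %s-identity arrangement", rc,
                   if (length(iSame)) "different" else "same"),
           call. = FALSE)
    respSame <- apply(r[, iSame, , drop = FALSE], 1L, mean)
    respDiff <- apply(r[, iDiff, , drop = FALSE], 1L, mean)
    out[[rc]] <- data.frame(
      participant = pid, group = as.character(vps@participantGroup),
      roi = roi, face_race = rc, response_same = respSame,
      response_different = respDiff, adaptation = respDiff - respSame,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
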