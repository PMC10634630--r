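#' Build behavioural similarity from same/different judgements
#'
#' Collapses a participants-by-trials table of binary same/different
#' identity judgements into one behavioural similarity value per trial:
#' the proportion of participants who judged the pair "same".
#'
#' @param judgements numeric/logical matrix, participants in rows, trials
#'   in columns (1 = "same"). Every participant must have judged every
#'   trial.
#' @param pairs pair table with one row per trial (see [pairTable()]).
#' @return The pair table with a `prop_same` column attached.
#' @export
behaviourSimilarity <- function(judgements, pairs) {
  pairs <- pairTable(pairs)
  judgements <- as.matrix(judgements)
  stopIfNot(ncol(judgements) == nrow(pairs),
            "judgements must have one column per trial (%d trials)",
            nrow(pairs))
  missing <- which(colSums(is.na(judgements)) > 0)
  if (length(missing))
    stop(sprintf("missing judgements for trial(s): %s",
                 paste(pairs$trial_id[missing], collapse = ", ")),
         call. = FALSE)
  stopIfNot(all(judgements %in% c(0, 1)),
            "judgements must be binary (0/1 or logical)")
  pairs$prop_same <- colMeans(judgements)
  pairs
}

#' Critical correlation at a one-tailed alpha
#'
#' The smallest Pearson r significant at the given one-tailed level for
#' `n - 2` degrees of freedom (the dashed-line criterion used when plotting
#' layer-wise brain/behaviour correlations).
#'
#' @param n number of paired observations.
#' @param alpha one-tailed significance level.
#' @return The critical r.
#' @export
criticalR <- function(n, alpha = 0.05) {
  stopIfNot(n >= 4L, "need at least 4 observations")
  df <- n - 2
  tc <- stats::qt(1 - alpha, df)
  tc / sqrt(df + tc^2)
}

#' Correlate a layer's pair similarities with behaviour
#'
#' Pearson-correlates the behavioural similarity (`prop_same`) of each
#' trial against the feature-space correlation of the same image pair in
#' one layer. Significance is assessed one-tailed against the critical r
#' at `alpha` (positive correlations expected).
#'
#' @param sm a [SimilarityMatrix-class] for one layer.
#' @param pairs pair table with a `prop_same` column.
#' @param alpha one-tailed level for the critical r.
#' @return One-row data.frame: `layer`, `r`, `n_pairs`, `critical_r`,
#'   `significant`.
#' @export
layerBehaviourCorrelation <- function(sm, pairs, alpha = 0.05) {
  pairs <- pairTable(pairs)
  stopIfNot(!is.null(pairs$prop_same),
            "pairs must carry a prop_same column (see behaviourSimilarity)")
  stopIfNot(nrow(pairs) >= 4L, "need at least 4 pairs")
  pr <- pairSimilarity(sm, pairs)
  stopIfNot(stats::sd(pr) > 0, "zero variance in pair similarities")
  stopIfNot(stats::sd(pairs$prop_same) > 0,
            "zero variance in behavioural proportions")
  r <- stats::cor(pairs$prop_same, pr)
  rc <- criticalR(nrow(pairs), alpha)
  data.frame(layer = sm@layerName, r = r, n_pairs = nrow(pairs),
             critical_r = rc, significant = r > rc,
             stringsAsFactors = FALSE)
}

#' Fisher z-transform of a correlation
#'
#' `atanh(r)` with r clamped to `1 - 1e-7` in absolute value so that
#' perfect correlations map to a large finite value.
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @return Fisher z value(s).
#' @examples
#' fisherZ(0.5)  # ~0.5493
#' @export
fisherZ <- function(r) {
  stopIfNot(all(abs(r) <= 1 + 1e-12, na.rm = TRUE),
            "correlations must lie in [-1, 1]")
  atanh(clampR(r))
}

#' Compare two independent correlations via Fisher z
#'
#' Standard independent-samples comparison:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-tailed normal p-value.
#'
#' @param r1,r2 the two correlations.
#' @param n1,n2 the sample sizes behind them (must be at least 4).
#' @return List with `z` and `p` (two-tailed).
#' @examples
#' fisherZCompare(0.6, 90, 0.3, 90)$z  # ~2.53
#' @export
fisherZCompare <- function(r1, n1, r2, n2) {
  stopIfNot(n1 >= 4L && n2 >= 4L, "both sample sizes must be at least 4")
  z <- (fisherZ(r1) - fisherZ(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
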