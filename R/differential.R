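#' @title Two-sample differential analysis of pathway activity and significance
#' @description Compares two samples either by the ratio of their pathway
#'   activity levels (calling pathways up/down past fold thresholds) or by
#'   combining their per-sample permutation p-values into the probDiff
#'   statistic, which calls a pathway differentially significant when it is
#'   confidently significant in one sample and confidently not in the other.
#' @name differential
NULL

#' Ratio of two activity levels
#'
#' `level1 / level2`, or `NA` (the undefined marker) when `level2` is zero;
#' both raw levels are kept alongside the ratio in the tabulating functions,
#' so undefined rows are reported rather than dropped.
#'
#' @param level1,level2 non-negative activity levels.
#' @return the ratio, or `NA_real_` when undefined.
#' @export
activity_ratio <- function(level1, level2) {
  stopifnot(all(level1 >= 0, na.rm = TRUE), all(level2 >= 0, na.rm = TRUE))
  ifelse(is.na(level1) | is.na(level2) | level2 == 0, NA_real_, level1 / level2)
}

#' Call differential activity from level ratios
#'
#' A pathway is called `up` when its ratio (sample1 / sample2) is at or
#' above `up_threshold` (default 1.5), `down` at or below `down_threshold`
#' (default 0.66), `unchanged` otherwise, and `undefined` when the ratio
#' could not be formed.
#'
#' @param ratio numeric vector of ratios (`NA` = undefined).
#' @param up_threshold,down_threshold fold thresholds, `0 < down < 1 < up`.
#' @return character vector of calls.
#' @export
call_differential_activity <- function(ratio, up_threshold = 1.5,
                                       down_threshold = 0.66) {
  stopifnot(down_threshold > 0, down_threshold < 1, up_threshold > 1)
  out <- rep("unchanged", length(ratio))
  out[!is.na(ratio) & ratio >= up_threshold] <- "up"
  out[!is.na(ratio) & ratio <= down_threshold] <- "down"
  out[is.na(ratio)] <- "undefined"
  out
}

#' probDiff: differential-significance probability
#'
#' Combines one pathway's empirical p-values from two samples:
#' \deqn{probDiff = (1 - p_1) p_2 \textrm{ if } p_2 \ge p_1, \quad
#'       (1 - p_2) p_1 \textrm{ otherwise.}}
#' Writing `p_small` and `p_large` for the ordered pair, this is
#' `(1 - p_small) * p_large`: the probability of being a real effect in the
#' low-p sample times the probability of being noise in the high-p sample.
#' It is symmetric in its arguments and lies in `[0, 1)`.
#'
#' @param p1,p2 p-values in (0, 1]; vectors recycle elementwise.
#' @return numeric vector of probDiff values.
#' @export
prob_diff <- function(p1, p2) {
  if (any(p1 <= 0 | p1 > 1) || any(p2 <= 0 | p2 > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  ifelse(p2 >= p1, (1 - p1) * p2, (1 - p2) * p1)
}

#' Call differential significance from probDiff
#'
#' A pathway is differentially significant when probDiff strictly exceeds
#' the cutoff (default 50 %).
#'
#' @param prob_diff numeric vector of probDiff values.
#' @param cutoff decision cutoff in (0, 1).
#' @return logical vector.
#' @export
call_differential_significance <- function(prob_diff, cutoff = 0.5) {
  stopifnot(cutoff > 0, cutoff < 1)
  !is.na(prob_diff) & prob_diff > cutoff
}

#' Differential activity table for two samples
#'
#' Outer join of two per-sample activity-level vectors on pathway id, with
#' ratio and call columns. Pathways present in only one sample keep their
#' one-sided level, an `NA` ratio and the call `one_sided`.
#'
#' @param levels1,levels2 named numeric vectors of activity levels (from
#'   [run_em()]).
#' @param up_threshold,down_threshold see [call_differential_activity()].
#' @return data frame with columns `pathway_id`, `level_sample1`,
#'   `level_sample2`, `ratio`, `call`, sorted by decreasing ratio.
#' @export
diff_activity_table <- function(levels1, levels2, up_threshold = 1.5,
                                down_threshold = 0.66) {
  ids <- union(names(levels1), names(levels2))
  l1 <- stats::setNames(levels1[ids], ids)
  l2 <- stats::setNames(levels2[ids], ids)
  one_sided <- is.na(l1) | is.na(l2)
  ratio <- activity_ratio(l1, l2)
  call <- call_differential_activity(ratio, up_threshold, down_threshold)
  call[one_sided] <- "one_sided"
  out <- data.frame(pathway_id = ids,
                    level_sample1 = unname(l1),
                    level_sample2 = unname(l2),
                    ratio = unname(ratio),
                    call = call,
                    stringsAsFactors = FALSE)
  out[order(-out$ratio, out$pathway_id, na.last = TRUE), , drop = FALSE]
}

#' Differential significance table for two samples
#'
#' Outer join of two per-sample p-value vectors on pathway id, with probDiff
#' and the differential call. probDiff is only defined when both p-values
#' are present; one-sided rows carry `NA` and `differential = NA`.
#'
#' @param p1,p2 named numeric vectors of per-pathway empirical p-values.
#' @param cutoff see [call_differential_significance()].
#' @return data frame with columns `pathway_id`, `p1`, `p2`, `prob_diff`,
#'   `differential`, sorted by decreasing probDiff.
#' @export
diff_significance_table <- function(p1, p2, cutoff = 0.5) {
  ids <- union(names(p1), names(p2))
  q1 <- stats::setNames(p1[ids], ids)
  q2 <- stats::setNames(p2[ids], ids)
  both <- !is.na(q1) & !is.na(q2)
  pd <- rep(NA_real_, length(ids))
  pd[both] <- prob_diff(q1[both], q2[both])
  diff <- rep(NA, length(ids))
  diff[both] <- call_differential_significance(pd[both], cutoff)
  out <- data.frame(pathway_id = ids, p1 = unname(q1), p2 = unname(q2),
                    prob_diff = pd, differential = diff,
                    stringsAsFactors = FALSE)
  out[order(-out$prob_diff, out$pathway_id, na.last = TRUE), , drop = FALSE]
}
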