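#' @title Uniform binary pathway-activity model
#' @description Iterative inference of pathway activity levels from a binary
#'   ortholog-group expression model. Each expressed ortholog group is
#'   assumed to participate equally in every currently active pathway that
#'   contains it; a pathway's activity level is the sum of its members'
#'   fractional participations, and its binary status is the level
#'   thresholded against T_w. Starting from all pathways active, levels and
#'   statuses are updated alternately until the status vector revisits a
#'   previous state: a fixed point (period 1) or an oscillation (period k).
#'   Reported levels are the mean over one terminal cycle.
#' @name em_activity
NULL

#' Fractional participation of one ortholog group in one pathway
#'
#' A group `g` contained in pathway `w` contributes
#' `1 / (1 + number of OTHER active pathways containing g)`
#' to `w`'s activity level: the group's unit of evidence is split equally
#' among the active pathways competing for it, plus `w` itself. The status
#' of `w` itself does not enter the denominator.
#'
#' @param g ortholog-group id; must be a member of `w`.
#' @param w pathway id.
#' @param collection a `pathway_collection`.
#' @param status named integer/logical vector of activity statuses, one per
#'   pathway in the collection.
#' @return the participation fraction in (0, 1].
#' @export
participation <- function(g, w, collection, status) {
  stopifnot(inherits(collection, "pathway_collection"))
  if (!w %in% names(collection$pathways) || !g %in% collection$pathways[[w]]) {
    stop(sprintf("group %s is not a member of pathway %s", g, w), call. = FALSE)
  }
  others <- setdiff(collection$group_index[[g]], w)
  1 / (1 + sum(as.integer(status[others])))
}

#' Activity levels of every pathway under a given status vector
#'
#' `f_w = sum over g in w of 1 / (1 + sum of delta(w') over other pathways
#' w' containing g)`. Computed for all pathways at once: the per-group count
#' of active containing pathways is formed once from the group index, and a
#' pathway's own status is subtracted from its members' denominators.
#'
#' @param collection a `pathway_collection`.
#' @param status named vector of 0/1 statuses covering every pathway.
#' @return named numeric vector of activity levels `f_w`.
#' @export
activity_levels <- function(collection, status) {
  stopifnot(inherits(collection, "pathway_collection"))
  pws <- names(collection$pathways)
  status <- as.integer(status[pws])
  names(status) <- pws
  if (anyNA(status)) stop("status vector must cover every pathway", call. = FALSE)
  # active_count[g] = number of active pathways containing g (including w)
  active_count <- vapply(collection$group_index,
                         function(p) sum(status[p]), integer(1))
  f <- vapply(pws, function(w) {
    g <- collection$pathways[[w]]
    sum(1 / (1 + active_count[g] - status[[w]]))
  }, numeric(1))
  stats::setNames(f, pws)
}

#' Threshold activity levels into binary statuses
#'
#' `delta(w) = 1` when `f_w >= T_w`, else 0. Thresholds may be a single
#' global value or a named vector with per-pathway overrides; pathways
#' absent from a named vector fall back to `default`.
#'
#' @param levels named numeric vector of activity levels.
#' @param thresholds numeric scalar or named vector of per-pathway T_w (> 0).
#' @param default global fallback threshold (default 1).
#' @return named integer vector of 0/1 statuses.
#' @export
update_status <- function(levels, thresholds = 1, default = 1) {
  tw <- resolve_thresholds(names(levels), thresholds, default)
  stats::setNames(as.integer(levels >= tw), names(levels))
}

resolve_thresholds <- function(pathway_ids, thresholds, default = 1) {
  if (is.null(names(thresholds)) && length(thresholds) == 1L) {
    tw <- rep(as.numeric(thresholds), length(pathway_ids))
  } else {
    tw <- as.numeric(thresholds[pathway_ids])
    tw[is.na(tw)] <- default
  }
  if (any(tw <= 0)) stop("thresholds T_w must be positive", call. = FALSE)
  stats::setNames(tw, pathway_ids)
}

#' Run the iterative activity algorithm
#'
#' Starts with every pathway active, then alternates [activity_levels()] and
#' [update_status()] while recording the status trajectory. Iteration stops
#' at the first status vector seen before; the distance back to its earlier
#' occurrence is the period `k` (`k = 1` is a fixed point, i.e. convergence).
#' Because the status space is finite the trajectory must enter a cycle;
#' `max_iter` merely bounds the search. Reported activity levels are the
#' arithmetic mean of `f_w` over the states of one terminal cycle, and the
#' reported final status is the status in the first state of that cycle.
#'
#' @param collection a non-empty `pathway_collection`, normally already
#'   restricted to the sample's expressed groups.
#' @param thresholds scalar or named vector of T_w (see [update_status()]).
#' @param max_iter iteration cap (default 1000).
#' @return an object of class `activity_result`: list with `levels`
#'   (cycle-mean f_w per pathway), `final_status` (0/1 per pathway, first
#'   state of the cycle), `cycle_states` (list of status vectors in the
#'   terminal cycle), `n_iterations`, `period`.
#' @export
run_em <- function(collection, thresholds = 1, max_iter = 1000L) {
  stopifnot(inherits(collection, "pathway_collection"))
  pws <- names(collection$pathways)
  if (length(pws) == 0L) stop("empty pathway collection", call. = FALSE)
  state <- stats::setNames(rep(1L, length(pws)), pws)
  history <- list(state)
  history_keys <- paste(state, collapse = "")
  repeat_at <- NA_integer_
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    f <- activity_levels(collection, state)
    state <- update_status(f, thresholds)
    key <- paste(state, collapse = "")
    hit <- match(key, history_keys)
    if (!is.na(hit)) {
      repeat_at <- hit
      break
    }
    history[[length(history) + 1L]] <- state
    history_keys <- c(history_keys, key)
  }
  if (is.na(repeat_at)) {
    stop(sprintf(paste0("no repeated status vector within %d iterations; ",
                        "partial trace has %d states"), max_iter, length(history)),
         call. = FALSE)
  }
  # terminal cycle: states repeat_at, ..., end of history
  cycle_states <- history[seq.int(repeat_at, length(history))]
  period <- length(cycle_states)
  f_cycle <- lapply(cycle_states, function(s) activity_levels(collection, s))
  levels <- Reduce(`+`, f_cycle) / period
  structure(list(levels = levels,
                 final_status = cycle_states[[1L]],
                 cycle_states = cycle_states,
                 n_iterations = iter,
                 period = period),
            class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("activity_result: %d pathways, period %d after %d iterations\n",
              length(x$levels), x$period, x$n_iterations))
  top <- utils::head(sort(x$levels, decreasing = TRUE), 5L)
  cat("top activity levels:\n")
  for (w in names(top)) cat(sprintf("  %s  %.4g\n", w, top[[w]]))
  invisible(x)
}
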