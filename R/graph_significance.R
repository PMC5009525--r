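#' @title Permutation null models and empirical pathway significance
#' @description Two randomization schemes generate the null ensemble against
#'   which an observed induced mapped subgraph is ranked. Vertex label
#'   swapping keeps the topology fixed and shuffles which nodes are mapped;
#'   edge swapping keeps the mapped labelling fixed and rewires edges while
#'   preserving every node's in- and out-degree. The empirical p-value is the
#'   1-based rank of the observed subgraph in the ensemble sorted by density
#'   (descending) then zero-degree fraction (ascending), divided by the
#'   ensemble size.
#' @name graph_significance
NULL

#' Vertex-label-swapping randomization
#'
#' Keeps the topology identical and performs `n_swaps` attempted swaps of the
#' mapped/unmapped labelling: each attempt draws two distinct nodes and, only
#' if their mapped flags differ, exchanges their flags (and ortholog-group
#' labels). Attempts drawing two same-flag nodes are rejected without effect,
#' so `n_swaps` counts attempts, not accepted swaps. The edge set, the degree
#' sequence and the number of mapped nodes are all invariant.
#'
#' Uses the current R RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param graph a `pathway_graph` with at least 2 nodes.
#' @param n_swaps number of attempted swaps.
#' @return a randomized `pathway_graph`; attribute `accepted_swaps` records
#'   how many attempts were accepted.
#' @export
vertex_label_swap <- function(graph, n_swaps) {
  stopifnot(inherits(graph, "pathway_graph"), n_swaps >= 0)
  n <- length(graph$nodes)
  if (n < 2L) stop("vertex label swapping needs at least 2 nodes", call. = FALSE)
  flags <- graph$mapped[graph$nodes]
  if (length(unique(flags)) < 2L) {
    message("all nodes carry the same mapped flag; no label swap possible")
    attr(graph, "accepted_swaps") <- 0L
    return(graph)
  }
  labels <- graph$labels[graph$nodes]
  accepted <- 0L
  if (n_swaps > 0) {
    for (s in seq_len(n_swaps)) {
      ij <- sample.int(n, 2L)
      i <- ij[1L]; j <- ij[2L]
      if (flags[i] != flags[j]) {
        tmp <- flags[i]; flags[i] <- flags[j]; flags[j] <- tmp
        tmpl <- labels[[i]]; labels[[i]] <- labels[[j]]; labels[[j]] <- tmpl
        accepted <- accepted + 1L
      }
    }
  }
  out <- pathway_graph(graph$pathway_id, graph$nodes,
                       labels = stats::setNames(labels, graph$nodes),
                       mapped = stats::setNames(unname(flags), graph$nodes),
                       edges = graph$edges)
  attr(out, "accepted_swaps") <- accepted
  out
}

#' Degree-preserving edge-swapping randomization
#'
#' Keeps node identities, labels and mapped flags fixed and performs
#' `n_swaps` attempted edge swaps: each attempt draws two distinct edges
#' (a -> b, c -> d) and proposes replacing them with (a -> d, c -> b), which
#' preserves every node's in-degree and out-degree. The attempt is rejected
#' when it would create a self-loop or an edge already present, so the graph
#' stays simple. `n_swaps` counts attempts.
#'
#' @param graph a `pathway_graph` with at least 2 edges.
#' @param n_swaps number of attempted swaps.
#' @return a randomized `pathway_graph`; attribute `accepted_swaps` records
#'   accepted attempts.
#' @export
edge_swap <- function(graph, n_swaps) {
  stopifnot(inherits(graph, "pathway_graph"), n_swaps >= 0)
  ne <- nrow(graph$edges)
  if (ne < 2L) {
    warning("edge swapping needs at least 2 edges; returning the graph unchanged",
            call. = FALSE)
    attr(graph, "accepted_swaps") <- 0L
    return(graph)
  }
  from <- graph$edges$from
  to <- graph$edges$to
  seen <- new.env(parent = emptyenv(), size = ne * 2L)
  for (k in seq_len(ne)) assign(paste(from[k], to[k], sep = "\r"), TRUE, envir = seen)
  accepted <- 0L
  if (n_swaps > 0) {
    for (s in seq_len(n_swaps)) {
      ij <- sample.int(ne, 2L)
      i <- ij[1L]; j <- ij[2L]
      a <- from[i]; b <- to[i]; cc <- from[j]; d <- to[j]
      if (a == d || cc == b) next                       # self-loop
      k1 <- paste(a, d, sep = "\r")
      k2 <- paste(cc, b, sep = "\r")
      if (exists(k1, envir = seen, inherits = FALSE) ||
          exists(k2, envir = seen, inherits = FALSE)) next  # duplicate edge
      rm(list = c(paste(a, b, sep = "\r"), paste(cc, d, sep = "\r")), envir = seen)
      assign(k1, TRUE, envir = seen)
      assign(k2, TRUE, envir = seen)
      to[i] <- d; to[j] <- b
      accepted <- accepted + 1L
    }
  }
  out <- pathway_graph(graph$pathway_id, graph$nodes, labels = graph$labels,
                       mapped = graph$mapped,
                       edges = data.frame(from = from, to = to,
                                          stringsAsFactors = FALSE))
  attr(out, "accepted_swaps") <- accepted
  out
}

#' Generate an ensemble of distinct randomized graphs
#'
#' Produces `m` pairwise-distinct randomizations of `graph` under the chosen
#' null model and records, for each, the metrics of its induced mapped
#' subgraph. Distinctness is judged on the mapped-flag assignment for the
#' vertex model and on the edge set for the edge model; duplicated null
#' states would bias the empirical rank, so slots that fail to produce a new
#' state within `max_retries` attempts raise an error (advising a smaller
#' `m`) instead of silently repeating.
#'
#' @param graph a `pathway_graph`; the whole pathway graph is permuted and
#'   the induced mapped subgraph re-derived per ensemble member.
#' @param model `"vertex_label_swap"` or `"edge_swap"`.
#' @param m ensemble size (default 200).
#' @param n_swaps attempted swaps per randomized graph (default 1e6; scale
#'   down for small fixtures).
#' @param seed optional integer seed applied before generation.
#' @param max_retries attempts allowed per ensemble slot (default 100).
#' @return an object of class `null_ensemble`: list with `model`, `m`,
#'   `n_swaps`, `seed`, `metrics_list` (length-`m` list of `graph_metrics`).
#' @export
generate_null_ensemble <- function(graph, model = c("vertex_label_swap", "edge_swap"),
                                   m = 200L, n_swaps = 1e6, seed = NULL,
                                   max_retries = 100L) {
  stopifnot(inherits(graph, "pathway_graph"), m >= 1)
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (model == "vertex_label_swap") {
    if (length(graph$nodes) < 2L || length(unique(graph$mapped)) < 2L)
      stop("graph admits no distinct label permutations; ",
           "needs >= 2 nodes with both mapped and unmapped present", call. = FALSE)
  } else {
    if (nrow(graph$edges) < 2L)
      stop("graph admits no edge swaps; needs >= 2 edges", call. = FALSE)
  }
  key_fun <- if (model == "vertex_label_swap") mapped_key else edge_key
  swap_fun <- if (model == "vertex_label_swap") vertex_label_swap else edge_swap
  seen <- new.env(parent = emptyenv(), size = m * 2L)
  metrics_list <- vector("list", m)
  for (slot in seq_len(m)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      g2 <- swap_fun(graph, n_swaps)
      key <- key_fun(g2)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        metrics_list[[slot]] <- compute_metrics(induced_mapped_subgraph(g2))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(paste0("could not generate %d distinct random graphs ",
                          "(stuck after %d at slot %d); the graph is too small or ",
                          "rigid -- use a smaller m"), m, slot - 1L, slot),
           call. = FALSE)
    }
  }
  structure(list(model = model, m = as.integer(m), n_swaps = n_swaps,
                 seed = seed, metrics_list = metrics_list),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: model %s, m = %d, n_swaps = %g\n",
              x$model, x$m, x$n_swaps))
  invisible(x)
}

#' Rank an observed subgraph in its null ensemble
#'
#' All `m` ensemble metric records plus the observed record are sorted by
#' density (largest to smallest), ties broken by zero-degree fraction
#' (smallest to largest). The observed record is placed after ensemble
#' entries with an identical sort key (conservative: ties inflate, never
#' deflate, the p-value). The empirical p-value is `rank / m`, clipped to 1
#' when the observed graph ranks last among the `m + 1` items.
#'
#' @param observed a `graph_metrics` record for the observed induced mapped
#'   subgraph.
#' @param ensemble a `null_ensemble`.
#' @param pathway_id optional pathway id carried into the result.
#' @return an object of class `significance_result`: list with `pathway_id`,
#'   `observed`, `rank`, `p_value` and `significance_class`.
#' @export
rank_and_pvalue <- function(observed, ensemble, pathway_id = NA_character_) {
  stopifnot(inherits(observed, "graph_metrics"), inherits(ensemble, "null_ensemble"),
            length(ensemble$metrics_list) >= 1L)
  d <- vapply(ensemble$metrics_list, `[[`, numeric(1), "density")
  z <- vapply(ensemble$metrics_list, `[[`, numeric(1), "zero_degree_fraction")
  ahead <- sum(d > observed$density |
                 (d == observed$density & z <= observed$zero_degree_fraction))
  rank <- 1L + ahead
  p <- min(1, rank / ensemble$m)
  structure(list(pathway_id = pathway_id, observed = observed, rank = rank,
                 p_value = p, significance_class = significance_class(p)),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("significance_result '%s': rank %d, p = %.4g (%s)\n",
              x$pathway_id, x$rank, x$p_value, x$significance_class))
  invisible(x)
}

#' Classify an empirical p-value
#'
#' A pathway mapping is `significant` when p < 5 %, `very_significant` when
#' p < 1 % and `most_significant` when p <= 0.5 %; otherwise
#' `not_significant`.
#'
#' @param p p-value(s) in (0, 1].
#' @return character vector of class labels.
#' @export
significance_class <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  ifelse(p <= 0.005, "most_significant",
         ifelse(p < 0.01, "very_significant",
                ifelse(p < 0.05, "significant", "not_significant")))
}

#' Significance test for one pathway graph
#'
#' Convenience wrapper: derives the induced mapped subgraph, generates the
#' null ensemble and ranks the observed metrics against it.
#'
#' @inheritParams generate_null_ensemble
#' @return a `significance_result`.
#' @export
pathway_significance <- function(graph, model = c("vertex_label_swap", "edge_swap"),
                                 m = 200L, n_swaps = 1e6, seed = NULL,
                                 max_retries = 100L) {
  model <- match.arg(model)
  observed <- compute_metrics(induced_mapped_subgraph(graph))
  ens <- generate_null_ensemble(graph, model, m = m, n_swaps = n_swaps,
                                seed = seed, max_retries = max_retries)
  rank_and_pvalue(observed, ens, pathway_id = graph$pathway_id)
}
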