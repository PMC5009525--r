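# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (triple loops, explicit sorts, full state simulation)
# and share no code with the package implementation they check.

# Brute-force simulation of the iterative binary activity model on a plain
# named list of member vectors.
oracle_em <- function(members, threshold) {
  pws <- names(members)
  f_of <- function(state) {
    vapply(pws, function(w) {
      terms <- vapply(members[[w]], function(g) {
        denom <- 1
        for (w2 in pws) {
          if (w2 != w && g %in% members[[w2]]) denom <- denom + state[[w2]]
        }
        1 / denom
      }, numeric(1))
      sum(terms)
    }, numeric(1))
  }
  state <- stats::setNames(rep(1L, length(pws)), pws)
  history <- list(state)
  keys <- paste(state, collapse = "")
  repeat {
    f <- f_of(state)
    state <- stats::setNames(as.integer(f >= threshold), pws)
    key <- paste(state, collapse = "")
    hit <- match(key, keys)
    if (!is.na(hit)) {
      cycle <- history[seq.int(hit, length(history))]
      f_cycle <- lapply(cycle, f_of)
      return(list(levels = Reduce(`+`, f_cycle) / length(cycle),
                  period = length(cycle),
                  n_iterations = length(keys),
                  final_status = cycle[[1L]]))
    }
    history <- c(history, list(state))
    keys <- c(keys, key)
  }
}

# Explicit-sort oracle for the empirical rank: sort the m null records plus
# the observed one by density (descending) then zero-degree fraction
# (ascending), observed after equal keys.
oracle_rank <- function(obs_density, obs_zdf, null_density, null_zdf) {
  df <- data.frame(density = c(null_density, obs_density),
                   zdf = c(null_zdf, obs_zdf),
                   is_obs = c(rep(FALSE, length(null_density)), TRUE))
  ord <- order(-df$density, df$zdf, df$is_obs)
  which(df$is_obs[ord])
}

# A small helper to build a pathway_graph from an edge string like
# "a->b b->c", with given mapped node names.
graph_from_edges <- function(edge_str, nodes = NULL, mapped = character(),
                             pathway_id = "koTEST") {
  pairs <- strsplit(strsplit(trimws(edge_str), "\\s+")[[1]], "->", fixed = TRUE)
  from <- vapply(pairs, `[`, character(1), 1)
  to <- vapply(pairs, `[`, character(1), 2)
  if (is.null(nodes)) nodes <- unique(c(from, to))
  flags <- stats::setNames(nodes %in% mapped, nodes)
  labels <- stats::setNames(as.list(paste0("K00", seq_along(nodes))), nodes)
  pathway_graph(pathway_id, nodes, labels = labels, mapped = flags,
                edges = data.frame(from = from, to = to, stringsAsFactors = FALSE))
}

# Random small pathway family as a plain named list (for oracle comparisons).
random_members <- function(n_pathways, n_groups, min_size = 1) {
  groups <- paste0("K", seq_len(n_groups))
  members <- lapply(seq_len(n_pathways), function(i) {
    size <- sample(seq.int(min_size, n_groups), 1)
    sample(groups, size)
  })
  stats::setNames(members, sprintf("ko%05d", seq_len(n_pathways)))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
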