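#' @title Seeded synthetic fixtures: pathway graphs, families and KGML files
#' @description Generators for the two kinds of input the pipeline consumes:
#'   directed enzyme graphs (optionally serialized as minimal KGML) and
#'   overlapping pathway families with a per-sample expressed set. All
#'   generators draw from the current R RNG stream, so a [set.seed()] call
#'   makes any fixture reproducible. The generators emulate the structural
#'   features the methods depend on -- overlapping membership, directed
#'   topology, partial mapping -- not biological realism.
#' @name synthetic_fixtures
NULL

#' Random simple directed pathway graph
#'
#' Draws a uniform simple directed graph (no self-loops, no parallel edges)
#' with exactly `n_nodes` nodes and `n_edges` edges. Each node carries one
#' synthetic KO label from the `K9xxxx` namespace; `mapped` flags are
#' assigned to a random subset of `round(mapped_fraction * n_nodes)` nodes.
#' The defaults match the smallest pathway graphs worth testing: 15 nodes
#' and 40 edges.
#'
#' @param n_nodes,n_edges graph size; requires
#'   `n_edges <= n_nodes * (n_nodes - 1)`.
#' @param mapped_fraction fraction of nodes flagged mapped (default 0.5).
#' @param pathway_id id given to the graph.
#' @param label_offset integer offset into the synthetic KO namespace, so
#'   several generated graphs can carry disjoint label sets.
#' @return a `pathway_graph`.
#' @export
random_pathway_graph <- function(n_nodes = 15L, n_edges = 40L,
                                 mapped_fraction = 0.5,
                                 pathway_id = "ko90001",
                                 label_offset = 0L) {
  stopifnot(n_nodes >= 1, n_edges >= 0, mapped_fraction >= 0, mapped_fraction <= 1)
  if (n_edges > n_nodes * (n_nodes - 1L)) {
    stop("infeasible: a simple directed graph on ", n_nodes,
         " nodes holds at most ", n_nodes * (n_nodes - 1L), " edges", call. = FALSE)
  }
  nodes <- paste0("n", seq_len(n_nodes))
  labels <- stats::setNames(as.list(sprintf("K9%04d", label_offset + seq_len(n_nodes))),
                            nodes)
  # enumerate ordered non-diagonal pairs and sample without replacement
  all_pairs <- seq_len(n_nodes * n_nodes)
  pairs <- all_pairs[(all_pairs - 1L) %% n_nodes != (all_pairs - 1L) %/% n_nodes]
  chosen <- if (n_edges > 0) sample(pairs, n_edges) else integer()
  from <- nodes[(chosen - 1L) %% n_nodes + 1L]
  to <- nodes[(chosen - 1L) %/% n_nodes + 1L]
  n_mapped <- round(mapped_fraction * n_nodes)
  mapped <- stats::setNames(rep(FALSE, n_nodes), nodes)
  if (n_mapped > 0) mapped[sample.int(n_nodes, n_mapped)] <- TRUE
  pathway_graph(pathway_id, nodes, labels = labels, mapped = mapped,
                edges = data.frame(from = from, to = to, stringsAsFactors = FALSE))
}

#' Random overlapping pathway family with an expressed sample
#'
#' Builds `n_pathways` pathways whose sizes are drawn uniformly from
#' `groups_range`. A fraction `overlap_fraction` of each pathway's members
#' is drawn from groups already used by earlier pathways (when any exist),
#' so pathways share ortholog groups the way KEGG maps do; the rest are
#' fresh groups. The expressed set contains every member of the
#' `planted_active` pathways plus a `background_fraction` of the remaining
#' groups, giving a planted signal recoverable by the activity and
#' significance branches.
#'
#' @param n_pathways number of pathways.
#' @param groups_range length-2 integer range of members per pathway.
#' @param overlap_fraction fraction of members reused from earlier pathways.
#' @param planted_active pathway ids (or integer indices) whose members are
#'   fully expressed; default none.
#' @param background_fraction fraction of non-planted groups expressed as
#'   background noise (default 0.1).
#' @param sample_id label for the generated sample.
#' @return list with elements `collection` (a `pathway_collection`) and
#'   `sample` (a `sample_expression`).
#' @export
random_pathway_family <- function(n_pathways = 20L, groups_range = c(4L, 10L),
                                  overlap_fraction = 0.3,
                                  planted_active = character(),
                                  background_fraction = 0.1,
                                  sample_id = "synthetic") {
  stopifnot(n_pathways >= 1, length(groups_range) == 2L,
            groups_range[1] >= 1, groups_range[2] >= groups_range[1],
            overlap_fraction >= 0, overlap_fraction <= 1,
            background_fraction >= 0, background_fraction <= 1)
  ids <- sprintf("ko9%04d", seq_len(n_pathways))
  if (is.numeric(planted_active)) planted_active <- ids[planted_active]
  pool <- character()
  next_group <- 1L
  members <- vector("list", n_pathways)
  for (i in seq_len(n_pathways)) {
    size <- if (groups_range[1] == groups_range[2]) groups_range[1] else
      sample(seq.int(groups_range[1], groups_range[2]), 1L)
    n_shared <- min(round(overlap_fraction * size), length(pool))
    shared <- if (n_shared > 0) sample(pool, n_shared) else character()
    n_new <- size - length(shared)
    fresh <- if (n_new > 0) sprintf("K0%04d", seq.int(next_group, next_group + n_new - 1L))
             else character()
    next_group <- next_group + n_new
    members[[i]] <- c(shared, fresh)
    pool <- union(pool, members[[i]])
  }
  names(members) <- ids
  collection <- pathway_collection(members)
  planted_groups <- unique(unlist(members[planted_active], use.names = FALSE))
  rest <- setdiff(pool, planted_groups)
  n_bg <- round(background_fraction * length(rest))
  background <- if (n_bg > 0) sample(rest, n_bg) else character()
  list(collection = collection,
       sample = sample_expression(c(planted_groups, background), sample_id))
}

#' Write a pathway graph as a minimal KGML file
#'
#' Serializes topology and labels in the KGML subset [parse_kgml()] reads:
#' one `ortholog`-type `<entry>` per node (labels as space-separated
#' `ko:`-prefixed names) and one `<relation>` per edge. `mapped` flags are a
#' per-sample property with no KGML representation, so
#' `parse_kgml(write_kgml_fixture(g))` reproduces `g`'s nodes, labels and
#' edges with all flags reset; use [mark_mapped()] to restore them.
#'
#' @param graph a `pathway_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kgml_fixture <- function(graph, path) {
  stopifnot(inherits(graph, "pathway_graph"))
  esc <- function(x) gsub("\"", "&quot;", gsub("<", "&lt;", gsub("&", "&amp;", x)))
  entry_lines <- vapply(graph$nodes, function(nid) {
    lab <- graph$labels[[nid]]
    nm <- if (length(lab)) paste(paste0("ko:", lab), collapse = " ") else ""
    sprintf('  <entry id="%s" name="%s" type="ortholog"/>', esc(nid), esc(nm))
  }, character(1))
  rel_lines <- if (nrow(graph$edges)) {
    sprintf('  <relation entry1="%s" entry2="%s" type="ECrel"/>',
            esc(graph$edges$from), esc(graph$edges$to))
  } else character()
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               sprintf('<pathway name="path:%s" org="ko" title="synthetic fixture">',
                       esc(graph$pathway_id)),
               entry_lines, rel_lines, "</pathway>"),
             path)
  invisible(path)
}
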