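#' @title Directed enzyme graphs from KGML pathway maps
#' @description A pathway map is viewed as a directed graph whose nodes are
#'   enzymes (KO/EC-labelled entries) and whose edges are the map's relations.
#'   Nodes carry a `mapped` flag: TRUE when any of the node's ortholog-group
#'   labels has RNA-Seq evidence in the sample under study (the "green"
#'   enzymes on a KEGG map rendering).
#' @name kgml_graph
NULL

#' Construct a pathway graph
#'
#' @param pathway_id pathway identifier.
#' @param nodes character vector of node ids (opaque strings, unique).
#' @param labels named list mapping each node id to a character vector of
#'   ortholog-group labels.
#' @param mapped named logical vector, one flag per node; defaults to all
#'   FALSE.
#' @param edges two-column data frame (`from`, `to`) of directed edges.
#'   Parallel edges are collapsed and self-loops dropped: density and degree
#'   statistics are defined on a simple directed graph.
#' @return an object of class `pathway_graph`.
#' @export
pathway_graph <- function(pathway_id, nodes, labels = NULL, mapped = NULL,
                          edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids", call. = FALSE)
  if (is.null(labels)) labels <- stats::setNames(vector("list", length(nodes)), nodes)
  labels <- labels[nodes]
  names(labels) <- nodes
  labels <- lapply(labels, function(x) if (is.null(x)) character() else as.character(x))
  if (is.null(mapped)) mapped <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  mapped <- stats::setNames(as.logical(mapped[nodes]), nodes)
  mapped[is.na(mapped)] <- FALSE
  if (is.null(edges)) edges <- data.frame(from = character(), to = character(),
                                          stringsAsFactors = FALSE)
  edges <- data.frame(from = as.character(edges$from), to = as.character(edges$to),
                      stringsAsFactors = FALSE)
  if (nrow(edges)) {
    bad <- !(edges$from %in% nodes) | !(edges$to %in% nodes)
    if (any(bad)) stop("edge endpoint not among nodes", call. = FALSE)
    edges <- edges[edges$from != edges$to, , drop = FALSE]
    edges <- unique(edges)
    rownames(edges) <- NULL
  }
  structure(list(pathway_id = pathway_id, nodes = nodes, labels = labels,
                 mapped = mapped, edges = edges),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph '%s': %d nodes (%d mapped), %d directed edges\n",
              x$pathway_id, length(x$nodes), sum(x$mapped), nrow(x$edges)))
  invisible(x)
}

# canonical sorted edge-key representation, used for equality and
# ensemble-distinctness checks
edge_key <- function(graph) {
  if (nrow(graph$edges) == 0L) return("")
  paste(sort(paste(graph$edges$from, graph$edges$to, sep = "\r")), collapse = "\n")
}

mapped_key <- function(graph) {
  paste(graph$nodes[graph$mapped[graph$nodes]], collapse = "\r")
}

#' Parse a KGML pathway map into a directed enzyme graph
#'
#' One node is created per KGML `<entry>` of type `ortholog`, `gene` or
#' `enzyme`; the entry `name` attribute is split on whitespace and the
#' `ko:`/`ec:` prefixes stripped to obtain the node's ortholog-group labels.
#' One directed edge is created per `<relation>` between two retained
#' entries. Entries of type `map` and `compound` are not nodes; a relation
#' chain passing through a compound entry is collapsed to a direct
#' enzyme-to-enzyme edge. Duplicate edges are collapsed and self-loops
#' dropped. All `mapped` flags start FALSE; see [mark_mapped()].
#'
#' @param path a KGML (KEGG XML) file.
#' @return a `pathway_graph`.
#' @export
parse_kgml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  pathway_id <- xml2::xml_attr(doc, "name")
  if (is.na(pathway_id)) pathway_id <- tools::file_path_sans_ext(basename(path))
  pathway_id <- sub("^path:", "", pathway_id)

  entries <- xml2::xml_find_all(doc, ".//entry")
  ids <- xml2::xml_attr(entries, "id")
  types <- xml2::xml_attr(entries, "type")
  enames <- xml2::xml_attr(entries, "name")
  enzyme_like <- types %in% c("ortholog", "gene", "enzyme")
  node_ids <- ids[enzyme_like]
  compound_ids <- ids[types %in% "compound"]
  labels <- lapply(enames[enzyme_like], function(nm) {
    if (is.na(nm) || !nzchar(nm)) return(character())
    toks <- strsplit(trimws(nm), "\\s+")[[1]]
    unique(sub("^(ko|ec):", "", toks))
  })
  names(labels) <- node_ids
  if (length(node_ids) == 0L) {
    warning("KGML file has no enzyme-type entries: ", path, call. = FALSE)
    return(pathway_graph(pathway_id, character()))
  }

  rels <- xml2::xml_find_all(doc, ".//relation")
  r1 <- xml2::xml_attr(rels, "entry1")
  r2 <- xml2::xml_attr(rels, "entry2")
  direct <- r1 %in% node_ids & r2 %in% node_ids
  from <- r1[direct]
  to <- r2[direct]
  # collapse enzyme -> compound -> enzyme relation chains
  for (cid in compound_ids) {
    ins <- r1[r2 == cid & r1 %in% node_ids]
    outs <- r2[r1 == cid & r2 %in% node_ids]
    if (length(ins) && length(outs)) {
      pairs <- expand.grid(from = ins, to = outs, stringsAsFactors = FALSE)
      from <- c(from, pairs$from)
      to <- c(to, pairs$to)
    }
  }
  pathway_graph(pathway_id, node_ids, labels = labels,
                edges = data.frame(from = from, to = to, stringsAsFactors = FALSE))
}

#' Flag nodes with expression evidence
#'
#' Sets `mapped = TRUE` for every node whose label set intersects the
#' sample's expressed ortholog groups; the topology is unchanged.
#'
#' @param graph a `pathway_graph`.
#' @param sample a `sample_expression`.
#' @return the graph with updated `mapped` flags.
#' @export
mark_mapped <- function(graph, sample) {
  stopifnot(inherits(graph, "pathway_graph"), inherits(sample, "sample_expression"))
  graph$mapped <- stats::setNames(
    vapply(graph$labels, function(l) any(l %in% sample$expressed), logical(1)),
    graph$nodes)
  graph
}

#' Induced subgraph of mapped nodes
#'
#' Restricts the pathway graph to its mapped (expressed) nodes and to the
#' edges with both endpoints mapped. This is the object whose coherence the
#' permutation tests score: under the model, the expressed enzymes of a truly
#' active pathway should form a connected, dense induced subgraph.
#'
#' @param graph a `pathway_graph`.
#' @return a `pathway_graph` containing only mapped nodes.
#' @export
induced_mapped_subgraph <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  keep <- graph$nodes[graph$mapped[graph$nodes]]
  e <- graph$edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  pathway_graph(graph$pathway_id, keep, labels = graph$labels[keep],
                mapped = graph$mapped[keep], edges = e)
}

#' Topology metrics of an induced mapped subgraph
#'
#' Computes the statistics used to rank a subgraph against its permutation
#' null ensemble:
#' \describe{
#'   \item{density}{edges / (nodes - 1); defined as 0 when the subgraph has
#'     at most one node.}
#'   \item{zero_degree_fraction}{(number of nodes with out-degree 0 + number
#'     with in-degree 0) / (2 * nodes); 0 for the empty graph. An isolated
#'     node contributes both terms, so the fraction lies in \[0, 1\].}
#'   \item{component statistics}{count of weakly connected components, and
#'     the largest node count and largest edge count over components.}
#' }
#'
#' @param graph a `pathway_graph`, normally the induced mapped subgraph.
#' @return an object of class `graph_metrics`: a list with fields
#'   `n_mapped_nodes`, `n_edges`, `density`, `zero_degree_fraction`,
#'   `n_components`, `largest_cc_nodes`, `largest_cc_edges`.
#' @export
compute_metrics <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  n <- length(graph$nodes)
  ne <- nrow(graph$edges)
  density <- if (n <= 1L) 0 else ne / (n - 1L)
  if (n == 0L) {
    zdf <- 0
    n_comp <- 0L
    cc_nodes <- 0L
    cc_edges <- 0L
  } else {
    out0 <- sum(!(graph$nodes %in% graph$edges$from))
    in0 <- sum(!(graph$nodes %in% graph$edges$to))
    zdf <- (out0 + in0) / (2 * n)
    ig <- igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                        vertices = data.frame(name = graph$nodes))
    comp <- igraph::components(ig, mode = "weak")
    n_comp <- comp$no
    cc_nodes <- max(comp$csize)
    memb <- comp$membership
    cc_edges <- if (ne == 0L) 0L else max(tabulate(memb[graph$edges$from], nbins = comp$no))
  }
  structure(list(n_mapped_nodes = n, n_edges = ne, density = density,
                 zero_degree_fraction = zdf, n_components = n_comp,
                 largest_cc_nodes = cc_nodes, largest_cc_edges = as.integer(cc_edges)),
            class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf(paste0("graph_metrics: %d nodes, %d edges, density %.4g, ",
                     "zero-degree fraction %.4g, %d weak components\n"),
              x$n_mapped_nodes, x$n_edges, x$density, x$zero_degree_fraction,
              x$n_components))
  invisible(x)
}

#' Dump a pathway graph as TSV tables
#'
#' Debug output: a two-column directed edge list and a node table
#' (`node_id`, semicolon-joined `labels`, `mapped`).
#'
#' @param graph a `pathway_graph`.
#' @param edge_path,node_path output paths (either may be NULL to skip).
#' @return invisibly, the graph.
#' @export
write_graph_tsv <- function(graph, edge_path = NULL, node_path = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (!is.null(edge_path)) {
    utils::write.table(graph$edges, edge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  if (!is.null(node_path)) {
    nt <- data.frame(node_id = graph$nodes,
                     labels = vapply(graph$labels, paste, character(1), collapse = ";"),
                     mapped = graph$mapped[graph$nodes],
                     stringsAsFactors = FALSE)
    utils::write.table(nt, node_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(graph)
}
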