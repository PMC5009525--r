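#' @title End-to-end analysis runs and TSV result files
#' @description Orchestration of the two analysis branches and the
#'   differential step. Each runner reads plain-text inputs, executes the
#'   corresponding model and (optionally) writes a TSV whose `#`-prefixed
#'   provenance header records the package version and all parameters, so a
#'   rerun with the same inputs and seed is byte-identical.
#' @name pipeline
NULL

provenance_header <- function(params) {
  c(sprintf("# pathact %s", as.character(utils::packageVersion("pathact"))),
    vapply(names(params), function(k) sprintf("# %s = %s", k, params[[k]]),
           character(1)))
}

write_result_tsv <- function(df, path, params) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a result TSV written by an analysis runner
#'
#' @param path a TSV with `#` comment header lines.
#' @return data frame.
#' @export
read_result_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the activity branch
#'
#' Membership table + expressed set -> restrict to expressed groups ->
#' (optional) minimum-size filter -> iterative activity model -> per-pathway
#' table of cycle-mean activity levels.
#'
#' @param pathways_file membership TSV (see [read_pathway_membership()]).
#' @param expressed_file expressed-set file (see [read_expressed_set()]).
#' @param out optional output TSV path.
#' @param threshold global activity threshold T_w (default 1).
#' @param min_groups minimum expressed members to keep a pathway in the
#'   activity branch (default 1: any pathway with evidence enters).
#' @param max_iter iteration cap for [run_em()].
#' @return data frame with columns `pathway_id`, `activity_level`,
#'   `final_status`, `period`, `n_iterations`, sorted by decreasing level.
#' @export
run_activity_analysis <- function(pathways_file, expressed_file, out = NULL,
                                  threshold = 1, min_groups = 1L,
                                  max_iter = 1000L) {
  collection <- read_pathway_membership(pathways_file)
  sample <- read_expressed_set(expressed_file)
  working <- filter_min_mapped(restrict_to_sample(collection, sample), min_groups)
  if (length(working) == 0L) {
    warning("no pathway has expressed members; empty result", call. = FALSE)
    df <- data.frame(pathway_id = character(), activity_level = numeric(),
                     final_status = integer(), period = integer(),
                     n_iterations = integer(), stringsAsFactors = FALSE)
  } else {
    res <- run_em(working, thresholds = threshold, max_iter = max_iter)
    df <- data.frame(pathway_id = names(res$levels),
                     activity_level = unname(res$levels),
                     final_status = unname(res$final_status[names(res$levels)]),
                     period = res$period,
                     n_iterations = res$n_iterations,
                     stringsAsFactors = FALSE)
    df <- df[order(-df$activity_level, df$pathway_id), , drop = FALSE]
  }
  if (!is.null(out)) {
    write_result_tsv(df, out, list(branch = "activity",
                                   pathways = pathways_file,
                                   expressed = expressed_file,
                                   threshold = threshold,
                                   min_groups = min_groups))
  }
  df
}

#' Run the graph-significance branch
#'
#' For every KGML file: parse to a directed enzyme graph, flag nodes with
#' expression evidence, skip pathways with fewer than `min_mapped` distinct
#' mapped ortholog groups, then generate the permutation null ensemble and
#' rank the observed induced subgraph. Skipped pathways appear in the output
#' with a `reason` and `NA` statistics.
#'
#' @param kgml_files character vector of KGML paths, or a directory whose
#'   `*.xml`/`*.kgml` files are used.
#' @param expressed_file expressed-set file.
#' @param out optional output TSV path.
#' @param model `"vertex_label_swap"` or `"edge_swap"`.
#' @param m ensemble size (default 200).
#' @param n_swaps attempted swaps per ensemble member (default 1e6).
#' @param seed integer seed for the whole run.
#' @param min_mapped minimum distinct mapped ortholog groups (default 3).
#' @return data frame with columns `pathway_id`, `model`, `n_mapped_nodes`,
#'   `density`, `zero_degree_fraction`, `rank`, `p_value`,
#'   `significance_class`, `reason`.
#' @export
run_significance_analysis <- function(kgml_files, expressed_file, out = NULL,
                                      model = c("vertex_label_swap", "edge_swap"),
                                      m = 200L, n_swaps = 1e6, seed = 1L,
                                      min_mapped = 3L) {
  model <- match.arg(model)
  if (length(kgml_files) == 1L && dir.exists(kgml_files)) {
    kgml_files <- list.files(kgml_files, pattern = "\\.(xml|kgml)$",
                             full.names = TRUE)
  }
  if (length(kgml_files) == 0L) stop("no KGML files to analyse", call. = FALSE)
  sample <- read_expressed_set(expressed_file)
  set.seed(seed)
  rows <- lapply(kgml_files, function(f) {
    graph <- mark_mapped(parse_kgml(f), sample)
    mapped_groups <- unique(unlist(graph$labels[graph$mapped[graph$nodes]],
                                   use.names = FALSE))
    mapped_groups <- intersect(mapped_groups, sample$expressed)
    base <- data.frame(pathway_id = graph$pathway_id, model = model,
                       n_mapped_nodes = NA_integer_, density = NA_real_,
                       zero_degree_fraction = NA_real_, rank = NA_integer_,
                       p_value = NA_real_, significance_class = NA_character_,
                       reason = "", stringsAsFactors = FALSE)
    if (length(mapped_groups) < min_mapped) {
      base$reason <- "min_mapped"
      return(base)
    }
    res <- tryCatch(
      pathway_significance(graph, model, m = m, n_swaps = n_swaps),
      error = function(e) e)
    if (inherits(res, "error")) {
      base$reason <- conditionMessage(res)
      return(base)
    }
    base$n_mapped_nodes <- res$observed$n_mapped_nodes
    base$density <- res$observed$density
    base$zero_degree_fraction <- res$observed$zero_degree_fraction
    base$rank <- res$rank
    base$p_value <- res$p_value
    base$significance_class <- res$significance_class
    base
  })
  df <- do.call(rbind, rows)
  if (!is.null(out)) {
    write_result_tsv(df, out, list(branch = "significance", model = model,
                                   expressed = expressed_file, m = m,
                                   n_swaps = format(n_swaps, scientific = FALSE),
                                   seed = seed, min_mapped = min_mapped))
  }
  df
}

#' Run the differential step on two same-branch result tables
#'
#' Joins two activity tables (ratio analysis) or two significance tables
#' (probDiff analysis) on pathway id. Mixing branches is an error.
#'
#' @param file1,file2 result TSVs written by [run_activity_analysis()] or
#'   [run_significance_analysis()] (sample 1 and sample 2).
#' @param type `"activity"` or `"significance"`.
#' @param out optional output TSV path.
#' @param up_threshold,down_threshold fold thresholds for the activity
#'   branch.
#' @param cutoff probDiff cutoff for the significance branch.
#' @return the differential data frame (see [diff_activity_table()] /
#'   [diff_significance_table()]).
#' @export
run_differential_analysis <- function(file1, file2,
                                      type = c("activity", "significance"),
                                      out = NULL, up_threshold = 1.5,
                                      down_threshold = 0.66, cutoff = 0.5) {
  type <- match.arg(type)
  t1 <- read_result_tsv(file1)
  t2 <- read_result_tsv(file2)
  if (type == "activity") {
    if (!all(c("pathway_id", "activity_level") %in% names(t1)) ||
        !all(c("pathway_id", "activity_level") %in% names(t2))) {
      stop("inputs are not activity-branch result tables", call. = FALSE)
    }
    df <- diff_activity_table(
      stats::setNames(t1$activity_level, t1$pathway_id),
      stats::setNames(t2$activity_level, t2$pathway_id),
      up_threshold, down_threshold)
    params <- list(branch = "diff-activity", sample1 = file1, sample2 = file2,
                   up_threshold = up_threshold, down_threshold = down_threshold)
  } else {
    if (!all(c("pathway_id", "p_value") %in% names(t1)) ||
        !all(c("pathway_id", "p_value") %in% names(t2))) {
      stop("inputs are not significance-branch result tables", call. = FALSE)
    }
    ok1 <- !is.na(t1$p_value); ok2 <- !is.na(t2$p_value)
    df <- diff_significance_table(
      stats::setNames(t1$p_value[ok1], t1$pathway_id[ok1]),
      stats::setNames(t2$p_value[ok2], t2$pathway_id[ok2]),
      cutoff)
    params <- list(branch = "diff-significance", sample1 = file1,
                   sample2 = file2, cutoff = cutoff)
  }
  if (!is.null(out)) write_result_tsv(df, out, params)
  df
}

#' Materialize a synthetic fixture suite on disk
#'
#' Writes, under `dir`: a pathway membership TSV, expressed-set files for
#' two samples (sample 1 with planted active pathways, sample 2 with a
#' different planted set), and one KGML file per generated pathway graph.
#' Each sample also expresses a random subset of every graph's enzyme
#' labels (a larger share in sample 1), so the significance branch has
#' mapped nodes to score. Everything derives from the current RNG stream;
#' call [set.seed()] first for a reproducible suite.
#'
#' @param dir output directory (created if needed).
#' @param n_pathways,n_graphs family and graph counts.
#' @param planted1,planted2 indices of pathways planted active in each
#'   sample.
#' @return invisibly, a list of the written paths.
#' @export
write_fixture_suite <- function(dir, n_pathways = 20L, n_graphs = 3L,
                                planted1 = 1:3, planted2 = 4:6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam1 <- random_pathway_family(n_pathways, planted_active = planted1,
                                sample_id = "sample1")
  sample2_groups <- unique(unlist(fam1$collection$pathways[planted2],
                                  use.names = FALSE))
  membership <- file.path(dir, "membership.tsv")
  write_pathway_membership(fam1$collection, membership)
  kgml <- character(n_graphs)
  graph_expr1 <- graph_expr2 <- character()
  for (i in seq_len(n_graphs)) {
    g <- random_pathway_graph(pathway_id = sprintf("ko8%04d", i),
                              label_offset = (i - 1L) * 100L)
    kgml[i] <- file.path(dir, sprintf("ko8%04d.xml", i))
    write_kgml_fixture(g, kgml[i])
    labs <- unlist(g$labels, use.names = FALSE)
    graph_expr1 <- c(graph_expr1, sample(labs, round(0.6 * length(labs))))
    graph_expr2 <- c(graph_expr2, sample(labs, round(0.3 * length(labs))))
  }
  s1 <- file.path(dir, "sample1_expressed.txt")
  writeLines(c(fam1$sample$expressed, graph_expr1), s1)
  s2 <- file.path(dir, "sample2_expressed.txt")
  writeLines(c(sample2_groups, graph_expr2), s2)
  invisible(list(membership = membership, sample1 = s1, sample2 = s2,
                 kgml = kgml))
}
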