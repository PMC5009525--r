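test_that("vertex label swap exchanges differing flags and keeps topology", {
  g <- graph_from_edges("a->b", mapped = "a")
  set.seed(1)
  g2 <- vertex_label_swap(g, 1)
  expect_identical(unname(g2$mapped[c("a", "b")]), c(FALSE, TRUE))
  expect_identical(g2$edges, g$edges)
  # labels travel with the flags
  expect_identical(g2$labels[["a"]], g$labels[["b"]])
  expect_identical(vertex_label_swap(g, 0)$mapped, g$mapped)
})

test_that("vertex label swap preserves edge set, degrees and mapped count", {
  set.seed(2)
  for (rep in 1:8) {
    g <- random_pathway_graph(sample(5:20, 1), sample(5:30, 1), runif(1, 0.2, 0.8))
    g2 <- vertex_label_swap(g, sample(c(0, 1, 50, 500), 1))
    expect_setequal(paste(g2$edges$from, g2$edges$to),
                    paste(g$edges$from, g$edges$to))
    expect_identical(g2$nodes, g$nodes)
    expect_equal(sum(g2$mapped), sum(g$mapped))
  }
  all_same <- graph_from_edges("a->b b->c", mapped = character())
  expect_message(g3 <- vertex_label_swap(all_same, 10), "no label swap")
  expect_identical(g3$mapped, all_same$mapped)
})

test_that("edge swap rewires a pair of edges when legal", {
  g <- graph_from_edges("a->b c->d", mapped = "a")
  set.seed(3)
  g2 <- edge_swap(g, 1)
  expect_setequal(paste(g2$edges$from, g2$edges$to), c("a d", "c b"))
  expect_identical(g2$mapped, g$mapped)
  expect_identical(edge_swap(g, 0)$edges, g$edges)
  small <- graph_from_edges("a->b")
  expect_warning(g3 <- edge_swap(small, 5), "at least 2 edges")
  expect_identical(g3$edges, small$edges)
})

test_that("edge swap preserves every node's in- and out-degree", {
  set.seed(4)
  for (rep in 1:8) {
    g <- random_pathway_graph(sample(6:20, 1), sample(10:40, 1), 0.5)
    g2 <- edge_swap(g, sample(c(10, 200, 2000), 1))
    for (v in g$nodes) {
      expect_equal(sum(g2$edges$from == v), sum(g$edges$from == v))
      expect_equal(sum(g2$edges$to == v), sum(g$edges$to == v))
    }
    # still simple: no self-loops, no duplicates
    expect_false(any(g2$edges$from == g2$edges$to))
    expect_false(anyDuplicated(paste(g2$edges$from, g2$edges$to)) > 0)
    expect_identical(g2$mapped, g$mapped)
    expect_identical(g2$labels, g$labels)
  }
})

test_that("null ensembles are distinct, seed-reproducible and sized m", {
  set.seed(9)
  g <- random_pathway_graph(15, 40, 0.5)
  for (model in c("vertex_label_swap", "edge_swap")) {
    ens <- generate_null_ensemble(g, model, m = 25, n_swaps = 500, seed = 123)
    expect_length(ens$metrics_list, 25)
    ens2 <- generate_null_ensemble(g, model, m = 25, n_swaps = 500, seed = 123)
    expect_identical(ens$metrics_list, ens2$metrics_list)
    one <- generate_null_ensemble(g, model, m = 1, n_swaps = 100, seed = 5)
    expect_length(one$metrics_list, 1)
  }
})

test_that("rigid or degenerate graphs refuse to build an ensemble", {
  all_mapped <- graph_from_edges("a->b b->c", mapped = c("a", "b", "c"))
  expect_error(generate_null_ensemble(all_mapped, "vertex_label_swap", m = 5,
                                      n_swaps = 10),
               "mapped and unmapped")
  # a 2-cycle admits no accepted edge swap: only one reachable edge set
  rigid <- graph_from_edges("a->b b->a", mapped = "a")
  expect_error(generate_null_ensemble(rigid, "edge_swap", m = 3, n_swaps = 50,
                                      seed = 1, max_retries = 10),
               "smaller m")
})

test_that("rank and p-value match an explicit-sort oracle, including ties", {
  make_metrics <- function(d, z) {
    structure(list(n_mapped_nodes = 5L, n_edges = 5L, density = d,
                   zero_degree_fraction = z, n_components = 1L,
                   largest_cc_nodes = 5L, largest_cc_edges = 5L),
              class = "graph_metrics")
  }
  make_ens <- function(d, z, model = "vertex_label_swap") {
    structure(list(model = model, m = length(d), n_swaps = 0, seed = NULL,
                   metrics_list = Map(make_metrics, d, z)),
              class = "null_ensemble")
  }
  # observed ties with 2 of 5 at the top -> placed after them: rank 3
  ens <- make_ens(d = c(2, 2, 1, 0.5, 0.2), z = c(0.1, 0.1, 0, 0, 0.5))
  r <- rank_and_pvalue(make_metrics(2, 0.1), ens)
  expect_equal(r$rank, 3)
  expect_equal(r$p_value, 3 / 5)
  # strictly worst of m = 4 -> rank 5, p clipped to 1
  ens4 <- make_ens(d = c(3, 2.5, 2, 1.5), z = rep(0, 4))
  worst <- rank_and_pvalue(make_metrics(0.1, 0.9), ens4)
  expect_equal(worst$rank, 5)
  expect_equal(worst$p_value, 1)
  # randomized cases against the oracle
  set.seed(10)
  for (rep in 1:25) {
    m <- sample(3:12, 1)
    d <- sample(seq(0, 2, 0.25), m, replace = TRUE)
    z <- sample(seq(0, 1, 0.25), m, replace = TRUE)
    od <- sample(seq(0, 2, 0.25), 1)
    oz <- sample(seq(0, 1, 0.25), 1)
    r <- rank_and_pvalue(make_metrics(od, oz), make_ens(d, z))
    expect_equal(r$rank, oracle_rank(od, oz, d, z))
    expect_equal(r$p_value, min(1, r$rank / m))
  }
})

test_that("significance classes follow the 0.5/1/5 percent boundaries", {
  expect_equal(significance_class(0.005), "most_significant")
  expect_equal(significance_class(0.004), "most_significant")
  expect_equal(significance_class(0.0075), "very_significant")
  expect_equal(significance_class(0.01), "significant")
  expect_equal(significance_class(0.049), "significant")
  expect_equal(significance_class(0.05), "not_significant")
  expect_equal(significance_class(0.75), "not_significant")
  expect_error(significance_class(0), "\\(0, 1\\]")
  expect_error(significance_class(1.2), "\\(0, 1\\]")
})

test_that("a full significance run is reproducible under a fixed seed", {
  set.seed(12)
  g <- random_pathway_graph(15, 40, 0.5)
  r1 <- pathway_significance(g, "edge_swap", m = 20, n_swaps = 300, seed = 77)
  r2 <- pathway_significance(g, "edge_swap", m = 20, n_swaps = 300, seed = 77)
  expect_identical(r1, r2)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
})
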