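kgml_fixture <- function(body, pathway = "ko00062") {
  write_lines_tmp(c('<?xml version="1.0"?>',
                    sprintf('<pathway name="path:%s" org="ko">', pathway),
                    body,
                    "</pathway>"), ".xml")
}

test_that("KGML entries and relations become nodes and directed edges", {
  f <- kgml_fixture(c('<entry id="1" name="ko:K00001" type="ortholog"/>',
                      '<entry id="2" name="ko:K00002 ko:K00003" type="ortholog"/>',
                      '<entry id="3" name="ec:1.1.1.1" type="enzyme"/>',
                      '<relation entry1="1" entry2="2" type="ECrel"/>',
                      '<relation entry1="2" entry2="3" type="ECrel"/>'))
  g <- parse_kgml(f)
  expect_identical(g$pathway_id, "ko00062")
  expect_length(g$nodes, 3)
  expect_equal(nrow(g$edges), 2)
  expect_setequal(g$labels[["2"]], c("K00002", "K00003"))  # prefixes stripped
  expect_equal(g$labels[["3"]], "1.1.1.1")
  expect_false(any(g$mapped))
})

test_that("duplicate relations collapse and map entries are excluded", {
  f <- kgml_fixture(c('<entry id="1" name="ko:K00001" type="ortholog"/>',
                      '<entry id="2" name="ko:K00002" type="gene"/>',
                      '<entry id="9" name="path:ko00100" type="map"/>',
                      '<relation entry1="1" entry2="2" type="ECrel"/>',
                      '<relation entry1="1" entry2="2" type="ECrel"/>',
                      '<relation entry1="1" entry2="9" type="maplink"/>'))
  g <- parse_kgml(f)
  expect_setequal(g$nodes, c("1", "2"))
  expect_equal(nrow(g$edges), 1)
})

test_that("a relation chain through a compound collapses to a direct edge", {
  f <- kgml_fixture(c('<entry id="1" name="ko:K00001" type="ortholog"/>',
                      '<entry id="5" name="cpd:C00022" type="compound"/>',
                      '<entry id="2" name="ko:K00002" type="ortholog"/>',
                      '<relation entry1="1" entry2="5" type="ECrel"/>',
                      '<relation entry1="5" entry2="2" type="ECrel"/>'))
  g <- parse_kgml(f)
  expect_setequal(g$nodes, c("1", "2"))
  expect_equal(g$edges, data.frame(from = "1", to = "2", stringsAsFactors = FALSE))
})

test_that("KGML with no enzyme entries warns and yields an empty graph", {
  f <- kgml_fixture('<entry id="9" name="path:ko00100" type="map"/>')
  expect_warning(g <- parse_kgml(f), "no enzyme")
  expect_length(g$nodes, 0)
  expect_error(parse_kgml(write_lines_tmp("<pathway", ".xml")))
})

test_that("parsing is deterministic", {
  set.seed(5)
  g <- random_pathway_graph(10, 20)
  f <- tempfile(fileext = ".xml")
  write_kgml_fixture(g, f)
  g1 <- parse_kgml(f)
  g2 <- parse_kgml(f)
  expect_identical(g1, g2)
})

test_that("mark_mapped flags exactly the nodes whose labels intersect the sample", {
  set.seed(6)
  for (rep in 1:5) {
    g <- random_pathway_graph(12, 25)
    expr <- sample(unlist(g$labels), sample(0:8, 1))
    se <- sample_expression(if (length(expr)) expr else character())
    gm <- mark_mapped(g, se)
    for (n in gm$nodes) {
      expect_identical(unname(gm$mapped[n]),
                       length(intersect(gm$labels[[n]], se$expressed)) > 0)
    }
    expect_identical(gm$edges, g$edges)
  }
  g <- random_pathway_graph(5, 6)
  expect_false(any(mark_mapped(g, sample_expression(character()))$mapped))
})

test_that("induced mapped subgraph keeps mapped nodes and within-edges only", {
  g <- graph_from_edges("a->b b->c", mapped = c("a", "c"))
  s <- induced_mapped_subgraph(g)
  expect_setequal(s$nodes, c("a", "c"))
  expect_equal(nrow(s$edges), 0)
  g2 <- graph_from_edges("a->b b->c", mapped = c("a", "b", "c"))
  s2 <- induced_mapped_subgraph(g2)
  expect_setequal(s2$nodes, g2$nodes)
  expect_equal(nrow(s2$edges), 2)
  # brute-force edge filter on random graphs
  set.seed(7)
  for (rep in 1:5) {
    g3 <- random_pathway_graph(12, 30, mapped_fraction = runif(1))
    s3 <- induced_mapped_subgraph(g3)
    keep <- names(which(g3$mapped))
    brute <- g3$edges[g3$edges$from %in% keep & g3$edges$to %in% keep, ]
    expect_setequal(paste(s3$edges$from, s3$edges$to),
                    paste(brute$from, brute$to))
    expect_setequal(s3$nodes, keep)
  }
})

test_that("metrics follow the density and zero-degree formulas", {
  # 9 nodes, 11 edges, one pure source and one pure sink:
  # density = 11/8 = 1.375, zero-degree fraction = 2/18
  g <- graph_from_edges(paste("s->a a->b b->c c->d d->e e->f f->g g->t",
                              "a->c c->e e->g"),
                        mapped = c("s", "a", "b", "c", "d", "e", "f", "g", "t"))
  m <- compute_metrics(g)
  expect_equal(m$n_mapped_nodes, 9)
  expect_equal(m$n_edges, 11)
  expect_equal(m$density, 1.375)
  expect_equal(m$zero_degree_fraction, 2 / 18)
  expect_equal(m$n_components, 1)

  single <- pathway_graph("x", "a", mapped = c(a = TRUE))
  ms <- compute_metrics(single)
  expect_equal(ms$density, 0)
  expect_equal(ms$zero_degree_fraction, 1)

  cyc <- graph_from_edges("a->b b->c c->a", mapped = c("a", "b", "c"))
  mc <- compute_metrics(cyc)
  expect_equal(mc$density, 1.5)
  expect_equal(mc$zero_degree_fraction, 0)

  empty <- pathway_graph("x", character())
  me <- compute_metrics(empty)
  expect_equal(me$density, 0)
  expect_equal(me$zero_degree_fraction, 0)
  expect_equal(me$n_components, 0)
})

test_that("component statistics report weak components and their maxima", {
  g <- graph_from_edges("a->b b->c x->y", mapped = c("a", "b", "c", "x", "y", "z"),
                        nodes = c("a", "b", "c", "x", "y", "z"))
  m <- compute_metrics(g)
  expect_equal(m$n_components, 3)
  expect_equal(m$largest_cc_nodes, 3)
  expect_equal(m$largest_cc_edges, 2)
})

test_that("zero-degree fraction stays in [0, 1] on random graphs", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(2:20, 1)
    g <- random_pathway_graph(n, sample(0:min(20, n * (n - 1)), 1), runif(1))
    m <- compute_metrics(induced_mapped_subgraph(g))
    expect_gte(m$zero_degree_fraction, 0)
    expect_lte(m$zero_degree_fraction, 1)
    expect_gte(m$density, 0)
  }
})

test_that("graph constructor enforces simple-graph invariants", {
  expect_error(pathway_graph("x", c("a", "a")), "duplicate")
  expect_error(pathway_graph("x", "a",
                             edges = data.frame(from = "a", to = "b")),
               "endpoint")
  g <- pathway_graph("x", c("a", "b"),
                     edges = data.frame(from = c("a", "a", "a"),
                                        to = c("b", "b", "a")))
  expect_equal(nrow(g$edges), 1)  # parallel edge collapsed, self-loop dropped
})
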