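test_that("flattening keeps atomic pairwise statements accessible", {
  fx <- build_worked_examples()
  sg <- flatten_atomic(fx$nfl_complex$graph)
  keys <- paste(sg$edges$from, sg$edges$predicate, sg$edges$to)
  expect_true("plasma NfL for diagnosis of AD-S" %in% keys)
  expect_true("plasma t-tau for diagnosis of AD-S" %in% keys)
  expect_true("plasma NfL is superior to plasma t-tau" %in% keys)
  # the nested owner is gone as a node
  expect_false(any(grepl("^\\[", sg$nodes)))
})

test_that("flattening a pairwise-only graph is the identity on edges", {
  g <- discovery_graph()
  g <- add_statement(g, "a", "r", "b")
  g <- add_statement(g, "b", "s", "c")
  sg <- flatten_atomic(g)
  expect_equal(nrow(sg$edges), 2L)
  expect_setequal(sg$nodes, c("a", "b", "c"))
})

test_that("anchored hyperedges project anchor-to-member pairs", {
  g <- reified_test_graph()   # {B1,B2,B3} reified, handle is_a A_test
  sg <- flatten_atomic(g)
  expect_setequal(sg_edge_keys(sg),
                  c("A_test~B1", "A_test~B2", "A_test~B3"))
  expect_false(any(grepl("^\\{", sg$nodes)))
})

test_that("flattening never drops an atomic pairwise statement", {
  fx <- build_worked_examples()
  for (f in fx) {
    g <- f$graph
    sg <- flatten_atomic(g)
    keys <- sg_edge_keys(sg)
    for (st in g$statements) {
      if (g$entities[[st$subject]]$kind != "SIMPLE" ||
          g$entities[[st$object]]$kind != "SIMPLE") next
      expect_true(pmin(st$subject, st$object) != "" &&
        paste(pmin(st$subject, st$object), pmax(st$subject, st$object),
              sep = "~") %in% keys,
        label = sprintf("%s: %s-%s survives flattening", f$name,
                        st$subject, st$object))
    }
  }
})

test_that("clique expansion turns a 3-member hyperedge into a triangle", {
  ex <- clique_expansion(list(c("B1", "B2", "B3")))
  expect_equal(nrow(ex$graph$edges), 3L)
  expect_setequal(sg_edge_keys(ex$graph), c("B1~B2", "B1~B3", "B2~B3"))
  expect_setequal(unlist(ex$provenance$edges), "h1")
})

test_that("clique expansion is the identity on 2-uniform hypergraphs", {
  for (rep in 1:5) {
    set.seed(100 + rep)
    sgx <- rand_simple_graph(7, 0.4)
    hs <- lapply(seq_len(nrow(sgx$edges)), function(i)
      c(sgx$edges$from[i], sgx$edges$to[i]))
    ex <- clique_expansion(hs)
    expect_identical(sg_edge_keys(ex$graph), sg_edge_keys(sgx))
  }
})

test_that("overlapping hyperedges merge duplicate edges with provenance", {
  ex <- clique_expansion(list(h1 = c("a", "b", "c"), h2 = c("c", "d"),
                              h3 = c("a", "b")))
  expect_setequal(sg_edge_keys(ex$graph), c("a~b", "a~c", "b~c", "c~d"))
  expect_setequal(ex$provenance$edges[[paste0("a", "\u001f", "b")]],
                  c("h1", "h3"))
})

test_that("star expansion is the bipartite incidence graph", {
  ex <- star_expansion(list(c("B1", "B2", "B3")))
  expect_equal(length(ex$graph$nodes), 4L)
  expect_equal(nrow(ex$graph$edges), 3L)
  expect_true(all(xor(grepl("^he:", ex$graph$edges$from),
                      grepl("^he:", ex$graph$edges$to))))
  expect_equal(nrow(star_expansion(list())$graph$edges), 0L)
})

test_that("line graph links hyperedges with overlapping members", {
  ex <- line_graph(list(h1 = c("a", "b", "c"), h2 = c("c", "d")))
  expect_equal(length(ex$graph$nodes), 2L)
  expect_equal(nrow(ex$graph$edges), 1L)
  expect_equal(nrow(line_graph(list(h1 = c("a", "b"),
                                    h2 = c("c", "d")))$graph$edges), 0L)
  single <- line_graph(list(h1 = c("a", "b")))
  expect_equal(length(single$graph$nodes), 1L)
  expect_equal(nrow(single$graph$edges), 0L)
})

test_that("all expansions match brute-force oracles on random hypergraphs", {
  for (rep in 1:20) {
    set.seed(rep)
    hs <- rand_hypergraph(sample(3:8, 1), sample(1:5, 1))
    expect_identical(sg_edge_keys(clique_expansion(hs)$graph),
                     oracle_clique_edges(hs))
    expect_equal(nrow(star_expansion(hs)$graph$edges),
                 oracle_star_edge_count(hs))
    expect_identical(sg_edge_keys(line_graph(hs)$graph),
                     oracle_line_edges(hs))
    # every produced edge carries resolvable provenance
    ex <- clique_expansion(hs)
    expect_true(all(unlist(ex$provenance$edges) %in% names(hs)))
  }
})

test_that("the hypergraph view includes pairwise statements as 2-edges", {
  g <- discovery_graph()
  g <- add_statement(g, "a", "r", "b")
  g <- add_hyperedge(g, c("b", "c", "d"))
  hs <- as_hypergraph(g)
  expect_length(hs, 2L)
  expect_true(any(vapply(hs, function(m) identical(m, c("a", "b")),
                         logical(1))))
  expect_length(as_hypergraph(g, include_pairwise = FALSE), 1L)
})
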