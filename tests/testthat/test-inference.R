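test_that("common neighbors counts shared intermediates", {
  sg <- fish_oil_graph()
  expect_equal(common_neighbors(sg, "fish oil", "Raynaud's Syndrome"), 3L)
  expect_error(common_neighbors(sg, "fish oil", "nonexistent"),
               "unknown node")

  disjoint <- simple_graph(data.frame(from = c("a", "c"), to = c("b", "d")))
  expect_equal(common_neighbors(disjoint, "a", "d"), 0L)
})

test_that("common neighbors equals the exhaustive oracle on random graphs", {
  for (rep in 1:15) {
    set.seed(300 + rep)
    sg <- rand_simple_graph(sample(4:10, 1), 0.35)
    pairs <- utils::combn(sg$nodes, 2)
    for (j in seq_len(ncol(pairs)))
      expect_equal(common_neighbors(sg, pairs[1, j], pairs[2, j]),
                   oracle_cn(sg, pairs[1, j], pairs[2, j]))
  }
})

test_that("ABC open discovery finds distance-2 non-neighbors", {
  sg <- fish_oil_graph()
  cands <- abc_candidates(sg, "fish oil")
  expect_equal(cands$c[1], "Raynaud's Syndrome")
  expect_equal(cands$support[1], 3L)
  expect_equal(cands$rank[1], 1L)
  expect_setequal(cands$b_terms[[1]],
                  c("blood viscosity", "platelet aggregability",
                    "vascular reactivity"))

  # star center: everything adjacent, no candidates
  star <- simple_graph(data.frame(from = "hub", to = letters[1:4]))
  expect_equal(nrow(abc_candidates(star, "hub")), 0L)

  # path a-b-c-d: from a only c is at distance 2
  path <- simple_graph(data.frame(from = c("a", "b", "c"),
                                  to = c("b", "c", "d")))
  out <- abc_candidates(path, "a")
  expect_identical(out$c, "c")
  expect_error(abc_candidates(path, "zz"), "unknown node")
})

test_that("ABC support always equals the CN score of the pair", {
  for (rep in 1:10) {
    set.seed(400 + rep)
    sg <- rand_simple_graph(8, 0.35)
    out <- abc_candidates(sg, sg$nodes[1])
    if (!nrow(out)) next
    for (i in seq_len(nrow(out)))
      expect_equal(out$support[i],
                   common_neighbors(sg, sg$nodes[1], out$c[i]))
  }
})

test_that("hyperlink CN averages pairwise CN on the chosen expansion", {
  hs <- list(h1 = c("a", "b", "c"), h2 = c("b", "c", "d"),
             h3 = c("a", "d"))
  ex <- clique_expansion(hs)$graph
  # 3-member candidate: mean of the three pairwise scores, by brute force
  cand <- c("a", "b", "d")
  manual <- mean(c(common_neighbors(ex, "a", "b"),
                   common_neighbors(ex, "a", "d"),
                   common_neighbors(ex, "b", "d")))
  expect_equal(hyper_cn(hs, cand, "clique"), manual)
  expect_error(hyper_cn(hs, "a"), "at least 2")
  expect_error(hyper_cn(hs, c("a", "zz")), "unknown node")
})

test_that("hyperlink CN reduces to classic CN on 2-member candidates", {
  for (rep in 1:10) {
    set.seed(500 + rep)
    hs <- rand_hypergraph(6, 4)
    ex <- clique_expansion(hs)$graph
    pairs <- utils::combn(ex$nodes, 2)
    for (j in seq_len(ncol(pairs)))
      expect_equal(hyper_cn(hs, pairs[, j], "clique"),
                   common_neighbors(ex, pairs[1, j], pairs[2, j]))
  }
  # on a 2-uniform hypergraph, the clique expansion is the input graph, so
  # hyper_cn equals CN on the original edges too
  set.seed(99)
  sg <- rand_simple_graph(7, 0.4)
  hs2 <- lapply(seq_len(nrow(sg$edges)), function(i)
    c(sg$edges$from[i], sg$edges$to[i]))
  pairs <- utils::combn(sg$nodes[sg$nodes %in% unlist(hs2)], 2)
  for (j in seq_len(ncol(pairs)))
    expect_equal(hyper_cn(hs2, pairs[, j], "clique"),
                 common_neighbors(sg, pairs[1, j], pairs[2, j]))
})

test_that("link ranking is a deterministic contiguous total order", {
  set.seed(7)
  sg <- rand_simple_graph(8, 0.3)
  p1 <- predict_links(sg)
  p2 <- predict_links(sg)
  expect_identical(p1, p2)
  if (nrow(p1)) {
    expect_identical(p1$rank, seq_len(nrow(p1)))
    expect_true(all(diff(p1$score) <= 0))
  }
})

test_that("the impact audit reproduces the three case studies", {
  sc <- worked_impact_scenarios()
  for (nm in names(sc)) {
    imp <- impact_audit(sc[[nm]]$prediction, sc[[nm]]$complex)
    expect_equal(imp$value, sc[[nm]]$expected, label = nm)
    expect_identical(imp$flags, IMPACT_FLAGS[[sc[[nm]]$expected]],
                     label = paste(nm, "flags"))
  }
  # severity flag matrix: strictly increasing feasibility/success pattern
  expect_identical(unname(IMPACT_FLAGS$EXPERIMENTALLY_INFEASIBLE),
                   c(FALSE, FALSE, FALSE))
  expect_identical(unname(IMPACT_FLAGS$LITERATURE_INCONSISTENT),
                   c(TRUE, FALSE, FALSE))
  expect_identical(unname(IMPACT_FLAGS$OVERSIMPLIFIED_EXPLANATION),
                   c(TRUE, TRUE, FALSE))
})

test_that("benign predictions audit to none; missing provenance errors", {
  fx <- build_worked_examples()
  benign <- prediction_result(c("tau", "amyloid load"), score = 1, rank = 1L)
  expect_null(impact_audit(benign, fx$nfl_complex$graph))
  expect_error(impact_audit(list(candidate = NULL),
                            fx$nfl_complex$graph), "audit impossible")
})

test_that("time-sliced precision at k behaves at the oracle limits", {
  set.seed(11)
  train <- rand_simple_graph(8, 0.35)
  cands <- predict_links(train)
  expect_gte(nrow(cands), 3)
  test_edges <- data.frame(from = cands$u[1:2], to = cands$v[1:2])
  oracle <- function(sg, u, v)
    as.numeric(paste0(pmin(u, v), "~", pmax(u, v)) %in%
                 paste0(pmin(test_edges$from, test_edges$to), "~",
                        pmax(test_edges$from, test_edges$to)))
  expect_equal(timeslice_eval(train, test_edges, k = 2, scorer = oracle), 1.0)
  empty <- data.frame(from = character(), to = character())
  expect_equal(timeslice_eval(train, empty, k = 2), 0)
  expect_warning(timeslice_eval(train, test_edges, k = 10000),
                 "exceeds")
})

test_that("a random scorer scores near the test-edge density", {
  set.seed(123)
  train <- rand_simple_graph(12, 0.3)
  cands <- predict_links(train)
  expect_gte(nrow(cands), 10)
  # plant half of the candidate pairs as test edges
  planted <- cands[sample(nrow(cands), floor(nrow(cands) / 2)), ]
  test_edges <- data.frame(from = planted$u, to = planted$v)
  density <- nrow(test_edges) / nrow(cands)
  k <- nrow(cands)
  set.seed(42)
  random_scorer <- function(sg, u, v) stats::runif(1)
  prec <- timeslice_eval(train, test_edges, k = k, scorer = random_scorer)
  se <- sqrt(density * (1 - density) / k)
  expect_lt(abs(prec - density), max(3 * se, 1e-9))
})
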