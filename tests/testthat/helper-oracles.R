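# Shared builders and independent brute-force oracles.

# Swanson's worked example: fish oil and Raynaud's Syndrome each linked to
# the three blood-parameter B-terms.
fish_oil_graph <- function() {
  b_terms <- c("blood viscosity", "platelet aggregability",
               "vascular reactivity")
  edges <- rbind(
    data.frame(from = "fish oil", to = b_terms, stringsAsFactors = FALSE),
    data.frame(from = b_terms, to = "Raynaud's Syndrome",
               stringsAsFactors = FALSE))
  edges$predicate <- "cooccurs_with"
  edges$directed <- FALSE
  simple_graph(edges)
}

# random simple graph over `n` nodes with edge probability p
rand_simple_graph <- function(n, p = 0.3) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  if (!any(keep)) return(simple_graph(nodes = nodes))
  edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                      predicate = "cooccurs_with", directed = FALSE,
                      stringsAsFactors = FALSE)
  simple_graph(edges, nodes = nodes)
}

# random hypergraph: named list of member sets over <= n_nodes nodes
rand_hypergraph <- function(n_nodes = 8, n_edges = 5) {
  nodes <- sprintf("v%02d", seq_len(n_nodes))
  hs <- lapply(seq_len(n_edges), function(i)
    sort(sample(nodes, sample(2:min(4, n_nodes), 1))))
  names(hs) <- sprintf("h%d", seq_len(n_edges))
  hs
}

# independent CN oracle: exhaustive neighbor-set intersection straight from
# the edge table, no reuse of package neighbor code
oracle_cn <- function(sg, u, v) {
  e <- sg$edges
  nb <- function(x) setdiff(unique(c(e$to[e$from == x], e$from[e$to == x])), x)
  length(intersect(nb(u), nb(v)))
}

# brute-force expansion oracles by direct enumeration
oracle_clique_edges <- function(hs) {
  keys <- character()
  for (m in hs) {
    if (length(m) < 2) next
    pr <- utils::combn(sort(m), 2)
    keys <- c(keys, paste(pr[1, ], pr[2, ], sep = "~"))
  }
  sort(unique(keys))
}
oracle_star_edge_count <- function(hs) sum(lengths(hs))
oracle_line_edges <- function(hs) {
  ids <- names(hs)
  keys <- character()
  if (length(ids) >= 2)
    for (i in 1:(length(ids) - 1)) for (j in (i + 1):length(ids))
      if (length(intersect(hs[[ids[i]]], hs[[ids[j]]])) > 0) {
        p <- sort(c(ids[i], ids[j]))
        keys <- c(keys, paste(p[1], p[2], sep = "~"))
      }
  sort(unique(keys))
}

# edge keys of a simple_graph, undirected
sg_edge_keys <- function(sg) {
  if (!nrow(sg$edges)) return(character())
  lo <- pmin(sg$edges$from, sg$edges$to)
  hi <- pmax(sg$edges$from, sg$edges$to)
  sort(unique(paste(lo, hi, sep = "~")))
}

# small discovery graph with a reified 3-member hyperedge and an anchor edge
reified_test_graph <- function() {
  g <- discovery_graph("test")
  g <- add_hyperedge(g, c("B1", "B2", "B3"))
  g <- reify_hyperedge(g, find_hyperedge(g, c("B1", "B2", "B3")))
  hd <- handle_for(g, find_hyperedge(g, c("B1", "B2", "B3")))
  add_statement(g, hd, "is_a", "A_test")
}
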