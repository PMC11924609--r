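# Lossless flattening of complex graphs to atomic pairwise graphs and the
# three standard hypergraph expansions (clique, star, line graph).

empty_edges <- function() data.frame(from = character(), to = character(),
                                     predicate = character(),
                                     directed = logical(),
                                     stringsAsFactors = FALSE)

#' Construct a simple graph
#'
#' A plain pairwise graph: a node set and binary edges only (no hyperedges,
#' no nesting semantics).
#'
#' @param edges data.frame with columns `from`, `to`, and optionally
#'   `predicate` and `directed` (defaults: `NA`, `FALSE`). Undirected edges
#'   are canonicalized to `from <= to` and duplicates merged.
#' @param nodes additional isolated node ids.
#' @return object of class `simple_graph`.
#' @export
simple_graph <- function(edges = empty_edges(), nodes = character()) {
  if (nrow(edges)) {
    if (is.null(edges$predicate)) edges$predicate <- NA_character_
    if (is.null(edges$directed)) edges$directed <- FALSE
    edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
    swap <- !edges$directed & edges$from > edges$to
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- unique(edges[c("from", "to", "predicate", "directed")])
    edges <- edges[order(edges$from, edges$predicate, edges$to), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  } else edges <- empty_edges()
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges), class = "simple_graph")
}

#' @export
print.simple_graph <- function(x, ...) {
  cat(sprintf("<simple_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Neighbors of a node (edges treated as undirected)
#' @param sg simple graph.
#' @param v node id.
#' @return character vector of neighbor ids.
#' @export
sg_neighbors <- function(sg, v) {
  if (!(v %in% sg$nodes)) stop("unknown node: ", v)
  e <- sg$edges
  sort(setdiff(unique(c(e$to[e$from == v], e$from[e$to == v])), v))
}

# undirected pair key, order-free
pair_key <- function(u, v) {
  lo <- pmin(u, v); hi <- pmax(u, v)
  paste(lo, hi, sep = "\u1f")
}

# atomic SIMPLE entities reachable from an entity: nested owners expand to
# their body entities, handles to their hyperedge members
atomic_entities <- function(g, id, seen = character()) {
  if (id %in% seen) return(character())
  e <- g$entities[[id]]
  if (is.null(e)) return(character())
  if (e$kind == "SIMPLE") return(id)
  seen <- c(seen, id)
  deps <- if (e$kind == "NESTED") g$nested[[id]]$body_entities
          else g$hyperedges[[g$handles[[id]]]]$members
  sort(unique(unlist(lapply(deps, atomic_entities, g = g, seen = seen))))
}

#' Flatten a complex graph to its atomic pairwise layer
#'
#' Lossless projection: every pairwise statement of the graph — including
#' those inside nested bodies — appears in the output between atomic (SIMPLE)
#' entities. Edges incident to a nested owner fan out to every body entity, so
#' atomic relationships such as a finding's subject linked to its context
#' remain accessible. Statements anchored on a reified handle project the
#' anchor onto each hyperedge member (the anchor-star reading); use
#' [clique_expansion()] for the member-member alternative. Nested owners and
#' handles are dropped as nodes; their bodies and members are retained.
#'
#' @param g a valid discovery graph.
#' @return a [simple_graph()].
#' @export
flatten_atomic <- function(g) {
  stopifnot(is_discovery_graph(g))
  rows <- list()
  for (st in g$statements) {
    subj <- atomic_entities(g, st$subject)
    obj <- atomic_entities(g, st$object)
    for (s in subj) for (o in obj) {
      if (s == o) next
      rows[[length(rows) + 1L]] <- data.frame(
        from = s, to = o, predicate = st$predicate, directed = st$directed,
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else empty_edges()
  atoms <- names(g$entities)[vapply(g$entities, function(e)
    e$kind == "SIMPLE", logical(1))]
  simple_graph(edges, nodes = atoms)
}

#' Hypergraph view of a discovery graph
#'
#' The member-set family the expansions operate on: every explicit hyperedge,
#' plus (by default) every pairwise statement as an implicit 2-member
#' hyperedge — a simple graph being the special 2-uniform hypergraph.
#'
#' @param g discovery graph.
#' @param include_pairwise include pairwise statements as 2-member edges.
#' @return object of class `hypergraph_view`: a named list of member vectors.
#' @export
as_hypergraph <- function(g, include_pairwise = TRUE) {
  members <- lapply(g$hyperedges, `[[`, "members")
  names(members) <- names(g$hyperedges)
  if (include_pairwise) {
    for (st in g$statements) {
      if (st$subject == st$object) next
      members[[paste0("s:", st$id)]] <- sort(c(st$subject, st$object))
    }
  }
  structure(members, class = "hypergraph_view")
}

as_member_sets <- function(x, include_pairwise = TRUE) {
  if (is_discovery_graph(x)) x <- as_hypergraph(x, include_pairwise)
  if (inherits(x, "hypergraph_view")) return(unclass(x))
  if (is.list(x)) {
    x <- lapply(x, function(m) sort(unique(as.character(m))))
    if (is.null(names(x)) || any(!nzchar(names(x))))
      names(x) <- sprintf("h%d", seq_along(x))
    return(x)
  }
  stop("expected a discovery_graph, hypergraph_view, or list of member sets")
}

new_expansion <- function(graph, edge_prov, node_prov, mode) {
  structure(list(graph = graph,
                 provenance = list(edges = edge_prov, nodes = node_prov),
                 mode = mode),
            class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat(sprintf("<expansion_result: %s> %d nodes, %d edges\n",
              x$mode, length(x$graph$nodes), nrow(x$graph$edges)))
  invisible(x)
}

#' Clique expansion of a hypergraph
#'
#' Each k-member hyperedge contributes all `choose(k, 2)` undirected
#' member-member edges; duplicate edges are merged with merged provenance.
#' On a 2-uniform hypergraph this is the identity.
#'
#' @param x discovery graph, hypergraph view, or list of member-set vectors.
#' @param include_pairwise when `x` is a discovery graph, also treat pairwise
#'   statements as 2-member hyperedges.
#' @return `expansion_result`: `$graph` is a [simple_graph()], `$provenance`
#'   maps each produced edge (key `"u\u1fv"` with `u <= v`) and node to the
#'   originating hyperedge ids.
#' @export
clique_expansion <- function(x, include_pairwise = TRUE) {
  hs <- as_member_sets(x, include_pairwise)
  edge_prov <- list(); node_prov <- list()
  rows <- list()
  for (hid in names(hs)) {
    m <- hs[[hid]]
    for (v in m) node_prov[[v]] <- c(node_prov[[v]], hid)
    if (length(m) < 2) next
    pairs <- utils::combn(m, 2)
    for (j in seq_len(ncol(pairs))) {
      key <- pair_key(pairs[1, j], pairs[2, j])
      edge_prov[[key]] <- c(edge_prov[[key]], hid)
      rows[[length(rows) + 1L]] <- data.frame(
        from = min(pairs[, j]), to = max(pairs[, j]),
        predicate = NA_character_, directed = FALSE, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) unique(do.call(rbind, rows)) else empty_edges()
  new_expansion(simple_graph(edges, nodes = names(node_prov)),
                edge_prov, node_prov, "clique")
}

#' Star expansion of a hypergraph
#'
#' Bipartite incidence graph: one node per entity plus one node per hyperedge
#' (prefixed `"he:"`), with one undirected edge per membership, so the edge
#' count equals the total membership count.
#'
#' @inheritParams clique_expansion
#' @return `expansion_result` (see [clique_expansion()]).
#' @export
star_expansion <- function(x, include_pairwise = TRUE) {
  hs <- as_member_sets(x, include_pairwise)
  edge_prov <- list(); node_prov <- list()
  rows <- list()
  for (hid in names(hs)) {
    hnode <- paste0("he:", hid)
    node_prov[[hnode]] <- hid
    for (v in hs[[hid]]) {
      node_prov[[v]] <- c(node_prov[[v]], hid)
      key <- pair_key(v, hnode)
      edge_prov[[key]] <- c(edge_prov[[key]], hid)
      rows[[length(rows) + 1L]] <- data.frame(
        from = min(v, hnode), to = max(v, hnode), predicate = NA_character_,
        directed = FALSE, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) unique(do.call(rbind, rows)) else empty_edges()
  new_expansion(simple_graph(edges, nodes = names(node_prov)),
                edge_prov, node_prov, "star")
}

#' Line graph of a hypergraph
#'
#' One node per hyperedge; two hyperedges are adjacent iff their member sets
#' intersect.
#'
#' @inheritParams clique_expansion
#' @return `expansion_result` (see [clique_expansion()]).
#' @export
line_graph <- function(x, include_pairwise = TRUE) {
  hs <- as_member_sets(x, include_pairwise)
  ids <- names(hs)
  edge_prov <- list()
  node_prov <- stats::setNames(as.list(ids), ids)
  rows <- list()
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1L)) for (j in seq(i + 1L, length(ids))) {
      if (length(intersect(hs[[ids[i]]], hs[[ids[j]]])) == 0) next
      key <- pair_key(ids[i], ids[j])
      edge_prov[[key]] <- c(ids[i], ids[j])
      rows[[length(rows) + 1L]] <- data.frame(
        from = min(ids[i], ids[j]), to = max(ids[i], ids[j]),
        predicate = NA_character_, directed = FALSE, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else empty_edges()
  new_expansion(simple_graph(edges, nodes = ids),
                edge_prov, node_prov, "line")
}

#' Apply a named expansion
#' @param x input accepted by [clique_expansion()].
#' @param mode one of `"clique"`, `"star"`, `"line"`.
#' @param include_pairwise see [clique_expansion()].
#' @return `expansion_result`.
#' @export
expand_hypergraph <- function(x, mode = c("clique", "star", "line"),
                              include_pairwise = TRUE) {
  mode <- match.arg(mode)
  switch(mode,
         clique = clique_expansion(x, include_pairwise),
         star = star_expansion(x, include_pairwise),
         line = line_graph(x, include_pairwise))
}
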