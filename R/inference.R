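# Open discovery and link prediction: Swanson ABC candidates,
# Common Neighbors, its hyperlink generalization, the impact audit of
# representation loss, and time-sliced evaluation.

#' Impact type vocabulary and their severity flags
#'
#' Three levels of increasing severity of representation loss on inferred
#' hypotheses, each with an experiment-feasibility (EF), experiment-success
#' (ES) and explanation-granularity (EG) flag pattern: experimentally
#' infeasible hypotheses fail all three; literature-inconsistent hypotheses
#' are feasible but misaligned with the literature; oversimplified
#' explanations are feasible and plausible but under-specified.
#'
#' @format Named list: type -> logical vector `c(EF =, ES =, EG =)`.
#' @export
IMPACT_FLAGS <- list(
  EXPERIMENTALLY_INFEASIBLE = c(EF = FALSE, ES = FALSE, EG = FALSE),
  LITERATURE_INCONSISTENT   = c(EF = TRUE,  ES = FALSE, EG = FALSE),
  OVERSIMPLIFIED_EXPLANATION = c(EF = TRUE, ES = TRUE,  EG = FALSE)
)

#' Common Neighbors link-prediction score
#'
#' `|N(u) ∩ N(v)|`, treating all edges as undirected.
#'
#' @param sg [simple_graph()].
#' @param u,v node ids (must exist in `sg`).
#' @return non-negative integer count.
#' @export
common_neighbors <- function(sg, u, v) {
  length(intersect(sg_neighbors(sg, u), sg_neighbors(sg, v)))
}

#' ABC open-discovery candidates
#'
#' Swanson's scheme by transitive closure: starting from a source term A,
#' candidate targets C are the non-neighbors of A at distance 2, connected
#' through shared intermediate B-terms. Support is the number of shared
#' intermediates, i.e. `common_neighbors(sg, a, c)`. Candidates are ranked by
#' support (descending), ties broken by label (ascending).
#'
#' @param sg [simple_graph()].
#' @param a source node id.
#' @param min_support minimum number of shared B-terms.
#' @return data.frame with columns `c`, `support`, `rank` and list column
#'   `b_terms`; zero rows when no candidate qualifies.
#' @export
abc_candidates <- function(sg, a, min_support = 1) {
  nb_a <- sg_neighbors(sg, a)
  cands <- sort(setdiff(unique(unlist(lapply(nb_a, sg_neighbors, sg = sg))),
                        c(a, nb_a)))
  rows <- lapply(cands, function(cc) {
    b <- intersect(nb_a, sg_neighbors(sg, cc))
    if (length(b) < min_support) return(NULL)
    data.frame(c = cc, support = length(b), stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(c = character(), support = integer(), rank = integer(),
                      b_terms = I(list()), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$support, out$c), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$b_terms <- I(lapply(out$c, function(cc)
    sort(intersect(nb_a, sg_neighbors(sg, cc)))))
  rownames(out) <- NULL
  out
}

#' Common Neighbors generalized to hyperlink candidates
#'
#' Scores a candidate hyperlink (a member set of size \eqn{\ge 2}) as the
#' mean of the pairwise Common Neighbors indices over all member pairs,
#' computed on the chosen hypergraph expansion of the input. On a 2-member
#' candidate this reduces exactly to classic CN on the expansion graph.
#'
#' @param x discovery graph, hypergraph view, or list of member sets.
#' @param candidate character vector of \eqn{\ge 2} member ids.
#' @param expansion backing simple graph: `"clique"` (default), `"star"` or
#'   `"line"`.
#' @param include_pairwise see [clique_expansion()].
#' @return numeric score.
#' @export
hyper_cn <- function(x, candidate, expansion = c("clique", "star", "line"),
                     include_pairwise = TRUE) {
  expansion <- match.arg(expansion)
  candidate <- unique(as.character(candidate))
  if (length(candidate) < 2)
    stop("a hyperlink candidate needs at least 2 members")
  sg <- expand_hypergraph(x, expansion, include_pairwise)$graph
  missing <- setdiff(candidate, sg$nodes)
  if (length(missing))
    stop("unknown node: ", paste(missing, collapse = ", "))
  pairs <- utils::combn(candidate, 2)
  mean(vapply(seq_len(ncol(pairs)), function(j)
    common_neighbors(sg, pairs[1, j], pairs[2, j]), numeric(1)))
}

#' Construct a prediction result
#'
#' @param candidate node pair (or member set) the prediction is about.
#' @param score non-negative score.
#' @param rank positive integer rank (ties broken deterministically).
#' @param explanation optional character vector of node labels along the
#'   supporting path (edge provenance).
#' @return object of class `prediction_result`.
#' @export
prediction_result <- function(candidate, score, rank = NA_integer_,
                              explanation = NULL) {
  stopifnot(length(candidate) >= 2, score >= 0)
  structure(list(candidate = as.character(candidate), score = score,
                 rank = as.integer(rank), explanation = explanation,
                 impact = NULL),
            class = "prediction_result")
}

# candidate pairs: non-adjacent node pairs, by default restricted to pairs
# within the same connected component (igraph does the component work)
candidate_pairs <- function(sg, all_pairs = FALSE) {
  n <- length(sg$nodes)
  if (n < 2) return(data.frame(u = character(), v = character()))
  comp <- if (all_pairs || nrow(sg$edges) == 0) {
    stats::setNames(rep(1L, n), sg$nodes)
  } else {
    ig <- igraph::graph_from_data_frame(sg$edges[c("from", "to")],
                                        directed = FALSE,
                                        vertices = sg$nodes)
    igraph::components(ig)$membership[sg$nodes]
  }
  adj <- new.env(parent = emptyenv())
  if (nrow(sg$edges))
    for (k in pair_key(sg$edges$from, sg$edges$to)) assign(k, TRUE, adj)
  nodes <- sort(sg$nodes)
  rows <- list()
  for (i in seq_len(length(nodes) - 1L)) for (j in seq(i + 1L, length(nodes))) {
    u <- nodes[i]; v <- nodes[j]
    if (!all_pairs && comp[[u]] != comp[[v]]) next
    if (!is.null(adj[[pair_key(u, v)]])) next
    rows[[length(rows) + 1L]] <- c(u, v)
  }
  if (!length(rows)) return(data.frame(u = character(), v = character()))
  m <- do.call(rbind, rows)
  data.frame(u = m[, 1], v = m[, 2], stringsAsFactors = FALSE)
}

#' Score and rank candidate links
#'
#' Enumerates candidate pairs (non-adjacent nodes within the same connected
#' component unless `all_pairs`), scores each with `scorer`, and returns a
#' deterministic total order: score descending, then pair label ascending,
#' ranks contiguous from 1.
#'
#' @param sg [simple_graph()].
#' @param scorer function `(sg, u, v) -> numeric`; defaults to
#'   [common_neighbors()].
#' @param top_k keep only the first `k` ranks (default all).
#' @param all_pairs lift the same-component restriction.
#' @return data.frame `u`, `v`, `score`, `rank`.
#' @export
predict_links <- function(sg, scorer = common_neighbors, top_k = Inf,
                          all_pairs = FALSE) {
  cand <- candidate_pairs(sg, all_pairs)
  if (!nrow(cand))
    return(data.frame(u = character(), v = character(), score = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  cand$score <- vapply(seq_len(nrow(cand)), function(i)
    as.numeric(scorer(sg, cand$u[i], cand$v[i])), numeric(1))
  cand <- cand[order(-cand$score, cand$u, cand$v), , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  utils::head(cand, n = if (is.finite(top_k)) top_k else nrow(cand))
}

#' Audit an inferred link against the enriched representation
#'
#' Classifies the damage representation loss did to a prediction made on the
#' flattened pairwise graph, by re-reading it against the complex graph it
#' came from:
#' \itemize{
#'   \item an endpoint is a `GENERAL_CONCEPT` whose contexts live in a
#'     hyperedge → `EXPERIMENTALLY_INFEASIBLE` (the hypothesis names an
#'     umbrella term with no testable referent);
#'   \item an endpoint is an individual member of a \eqn{\ge 3}-member
#'     collective hyperedge whose handle — not the member — carries the
#'     outcome link → `LITERATURE_INCONSISTENT` (the literature asserts the
#'     combination, not the member);
#'   \item the explanation path traverses an entity that is modifier-nested
#'     in the complex graph → `OVERSIMPLIFIED_EXPLANATION` (the explanation
#'     drops the modifier).
#' }
#' Flag patterns follow `IMPACT_FLAGS`. Returns `NULL` when none applies.
#'
#' @param p a [prediction_result()] (or list with `candidate` and optional
#'   `explanation`).
#' @param complex the enriched discovery graph the prediction's inputs were
#'   flattened/expanded from.
#' @return object of class `impact_type` (`$value`, `$flags`) or `NULL`.
#' @export
impact_audit <- function(p, complex) {
  stopifnot(is_discovery_graph(complex))
  if (is.null(p$candidate) || length(p$candidate) < 2)
    stop("audit impossible: prediction carries no candidate provenance")
  ends <- normalize_label(p$candidate)

  concept_in_hyperedge <- function(id) {
    if (!has_tag(complex, id, "GENERAL_CONCEPT")) return(FALSE)
    in_he <- any(vapply(complex$hyperedges, function(h) id %in% h$members,
                        logical(1)))
    handle_linked <- any(vapply(complex$statements, function(st)
      (st$subject %in% names(complex$handles) && st$object == id) ||
        (st$object %in% names(complex$handles) && st$subject == id),
      logical(1)))
    in_he || handle_linked
  }
  if (any(vapply(ends, concept_in_hyperedge, logical(1))))
    return(new_impact("EXPERIMENTALLY_INFEASIBLE"))

  collective_member <- function(id) {
    for (hd in names(complex$handles)) {
      h <- complex$hyperedges[[complex$handles[[hd]]]]
      if (length(h$members) >= 3 && id %in% h$members &&
          length(incident_statements(complex, hd)) > 0)
        return(TRUE)
    }
    FALSE
  }
  if (any(vapply(ends, collective_member, logical(1))))
    return(new_impact("LITERATURE_INCONSISTENT"))

  if (!is.null(p$explanation)) {
    path <- normalize_label(p$explanation)
    modifier_nested <- function(id) {
      for (n in complex$nested) {
        if (!(id %in% n$body_entities)) next
        others <- setdiff(n$body_entities, id)
        if (any(vapply(others, has_tag, logical(1), g = complex,
                       tag = "MODIFIER")))
          return(TRUE)
      }
      FALSE
    }
    if (any(vapply(path, modifier_nested, logical(1))))
      return(new_impact("OVERSIMPLIFIED_EXPLANATION"))
  }
  NULL
}

new_impact <- function(value) {
  structure(list(value = value, flags = IMPACT_FLAGS[[value]]),
            class = "impact_type")
}

#' @export
print.impact_type <- function(x, ...) {
  cat(sprintf("<impact_type> %s (EF=%s ES=%s EG=%s)\n", x$value,
              x$flags[["EF"]], x$flags[["ES"]], x$flags[["EG"]]))
  invisible(x)
}

#' Time-sliced precision-at-k evaluation
#'
#' Trains on the earlier-years graph, scores all candidate (non-train) pairs
#' with `scorer`, and reports the fraction of the top-`k` predictions present
#' in the test-year edge set.
#'
#' @param train [simple_graph()] built from the training years.
#' @param test_edges data.frame with columns `from`, `to` (undirected test
#'   co-occurrence links), or a character vector of keys `"u\u1fv"`.
#' @param k evaluation depth; if larger than the candidate count the
#'   evaluation proceeds at the candidate count with a warning.
#' @param scorer function `(sg, u, v) -> numeric`; defaults to
#'   [common_neighbors()].
#' @param all_pairs lift the same-component candidate restriction.
#' @return precision at `k` in `[0, 1]`.
#' @export
timeslice_eval <- function(train, test_edges, k, scorer = common_neighbors,
                           all_pairs = FALSE) {
  stopifnot(k >= 1)
  keys <- if (is.character(test_edges)) test_edges
          else if (nrow(test_edges)) pair_key(test_edges$from, test_edges$to)
          else character()
  preds <- predict_links(train, scorer = scorer, all_pairs = all_pairs)
  if (!nrow(preds)) return(0)
  if (k > nrow(preds)) {
    warning(sprintf("k = %d exceeds the %d candidates; evaluating at %d",
                    k, nrow(preds), nrow(preds)))
    k <- nrow(preds)
  }
  top <- preds[seq_len(k), , drop = FALSE]
  mean(pair_key(top$u, top$v) %in% keys)
}
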