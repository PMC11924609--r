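# Diagnostics: representation-component classification, the seven-type
# taxonomy of pairwise-representation limitations, and corpus distributions.

#' Limitation type vocabulary
#'
#' The seven ways a pairwise-only knowledge graph loses information relative
#' to the enriched representation: a finding constrained by a specific
#' context, a finding tied to an experimental model, a method linked to a
#' composite finding, a mechanism/process built from a modified entity, a
#' modifier adding granular information, a general concept lacking its
#' contexts, and more than two entities interacting together.
#'
#' @format Character vector of the 7 types.
#' @export
LIMITATION_TYPES <- c("SPECIFIC_CONTEXT", "EXPERIMENTAL_MODEL",
                      "USE_OF_METHOD", "MECHANISM_FROM_MODIFIED",
                      "MODIFIER_GRANULARITY", "GENERAL_CONCEPT_CONTEXT",
                      "MULTI_ENTITY_INTERACTION")

#' Representation component classes
#'
#' `P`: pairwise relationships suffice; `PN`: nested relationships also
#' required; `PH`: hypergraphs also required; `PNH`: all three. The classes
#' are exhaustive and mutually exclusive.
#' @format Character vector of the 4 classes.
#' @export
COMPONENT_CLASSES <- c("P", "PN", "PH", "PNH")

has_tag <- function(g, id, tag) {
  e <- g$entities[[id]]
  !is.null(e) && tag %in% e$role_tags
}

#' Classify a graph by required representation components
#'
#' `P` iff the graph has no nested entities, no hyperedge of 3 or more
#' members, and no handle. Nesting sets the `N` bit; a \eqn{\ge 3}-member
#' hyperedge or a reified handle sets the `H` bit (2-member hyperedges are
#' equivalent to pairwise links and do not).
#'
#' @param g valid discovery graph.
#' @return one of `COMPONENT_CLASSES`.
#' @export
component_class <- function(g) {
  stopifnot(is_discovery_graph(g))
  has_n <- length(g$nested) > 0
  has_h <- length(g$handles) > 0 ||
    any(vapply(g$hyperedges, function(h) length(h$members) >= 3, logical(1)))
  paste0("P", if (has_n) "N" else "", if (has_h) "H" else "")
}

# statements incident to entity `id`
incident_statements <- function(g, id)
  Filter(function(st) st$subject == id || st$object == id, g$statements)

other_end <- function(st, id) if (st$subject == id) st$object else st$subject

# is statement `st` an is_a link from handle `hd` to a GENERAL_CONCEPT node?
is_concept_anchor <- function(g, st, hd)
  st$predicate == "is_a" && st$subject == hd &&
    has_tag(g, st$object, "GENERAL_CONCEPT")

#' Identify the limitation types a graph's structure encodes
#'
#' Structural rule table over the enriched graph (the classification is of
#' representation structures, not raw prose):
#' \itemize{
#'   \item a `FINDING`-tagged nested entity linked to a `CONTEXT`-tagged node
#'     → `SPECIFIC_CONTEXT`;
#'   \item a `FINDING`-tagged nested entity linked via an `in` edge to an
#'     `EXPERIMENTAL_MODEL` node → `EXPERIMENTAL_MODEL`;
#'   \item a `METHOD`-tagged node with a nested object → `USE_OF_METHOD`;
#'   \item a nested entity grouping a `MODIFIER`-tagged entity, owner tagged
#'     `PROCESS` → `MECHANISM_FROM_MODIFIED`; owner not `PROCESS`-tagged →
#'     `MODIFIER_GRANULARITY`;
#'   \item a handle linked `is_a` to a `GENERAL_CONCEPT` node →
#'     `GENERAL_CONCEPT_CONTEXT`;
#'   \item a \eqn{\ge 3}-member reified hyperedge whose handle carries any
#'     other anchored relation → `MULTI_ENTITY_INTERACTION`.
#' }
#' A nested grouping without role tags yields a warning and no label.
#'
#' @param g valid discovery graph with role tags.
#' @return sorted character vector, a subset of `LIMITATION_TYPES` (empty for
#'   pairwise-only graphs).
#' @export
limitation_types <- function(g) {
  stopifnot(is_discovery_graph(g))
  out <- character()
  for (owner in names(g$nested)) {
    e <- g$entities[[owner]]
    if (length(e$role_tags) == 0) {
      warning("nested entity '", owner, "' carries no role tag; not classified")
      next
    }
    inc <- incident_statements(g, owner)
    if ("FINDING" %in% e$role_tags) {
      for (st in inc) {
        oth <- other_end(st, owner)
        if (has_tag(g, oth, "CONTEXT"))
          out <- c(out, "SPECIFIC_CONTEXT")
        if (st$predicate == "in" && st$subject == owner &&
            has_tag(g, oth, "EXPERIMENTAL_MODEL"))
          out <- c(out, "EXPERIMENTAL_MODEL")
      }
    }
    modifier_grouped <- any(vapply(g$nested[[owner]]$body_entities,
                                   has_tag, logical(1), g = g,
                                   tag = "MODIFIER"))
    if (modifier_grouped) {
      out <- c(out, if ("PROCESS" %in% e$role_tags) "MECHANISM_FROM_MODIFIED"
                    else "MODIFIER_GRANULARITY")
    }
  }
  for (st in g$statements) {
    if (has_tag(g, st$subject, "METHOD") &&
        !is.null(g$entities[[st$object]]) &&
        g$entities[[st$object]]$kind == "NESTED")
      out <- c(out, "USE_OF_METHOD")
  }
  for (hd in names(g$handles)) {
    inc <- incident_statements(g, hd)
    if (!length(inc)) next
    concept_anchored <- vapply(inc, is_concept_anchor, logical(1),
                               g = g, hd = hd)
    if (any(concept_anchored)) out <- c(out, "GENERAL_CONCEPT_CONTEXT")
    members <- g$hyperedges[[g$handles[[hd]]]]$members
    if (length(members) >= 3 && any(!concept_anchored))
      out <- c(out, "MULTI_ENTITY_INTERACTION")
  }
  sort(unique(out))
}

#' Corpus-level distribution of representation components and limitations
#'
#' Counts statements by component class (each graph falls in exactly one
#' class, so class counts sum to the corpus size) and limitation types at
#' article level: a type is counted once per PMID, and one article may carry
#' several types, so limitation counts can exceed the article count.
#'
#' @param graphs non-empty list of valid discovery graphs.
#' @return object of class `distribution_report` with `n_statements`,
#'   `n_articles`, `class_counts`, `class_percent` (percentages summing to
#'   100 up to rounding) and `limitation_counts`.
#' @export
corpus_distribution <- function(graphs) {
  if (length(graphs) == 0) stop("empty corpus")
  classes <- vapply(graphs, component_class, character(1))
  class_counts <- vapply(COMPONENT_CLASSES, function(k) sum(classes == k),
                         integer(1))
  pmids <- vapply(seq_along(graphs), function(i) {
    p <- graphs[[i]]$pmid
    if (is.null(p) || is.na(p) || !nzchar(p)) sprintf("row:%d", i) else p
  }, character(1))
  lims <- lapply(graphs, limitation_types)
  limitation_counts <- vapply(LIMITATION_TYPES, function(t)
    length(unique(pmids[vapply(lims, function(l) t %in% l, logical(1))])),
    integer(1))
  structure(list(
    n_statements = length(graphs),
    n_articles = length(unique(pmids)),
    class_counts = class_counts,
    class_percent = 100 * class_counts / length(graphs),
    limitation_counts = limitation_counts
  ), class = "distribution_report")
}

#' @export
print.distribution_report <- function(x, ...) {
  cat(sprintf("<distribution_report> %d statements, %d articles\n",
              x$n_statements, x$n_articles))
  cat("Representation components (statement level):\n")
  for (k in names(x$class_counts))
    cat(sprintf("  %-4s %4d  (%d%%)\n", k, x$class_counts[[k]],
                round(x$class_percent[[k]])))
  cat("Pairwise-limitation types (article level):\n")
  for (t in names(x$limitation_counts))
    cat(sprintf("  %-26s %4d\n", t, x$limitation_counts[[t]]))
  invisible(x)
}

#' Format a distribution report as markdown
#' @param x `distribution_report`.
#' @return character vector of markdown lines.
#' @export
format_distribution_md <- function(x) {
  stopifnot(inherits(x, "distribution_report"))
  c("# Representation component and limitation distribution",
    "",
    sprintf("%d statements across %d articles.", x$n_statements, x$n_articles),
    "",
    "| Component class | Statements | % |",
    "|---|---|---|",
    vapply(names(x$class_counts), function(k)
      sprintf("| %s | %d | %d%% |", k, x$class_counts[[k]],
              round(x$class_percent[[k]])), character(1)),
    "",
    "| Limitation type | Articles |",
    "|---|---|",
    vapply(names(x$limitation_counts), function(t)
      sprintf("| %s | %d |", t, x$limitation_counts[[t]]), character(1)))
}
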