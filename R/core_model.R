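# Core data model: entities, pairwise statements, nested entities,
# hyperedges and reified handles, assembled into a discovery graph.

#' Role tag vocabulary
#'
#' Closed vocabulary of semantic role tags carried by entities. Tags mark the
#' role an entity (or a grouped, nested entity) plays in a discovery
#' statement: a `FINDING` is a grouped claim, a `CONTEXT` constrains where a
#' finding holds, an `EXPERIMENTAL_MODEL` is the animal/clinical system it was
#' observed in, a `METHOD` produced it, a `MODIFIER` refines another entity,
#' a `GENERAL_CONCEPT` is an under-specified umbrella term, a `PROCESS` is a
#' mechanism or process built from modified entities, and `PLAIN` is the
#' untagged default.
#'
#' @format Character vector of the 8 admissible tags.
#' @export
ROLE_TAGS <- c("FINDING", "CONTEXT", "EXPERIMENTAL_MODEL", "METHOD",
               "MODIFIER", "GENERAL_CONCEPT", "PROCESS", "PLAIN")

#' Entity kinds
#' @format Character vector: simple surface-term node, nested-group owner,
#'   or reified-hyperedge handle.
#' @export
ENTITY_KINDS <- c("SIMPLE", "NESTED", "HANDLE")

#' Normalize an entity label
#'
#' Labels are normalized to Unicode NFC with runs of whitespace collapsed to a
#' single space and surrounding whitespace trimmed; case is preserved. Two
#' entities are the same node iff their normalized labels match within the
#' graph's article scope, so the normalized label doubles as the entity id.
#'
#' @param x character vector of labels.
#' @return normalized character vector.
#' @export
normalize_label <- function(x) {
  x <- stringi::stri_trans_nfc(enc2utf8(as.character(x)))
  x <- stringi::stri_replace_all_regex(x, "\\p{WHITE_SPACE}+", " ")
  stringi::stri_trim_both(x)
}

#' Create an empty discovery graph
#'
#' A discovery graph holds one statement's (or one article's) knowledge
#' representation: entities, directed/undirected pairwise statements, nested
#' entities (grouped subgraphs usable in entity role), hyperedges (sets of
#' \eqn{\ge 2} related entities) and handles binding reified hyperedges to
#' nodes.
#'
#' @param pmid optional source-article identifier.
#' @param statement_text optional source sentence(s).
#' @return an object of class `discovery_graph`.
#' @export
discovery_graph <- function(pmid = NA_character_, statement_text = NA_character_) {
  structure(
    list(
      pmid = as.character(pmid),
      statement_text = as.character(statement_text),
      entities = list(),    # id -> list(id, label, kind, role_tags, pmid)
      statements = list(),  # sid -> list(id, subject, predicate, object, directed)
      hyperedges = list(),  # hid -> list(id, members, label)
      handles = list(),     # handle entity id -> hyperedge id
      nested = list()       # owner entity id -> list(owner, body_statements, body_entities)
    ),
    class = "discovery_graph"
  )
}

#' @export
print.discovery_graph <- function(x, ...) {
  cat(sprintf(
    "<discovery_graph> pmid=%s: %d entities, %d statements, %d hyperedges, %d handles, %d nested\n",
    ifelse(is.na(x$pmid), "?", x$pmid),
    length(x$entities), length(x$statements),
    length(x$hyperedges), length(x$handles), length(x$nested)))
  invisible(x)
}

#' Test for a discovery graph
#' @param x object.
#' @export
is_discovery_graph <- function(x) inherits(x, "discovery_graph")

#' Add (or merge) an entity
#'
#' Entity identity is the normalized label: adding a label already present
#' merges role tags and returns the graph unchanged otherwise.
#'
#' @param g discovery graph.
#' @param label surface text; becomes the entity id after normalization.
#' @param kind one of `ENTITY_KINDS`.
#' @param role_tags character subset of `ROLE_TAGS`.
#' @param pmid optional per-entity source article (defaults to the graph's).
#' @return the modified graph.
#' @export
add_entity <- function(g, label, kind = "SIMPLE", role_tags = character(),
                       pmid = NULL) {
  stopifnot(is_discovery_graph(g))
  id <- normalize_label(label)
  if (!nzchar(id)) stop("entity label must be non-empty")
  kind <- match.arg(kind, ENTITY_KINDS)
  bad <- setdiff(role_tags, ROLE_TAGS)
  if (length(bad)) stop("unknown role tag(s): ", paste(bad, collapse = ", "))
  if (!is.null(g$entities[[id]])) {
    g$entities[[id]]$role_tags <-
      sort(unique(c(g$entities[[id]]$role_tags, role_tags)))
    return(g)
  }
  g$entities[[id]] <- list(
    id = id, label = id, kind = kind,
    role_tags = sort(unique(as.character(role_tags))),
    pmid = if (is.null(pmid)) g$pmid else as.character(pmid))
  g
}

resolve_entity <- function(g, label) {
  id <- normalize_label(label)
  if (is.null(g$entities[[id]])) NULL else id
}

#' Add a pairwise statement
#'
#' Subject and object entities are added as `SIMPLE` nodes when absent.
#' Undirected statements model co-occurrence and default to the
#' `cooccurs_with` predicate; predicate statements are directed.
#' Duplicate statements (same endpoints, predicate and direction) are merged.
#'
#' @param g discovery graph.
#' @param subject,object entity labels.
#' @param predicate relation label.
#' @param directed logical; `FALSE` for co-occurrence edges.
#' @return the modified graph.
#' @export
add_statement <- function(g, subject, predicate, object, directed = TRUE) {
  stopifnot(is_discovery_graph(g))
  s <- normalize_label(subject); o <- normalize_label(object)
  p <- normalize_label(predicate)
  if (!nzchar(s) || !nzchar(o)) stop("statement endpoints must be non-empty")
  if (!nzchar(p)) stop("predicate must be non-empty")
  if (is.null(g$entities[[s]])) g <- add_entity(g, s)
  if (is.null(g$entities[[o]])) g <- add_entity(g, o)
  if (!directed && s > o) { tmp <- s; s <- o; o <- tmp }  # canonical endpoint order
  if (!is.null(find_statement(g, s, p, o, directed))) return(g)
  sid <- sprintf("s%d", length(g$statements) + 1L)
  g$statements[[sid]] <- list(id = sid, subject = s, predicate = p,
                              object = o, directed = isTRUE(directed))
  g
}

#' Look up a statement id
#' @param g discovery graph.
#' @param subject,predicate,object labels.
#' @param directed logical.
#' @return statement id or `NULL`.
#' @export
find_statement <- function(g, subject, predicate, object, directed = TRUE) {
  s <- normalize_label(subject); p <- normalize_label(predicate)
  o <- normalize_label(object)
  if (!directed && s > o) { tmp <- s; s <- o; o <- tmp }
  for (st in g$statements) {
    if (st$subject == s && st$predicate == p && st$object == o &&
        st$directed == isTRUE(directed)) return(st$id)
  }
  NULL
}

#' Add a hyperedge
#'
#' A hyperedge relates an arbitrary set of \eqn{\ge 2} entities. A 2-member
#' hyperedge is the special case equivalent to an undirected pairwise link.
#' Members are added as `SIMPLE` entities when absent; a hyperedge with the
#' same member set is merged.
#'
#' @param g discovery graph.
#' @param members character vector of \eqn{\ge 2} entity labels.
#' @param label optional hyperedge label.
#' @return the modified graph.
#' @export
add_hyperedge <- function(g, members, label = NULL) {
  stopifnot(is_discovery_graph(g))
  members <- sort(unique(normalize_label(members)))
  if (length(members) < 2) stop("a hyperedge needs at least 2 members")
  for (m in members) if (is.null(g$entities[[m]])) g <- add_entity(g, m)
  if (!is.null(find_hyperedge(g, members))) return(g)
  hid <- sprintf("h%d", length(g$hyperedges) + 1L)
  g$hyperedges[[hid]] <- list(id = hid, members = members,
                              label = if (is.null(label)) NA_character_ else label)
  g
}

#' Look up a hyperedge id by member set
#' @param g discovery graph.
#' @param members entity labels.
#' @return hyperedge id or `NULL`.
#' @export
find_hyperedge <- function(g, members) {
  members <- sort(unique(normalize_label(members)))
  for (h in g$hyperedges) if (identical(h$members, members)) return(h$id)
  NULL
}

hyperedge_handle <- function(g, hid) {
  hits <- names(g$handles)[vapply(g$handles, identical, logical(1), hid)]
  if (length(hits)) hits[[1]] else NULL
}

default_handle_label <- function(members)
  paste0("{", paste(sort(members), collapse = " | "), "}")

#' Reify a hyperedge as a handle node
#'
#' Reification turns a hyperedge into a node (its handle) so the collective
#' relation can itself participate in pairwise statements — e.g. a reified set
#' of biomarkers linked `is_a` to a diagnostic test. Each hyperedge can carry
#' at most one handle (handles and reified hyperedges are in bijection).
#'
#' @param g discovery graph.
#' @param hyperedge hyperedge id (or member-set vector accepted by
#'   [find_hyperedge()]).
#' @param label optional handle label; defaults to `{m1 | m2 | ...}` over the
#'   sorted member set.
#' @return the modified graph; the handle's entity id is the (normalized)
#'   label, retrievable with [handle_for()].
#' @export
reify_hyperedge <- function(g, hyperedge, label = NULL) {
  stopifnot(is_discovery_graph(g))
  hid <- if (length(hyperedge) > 1 || is.null(g$hyperedges[[hyperedge]]))
    find_hyperedge(g, hyperedge) else hyperedge
  if (is.null(hid) || is.null(g$hyperedges[[hid]]))
    stop("no such hyperedge")
  if (!is.null(hyperedge_handle(g, hid)))
    stop("hyperedge ", hid, " is already reified")
  if (is.null(label)) label <- default_handle_label(g$hyperedges[[hid]]$members)
  id <- normalize_label(label)
  if (!is.null(g$entities[[id]]))
    stop("handle label collides with existing entity: ", id)
  g <- add_entity(g, id, kind = "HANDLE")
  g$handles[[id]] <- hid
  g
}

#' Handle entity bound to a hyperedge
#' @param g discovery graph.
#' @param hyperedge hyperedge id or member set.
#' @return handle entity id, or `NULL` if the hyperedge is not reified.
#' @export
handle_for <- function(g, hyperedge) {
  hid <- if (length(hyperedge) > 1 || is.null(g$hyperedges[[hyperedge]]))
    find_hyperedge(g, hyperedge) else hyperedge
  if (is.null(hid)) return(NULL)
  hyperedge_handle(g, hid)
}

#' Dereify a handle
#'
#' Inverse of [reify_hyperedge()]: removes the handle node and its binding,
#' recovering exactly the pre-reification graph. Refuses when the handle
#' participates in pairwise statements (removing it would drop knowledge).
#'
#' @param g discovery graph.
#' @param handle handle entity id.
#' @return the modified graph.
#' @export
dereify_handle <- function(g, handle) {
  id <- normalize_label(handle)
  if (is.null(g$handles[[id]])) stop("no such handle: ", id)
  used <- vapply(g$statements, function(st)
    st$subject == id || st$object == id, logical(1))
  if (any(used))
    stop("handle ", id, " participates in statements; remove them first")
  g$handles[[id]] <- NULL
  g$entities[[id]] <- NULL
  g
}

# Entities reachable downward through nesting containment from owner `id`.
nested_closure <- function(g, id, seen = character()) {
  if (id %in% seen) return(seen)  # cycle guard; validate_graph reports it
  seen <- c(seen, id)
  n <- g$nested[[id]]
  if (is.null(n)) return(seen)
  for (e in n$body_entities) seen <- nested_closure(g, e, seen)
  seen
}

#' Group statements as a nested entity
#'
#' Promotes a set of pairwise statements to entity role: a new `NESTED` node
#' owns the grouped statements and their endpoint entities as its body. The
#' grouped statements remain present in the graph (nesting preserves, never
#' overwrites, the pairwise layer), so the edge count never decreases.
#'
#' @param g discovery graph.
#' @param statement_refs character vector of statement ids to group.
#' @param role role tag carried by the new owner (see `ROLE_TAGS`).
#' @param label optional owner label; defaults to the bracketed canonical
#'   notation of the body, which makes serialization round-trip exactly.
#' @return the modified graph; the owner id is the normalized label,
#'   retrievable via [find_nested()].
#' @export
group_as_nested <- function(g, statement_refs, role, label = NULL) {
  stopifnot(is_discovery_graph(g))
  statement_refs <- unique(as.character(statement_refs))
  if (length(statement_refs) == 0) stop("empty body: no statements to group")
  role <- match.arg(role, ROLE_TAGS)
  missing <- setdiff(statement_refs, names(g$statements))
  if (length(missing)) stop("unknown statement ref(s): ",
                            paste(missing, collapse = ", "))
  body_entities <- sort(unique(unlist(lapply(
    g$statements[statement_refs], function(st) c(st$subject, st$object)))))
  if (is.null(label)) {
    body <- vapply(g$statements[statement_refs], function(st)
      render_statement(g, st), character(1))
    label <- paste0("[", paste(sort(body), collapse = "; "), "]{", role, "}")
  }
  id <- normalize_label(label)
  # a cycle would require the owner (or a nested entity containing it) to sit
  # inside its own body closure
  closure <- unique(unlist(lapply(body_entities, function(e)
    nested_closure(g, e))))
  if (id %in% closure)
    stop("grouping would create a containment cycle at ", id)
  if (!is.null(g$entities[[id]]) && g$entities[[id]]$kind != "NESTED")
    stop("label collides with existing non-nested entity: ", id)
  g <- add_entity(g, id, kind = "NESTED", role_tags = role)
  g$entities[[id]]$kind <- "NESTED"
  g$nested[[id]] <- list(owner = id,
                         body_statements = sort(statement_refs),
                         body_entities = body_entities)
  g
}

#' Find a nested entity owning a given statement set
#' @param g discovery graph.
#' @param statement_refs statement ids.
#' @return owner entity id or `NULL`.
#' @export
find_nested <- function(g, statement_refs) {
  want <- sort(unique(as.character(statement_refs)))
  for (n in g$nested) if (identical(n$body_statements, want)) return(n$owner)
  NULL
}

#' Validate a discovery graph
#'
#' Checks referential integrity (statements, hyperedges, handles and nested
#' bodies resolve), hyperedge cardinality, handle/hyperedge bijection, the
#' acyclicity (DAG) of nesting containment, kind consistency, role-tag
#' vocabulary, and that undirected statements are co-occurrences. Problems are
#' reported, not raised.
#'
#' @param g discovery graph.
#' @return character vector of violation messages; empty means valid.
#' @export
validate_graph <- function(g) {
  v <- character()
  if (!is_discovery_graph(g)) return("not a discovery_graph")
  ids <- names(g$entities)
  for (e in g$entities) {
    if (!all(e$role_tags %in% ROLE_TAGS))
      v <- c(v, sprintf("entity '%s' carries unknown role tag", e$id))
    if (e$kind == "NESTED" && is.null(g$nested[[e$id]]))
      v <- c(v, sprintf("NESTED entity '%s' owns no nested body", e$id))
    if (e$kind == "HANDLE" && is.null(g$handles[[e$id]]))
      v <- c(v, sprintf("HANDLE entity '%s' is bound to no hyperedge", e$id))
    if (e$kind == "SIMPLE" &&
        (!is.null(g$nested[[e$id]]) || !is.null(g$handles[[e$id]])))
      v <- c(v, sprintf("SIMPLE entity '%s' has nested/handle bindings", e$id))
  }
  for (st in g$statements) {
    for (end in c(st$subject, st$object))
      if (!(end %in% ids))
        v <- c(v, sprintf("statement %s references missing entity '%s'",
                          st$id, end))
    if (!st$directed && st$predicate != "cooccurs_with")
      v <- c(v, sprintf(
        "statement %s is undirected but not a co-occurrence ('%s')",
        st$id, st$predicate))
  }
  for (h in g$hyperedges) {
    if (length(h$members) < 2)
      v <- c(v, sprintf("hyperedge %s has fewer than 2 members", h$id))
    for (m in h$members)
      if (!(m %in% ids))
        v <- c(v, sprintf("hyperedge %s references missing entity '%s'",
                          h$id, m))
  }
  if (length(g$handles)) {
    for (hd in names(g$handles)) {
      if (!(hd %in% ids))
        v <- c(v, sprintf("handle '%s' is not an entity", hd))
      else if (g$entities[[hd]]$kind != "HANDLE")
        v <- c(v, sprintf("handle '%s' is not of kind HANDLE", hd))
      if (is.null(g$hyperedges[[g$handles[[hd]]]]))
        v <- c(v, sprintf("handle '%s' references missing hyperedge '%s'",
                          hd, g$handles[[hd]]))
    }
    if (anyDuplicated(unlist(g$handles)))
      v <- c(v, "multiple handles bound to the same hyperedge")
  }
  for (n in g$nested) {
    if (length(n$body_statements) == 0)
      v <- c(v, sprintf("nested entity '%s' has an empty body", n$owner))
    miss_s <- setdiff(n$body_statements, names(g$statements))
    if (length(miss_s))
      v <- c(v, sprintf("nested entity '%s' references missing statement(s) %s",
                        n$owner, paste(miss_s, collapse = ", ")))
    miss_e <- setdiff(n$body_entities, ids)
    if (length(miss_e))
      v <- c(v, sprintf("nested entity '%s' references missing entity(ies) %s",
                        n$owner, paste(miss_e, collapse = ", ")))
    for (sid in intersect(n$body_statements, names(g$statements))) {
      st <- g$statements[[sid]]
      if (!all(c(st$subject, st$object) %in% n$body_entities))
        v <- c(v, sprintf(
          "nested entity '%s': body statement %s has endpoints outside the body",
          n$owner, sid))
    }
  }
  # containment DAG over owner -> nested body entities
  if (length(g$nested)) {
    owners <- names(g$nested)
    edges <- list()
    for (o in owners)
      edges[[o]] <- intersect(g$nested[[o]]$body_entities, owners)
    state <- stats::setNames(rep(0L, length(owners)), owners)  # 0 new 1 open 2 done
    cyclic <- FALSE
    visit <- function(u) {
      if (state[[u]] == 1L) { cyclic <<- TRUE; return() }
      if (state[[u]] == 2L) return()
      state[[u]] <<- 1L
      for (w in edges[[u]]) visit(w)
      state[[u]] <<- 2L
    }
    for (o in owners) visit(o)
    if (cyclic) v <- c(v, "cyclic nesting containment (must be a DAG)")
  }
  v
}

#' Structural equality of discovery graphs
#'
#' Two graphs are equal when they have the same entities (id and kind), the
#' same statement set (endpoints, predicate, direction — internal ids are
#' ignored), the same hyperedge member sets, the same handle bindings and the
#' same nested bodies. Because entity identity is the normalized label, this
#' is labeled-graph isomorphism. Role tags on entities are compared only when
#' `compare_role_tags = TRUE`: the statement notation carries roles for nested
#' groups but not for plain entities, so the notation round trip preserves
#' structure and labels but not out-of-band entity tags (the JSON interchange
#' preserves everything).
#'
#' @param a,b discovery graphs.
#' @param compare_role_tags also require identical role tags per entity.
#' @return logical.
#' @export
graph_equal <- function(a, b, compare_role_tags = FALSE) {
  key_ents <- function(g) {
    k <- vapply(g$entities, function(e)
      paste(e$id, e$kind,
            if (compare_role_tags) paste(e$role_tags, collapse = ",") else "",
            sep = "\u1f"),
      character(1))
    sort(unname(k))
  }
  key_sts <- function(g) {
    k <- vapply(g$statements, function(st)
      paste(st$subject, st$predicate, st$object, st$directed, sep = "\u1f"),
      character(1))
    sort(unname(k))
  }
  key_hes <- function(g) sort(vapply(g$hyperedges, function(h)
    paste(h$members, collapse = "\u1f"), character(1), USE.NAMES = FALSE))
  key_handles <- function(g) sort(vapply(names(g$handles), function(hd)
    paste(hd, paste(g$hyperedges[[g$handles[[hd]]]]$members, collapse = ","),
          sep = "\u1f"), character(1), USE.NAMES = FALSE))
  key_nested <- function(g) sort(vapply(g$nested, function(n) {
    body <- vapply(g$statements[n$body_statements], function(st)
      paste(st$subject, st$predicate, st$object, st$directed, sep = "|"),
      character(1))
    paste(n$owner, paste(sort(body), collapse = ";"), sep = "\u1f")
  }, character(1), USE.NAMES = FALSE))
  identical(key_ents(a), key_ents(b)) &&
    identical(key_sts(a), key_sts(b)) &&
    identical(key_hes(a), key_hes(b)) &&
    identical(key_handles(a), key_handles(b)) &&
    identical(key_nested(a), key_nested(b))
}

#' Entity accessor
#' @param g discovery graph.
#' @param id entity id (normalized label).
#' @return the entity record, or `NULL`.
#' @export
entity <- function(g, id) g$entities[[normalize_label(id)]]

#' Statement ids not contained in any nested body
#' @param g discovery graph.
#' @return character vector of statement ids.
#' @export
top_level_statements <- function(g) {
  inside <- unique(unlist(lapply(g$nested, `[[`, "body_statements")))
  setdiff(names(g$statements), inside)
}
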