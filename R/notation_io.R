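# Statement-notation parsing and serialization, annotation-table I/O,
# JSON graph interchange, and a simplified BEL-style rendering.
#
# Notation grammar (an extension of the plain "subject::predicate::object"
# triple format):
#
#   document  :=  line (";" line)*            (newlines also separate lines)
#   line      :=  statement | term            (bare terms declare structure)
#   statement :=  term "::" predicate "::" term
#              |  term "<->" term             (undirected co-occurrence)
#   term      :=  simple
#              |  "[" statement (";" statement)* "]" "{" ROLE "}"   (nested)
#              |  "{" label ("|" label)* "}"                        (hyperedge)
#
# A hyperedge used in entity position is reified as a handle; a bare
# hyperedge line declares the hyperedge without reifying it.

syntax_error <- function(pos, msg) {
  stop(structure(
    class = c("notation_syntax_error", "error", "condition"),
    list(message = sprintf("syntax error at position %d: %s", pos, msg),
         call = sys.call(-1))))
}

new_parse_ctx <- function(text) {
  env <- new.env(parent = emptyenv())
  env$text <- text
  env$chars <- strsplit(text, "", fixed = TRUE)[[1]]
  env$pos <- 1L
  env
}

ctx_eof <- function(ctx) ctx$pos > length(ctx$chars)
ctx_peek <- function(ctx, n = 1L) {
  if (ctx_eof(ctx)) return("")
  paste(ctx$chars[ctx$pos:min(length(ctx$chars), ctx$pos + n - 1L)],
        collapse = "")
}
ctx_skip_ws <- function(ctx) {
  while (!ctx_eof(ctx) && grepl("^[ \t\r]$", ctx$chars[ctx$pos]))
    ctx$pos <- ctx$pos + 1L
}
ctx_expect <- function(ctx, tok) {
  ctx_skip_ws(ctx)
  if (ctx_peek(ctx, nchar(tok)) != tok)
    syntax_error(ctx$pos, sprintf("expected '%s'", tok))
  ctx$pos <- ctx$pos + nchar(tok)
}

# Read a plain label up to a structural delimiter. `extra` adds context-local
# terminators (e.g. "|", "]" or "}").
read_label <- function(ctx, extra = character()) {
  ctx_skip_ws(ctx)
  start <- ctx$pos
  out <- character()
  repeat {
    if (ctx_eof(ctx)) break
    two <- ctx_peek(ctx, 2L); three <- ctx_peek(ctx, 3L); one <- ctx_peek(ctx)
    if (two == "::" || three == "<->" || one %in% c(";", "\n") ||
        one %in% extra) break
    if (one %in% c("[", "{"))
      syntax_error(ctx$pos, sprintf("unexpected '%s' inside a label", one))
    if (one %in% c("]", "}", "|"))
      syntax_error(ctx$pos, sprintf("unexpected '%s'", one))
    out <- c(out, one)
    ctx$pos <- ctx$pos + 1L
  }
  label <- trimws(paste(out, collapse = ""))
  if (!nzchar(label)) syntax_error(start, "expected a label")
  label
}

# Parse one term. Returns list(id =, bare_hyper = logical).
parse_term <- function(ctx, g_env, extra = character()) {
  ctx_skip_ws(ctx)
  ch <- ctx_peek(ctx)
  if (ch == "[") {                     # nested group
    ctx_expect(ctx, "[")
    sids <- character()
    repeat {
      sids <- c(sids, parse_statement_required(ctx, g_env, extra = "]"))
      ctx_skip_ws(ctx)
      if (ctx_peek(ctx) == ";") { ctx_expect(ctx, ";"); next }
      break
    }
    ctx_expect(ctx, "]")
    ctx_expect(ctx, "{")
    role_pos <- ctx$pos
    role <- read_label(ctx, extra = "}")
    ctx_expect(ctx, "}")
    if (!(role %in% ROLE_TAGS))
      syntax_error(role_pos, sprintf("unknown role tag '%s'", role))
    g <- g_env$g
    body <- sort(vapply(g$statements[unique(sids)],
                        function(st) render_statement(g, st), character(1)))
    label <- paste0("[", paste(body, collapse = "; "), "]{", role, "}")
    owner <- normalize_label(label)
    if (is.null(g$entities[[owner]]))
      g <- group_as_nested(g, unique(sids), role, label = label)
    g_env$g <- g
    list(id = owner, bare_hyper = FALSE)
  } else if (ch == "{") {              # hyperedge
    ctx_expect(ctx, "{")
    members <- character()
    repeat {
      members <- c(members, read_label(ctx, extra = c("|", "}")))
      ctx_skip_ws(ctx)
      if (ctx_peek(ctx) == "|") { ctx_expect(ctx, "|"); next }
      break
    }
    ctx_expect(ctx, "}")
    if (length(unique(normalize_label(members))) < 2)
      syntax_error(ctx$pos, "a hyperedge needs at least 2 distinct members")
    g_env$g <- add_hyperedge(g_env$g, members)
    list(id = NA_character_, members = members, bare_hyper = TRUE)
  } else {                             # simple label
    list(id = read_label(ctx, extra = extra), bare_hyper = FALSE)
  }
}

# Hyperedge terms used in entity position are reified on demand.
term_as_entity <- function(term, g_env) {
  if (!term$bare_hyper) return(term$id)
  g <- g_env$g
  hid <- find_hyperedge(g, term$members)
  hd <- handle_for(g, hid)
  if (is.null(hd)) {
    g <- reify_hyperedge(g, hid)
    hd <- handle_for(g, hid)
  }
  g_env$g <- g
  hd
}

# in-body statements must really be statements
parse_statement_required <- function(ctx, g_env, extra = character()) {
  pos0 <- ctx$pos
  lhs <- parse_term(ctx, g_env, extra = extra)
  ctx_skip_ws(ctx)
  if (ctx_peek(ctx, 2L) == "::") {
    ctx_expect(ctx, "::")
    pred <- read_label(ctx)
    ctx_expect(ctx, "::")
    rhs <- parse_term(ctx, g_env, extra = extra)
    s <- term_as_entity(lhs, g_env); o <- term_as_entity(rhs, g_env)
    g_env$g <- add_statement(g_env$g, s, pred, o, directed = TRUE)
    find_statement(g_env$g, s, pred, o, directed = TRUE)
  } else if (ctx_peek(ctx, 3L) == "<->") {
    ctx_expect(ctx, "<->")
    rhs <- parse_term(ctx, g_env, extra = extra)
    s <- term_as_entity(lhs, g_env); o <- term_as_entity(rhs, g_env)
    g_env$g <- add_statement(g_env$g, s, "cooccurs_with", o, directed = FALSE)
    find_statement(g_env$g, s, "cooccurs_with", o, directed = FALSE)
  } else {
    syntax_error(pos0, "expected a statement inside a nested group")
  }
}

#' Parse statement notation into a discovery graph
#'
#' Accepts the extended `subject::predicate::object` notation: `a <-> b` for
#' undirected co-occurrences, `[ statement; ... ]{ROLE}` for nested groups
#' promoted to entity role, and `{m1 | m2 | ...}` for hyperedges (reified as a
#' handle when used in entity position, left bare when declared on a line of
#' their own). Lines are separated by `;` or newlines; a bare simple label
#' declares an isolated entity.
#'
#' @param s notation string.
#' @param pmid,statement_text metadata attached to the resulting graph.
#' @return a [discovery_graph()].
#' @export
parse_notation <- function(s, pmid = NA_character_, statement_text = NULL) {
  if (length(s) != 1 || is.na(s)) stop("s must be a single string")
  if (!nzchar(trimws(s)))
    syntax_error(0L, "empty notation string")
  if (is.null(statement_text)) statement_text <- s
  ctx <- new_parse_ctx(s)
  g_env <- new.env(parent = emptyenv())
  g_env$g <- discovery_graph(pmid = pmid, statement_text = statement_text)
  repeat {
    ctx_skip_ws(ctx)
    while (!ctx_eof(ctx) && ctx_peek(ctx) %in% c(";", "\n")) {
      ctx$pos <- ctx$pos + 1L
      ctx_skip_ws(ctx)
    }
    if (ctx_eof(ctx)) break
    lhs <- parse_term(ctx, g_env)
    ctx_skip_ws(ctx)
    if (ctx_peek(ctx, 2L) == "::") {
      ctx_expect(ctx, "::")
      pred <- read_label(ctx)
      ctx_expect(ctx, "::")
      rhs <- parse_term(ctx, g_env)
      s1 <- term_as_entity(lhs, g_env); o1 <- term_as_entity(rhs, g_env)
      g_env$g <- add_statement(g_env$g, s1, pred, o1, directed = TRUE)
    } else if (ctx_peek(ctx, 3L) == "<->") {
      ctx_expect(ctx, "<->")
      rhs <- parse_term(ctx, g_env)
      s1 <- term_as_entity(lhs, g_env); o1 <- term_as_entity(rhs, g_env)
      g_env$g <- add_statement(g_env$g, s1, "cooccurs_with", o1,
                               directed = FALSE)
    } else if (!ctx_eof(ctx) && !(ctx_peek(ctx) %in% c(";", "\n"))) {
      syntax_error(ctx$pos, "expected '::', '<->', ';' or end of input")
    } else if (!lhs$bare_hyper && !is.null(lhs$id) &&
               is.null(g_env$g$entities[[normalize_label(lhs$id)]])) {
      g_env$g <- add_entity(g_env$g, lhs$id)
    }
  }
  g_env$g
}

# --- serialization -----------------------------------------------------------

render_entity <- function(g, id) {
  e <- g$entities[[id]]
  if (is.null(e)) stop("cannot render unknown entity '", id, "'")
  switch(e$kind,
    SIMPLE = e$id,
    HANDLE = default_handle_label(g$hyperedges[[g$handles[[id]]]]$members),
    NESTED = {
      n <- g$nested[[id]]
      body <- sort(vapply(g$statements[n$body_statements],
                          function(st) render_statement(g, st), character(1)))
      role <- if (length(e$role_tags)) e$role_tags[[1]] else "PLAIN"
      paste0("[", paste(body, collapse = "; "), "]{", role, "}")
    })
}

render_statement <- function(g, st) {
  if (st$directed)
    paste0(render_entity(g, st$subject), "::", st$predicate, "::",
           render_entity(g, st$object))
  else
    paste0(render_entity(g, st$subject), " <-> ", render_entity(g, st$object))
}

#' Serialize a discovery graph to canonical notation
#'
#' Deterministic canonical form: top-level statements sorted lexicographically
#' by rendered subject, then predicate, then rendered object; bare (unreified,
#' unanchored) hyperedges and isolated entities follow as their own lines.
#' `parse_notation(serialize_notation(g))` is structurally equal to `g`, and
#' serialize-parse-serialize is idempotent. Custom handle labels are not part
#' of the notation (handles render as their member set); use the JSON
#' interchange to preserve them.
#'
#' @param g a valid discovery graph.
#' @return single-line notation string (lines joined by `"; "`).
#' @export
serialize_notation <- function(g) {
  viol <- validate_graph(g)
  if (length(viol))
    stop("cannot serialize an invalid graph: ", paste(viol, collapse = "; "))
  lines <- sort(vapply(g$statements[top_level_statements(g)],
                       function(st) render_statement(g, st), character(1),
                       USE.NAMES = FALSE))
  anchored <- unique(unlist(g$handles[vapply(names(g$handles), function(hd)
    any(vapply(g$statements, function(st)
      st$subject == hd || st$object == hd, logical(1))), logical(1))]))
  bare_h <- setdiff(names(g$hyperedges), anchored)
  lines <- c(lines, sort(vapply(g$hyperedges[bare_h], function(h)
    default_handle_label(h$members), character(1), USE.NAMES = FALSE)))
  used <- unique(c(
    unlist(lapply(g$statements, function(st) c(st$subject, st$object))),
    unlist(lapply(g$hyperedges, `[[`, "members")),
    unlist(lapply(g$nested, `[[`, "body_entities")),
    names(g$handles)))
  isolated <- setdiff(names(g$entities), c(used, names(g$nested)))
  isolated <- isolated[vapply(g$entities[isolated], function(e)
    e$kind == "SIMPLE", logical(1))]
  lines <- c(lines, sort(isolated))
  # nested owners referenced nowhere still need a declaration line
  dangling_owner <- setdiff(names(g$nested), used)
  lines <- c(lines, sort(vapply(dangling_owner, function(o)
    render_entity(g, o), character(1), USE.NAMES = FALSE)))
  paste(lines, collapse = "; ")
}

# --- annotation tables -------------------------------------------------------

ANNOTATION_COLUMNS <- c("pmid", "article", "statement", "entities",
                        "representation")

#' Read a five-column annotation table
#'
#' One row per discovery statement: article PMID, article title, the
#' natural-language statement, the extracted entities (separated by `;`), and
#' the ideal representation in statement notation. Multiple statements from
#' one article are multiple rows sharing a PMID. UTF-8, tab-separated by
#' default with comma fallback.
#'
#' @param path TSV/CSV file with a header row.
#' @param header_map optional named character vector mapping canonical column
#'   names (`pmid`, `article`, `statement`, `entities`, `representation`) to
#'   the file's actual headers.
#' @param sep field separator; inferred from the file when `NULL`.
#' @return data.frame with the five canonical columns; `entities` is a list
#'   column of character vectors. Representations are parsed lazily — see
#'   [annotation_graphs()].
#' @export
read_annotation_table <- function(path, header_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L, encoding = "UTF-8")
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tbl <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           encoding = "UTF-8", comment.char = "")
  nm <- tolower(trimws(names(tbl)))
  names(tbl) <- nm
  if (!is.null(header_map)) {
    for (canon in names(header_map)) {
      actual <- tolower(trimws(header_map[[canon]]))
      if (actual %in% names(tbl)) names(tbl)[names(tbl) == actual] <- canon
    }
  }
  missing <- setdiff(ANNOTATION_COLUMNS, names(tbl))
  if (length(missing))
    stop("annotation table is missing column(s): ",
         paste(missing, collapse = ", "))
  out <- tbl[ANNOTATION_COLUMNS]
  out$pmid <- as.character(out$pmid)
  out$entities <- lapply(strsplit(as.character(out$entities), ";", fixed = TRUE),
                         function(x) trimws(x[nzchar(trimws(x))]))
  out
}

#' Write an annotation table
#' @param tbl data.frame as returned by [read_annotation_table()].
#' @param path output file.
#' @param sep field separator (tab default; use `","` for CSV).
#' @export
write_annotation_table <- function(tbl, path, sep = "\t") {
  missing <- setdiff(ANNOTATION_COLUMNS, names(tbl))
  if (length(missing))
    stop("annotation table is missing column(s): ",
         paste(missing, collapse = ", "))
  out <- tbl[ANNOTATION_COLUMNS]
  out$entities <- vapply(out$entities, paste, character(1), collapse = "; ")
  utils::write.table(out, path, sep = sep, quote = (sep == ","),
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Parse the representation column of an annotation table
#'
#' @param tbl annotation table.
#' @return named list of discovery graphs (one per row, named by row index);
#'   a row whose representation fails to parse raises an error naming its
#'   PMID.
#' @export
annotation_graphs <- function(tbl) {
  out <- vector("list", nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    out[[i]] <- tryCatch(
      parse_notation(tbl$representation[[i]], pmid = tbl$pmid[[i]],
                     statement_text = tbl$statement[[i]]),
      error = function(e) stop(sprintf(
        "row %d (PMID %s): %s", i, tbl$pmid[[i]], conditionMessage(e)),
        call. = FALSE))
  }
  names(out) <- as.character(seq_len(nrow(tbl)))
  out
}

# --- BEL-style rendering -----------------------------------------------------

#' Render an entity in a simplified BEL style
#'
#' Nested entities render as function-wrapped terms: a `METHOD`-tagged entity
#' renders as `method(label)`, a modifier attaches as a `modifier(...)` suffix
#' to the entity it modifies, and handles render their member list. The output
#' is deterministic (body statements in canonical order). Illustrative only —
#' no namespaces or full BEL grammar.
#'
#' @param g discovery graph.
#' @param entity entity label/id to render.
#' @return character string.
#' @export
render_bel <- function(g, entity) {
  id <- resolve_entity(g, entity)
  if (is.null(id)) stop("no such entity: ", entity)
  bel_term(g, id, top = TRUE)
}

bel_term <- function(g, id, top = FALSE) {
  e <- g$entities[[id]]
  if (e$kind == "HANDLE") {
    members <- sort(g$hyperedges[[g$handles[[id]]]]$members)
    return(paste0("(", paste(vapply(members, function(m) bel_term(g, m),
                                    character(1)), collapse = ", "), ")"))
  }
  if (e$kind == "NESTED") {
    n <- g$nested[[id]]
    sts <- g$statements[sort(n$body_statements)]
    keys <- vapply(sts, function(st) render_statement(g, st), character(1))
    sts <- sts[order(keys)]
    if (length(sts) == 1 && sts[[1]]$predicate == "modify") {
      st <- sts[[1]]
      return(paste0("(", bel_term(g, st$object), ", modifier(",
                    g$entities[[st$subject]]$label, "))"))
    }
    rendered <- vapply(sts, function(st) {
      if (st$directed)
        paste0(bel_term(g, st$subject), " ", st$predicate, " ",
               bel_term(g, st$object))
      else
        paste0(bel_term(g, st$subject), " cooccurs_with ",
               bel_term(g, st$object))
    }, character(1))
    body <- paste(sort(rendered), collapse = "; ")
    return(if (top) body else paste0("(", body, ")"))
  }
  if ("METHOD" %in% e$role_tags) return(paste0("method(", e$label, ")"))
  if ("MODIFIER" %in% e$role_tags &&
      !top) return(e$label)  # wrapped by the statement that uses it
  e$label
}

# --- JSON interchange --------------------------------------------------------

#' Serialize a discovery graph to the JSON interchange format
#'
#' One JSON document per graph with arrays `entities`, `statements`,
#' `hyperedges`, `handles` and `nested` (schema shipped at
#' `system.file("schema", "discovery-graph.schema.json", package =
#' "hypernest")`).
#'
#' @param g discovery graph.
#' @param path optional file to write; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
graph_to_json <- function(g, path = NULL) {
  doc <- list(
    pmid = g$pmid,
    statement_text = g$statement_text,
    entities = unname(lapply(g$entities, function(e)
      list(id = e$id, label = e$label, kind = e$kind,
           role_tags = as.list(e$role_tags), pmid = e$pmid))),
    statements = unname(lapply(g$statements, function(st)
      list(id = st$id, subject = st$subject, predicate = st$predicate,
           object = st$object, directed = st$directed))),
    hyperedges = unname(lapply(g$hyperedges, function(h)
      list(id = h$id, members = as.list(h$members), label = h$label))),
    handles = unname(lapply(names(g$handles), function(hd)
      list(handle = hd, hyperedge = g$handles[[hd]]))),
    nested = unname(lapply(g$nested, function(n)
      list(owner = n$owner,
           body_statements = as.list(n$body_statements),
           body_entities = as.list(n$body_entities))))
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", na = "null",
                           pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

req_field <- function(x, field, where) {
  if (is.null(x[[field]]))
    stop(sprintf("JSON graph document: missing '%s' in %s", field, where))
  x[[field]]
}

#' Read a discovery graph from the JSON interchange format
#'
#' @param x path to a JSON file, or a JSON string.
#' @return a [discovery_graph()]; the document is validated structurally and
#'   with [validate_graph()], and reading fails on any violation.
#' @export
graph_from_json <- function(x) {
  if (length(x) == 1 && !grepl("[{]", x) && file.exists(x))
    x <- paste(readLines(x, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  doc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  for (f in c("entities", "statements", "hyperedges", "handles", "nested"))
    if (is.null(doc[[f]])) stop("JSON graph document: missing array '", f, "'")
  g <- discovery_graph(
    pmid = if (is.null(doc$pmid)) NA_character_ else doc$pmid,
    statement_text = if (is.null(doc$statement_text)) NA_character_
                     else doc$statement_text)
  for (e in doc$entities) {
    id <- normalize_label(req_field(e, "id", "entity"))
    kind <- req_field(e, "kind", "entity")
    if (!(kind %in% ENTITY_KINDS)) stop("unknown entity kind: ", kind)
    g$entities[[id]] <- list(
      id = id,
      label = if (is.null(e$label)) id else normalize_label(e$label),
      kind = kind,
      role_tags = sort(unique(unlist(e$role_tags))),
      pmid = if (is.null(e$pmid)) g$pmid else as.character(e$pmid))
  }
  for (st in doc$statements) {
    sid <- req_field(st, "id", "statement")
    g$statements[[sid]] <- list(
      id = sid,
      subject = normalize_label(req_field(st, "subject", "statement")),
      predicate = normalize_label(req_field(st, "predicate", "statement")),
      object = normalize_label(req_field(st, "object", "statement")),
      directed = isTRUE(req_field(st, "directed", "statement")))
  }
  for (h in doc$hyperedges) {
    hid <- req_field(h, "id", "hyperedge")
    g$hyperedges[[hid]] <- list(
      id = hid,
      members = sort(unique(normalize_label(unlist(
        req_field(h, "members", "hyperedge"))))),
      label = if (is.null(h$label) || is.na(h$label)) NA_character_
              else h$label)
  }
  for (hd in doc$handles)
    g$handles[[normalize_label(req_field(hd, "handle", "handle"))]] <-
      req_field(hd, "hyperedge", "handle")
  for (n in doc$nested) {
    owner <- normalize_label(req_field(n, "owner", "nested"))
    g$nested[[owner]] <- list(
      owner = owner,
      body_statements = sort(unlist(req_field(n, "body_statements", "nested"))),
      body_entities = sort(normalize_label(unlist(
        req_field(n, "body_entities", "nested")))))
  }
  viol <- validate_graph(g)
  if (length(viol))
    stop("invalid graph document: ", paste(viol, collapse = "; "))
  g
}

#' Write the flattened simple graph as a plain edge list
#'
#' GraphML-style tab-separated edge list (`from`, `predicate`, `to`,
#' `directed`) of [flatten_atomic()] output, for interchange with standard
#' graph tooling.
#'
#' @param g discovery graph or [simple_graph()].
#' @param path output TSV path.
#' @export
write_edge_list <- function(g, path) {
  sg <- if (inherits(g, "simple_graph")) g else flatten_atomic(g)
  utils::write.table(
    sg$edges[c("from", "predicate", "to", "directed")], path, sep = "\t",
    quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
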