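test_that("plain triples parse to directed statements over SIMPLE entities", {
  g <- parse_notation("plasma NfL::is superior to::plasma t-tau")
  expect_length(g$statements, 1L)
  st <- g$statements[[1]]
  expect_true(st$directed)
  expect_equal(st$subject, "plasma NfL")
  expect_equal(st$predicate, "is superior to")
  expect_equal(st$object, "plasma t-tau")
  expect_equal(sort(vapply(g$entities, `[[`, character(1), "kind")),
               c("SIMPLE", "SIMPLE"), ignore_attr = TRUE)
})

test_that("bracketed groups parse to nested entities in entity role", {
  g <- parse_notation(
    "[ plasma NfL::is superior to::plasma t-tau ]{FINDING}::for::diagnosis of AD-S")
  expect_length(g$nested, 1L)
  owner <- names(g$nested)
  expect_equal(g$entities[[owner]]$kind, "NESTED")
  expect_true("FINDING" %in% g$entities[[owner]]$role_tags)
  # both the inner statement and the outer `for` edge are present
  expect_length(g$statements, 2L)
  expect_false(is.null(find_statement(g, owner, "for", "diagnosis of AD-S")))
  expect_identical(validate_graph(g), character())
})

test_that("hyperedges parse; entity position reifies, bare lines do not", {
  g <- parse_notation("{B1 | B2 | B3}::is_a::A_test")
  expect_length(g$hyperedges, 1L)
  expect_length(g$handles, 1L)
  expect_equal(g$hyperedges[[1]]$members, c("B1", "B2", "B3"))
  hd <- names(g$handles)
  expect_false(is.null(find_statement(g, hd, "is_a", "A_test")))

  g2 <- parse_notation("{B1 | B2 | B3}")
  expect_length(g2$hyperedges, 1L)
  expect_length(g2$handles, 0L)
})

test_that("undirected co-occurrence uses the <-> marker both ways", {
  g <- parse_notation("tau <-> amyloid")
  st <- g$statements[[1]]
  expect_false(st$directed)
  expect_equal(st$predicate, "cooccurs_with")
  expect_match(serialize_notation(g), "<->", fixed = TRUE)
})

test_that("syntax errors carry a position; unknown roles are rejected", {
  err <- tryCatch(parse_notation(""), condition = identity)
  expect_s3_class(err, "notation_syntax_error")
  expect_match(conditionMessage(err), "position 0")
  expect_error(parse_notation("a::b"), class = "notation_syntax_error")
  expect_error(parse_notation("[a::b::c]{NOT_A_ROLE}::d::e"),
               "unknown role tag")
  expect_error(parse_notation("{solo}::r::x"), "at least 2")
})

test_that("parse/serialize round-trips every fixture to an equal graph", {
  for (f in build_worked_examples()) {
    s <- serialize_notation(f$graph)
    g2 <- parse_notation(s, pmid = f$graph$pmid)
    expect_true(graph_equal(f$graph, g2), label = paste("round trip:", f$name))
    expect_identical(serialize_notation(g2), s,
                     label = paste("idempotence:", f$name))
  }
})

test_that("serialization is canonical: ordering is deterministic", {
  g1 <- discovery_graph()
  g1 <- add_statement(g1, "b", "r", "c")
  g1 <- add_statement(g1, "a", "r", "b")
  g2 <- discovery_graph()
  g2 <- add_statement(g2, "a", "r", "b")
  g2 <- add_statement(g2, "b", "r", "c")
  expect_identical(serialize_notation(g1), serialize_notation(g2))
  expect_equal(strsplit(serialize_notation(g1), "; ", fixed = TRUE)[[1]][1],
               "a::r::b")
})

test_that("annotation tables round-trip and report schema problems", {
  fx <- build_worked_examples()
  tbl <- worked_example_table(fx)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(tbl, path)
  back <- read_annotation_table(path)
  expect_equal(back$pmid, tbl$pmid)
  expect_equal(back$representation, tbl$representation)
  expect_equal(back$entities, tbl$entities, ignore_attr = TRUE)

  graphs <- annotation_graphs(back)
  expect_length(graphs, nrow(tbl))
  for (i in seq_along(graphs))
    expect_identical(validate_graph(graphs[[i]]), character())

  # four-column file: schema error naming the column
  bad <- withr::local_tempfile(fileext = ".tsv")
  four <- tbl[c("pmid", "article", "statement", "entities")]
  four$entities <- vapply(four$entities, paste, character(1), collapse = "; ")
  utils::write.table(four, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_annotation_table(bad), "representation")

  # unparsable representation: per-row error with the pmid
  tbl2 <- tbl[1, ]
  tbl2$representation <- "a::b"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(tbl2, path2)
  expect_error(annotation_graphs(read_annotation_table(path2)), tbl2$pmid[1])
})

test_that("header mapping and CSV dialect are accepted", {
  tbl <- worked_example_table()[1:3, ]
  path <- withr::local_tempfile(fileext = ".csv")
  out <- tbl
  out$entities <- vapply(out$entities, paste, character(1), collapse = "; ")
  names(out) <- c("PMID", "Article", "Statement", "Entities",
                  "Ideal representation")
  utils::write.table(out, path, sep = ",", quote = TRUE, row.names = FALSE)
  back <- read_annotation_table(
    path, header_map = c(representation = "Ideal representation"))
  expect_equal(back$representation, tbl$representation)
})

test_that("BEL rendering wraps methods and modifiers deterministically", {
  fx <- build_worked_examples()
  g <- fx$amyloidload_complex$graph
  outer <- names(g$nested)[vapply(names(g$nested), function(o)
    length(g$nested[[o]]$body_statements) == 1 &&
      g$statements[[g$nested[[o]]$body_statements]]$subject ==
        "PET measurement", logical(1))]
  expect_equal(render_bel(g, outer),
               "method(PET measurement) of (amyloid load, modifier(longitudinal))")
  expect_identical(render_bel(g, outer), render_bel(g, outer))

  g2 <- add_entity(discovery_graph(), "tau")
  expect_equal(render_bel(g2, "tau"), "tau")

  # handles render their member list and never raise on valid graphs
  g3 <- reified_test_graph()
  expect_equal(render_bel(g3, handle_for(g3, "h1")), "(B1, B2, B3)")
  expect_error(render_bel(g3, "nonexistent"), "no such entity")
})

test_that("JSON interchange preserves the full graph including role tags", {
  for (f in build_worked_examples()) {
    g2 <- graph_from_json(graph_to_json(f$graph))
    expect_true(graph_equal(f$graph, g2, compare_role_tags = TRUE),
                label = paste("json round trip:", f$name))
  }
  path <- withr::local_tempfile(fileext = ".json")
  g <- build_worked_examples()$panel_complex$graph
  graph_to_json(g, path)
  expect_true(graph_equal(g, graph_from_json(path), compare_role_tags = TRUE))
  expect_error(graph_from_json('{"entities": []}'), "missing array")
})

test_that("the interchange schema ships with the package", {
  schema <- system.file("schema", "discovery-graph.schema.json",
                        package = "hypernest")
  expect_true(nzchar(schema))
  doc <- jsonlite::fromJSON(schema)
  expect_setequal(doc$required,
                  c("entities", "statements", "hyperedges", "handles",
                    "nested"))
})
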