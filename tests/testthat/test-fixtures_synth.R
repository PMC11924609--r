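test_that("the worked-example corpus is complete and faithful", {
  fx <- build_worked_examples()
  expect_gte(length(fx), 13L)
  pmids <- unique(na.omit(vapply(fx, `[[`, character(1), "pmid")))
  for (p in c("33958804", "33933117", "33450230", "33421595", "33257949",
              "33980574", "33589840", "33723967", "BioNLP2009"))
    expect_true(p %in% pmids, label = paste("fixture for", p))
  for (f in fx)
    expect_identical(validate_graph(f$graph), character(),
                     label = paste(f$name, "validates"))
})

test_that("key worked structures carry the printed cardinalities", {
  fx <- build_worked_examples()
  # three-biomarker hyperedge behind the blood-test statement
  he <- fx$bloodtest_complex$graph$hyperedges[[1]]
  expect_length(he$members, 3L)
  # four context nodes attached to the plasma-NfL finding
  g5 <- fx$nfl_complex$graph
  owner <- names(g5$nested)[1]
  ctx <- vapply(g5$statements, function(st)
    st$subject == owner && st$predicate == "for", logical(1))
  expect_equal(sum(ctx), 4L)
  # three major binding sites grouped behind the general concept
  g10 <- fx$bindingsites_complex$graph
  expect_length(g10$hyperedges[[1]]$members, 3L)
})

test_that("the nested-event sentence encodes three chained statements", {
  g <- build_worked_examples()$bionlp_events$graph
  expect_length(g$statements, 3L)
  expect_length(g$nested, 2L)
  # chain: negative regulation contains positive regulation contains expression
  s1 <- Filter(function(st) st$subject == "SQ 22536", g$statements)[[1]]
  e2 <- s1$object
  expect_equal(g$entities[[e2]]$kind, "NESTED")
  inner_sids <- g$nested[[e2]]$body_statements
  s2 <- g$statements[[inner_sids]]
  expect_equal(s2$subject, "gp41")
  e3 <- s2$object
  expect_equal(g$entities[[e3]]$kind, "NESTED")
  s3 <- g$statements[[g$nested[[e3]]$body_statements]]
  expect_equal(s3$object, "IL-10")
})

test_that("the generator honors degenerate and planted mixtures", {
  pure <- generate_corpus(30, mixture = c(1, 0, 0), seed = 5)
  expect_true(all(vapply(pure$graphs, component_class, character(1)) == "P"))
  expect_error(generate_corpus(10, mixture = c(0.5, 0.4, 0.2)),
               "summing to 1")
  expect_error(generate_corpus(0), "n_statements")
})

test_that("the generator is deterministic under a fixed seed", {
  a <- generate_corpus(40, seed = 21)
  b <- generate_corpus(40, seed = 21)
  expect_identical(a, b)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_corpus(a, d1); write_corpus(b, d2)
  expect_identical(readLines(file.path(d1, "annotations.tsv")),
                   readLines(file.path(d2, "annotations.tsv")))
  expect_identical(unname(tools::md5sum(list.files(file.path(d1, "graphs"),
                                                   full.names = TRUE))),
                   unname(tools::md5sum(list.files(file.path(d2, "graphs"),
                                                   full.names = TRUE))))
})

test_that("generated graphs validate and their notation re-parses", {
  co <- generate_corpus(25, seed = 3)
  for (i in seq_along(co$graphs)) {
    expect_identical(validate_graph(co$graphs[[i]]), character())
    g2 <- parse_notation(co$records$representation[i])
    expect_true(graph_equal(co$graphs[[i]], g2))
  }
})

test_that("the planted class is recovered by the classifier per statement", {
  co <- generate_corpus(120, seed = 9)
  observed <- vapply(co$graphs, component_class, character(1))
  expect_identical(observed, co$classes)
})

test_that("corpus round-trips through the on-disk layout", {
  co <- generate_corpus(15, seed = 30)
  dir <- withr::local_tempdir()
  write_corpus(co, dir)
  back <- read_corpus(dir)
  expect_equal(length(back$graphs), 15L)
  expect_identical(back$years, co$years)
  for (i in seq_along(co$graphs))
    expect_true(graph_equal(co$graphs[[i]], back$graphs[[i]],
                            compare_role_tags = TRUE))
})

test_that("the time-slice split partitions the corpus by year", {
  co <- generate_corpus(60, year_range = c(2019L, 2021L), seed = 13)
  sl <- split_timeslice(co, 2021L)
  n_test <- sum(co$years == 2021L)
  expect_equal(length(sl$train_graphs), sum(co$years < 2021L))
  expect_equal(length(sl$train_graphs) + n_test, 60L)
  expect_gt(n_test, 0)
  # test edges only come from test-year statements
  test_keys <- paste(sl$test_edges$from, sl$test_edges$to, sep = "~")
  from_test_year <- unlist(lapply(which(co$years == 2021L), function(i) {
    e <- flatten_atomic(co$graphs[[i]])$edges
    paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "~")
  }))
  expect_true(all(test_keys %in% from_test_year))

  expect_warning(sl0 <- split_timeslice(co, 1900L), "empty")
  expect_equal(nrow(sl0$test_edges), 0L)
  expect_equal(length(sl0$train_graphs), 0L)
})
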