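# Synthetic annotated corpora with planted representation-component mixtures,
# emulating a curated discovery-statement collection spanning 1977-2021.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

default_vocab_sizes <- function() {
  c(biomarker = 30L, outcome = 12L, context = 10L, model = 8L,
    method = 8L, modifier = 6L, concept = 10L)
}

vocab <- function(role, n) sprintf("%s_%02d", toupper(role), seq_len(n))

#' Generate a synthetic annotated corpus
#'
#' Draws `n_statements` discovery graphs from a planted mixture over the
#' component classes: `P` statements are 1-3 plain triples; `PN` statements
#' add a `FINDING`-tagged nested group decorated (uniformly at random) with a
#' context, an experimental model, a method, or a modifier grouping; `PNH`
#' statements additionally plant a reified hyperedge of 3-4 members. Entity
#' labels come from role-specific vocabularies (`BIOMARKER_01`, `CONTEXT_03`,
#' ...) so role tags are self-evident; no attempt is made to mimic real
#' Alzheimer's-disease terminology. Year stamps are uniform over
#' `year_range`. Deterministic under a fixed seed.
#'
#' @param n_statements number of statements (\eqn{\ge 1}).
#' @param mixture probability triple `(P, PN, PNH)` summing to 1.
#' @param vocab_sizes named integer vector of per-role vocabulary sizes.
#' @param year_range inclusive publication-year span.
#' @param seed RNG seed (default 17).
#' @param exact plant `round(n * mixture)` statements per class (largest
#'   remainder) instead of multinomial sampling — use to reproduce a printed
#'   corpus composition exactly.
#' @return object of class `synthetic_corpus`: `$records` (five-column
#'   annotation data.frame plus a `year` column), `$graphs`, `$years`,
#'   `$classes` (the planted class per statement).
#' @export
generate_corpus <- function(n_statements = 56,
                            mixture = c(P = 0.20, PN = 0.73, PNH = 0.07),
                            vocab_sizes = default_vocab_sizes(),
                            year_range = c(1977L, 2021L),
                            seed = 17, exact = FALSE) {
  if (n_statements < 1) stop("n_statements must be >= 1")
  mixture <- as.numeric(mixture)
  if (length(mixture) != 3 || any(mixture < 0) || any(mixture > 1) ||
      abs(sum(mixture) - 1) > 1e-9)
    stop("mixture must be a probability triple (P, PN, PNH) summing to 1")
  vs <- default_vocab_sizes()
  vs[names(vocab_sizes)] <- vocab_sizes
  voc <- lapply(stats::setNames(nm = names(vs)), function(r) vocab(r, vs[[r]]))
  preds <- c("associate with", "reduce", "increase", "inhibit")

  with_seed(seed, {
    classes <- if (exact) {
      quota <- floor(n_statements * mixture)
      rem <- n_statements - sum(quota)
      frac <- n_statements * mixture - quota
      quota[order(-frac)[seq_len(rem)]] <- quota[order(-frac)[seq_len(rem)]] + 1L
      rep(c("P", "PN", "PNH"), times = quota)
    } else {
      sample(c("P", "PN", "PNH"), n_statements, replace = TRUE, prob = mixture)
    }
    years <- sample(seq(year_range[1], year_range[2]), n_statements,
                    replace = TRUE)
    graphs <- vector("list", n_statements)
    rows <- vector("list", n_statements)
    for (i in seq_len(n_statements)) {
      pmid <- sprintf("SYN%05d", i)
      g <- discovery_graph(pmid, sprintf("synthetic statement %d", i))
      base_subj <- sample(voc$biomarker, 1)
      base_pred <- sample(preds, 1)
      base_obj <- sample(voc$outcome, 1)
      g <- add_statement(g, base_subj, base_pred, base_obj)
      if (classes[i] == "P") {
        for (k in seq_len(sample(0:2, 1))) {
          s <- sample(voc$biomarker, 1); o <- sample(voc$outcome, 1)
          g <- add_statement(g, s, sample(preds, 1), o)
        }
      } else {
        deco <- sample(c("context", "model", "method", "modifier"), 1)
        if (deco == "modifier") {
          m <- sample(voc$modifier, 1); b <- sample(voc$biomarker, 1)
          g <- add_entity(g, m, role_tags = "MODIFIER")
          g <- add_statement(g, m, "modify", b)
          role <- sample(c("PROCESS", "PLAIN"), 1)
          g <- group_as_nested(g, find_statement(g, m, "modify", b), role)
          owner <- find_nested(g, find_statement(g, m, "modify", b))
          g <- add_statement(g, owner, "associate with", sample(voc$outcome, 1))
        } else {
          s0 <- find_statement(g, base_subj, base_pred, base_obj)
          g <- group_as_nested(g, s0, "FINDING")
          owner <- find_nested(g, s0)
          if (deco == "context") {
            ctx <- sample(voc$context, 1)
            g <- add_entity(g, ctx, role_tags = "CONTEXT")
            g <- add_statement(g, owner, "for", ctx)
          } else if (deco == "model") {
            mdl <- sample(voc$model, 1)
            g <- add_entity(g, mdl, role_tags = "EXPERIMENTAL_MODEL")
            g <- add_statement(g, owner, "in", mdl)
          } else {
            mth <- sample(voc$method, 1)
            g <- add_entity(g, mth, role_tags = "METHOD")
            g <- add_statement(g, mth, "identify", owner)
          }
        }
        if (classes[i] == "PNH") {
          members <- sample(voc$biomarker, sample(3:4, 1))
          g <- add_hyperedge(g, members)
          g <- reify_hyperedge(g, find_hyperedge(g, members))
          hd <- handle_for(g, find_hyperedge(g, members))
          if (stats::runif(1) < 0.5) {
            cpt <- sample(voc$concept, 1)
            g <- add_entity(g, cpt, role_tags = "GENERAL_CONCEPT")
            g <- add_statement(g, hd, "is_a", cpt)
          } else {
            g <- add_statement(g, hd, "identify", sample(voc$outcome, 1))
          }
        }
      }
      graphs[[i]] <- g
      ents <- names(g$entities)[vapply(g$entities, function(e)
        e$kind == "SIMPLE", logical(1))]
      rows[[i]] <- data.frame(
        pmid = pmid, article = sprintf("synthetic article %d", i),
        statement = g$statement_text,
        entities = paste(sort(ents), collapse = "; "),
        representation = serialize_notation(g),
        year = years[i], stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rows)
    records$entities <- strsplit(records$entities, "; ", fixed = TRUE)
    structure(list(records = records, graphs = graphs, years = years,
                   classes = classes, mixture = mixture, seed = seed),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d statements, years %d-%d, seed %s\n",
              length(x$graphs), min(x$years), max(x$years),
              format(x$seed)))
  invisible(x)
}

#' Split a corpus at a publication year
#'
#' Statements published before `test_year` form the training corpus;
#' the flattened co-occurrence edges of statements published in `test_year`
#' form the test edge set, following the train-on-earlier / test-on-later
#' evaluation design.
#'
#' @param corpus a `synthetic_corpus`, or a list with `$graphs` and `$years`.
#' @param test_year the held-out year.
#' @return list: `train_graphs`, `train` (merged flattened [simple_graph()]
#'   over the training statements), `test_edges` (data.frame `from`, `to`).
#'   Warns when no statement falls in `test_year`.
#' @export
split_timeslice <- function(corpus, test_year) {
  stopifnot(!is.null(corpus$graphs), !is.null(corpus$years),
            length(corpus$graphs) == length(corpus$years))
  train_idx <- which(corpus$years < test_year)
  test_idx <- which(corpus$years == test_year)
  if (!length(test_idx))
    warning("no statements published in test year ", test_year,
            "; test edge set is empty")
  flat <- function(idx) {
    if (!length(idx)) return(empty_edges())
    do.call(rbind, lapply(corpus$graphs[idx],
                          function(g) flatten_atomic(g)$edges))
  }
  train_edges <- flat(train_idx)
  test_edges <- flat(test_idx)
  if (nrow(test_edges)) {
    lo <- pmin(test_edges$from, test_edges$to)
    hi <- pmax(test_edges$from, test_edges$to)
    test_edges <- unique(data.frame(from = lo, to = hi,
                                    stringsAsFactors = FALSE))
    rownames(test_edges) <- NULL
  } else {
    test_edges <- data.frame(from = character(), to = character(),
                             stringsAsFactors = FALSE)
  }
  list(train_graphs = corpus$graphs[train_idx],
       train = simple_graph(train_edges),
       test_edges = test_edges)
}

#' Write a synthetic corpus to a directory
#'
#' Plain-text layout: `annotations.tsv` (five columns plus `year`) and one
#' JSON graph document per statement under `graphs/`.
#'
#' @param corpus `synthetic_corpus`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(file.path(dir, "graphs"), recursive = TRUE, showWarnings = FALSE)
  tbl <- corpus$records
  tbl$entities <- vapply(tbl$entities, paste, character(1), collapse = "; ")
  utils::write.table(tbl, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  for (i in seq_along(corpus$graphs))
    graph_to_json(corpus$graphs[[i]],
                  file.path(dir, "graphs", sprintf("%05d.json", i)))
  invisible(dir)
}

#' Read a corpus directory written by [write_corpus()]
#' @param dir corpus directory.
#' @return list with `records`, `graphs`, `years` (compatible with
#'   [split_timeslice()] and [corpus_distribution()]).
#' @export
read_corpus <- function(dir) {
  tbl_path <- file.path(dir, "annotations.tsv")
  if (!file.exists(tbl_path)) stop("no annotations.tsv under ", dir)
  tbl <- utils::read.table(tbl_path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           encoding = "UTF-8", comment.char = "")
  tbl$pmid <- as.character(tbl$pmid)
  tbl$entities <- strsplit(as.character(tbl$entities), "; ", fixed = TRUE)
  files <- sort(list.files(file.path(dir, "graphs"), pattern = "\\.json$",
                           full.names = TRUE))
  graphs <- lapply(files, graph_from_json)
  list(records = tbl, graphs = graphs,
       years = as.integer(tbl$year))
}
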