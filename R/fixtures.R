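# Worked-example fixtures: the discovery statements discussed in the source
# articles (blood-test biomarker panel, plasma NfL comparison, semorinemab,
# AD risk loci, amyloid-load imaging, p-tau181, tau-filament binding sites,
# ApoE/MHC-I neurodegeneration) and the BioNLP 2009 nested-event sentence,
# each as a machine-readable graph with role tags and an annotation record.

GREEK_BETA <- "\u03b2"

fixture <- function(name, pmid, figure, variant, graph, expected = character(),
                    article = NA_character_, statement = NA_character_) {
  ents <- names(graph$entities)[vapply(graph$entities, function(e)
    e$kind == "SIMPLE", logical(1))]
  list(name = name, pmid = pmid, figure = figure, variant = variant,
       graph = graph, expected_limitations = expected,
       record = list(pmid = pmid, article = article, statement = statement,
                     entities = sort(ents),
                     representation = serialize_notation(graph)))
}

sid <- function(g, s, p, o, directed = TRUE) find_statement(g, s, p, o, directed)

#' Build the packaged worked-example fixtures
#'
#' Machine-readable encodings of the worked discovery statements: for most, a
#' pairwise-only ("simple") variant and an enriched ("complex") variant with
#' nested entities, hyperedges and role tags. Every fixture graph validates;
#' each complex fixture carries the limitation type(s) its structure encodes
#' in `$expected_limitations`.
#'
#' @return named list of fixtures; each is a list with `name`, `pmid`,
#'   `figure`, `variant` (`"simple"` or `"complex"`), `graph`,
#'   `expected_limitations`, and a five-field annotation `record` whose
#'   `representation` is the graph's canonical notation.
#' @export
build_worked_examples <- function() {
  fx <- list()
  add <- function(f) { fx[[f$name]] <<- f; invisible(NULL) }
  B <- GREEK_BETA

  ## ApoE / MHC-I neurodegeneration statement: co-occurrence vs semantic view
  st1 <- paste("Neuronal ApoE upregulates MHC-I expression to drive selective",
               "neurodegeneration in Alzheimer's disease")
  g <- discovery_graph("33958804", st1)
  g <- add_statement(g, "Neuronal ApoE", "cooccurs_with", "MHC-I expression",
                     directed = FALSE)
  g <- add_statement(g, "MHC-I expression", "cooccurs_with",
                     "selective neurodegeneration", directed = FALSE)
  g <- add_statement(g, "selective neurodegeneration", "cooccurs_with",
                     "Alzheimer's disease", directed = FALSE)
  add(fixture("apoe_cooccurrence", "33958804", "knowledge-graph example",
              "simple", g, article = "Neuronal ApoE and MHC-I in AD",
              statement = st1))

  g <- discovery_graph("33958804", st1)
  g <- add_statement(g, "Neuronal ApoE", "upregulate", "MHC-I expression")
  g <- add_statement(g, "MHC-I expression", "drive",
                     "selective neurodegeneration")
  g <- add_statement(g, "selective neurodegeneration", "in",
                     "Alzheimer's disease")
  add(fixture("apoe_semantic", "33958804", "knowledge-graph example",
              "simple", g, article = "Neuronal ApoE and MHC-I in AD",
              statement = st1))

  ## blood-based diagnostic test built from three biomarkers
  biomarkers <- c(paste0("plasma A", B, "42/40 ratio"), "ApoE proteotype",
                  "age")
  st2 <- paste0("A blood-based diagnostic test incorporating plasma A", B,
                "42/40 ratio, ApoE proteotype and age identifies brain ",
                "amyloid status")
  g <- discovery_graph("33933117", st2)
  for (b in biomarkers)
    g <- add_hyperedge(g, c("a blood-based diagnostic test", b))
  add(fixture("bloodtest_simple", "33933117", "higher-order interaction",
              "simple", g, article = "Blood-based biomarker panel for amyloid",
              statement = st2))

  g <- discovery_graph("33933117", st2)
  g <- add_hyperedge(g, biomarkers)
  g <- reify_hyperedge(g, find_hyperedge(g, biomarkers))
  hd <- handle_for(g, find_hyperedge(g, biomarkers))
  g <- add_statement(g, hd, "is_a", "a blood-based diagnostic test")
  add(fixture("bloodtest_complex", "33933117", "higher-order interaction",
              "complex", g, expected = "MULTI_ENTITY_INTERACTION",
              article = "Blood-based biomarker panel for amyloid",
              statement = st2))

  ## familial AD mutations in APP alter proteolysis
  st3 <- paste("Familial Alzheimer's disease mutations in amyloid protein",
               "precursor alter proteolysis")
  g <- discovery_graph("33450230", st3)
  g <- add_statement(g, "Familial Alzheimer's disease mutations", "in",
                     "amyloid protein precursor")
  g <- add_statement(g, "amyloid protein precursor", "alter", "proteolysis")
  add(fixture("app_mutation_simple", "33450230", "nested-relationship example",
              "simple", g, article = "APP mutations and proteolysis",
              statement = st3))

  g <- discovery_graph("33450230", st3)
  g <- add_statement(g, "Familial Alzheimer's disease mutations", "in",
                     "amyloid protein precursor")
  g <- group_as_nested(g, sid(g, "Familial Alzheimer's disease mutations",
                              "in", "amyloid protein precursor"), "PROCESS")
  owner <- find_nested(g, sid(g, "Familial Alzheimer's disease mutations",
                              "in", "amyloid protein precursor"))
  g <- add_statement(g, owner, "alter", "proteolysis")
  add(fixture("app_mutation_complex", "33450230",
              "nested-relationship example", "complex", g,
              article = "APP mutations and proteolysis", statement = st3))

  ## plasma NfL vs plasma t-tau under four diagnostic contexts
  contexts <- c("diagnosis of FTLD-S", "diagnosis of AD-S",
                "prediction of clinical progression of FTLD-S",
                "prediction of clinical progression of AD-S")
  st5 <- paste("Plasma NfL is superior to plasma t-tau for diagnosis and",
               "prediction of clinical progression of FTLD-S and AD-S")
  g <- discovery_graph(NA_character_, st5)
  for (ctx in contexts) {
    g <- add_statement(g, "plasma NfL", "for", ctx)
    g <- add_statement(g, "plasma t-tau", "for", ctx)
  }
  add(fixture("nfl_simple", NA_character_, "specific context as a constraint",
              "simple", g, article = "Plasma NfL vs t-tau biomarker comparison",
              statement = st5))

  g <- discovery_graph(NA_character_, st5)
  g <- add_statement(g, "plasma NfL", "is superior to", "plasma t-tau")
  g <- group_as_nested(g, sid(g, "plasma NfL", "is superior to",
                              "plasma t-tau"), "FINDING")
  owner <- find_nested(g, sid(g, "plasma NfL", "is superior to",
                              "plasma t-tau"))
  for (ctx in contexts) {
    g <- add_entity(g, ctx, role_tags = "CONTEXT")
    g <- add_statement(g, owner, "for", ctx)
  }
  add(fixture("nfl_complex", NA_character_,
              "specific context as a constraint", "complex", g,
              expected = "SPECIFIC_CONTEXT",
              article = "Plasma NfL vs t-tau biomarker comparison",
              statement = st5))

  ## semorinemab findings in two experimental models
  st6 <- paste("Antibody semorinemab reduces tau pathology in a transgenic",
               "mouse model and engages tau in patients with Alzheimer's",
               "disease")
  g <- discovery_graph("33980574", st6)
  g <- add_statement(g, "antibody semorinemab", "reduce", "tau pathology")
  g <- add_statement(g, "tau pathology", "in", "a transgenic mouse model")
  g <- add_statement(g, "antibody semorinemab", "engage", "tau")
  g <- add_statement(g, "tau", "in", "patients with Alzheimer's disease")
  add(fixture("semorinemab_simple", "33980574",
              "experimental model as a constraint", "simple", g,
              article = "Semorinemab tau antibody study", statement = st6))

  g <- discovery_graph("33980574", st6)
  g <- add_statement(g, "antibody semorinemab", "reduce", "tau pathology")
  g <- group_as_nested(g, sid(g, "antibody semorinemab", "reduce",
                              "tau pathology"), "FINDING")
  f1 <- find_nested(g, sid(g, "antibody semorinemab", "reduce",
                           "tau pathology"))
  g <- add_entity(g, "a transgenic mouse model",
                  role_tags = "EXPERIMENTAL_MODEL")
  g <- add_statement(g, f1, "in", "a transgenic mouse model")
  g <- add_statement(g, "antibody semorinemab", "engage", "tau")
  g <- group_as_nested(g, sid(g, "antibody semorinemab", "engage", "tau"),
                       "FINDING")
  f2 <- find_nested(g, sid(g, "antibody semorinemab", "engage", "tau"))
  g <- add_entity(g, "patients with Alzheimer's disease",
                  role_tags = "EXPERIMENTAL_MODEL")
  g <- add_statement(g, f2, "in", "patients with Alzheimer's disease")
  add(fixture("semorinemab_complex", "33980574",
              "experimental model as a constraint", "complex", g,
              expected = "EXPERIMENTAL_MODEL",
              article = "Semorinemab tau antibody study", statement = st6))

  ## genome-wide meta-analysis identifying risk loci near four genes
  genes <- c("CCDC6", "TSPAN14", "NCK2", "SPRED2")
  st7 <- paste("Genome-wide AD meta-analysis identifies risk loci including",
               "new associations near CCDC6, TSPAN14, NCK2 and SPRED2")
  g <- discovery_graph("33589840", st7)
  g <- add_entity(g, "genome-wide AD meta-analysis", role_tags = "METHOD")
  g <- add_statement(g, "genome-wide AD meta-analysis", "identify",
                     "risk loci")
  for (gene in genes) g <- add_entity(g, gene)
  add(fixture("riskloci_simple", "33589840", "use of a method", "simple", g,
              article = "Genome-wide AD meta-analysis",
              statement = st7))

  g <- discovery_graph("33589840", st7)
  sids <- character()
  for (gene in genes) {
    g <- add_statement(g, "risk loci", "include", gene)
    sids <- c(sids, sid(g, "risk loci", "include", gene))
  }
  g <- group_as_nested(g, sids, "FINDING")
  owner <- find_nested(g, sids)
  g <- add_entity(g, "genome-wide AD meta-analysis", role_tags = "METHOD")
  g <- add_statement(g, "genome-wide AD meta-analysis", "identify", owner)
  add(fixture("riskloci_complex", "33589840", "use of a method", "complex", g,
              expected = "USE_OF_METHOD",
              article = "Genome-wide AD meta-analysis", statement = st7))

  ## PET measurement of longitudinal amyloid load
  st8 <- paste("PET measurement of longitudinal amyloid load identifies",
               "patients with Down syndrome at risk for Alzheimer's disease")
  g <- discovery_graph("33421595", st8)
  g <- add_entity(g, "longitudinal", role_tags = "MODIFIER")
  g <- add_statement(g, "longitudinal", "modify", "amyloid load")
  g <- add_entity(g, "PET measurement", role_tags = "METHOD")
  g <- add_statement(g, "PET measurement", "of", "amyloid load")
  add(fixture("amyloidload_simple", "33421595",
              "mechanism from a modified entity", "simple", g,
              article = "Longitudinal amyloid PET in Down syndrome",
              statement = st8))

  g <- discovery_graph("33421595", st8)
  g <- add_entity(g, "longitudinal", role_tags = "MODIFIER")
  g <- add_statement(g, "longitudinal", "modify", "amyloid load")
  g <- group_as_nested(g, sid(g, "longitudinal", "modify", "amyloid load"),
                       "PROCESS")
  proc <- find_nested(g, sid(g, "longitudinal", "modify", "amyloid load"))
  g <- add_entity(g, "PET measurement", role_tags = "METHOD")
  g <- add_statement(g, "PET measurement", "of", proc)
  g <- group_as_nested(g, sid(g, "PET measurement", "of", proc), "FINDING")
  meas <- find_nested(g, sid(g, "PET measurement", "of", proc))
  g <- add_statement(g, meas, "identify",
                     "patients with Down syndrome at risk for Alzheimer's disease")
  add(fixture("amyloidload_complex", "33421595",
              "mechanism from a modified entity", "complex", g,
              expected = c("MECHANISM_FROM_MODIFIED", "USE_OF_METHOD"),
              article = "Longitudinal amyloid PET in Down syndrome",
              statement = st8))

  ## plasma p-tau181 increase and widespread cortical amyloid-beta pathology
  path_lbl <- paste0("cortical amyloid-", B, " pathology")
  st9 <- paste0("Plasma p-tau181 increase is associated with widespread ",
                "cortical amyloid-", B, " pathology")
  g <- discovery_graph("33257949", st9)
  g <- add_entity(g, "widespread", role_tags = "MODIFIER")
  g <- add_statement(g, "widespread", "modify", path_lbl)
  g <- add_statement(g, "plasma p-tau181 increase", "associate with", path_lbl)
  add(fixture("ptau_simple", "33257949", "modifier granularity", "simple", g,
              article = "Plasma p-tau181 and amyloid pathology",
              statement = st9))

  g <- discovery_graph("33257949", st9)
  g <- add_entity(g, "widespread", role_tags = "MODIFIER")
  g <- add_statement(g, "widespread", "modify", path_lbl)
  g <- group_as_nested(g, sid(g, "widespread", "modify", path_lbl), "PLAIN")
  granular <- find_nested(g, sid(g, "widespread", "modify", path_lbl))
  g <- add_entity(g, "increase", role_tags = "MODIFIER")
  g <- add_statement(g, "increase", "modify", "plasma p-tau181")
  g <- group_as_nested(g, sid(g, "increase", "modify", "plasma p-tau181"),
                       "PROCESS")
  proc <- find_nested(g, sid(g, "increase", "modify", "plasma p-tau181"))
  g <- add_statement(g, proc, "associate with", granular)
  add(fixture("ptau_complex", "33257949", "modifier granularity", "complex", g,
              expected = c("MECHANISM_FROM_MODIFIED", "MODIFIER_GRANULARITY"),
              article = "Plasma p-tau181 and amyloid pathology",
              statement = st9))

  ## three tau-filament binding sites behind a general concept
  sites <- c(paste0(B, "-helix of PHFs"), paste0(B, "-helix of SFs"),
             "C-shaped cavity of SFs")
  st10 <- paste("Electron cryo-microscopy determines binding sites of",
                "APN-1607 in the Alzheimer fold: the", B, "-helix of PHFs,",
                "the", B, "-helix of SFs, and the C-shaped cavity of SFs")
  g <- discovery_graph("33723967", st10)
  for (s in sites) g <- add_statement(g, s, "is_a", "binding sites")
  g <- add_entity(g, "electron cryo-microscopy", role_tags = "METHOD")
  g <- add_statement(g, "electron cryo-microscopy", "determine",
                     "binding sites")
  add(fixture("bindingsites_simple", "33723967",
              "lack of context for a general concept", "simple", g,
              article = "Tau filament ligand binding sites",
              statement = st10))

  g <- discovery_graph("33723967", st10)
  for (s in sites) g <- add_entity(g, s, role_tags = "CONTEXT")
  g <- add_hyperedge(g, sites)
  g <- reify_hyperedge(g, find_hyperedge(g, sites))
  hd <- handle_for(g, find_hyperedge(g, sites))
  g <- add_entity(g, "binding sites", role_tags = "GENERAL_CONCEPT")
  g <- add_statement(g, hd, "is_a", "binding sites")
  g <- add_entity(g, "electron cryo-microscopy", role_tags = "METHOD")
  g <- add_statement(g, "electron cryo-microscopy", "determine",
                     "binding sites")
  add(fixture("bindingsites_complex", "33723967",
              "lack of context for a general concept", "complex", g,
              expected = "GENERAL_CONCEPT_CONTEXT",
              article = "Tau filament ligand binding sites",
              statement = st10))

  ## biomarker panel with the downstream outcome link
  g <- discovery_graph("33933117", st2)
  for (b in biomarkers)
    g <- add_statement(g, b, "incorporate into", "a blood-based diagnostic test")
  g <- add_statement(g, "a blood-based diagnostic test", "identify",
                     "brain amyloid status")
  add(fixture("panel_simple", "33933117",
              "more than two entities interacting together", "simple", g,
              article = "Blood-based biomarker panel for amyloid",
              statement = st2))

  g <- discovery_graph("33933117", st2)
  g <- add_hyperedge(g, biomarkers)
  g <- reify_hyperedge(g, find_hyperedge(g, biomarkers))
  hd <- handle_for(g, find_hyperedge(g, biomarkers))
  g <- add_statement(g, hd, "is_a", "a blood-based diagnostic test")
  g <- add_statement(g, "a blood-based diagnostic test", "identify",
                     "brain amyloid status")
  add(fixture("panel_complex", "33933117",
              "more than two entities interacting together", "complex", g,
              expected = "MULTI_ENTITY_INTERACTION",
              article = "Blood-based biomarker panel for amyloid",
              statement = st2))

  ## BioNLP 2009 nested regulation events
  stb <- "SQ 22536 suppressed gp41-induced IL-10 production in monocytes."
  g <- discovery_graph("BioNLP2009", stb)
  g <- add_statement(g, "production", "of", "IL-10")        # Gene_expression
  g <- group_as_nested(g, sid(g, "production", "of", "IL-10"), "PROCESS")
  e3 <- find_nested(g, sid(g, "production", "of", "IL-10"))
  g <- add_statement(g, "gp41", "positively regulate", e3)  # Positive_Regulation
  g <- group_as_nested(g, sid(g, "gp41", "positively regulate", e3), "PROCESS")
  e2 <- find_nested(g, sid(g, "gp41", "positively regulate", e3))
  g <- add_statement(g, "SQ 22536", "negatively regulate", e2) # Negative_Regulation
  add(fixture("bionlp_events", "BioNLP2009", "nested biomedical events",
              "complex", g, article = "BioNLP 2009 shared-task sentence",
              statement = stb))

  fx
}

#' Fixture graphs only
#' @param fixtures output of [build_worked_examples()] (built when missing).
#' @param variant optional filter: `"simple"` or `"complex"`.
#' @return named list of discovery graphs.
#' @export
worked_example_graphs <- function(fixtures = build_worked_examples(),
                                  variant = NULL) {
  if (!is.null(variant))
    fixtures <- Filter(function(f) f$variant == variant, fixtures)
  lapply(fixtures, `[[`, "graph")
}

#' Fixture annotation table
#' @param fixtures output of [build_worked_examples()].
#' @return five-column annotation data.frame (one row per fixture).
#' @export
worked_example_table <- function(fixtures = build_worked_examples()) {
  rows <- lapply(fixtures, function(f) data.frame(
    pmid = f$record$pmid, article = f$record$article,
    statement = f$record$statement,
    entities = paste(f$record$entities, collapse = "; "),
    representation = f$record$representation, stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$entities <- strsplit(out$entities, "; ", fixed = TRUE)
  rownames(out) <- NULL
  out
}

#' Worked impact-audit scenarios
#'
#' Three inference case studies: a hypothesis inferred against a bare general
#' concept (binding sites without their three filament-site contexts), a
#' hypothesis inferred from a single member of a three-biomarker panel, and a
#' hypothesis whose explanation path drops the modifier "widespread". Each
#' scenario pairs a prediction made on the flattened graph with the enriched
#' graph the audit reads.
#'
#' @param fixtures output of [build_worked_examples()].
#' @return named list of scenarios: `prediction`, `complex` (graph),
#'   `expected` impact type.
#' @export
worked_impact_scenarios <- function(fixtures = build_worked_examples()) {
  B <- GREEK_BETA
  list(
    infeasible = list(
      prediction = prediction_result(
        c("new PET ligands with increased specificity and binding activity",
          "binding sites"), score = 1, rank = 1L),
      complex = fixtures$bindingsites_complex$graph,
      expected = "EXPERIMENTALLY_INFEASIBLE"),
    inconsistent = list(
      prediction = prediction_result(
        c("participants for Alzheimer's disease drug trials",
          "ApoE proteotype"), score = 1, rank = 1L),
      complex = fixtures$panel_complex$graph,
      expected = "LITERATURE_INCONSISTENT"),
    oversimplified = list(
      prediction = prediction_result(
        c("a diagnostic and screening tool for Alzheimer's disease",
          "plasma p-tau181"), score = 1, rank = 1L,
        explanation = c(
          "a diagnostic and screening tool for Alzheimer's disease",
          "plasma p-tau181", paste0("cortical amyloid-", B, " pathology"))),
      complex = fixtures$ptau_complex$graph,
      expected = "OVERSIMPLIFIED_EXPLANATION")
  )
}
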