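---
title: "Enriched knowledge representation for literature-based discovery: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enriched knowledge representation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypernest)
```

## The representation model

A *discovery graph* holds one discovery statement's knowledge in four layers:

1. **Pairwise statements.** Directed `subject::predicate::object` triples and
   undirected co-occurrences. Co-occurrence edges are undirected by design and
   are constrained to the `cooccurs_with` predicate; an undirected edge with
   any other predicate is flagged by `validate_graph()` rather than silently
   re-labelled, because direction loss on a semantic predicate is an error
   worth surfacing.
2. **Nested entities.** A set of statements grouped into a unit that can
   itself stand in subject or object role (a finding linked to its contexts,
   a method linked to a composite result). Grouping never removes the inner
   statements: the pairwise layer is preserved, so the edge count after
   `group_as_nested()` is always ≥ the count before. Containment may recurse
   (events within events) but must stay acyclic; `validate_graph()` proves
   the DAG property on every graph it accepts.
3. **Hyperedges.** Relations over arbitrary entity sets with |e| ≥ 2. A
   2-member hyperedge is the degenerate case equivalent to an undirected
   pairwise link, and the component classifier treats it as pairwise — only
   ≥ 3-member hyperedges (or reified handles) demand hypergraph machinery.
4. **Reified handles.** To let a collective relation participate in further
   statements, a hyperedge can be *reified* as a handle node bound
   one-to-one to it. Reification was chosen over named graphs as the
   concrete mechanism because it keeps everything inside one node/edge
   vocabulary; named graphs would be a reasonable alternative
   implementation of the same semantics, and the JSON interchange format
   would accommodate either. `reify_hyperedge()`/`dereify_handle()` are
   exact inverses on the member set; dereification refuses while the handle
   still participates in statements, because removing it then would drop
   knowledge.

**Entity identity.** Entities are surface terms, not ontology identifiers
(identifier normalization such as mapping a term to a MeSH or ChEBI id is out
of scope). Two mentions are the same node iff their labels agree after
Unicode NFC normalization and whitespace collapse, case preserved. The
normalized label doubles as the node id, which keeps notation, JSON and graph
structure trivially aligned.

**Role tags.** The limitation taxonomy below distinguishes groupings
*semantically* — a context is not an experimental model is not a method —
and structure alone cannot make those distinctions. Each entity therefore
carries zero or more tags from a closed 8-value vocabulary (`FINDING`,
`CONTEXT`, `EXPERIMENTAL_MODEL`, `METHOD`, `MODIFIER`, `GENERAL_CONCEPT`,
`PROCESS`, `PLAIN`). Annotated corpora are expected to carry tags; a nested
grouping without any tag yields a warning and no limitation label rather
than a guessed one.

## Notation

The statement notation extends the plain triple format with the smallest
grammar that covers the worked structures:

```
document  :=  line (";" line)*           (newlines also separate)
line      :=  statement | term
statement :=  term "::" predicate "::" term  |  term "<->" term
term      :=  label
           |  "[" statement (";" statement)* "]" "{" ROLE "}"
           |  "{" label ("|" label)* "}"
```

A hyperedge used in entity position is reified on the spot; a bare
hyperedge line declares it unreified. Serialization is canonical
(statements sorted by rendered subject, predicate, object; hyperedge
members sorted), so serialize ∘ parse ∘ serialize = serialize, and
`parse_notation(serialize_notation(g))` is structurally equal to `g`. Two
caveats are deliberate: custom handle labels are not part of the notation
(handles render as their member set), and role tags on *plain* entities are
carried by annotation tables and the JSON interchange, not by notation —
`graph_equal()` therefore compares tags only on request. The BEL-style
renderer (`render_bel()`) is output-only and illustrative; it makes no
attempt at namespace identifiers or full grammar compliance.

## Transforms

`flatten_atomic()` projects a complex graph onto its atomic pairwise layer
without losing any pairwise statement: statements inside nested bodies are
emitted as-is, edges incident to a nested owner fan out to *every* body
entity, and a statement anchored on a reified handle pairs the anchor with
each hyperedge member (the anchor-star reading of the pairwise projection).
The member–member alternative is available as `clique_expansion()`; both
are exposed because they answer different questions (what does the
collective relate to, versus which members co-participate). The fan-out
choice for nested owners — all body entities rather than only the body's
head subject — is the permissive reading: it keeps every atomic pair
reachable for downstream link prediction at the cost of some spurious
pairs, and it is flagged here because the opposite choice is defensible.

The three standard hypergraph expansions are implemented over a *hypergraph
view* that includes pairwise statements as implicit 2-member edges (a
simple graph being the 2-uniform special case): clique expansion (all
member pairs, duplicates merged with merged provenance), star expansion
(bipartite incidence graph, one edge per membership), and the line graph
(hyperedges adjacent iff their member sets intersect). Every produced edge
and node carries provenance back to its originating hyperedges; tests check
all three against independent brute-force enumerations on random
hypergraphs of up to 8 nodes and 5 hyperedges.

## Diagnostics

`component_class()` assigns exactly one of `P`, `PN`, `PH`, `PNH`: nesting
sets the N bit, a ≥ 3-member hyperedge or handle sets the H bit. `PH`
(hypergraphs without nesting) is retained for exhaustiveness even though
realistic corpora may leave it empty.

`limitation_types()` applies a structural rule table for the seven ways a
pairwise-only graph loses information:

| Type | Structural trigger |
|---|---|
| `SPECIFIC_CONTEXT` | `FINDING`-tagged nested entity linked to a `CONTEXT`-tagged node |
| `EXPERIMENTAL_MODEL` | `FINDING`-tagged nested entity linked via `in` to an `EXPERIMENTAL_MODEL` node |
| `USE_OF_METHOD` | `METHOD`-tagged node with a nested object |
| `MECHANISM_FROM_MODIFIED` | nested entity grouping a `MODIFIER`-tagged entity, owner tagged `PROCESS` |
| `MODIFIER_GRANULARITY` | the same grouping with a non-`PROCESS` owner |
| `GENERAL_CONCEPT_CONTEXT` | handle linked `is_a` to a `GENERAL_CONCEPT`-tagged node |
| `MULTI_ENTITY_INTERACTION` | ≥ 3-member reified hyperedge whose handle carries any other anchored relation |

One rule needed a design decision: the worked multi-entity example anchors
its handle with `is_a` too, so "any non-`is_a` anchored relation" cannot be
the discriminator between the two hypergraph-backed types. The
discriminator used here is the *target*: an `is_a` link into a
`GENERAL_CONCEPT`-tagged node marks contexts supplied for an
under-specified concept, any other anchored relation marks a collective
interaction. Both worked examples then classify as documented. Whether a
taxonomic link other than `is_a` should also count for the general-concept
rule is left conservative (only `is_a` counts), matching the worked
example.

`corpus_distribution()` counts classes at statement level (each statement in
exactly one class; counts sum to the corpus size) and limitation types at
article level — a type is counted once per PMID, and one article may carry
several types, so limitation counts may exceed the article count.

## Inference

Link prediction uses Common Neighbors, with direction ignored for
neighborhoods (co-occurrence layers are undirected; predicate direction is
preserved only in explanations). `abc_candidates()` implements open
discovery: candidates are non-neighbors of the source at distance 2, ranked
by shared-intermediate support, ties broken by label so the order is a
deterministic total order with contiguous ranks. The candidate universe for
`predict_links()` is non-adjacent pairs within the same connected component —
a desk-scale default, since cross-component pairs have CN = 0 anyway —
liftable with `all_pairs = TRUE`.

`hyper_cn()` generalizes CN to hyperlink candidates as the mean of pairwise
CN over all member pairs, computed on a chosen expansion. The expansion on
which those pairwise indices are computed is not canonically fixed anywhere;
the default here is the clique expansion (the least structured choice, and
the one on which size-2 candidates reduce exactly to classic CN), with star
and line exposed. Resource-allocation and embedding-based hyperlink
predictors are out of scope.

`impact_audit()` re-reads a prediction made on the flattened graph against
the enriched graph and assigns at most one of three severities, each with a
fixed feasibility/success/granularity flag pattern: an endpoint that is a
`GENERAL_CONCEPT` whose contexts live in a hyperedge (infeasible, ✗✗✗); an
endpoint that is an individual member of a ≥ 3-member collective whose
handle carries the outcome link (literature-inconsistent, ✓✗✗); an
explanation path traversing a modifier-nested entity (oversimplified
explanation, ✓✓✗). The checks run in severity order and the first match
wins; a prediction with no candidate provenance cannot be audited and
raises an error rather than returning a silent "none".

`timeslice_eval()` scores candidates on a training graph and reports the
fraction of the top-k present in a later year's edge set. If k exceeds the
candidate count the evaluation proceeds at the candidate count with a
warning.

## The synthetic corpus generator

`generate_corpus()` emulates an annotated discovery-statement corpus: each
statement is drawn from a planted mixture over `(P, PN, PNH)` — default
`(0.20, 0.73, 0.07)`, the documented composition of the annotated corpus
this package's diagnostics were designed around — with year stamps uniform
over 1977–2021 (the span of that corpus; no per-year counts are documented,
so uniform is the neutral choice). `P` statements are 1–3 plain triples;
`PN` statements add a `FINDING`-nested group decorated uniformly at random
with a context, model, method, or modifier grouping; `PNH` statements
additionally plant a reified 3–4-member hyperedge. Entity labels come from
role-specific vocabularies (`BIOMARKER_07`, `CONTEXT_03`, ...), so the role
tags are self-evident and no real terminology is imitated. `exact = TRUE`
plants `round(n × mixture)` statements per class (largest-remainder
apportionment) for reproducing a printed composition exactly, as the
acceptance checks do for the 56-statement stand-in (11 / 41 / 4).

What the generator does *not* emulate matters for interpreting green tests:
there is no natural-language text, no entity-recognition noise, no
multi-statement articles, no correlation between years and structures, and
no temporal signal linking training-year to test-year edges. Passing tests
therefore demonstrate that the representation, classification and
evaluation machinery are correct, not that Common Neighbors predicts real
2021 links — on this corpus CN precision is expected at (and lands near)
the test-edge density baseline, which the acceptance script reports
alongside an oracle-scorer check of the evaluation machinery itself.

## Numerical and procedural choices

* All randomness flows through explicit seeds (generator default 17); the
  generator is byte-identical across runs at a fixed seed, and every CLI
  subcommand is idempotent given identical inputs and seed.
* Ties in every ranking are broken lexicographically by label; ranks are
  contiguous from 1.
* Duplicate edges from expansions are merged under canonical (sorted)
  endpoint order, with provenance unioned.
* Statistical test tolerances: planted-mixture recovery is asserted within
  3 multinomial standard errors per class (n = 1000, 20 seeds); the
  random-scorer precision check uses 3 binomial standard errors.
* Problem sizes in the test suite — random graphs ≤ 10 nodes, hypergraphs
  ≤ 8 nodes / 5 hyperedges, corpora of 56–1000 statements — were chosen so
  the brute-force oracles stay exact and the whole suite runs in about a
  minute.
* Degenerate inputs: empty notation is a position-0 syntax error; empty
  nested bodies and singleton hyperlink candidates are errors; an empty
  test-year slice is a warning with an empty edge set; an empty corpus is
  an error for distribution reports.

## Known limitations

* Whether a nested entity may span multiple sentences of an abstract is
  unconstrained here; the worked examples are single-statement, and the
  model itself is agnostic.
* The deposited annotation spreadsheet's exact column headers are not
  fixed; `read_annotation_table()` takes a `header_map` so any five-column
  layout can be ingested.
* Limitation typing classifies *structures*, not prose: a corpus without
  role tags will classify components correctly but yields no limitation
  labels (with warnings), by design.
* Corpus-level reproduction of the original annotated collection requires
  that collection to be present locally as an annotation table; the package
  ships a synthetic stand-in generator instead of the data.
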