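# hypernest

Enriched knowledge representation for literature-based discovery (LBD).

## The problem

LBD systems infer new biomedical hypotheses from published findings using
Swanson's ABC model: if the literature states that A relates to B and,
elsewhere, that B relates to C, the transitive closure A–C is a candidate
discovery (the classic example being dietary fish oil and Raynaud's
Syndrome, connected through shared blood-parameter intermediates). Modern
systems automate this over *knowledge graphs* whose building block is the
pairwise relationship — an undirected co-occurrence or a directed semantic
triple between two entities.

Many biomedical discovery statements do not fit in entity pairs. A finding
such as *plasma NfL is superior to plasma t-tau* is itself the subject of
further relations (it holds *for* four diagnostic contexts); a blood-based
diagnostic test is the *combination* of three biomarkers, not any one of
them; a general concept like *binding sites* is meaningless without its
specific contexts. Flattening these statements to entity pairs loses
information, and the loss propagates into inference: hypotheses can become
experimentally infeasible, inconsistent with the literature they came from,
or stripped of the modifiers that made their explanation meaningful.

`hypernest` implements an enriched representation and the tooling around it:

* **Data model** — entities, directed/undirected pairwise statements,
  *nested entities* (a grouped subgraph promoted to subject/object role,
  preserving its internal pairwise relations), *hyperedges* (relations over
  arbitrary entity sets, |e| ≥ 2), and *reified handles* that let a
  hyperedge participate in statements as a node.
* **Notation** — an extension of the `subject::predicate::object` format:
  `a <-> b` for co-occurrences, `[ ... ]{ROLE}` for nested groups,
  `{m1 | m2 | ...}` for hyperedges; plus a JSON interchange format,
  five-column annotation tables, and an illustrative BEL-style rendering.
* **Transforms** — lossless flattening to the atomic pairwise layer, and
  the clique, star and line-graph hypergraph expansions.
* **Diagnostics** — classification of each statement by required
  representation components (`P`, `PN`, `PH`, `PNH`) and by seven
  limitation types of pairwise-only representation; corpus-level
  distribution reports.
* **Inference** — Common Neighbors `|N(u) ∩ N(v)|`, ABC open discovery
  (distance-2 candidates ranked by shared-intermediate support), a
  hyperlink generalization of CN (mean pairwise CN over candidate member
  pairs on a chosen expansion), time-sliced precision-at-k evaluation, and
  a three-level impact audit of predictions against the enriched graph
  (experimentally infeasible / literature-inconsistent / oversimplified
  explanation).
* **Fixtures & simulation** — worked examples as machine-readable graphs,
  and a synthetic corpus generator with planted component mixtures.

## Worked example

```r
library(hypernest)

g <- parse_notation(
  "[ plasma NfL::is superior to::plasma t-tau ]{FINDING}::for::diagnosis of AD-S")
g
#> <discovery_graph> pmid=?: 4 entities, 2 statements, 0 hyperedges, 0 handles, 1 nested
```

The bracketed finding became a nested entity usable in subject role. The
inner comparison is still a first-class statement, and flattening recovers
every atomic pairwise relationship — including `plasma NfL for diagnosis
of AD-S`, which the nesting never overwrote:

```r
flatten_atomic(g)$edges
#>           from                to      predicate directed
#> 1   plasma NfL diagnosis of AD-S            for     TRUE
#> 2   plasma NfL      plasma t-tau is superior to     TRUE
#> 3 plasma t-tau diagnosis of AD-S            for     TRUE
```

Diagnostics over the packaged enriched fixtures enumerate all seven
limitation types and the component classes:

```r
fx <- build_worked_examples()
corpus_distribution(worked_example_graphs(fx, variant = "complex"))
#> <distribution_report> 10 statements, 9 articles
#> Representation components (statement level):
#>   P       0  (0%)
#>   PN      7  (70%)
#>   PH      3  (30%)
#>   PNH     0  (0%)
#> Pairwise-limitation types (article level):
#>   SPECIFIC_CONTEXT              1
#>   EXPERIMENTAL_MODEL            1
#>   USE_OF_METHOD                 2
#>   MECHANISM_FROM_MODIFIED       2
#>   MODIFIER_GRANULARITY          1
#>   GENERAL_CONCEPT_CONTEXT       1
#>   MULTI_ENTITY_INTERACTION      1
```

ABC open discovery on the fish-oil toy graph ranks the expected target
first, supported by the three shared intermediates:

```r
b <- c("blood viscosity", "platelet aggregability", "vascular reactivity")
toy <- simple_graph(rbind(data.frame(from = "fish oil", to = b),
                          data.frame(from = b, to = "Raynaud's Syndrome")))
abc_candidates(toy, "fish oil")[, c("c", "support", "rank")]
#>                    c support rank
#> 1 Raynaud's Syndrome       3    1
```

## Command line

A thin wrapper over the same functions is installed at
`exec/hypernest`:

```sh
hypernest simulate --n 56 --seed 17 --out corpus/
hypernest diagnose --in corpus/ --out report        # report.json + report.md
hypernest parse    --in statement.txt --out graph.json
hypernest expand   --in graph.json --mode clique --out edges.tsv
hypernest predict  --in graph.json --scorer cn --top 10 --out preds.tsv
hypernest audit    --in preds.tsv --graph graph.json --out audit.json
hypernest evaluate --in corpus/ --test-year 2021 --k 10 --out eval.json
```

Exit codes: 0 success, 2 parse/schema errors, 1 internal errors.

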