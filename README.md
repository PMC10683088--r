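# stratcheck

Verification of rule strategies attached to biomedical ontologies.

Smart healthcare systems drive their decisions with a *strategy*: a set of
inference rules (*statements*) layered on an ontology, each of the form
`premise -> conclusion` where both sides are positive conjunctions of atoms —
class memberships like `Patient(x)`, object/data properties like
`hasFood(x,y)` or `age(x,47)`, and comparison builtins like
`equalOrGreaterThan(i,1.26)`. As a strategy is edited over time it
accumulates anomalies: equivalent or subsumed duplicates, shortcut rules a
chain of others already implies, dependency cycles, contradictory pairs, and
rules that can never fire. `stratcheck` is for the maintainers of such rule
bases: it finds these anomalies, resolves the ones that are safe to resolve
automatically, and saves the rest for expert review.

## Method

Verification runs in two stages.

**Relation extraction.** For every statement pair, two analyses propose a
directed dependency with a confidence degree CD ∈ [0, 1]:

* *conclusion–premise*: the strongest ontology relation between a class
  referenced by one statement's conclusion and a class referenced by the
  other's premise, scored through a weight table with `w(equal) = 1`,
  `w(equivalent) = 0.9`, `w(hierarchy) = 0.7`, `w(none) = 0`;
* *conclusion–conclusion*: declared object properties linking the classes one
  conclusion references to those the other references (direct link 1,
  link via subclass substitution 0.7).

A filter keeps, per pair, the relation maximising `CD_i × c_i` with technique
coefficients `c_CP = 0.5` and `c_CC = 1`. The surviving arcs form the
dependency graph; statements with identical incoming and outgoing arcs are
grouped, and the groups prune all later candidate searches.

**Anomaly resolution**, in phase order: equivalence → subsumption →
transitivity → cycles → conflicts → inaccessible statements → illegal
values. Redundant statements are deleted (keeping the more general phrasing,
so no inferable knowledge is lost); transitive shortcuts are confirmed by
forward-chaining the shortcut against its chain on generated boundary
witnesses; cycles are classified *fake* or *real* by instantiation; strong
conflicts are resolved by policy while probable conflicts — and all cycle
verdicts — persist in an anomalies knowledge base (`anomalies_kb.json`) so
expert decisions survive re-runs.

## Worked example

`inst/extdata/` carries a corpus of small schema/strategy fixtures. Four
phrasings of "a patient eats the ingredients of their food" differ by atom
order, by a sub-property in the premise (`hasLunch < hasFood`), and by a
sub-property in the conclusion (`gets < eats`):

```r
library(stratcheck)
ont      <- load_ontology(system.file("extdata", "food.onto",  package = "stratcheck"))
strategy <- load_strategy(system.file("extdata", "ex4.rules", package = "stratcheck"), ont)

build_graph(strategy, ont)
#> <dependency graph: 4 statements, 6 relations>
#>   S01 -> S02  [CC 1.00]
#>   S01 -> S03  [CC 1.00]
#>   S01 -> S04  [CC 1.00]
#>   S02 -> S03  [CC 1.00]
#>   S02 -> S04  [CC 1.00]
#>   S03 -> S04  [CC 1.00]

run_pipeline(strategy, ont)
#> <verification report: 4 -> 1 statements, 3 finding(s)>
#>   equivalence:
#>     equivalence [S01,S02] deleted:S02
#>     equivalence [S01,S03] deleted:S03
#>     equivalence [S01,S04] deleted:S04
```

All four statements land in one group (their mutual arcs are symmetric
ties), the equivalence phase deletes the reordered duplicate `S02`, the
premise specialisation `S03` and the conclusion specialisation `S04`, and
only the general rule `S01` survives. The per-record `case` field
(`case1`, `case2.1`, `case2.2`) says which equivalence pattern fired.

A command-line wrapper covers the same flow from a shell
(`exec/stratcheck`): `extract` writes DOT/GraphML graphs and a groups JSON,
`check` detects without changing anything (exit 1 when findings exist),
`resolve` writes the cleaned strategy plus a JSON report, `simulate`
generates labelled synthetic cases, `evaluate` scores a report against
ground truth, and `kb` lists the anomalies knowledge base and records
expert verdicts.

## Synthetic evaluation

`generate_case(gen_config(seed))` builds a layered, anomaly-free base
strategy and injects labelled anomalies of every kind (the default emulates
a mid-sized case: 24 base statements, +8 redundant, +4 cycle-forming,
+8 conflicting, +3 inaccessible). `score_detection()` compares the pipeline's
records with the ground truth and reports per-kind precision and recall; on
the default configuration the pipeline removes every injected redundant and
inaccessible statement, detects every injected cycle and conflict, and
deletes no base statement.

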