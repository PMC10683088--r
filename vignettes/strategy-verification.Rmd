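---
title: "Verifying rule strategies attached to biomedical ontologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying rule strategies attached to biomedical ontologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratcheck)
```

## The problem

Clinical decision-support systems attach rule bases — *strategies* — to
ontologies: each *statement* is an implication `premise -> conclusion` whose
sides are positive conjunctions of atoms (class memberships, object/data
properties, comparison builtins). As strategies grow past a few dozen
statements, edits accumulate anomalies: duplicated or subsumed rules,
composed shortcuts, dependency cycles, contradictory pairs, and rules that
can never fire. Each anomaly either wastes inference effort or, worse,
produces wrong clinical recommendations. `stratcheck` verifies a strategy in
two stages: it extracts a confidence-weighted dependency graph between
statements, groups statements by their arcs, and then detects and resolves
anomalies using the groups to prune candidate pairs.

## The dependency graph

For every unordered statement pair, two analyses each propose a directed
relation with a confidence degree (CD) in $[0, 1]$:

* **Conclusion–premise (CP).** The facts one statement infers may be consumed
  by the other's premise. For each atom pair (one conclusion atom, one premise
  atom) the analysis extracts the class sets the atoms reference (a class atom
  references its class, a property atom its domain and range, a builtin
  nothing) and scores the pair by the strongest ontology relation between any
  two referenced classes, through a weight table
  $w(\text{equal}) = 1 > w(\text{equivalent}) = 0.9 > w(\text{hierarchy}) =
  0.7 > w(\text{disjoint}) = w(\text{none}) = 0$. Only the two endpoints of
  that table are externally fixed; the intermediate values are this package's
  strictly-ordered choice and sit in `sc_config()`. The pair CD is the
  maximum over atom pairs, computed in both directions.
* **Conclusion–conclusion (CC).** Two conclusions may describe linked
  objects: the analysis looks for declared object properties whose domain
  matches the classes referenced by one conclusion and whose range matches
  the other's. A property matching by equality/equivalence on both ends
  scores 1; a match that needs a subclass substitution scores the hierarchy
  weight; no link scores 0.

A filtering step multiplies each CD by a technique coefficient —
$c_{CP} = 0.5$, $c_{CC} = 1$, the calibration carried by the method — and
keeps the relation with the larger product (ties prefer CC). Directions are
decided per technique by the larger CD; a CD tie falls back, in order, to the
predicate-level consumption signal (the direction in which a conclusion
predicate literally appears in the other premise), to the other technique's
strictly directional result, and finally to lexicographic statement id. The
last two fallbacks are design choices this package makes where the method
leaves direction underdetermined: without the predicate-consumption and
cross-technique fallbacks, a three-statement loop whose conclusions all
reference the same classes ties in every direction and the cycle can never
appear in the graph. Using ids rather than file position keeps the graph
invariant under reordering of the strategy file.

Statements are then grouped: members of a group must share identical
predecessor and successor sets, where arcs internal to the candidate group
are set aside and a merge is accepted only when every internal arc was a
tie-broken (symmetric-confidence) relation. The tie restriction is what keeps
a genuine chain `S10 -> S11` out of one group while merging the four
interchangeable phrasings of a rule, whose mutual arcs carry no real
direction. Statements with no arcs at all stay singletons — merging unrelated
statements would corrupt every group-based pruning rule downstream.

## Anomaly phases

Phases run in a fixed order — equivalence, subsumption, transitivity, cycles,
conflicts, inaccessible statements, illegal values — recomputing the graph
and groups after every phase that deleted something, and a second run on the
output deletes nothing (idempotence).

**Equivalence** compares pairs within a group for corresponding premises and
conclusions under one shared variable bijection (complete backtracking
search; constants never unify). Identical parts up to atom order delete the
later-declared statement. A hierarchy substitution — in the premise (Case
2.1) or the conclusion (Case 2.2) — deletes the statement whose substituted
atom references the more specific entity. For Case 2.2 the method's prose and
its worked outcome disagree about the victim; the package follows the worked
outcome, which also makes the two cases uniform. The cost is visible in the
knowledge-preservation test: after a Case 2.2 deletion the surviving
statement concludes the more general property, so fact sets before and after
are compared *up to hierarchy* rather than by strict entailment.

**Subsumption** handles the premise-side containment cases: a statement whose
premise properly embeds another's with the same conclusion is deleted
(simple), and each specialisation of a general statement via
sub-properties/subclasses is deleted independently (semantic). Candidates are
pairs within a group plus group pairs with properly nested incoming arcs and
equal outgoing arcs. The semantic case is structurally the same pattern as
equivalence Case 2.1, so in the full pipeline the equivalence phase usually
claims those deletions first; the synthetic scorer accepts either label.

**Transitivity** deletes a statement that a chain of others reproduces.
Candidate chains (length 2–`chain_bound`, default 4 — enumeration is
exponential in this bound and the printed cases need only 2) must match the
candidate group's external arcs, with arcs involving the chain or the group
itself set aside, because the redundancy under test creates exactly those
arcs. The premise-signature condition — the chain's net input (union of
member premises minus what earlier members conclude) equals the candidate's
premise — screens structurally; the decisive check instantiates both on
generated witnesses and compares the derived facts over the conclusion
predicates (the chain legitimately derives intermediates the shortcut does
not).

**Witnesses.** Wherever statements are instantiated (transitivity, cycle
classification, literal saturation), the package generates one fresh
individual per non-numeric variable and, for every comparison threshold $t$,
the numeric probes $t - \varepsilon, t, t + \varepsilon$ with
$\varepsilon = \max(0.01\,|t|, 0.01)$. Boundary probes are what separate a
shortcut with a laxer threshold from its chain; a single generic value would
not.

**Cycles** are enumerated exactly (anchored depth-first search over
elementary cycles, checked in the test suite against an independent
brute-force path-extension enumerator), then classified: the cycle's
statements are instantiated on witnesses (variables shared by name, as the
printed loop example requires) and forward-chained alone with a round budget
of $2|\text{cycle}| + 2$. Reaching the fixpoint inside the budget means the
graph loop does not loop on instances — a *fake* cycle; exhausting the budget
marks it *real*. Both verdicts persist in the anomalies knowledge base, and a
cycle already recorded fake is skipped on later runs. Nothing is deleted
automatically; real cycles are an expert's call.

**Conflicts.** Contradiction between literals means: one variable placed in
declared-disjoint classes; comparison constraints on the same quantity whose
satisfying sets are disjoint — with `strict_boundary = TRUE` (default) the
complementary inclusive pair `GE(t)` vs `LE(t)` also counts, because that is
precisely the printed conflicting pair, although the sets share the boundary
point; or declared-inverse object properties applied to one argument pair.
Within a *single* premise, however, `GE(t)` and `LE(t)` jointly mean
`== t` and are satisfiable, so inaccessibility checking uses pure interval
emptiness. Corresponding premises with contradictory conclusions are a
*strong* conflict, resolved by policy (`delete_added` by default — the
provenance-tagged newer statement goes; `delete_later` and `delete_none` are
available because the victim-selection rule is otherwise unspecified).
Contradictory or partially contradictory premises with corresponding
conclusions, and corresponding premises whose conclusions assign different
constants to one property, are *probable* conflicts: saved to the knowledge
base for expert review, never deleted, and suppressed on re-runs once an
expert marks them false. A class-vs-measurement contradiction (a diagnostic
pattern against the disjoint diagnosis) is only visible after one inference
step; `contradictory_literals()` takes bridging statements and saturates each
literal's instantiation (adding the domain/range memberships property atoms
imply) before the disjointness check.

**Inaccessible statements** are screened through the groups: only members of
groups with no incoming or no outgoing arcs are scanned — the screen is
necessary, not sufficient, and legitimate initial/terminal statements pass
it unharmed; `exhaustive_inaccessible = TRUE` scans everything. A statement
whose premise or conclusion contains an unsatisfiable literal is deleted.
**Illegal values** — constants violating a data property's declared range —
are flagged, never deleted, and properties without a declared range are
reported as unchecked rather than illegal.

## The synthetic generator

`generate_case()` builds labelled test cases. The base strategy is a layered
chain: a layer-$k$ statement consumes a stage class (layer 1 adds a
measurement data property and a threshold builtin) and concludes its own
fresh stage class. Unique conclusion classes make the base anomaly-free by
construction, and the dependency graph is exactly the designed DAG, which the
fixed-point test (`run_pipeline` deletes nothing on an injection-free base)
confirms per seed. Injections are *constructive* — each clones or perturbs a
base statement so that it satisfies one anomaly definition exactly — rather
than random edits, because constructive injection gives exact ground truth.
The default configuration emulates the mid-sized evaluation scenario: 24
base statements in 3 layers, plus 8 redundant, 4 cycle-forming, 8 conflicting
and 3 inaccessible statements.

What the generator does *not* emulate: real strategies mix atom styles within
one rule, share conclusion vocabulary between unrelated rules (which creates
the tie-heavy graphs the fixture corpus exercises), and carry annotation
noise. Passing the recovery test therefore shows the detectors are correct on
clean constructions, not that precision would be 1.0 on a curated clinical
rule base. Two further desk-scale limits are deliberate: injected cycles are
scored on *detection*, because under the canonical witness instantiation a
ground store is finite and forward chaining always reaches a fixpoint inside
the round budget, so constructively injected loops classify as fake; and
`cycle_real`/`cycle_fake` injections share one construction for that reason.
Scoring follows $\mathrm{precision} = TP/(TP+FP)$ and
$\mathrm{recall} = TP/(TP+FN)$ per anomaly kind, reporting $0/0$ as
undefined, never as 1.

## Numerical and degenerate-input choices

* Confidence products and weights live in $[0, 1]$; the edge threshold
  defaults to 0, so any strictly positive filtered product becomes an arc.
* Builtin spellings normalise at parse time to six canonical operators
  (`GE`, `LE`, `GT`, `LT`, `EQ`, `NE`). `normalize_integer_builtins = FALSE`
  by default: `GE(21)` and `GT(20)` are *not* identified, so the
  spelled-differently redundancy pair survives, mirroring the residual the
  method reports; switching the flag on detects it.
* Statement ids break direction ties; declaration order (ordinals) picks
  deletion victims between otherwise symmetric statements.
* The knowledge base keys entries by a readable canonical string (kind
  family plus rotation-normalised members) — deterministic and diff-able;
  expert verdicts are never downgraded by re-detection.
* Problem sizes in the test suite — the 24-statement recovery case, twenty
  12-statement preservation cases, 200 eight-node digraphs for the cycle
  oracle — were chosen as the smallest scales at which every code path and
  every injection kind is exercised.

## Limitations

* The ontology model is a taxonomy with disjointness, inverses and data
  ranges — not a reasoner. No existential or cardinality axioms, no ABox
  classification; equivalence with any particular SWRL engine is not claimed.
* Conclusions cannot introduce fresh individuals; every printed statement is
  safe in that sense, and unsafe statements are skipped with a warning.
* Chain enumeration caps at `chain_bound`; a transitive shortcut of a longer
  chain goes undetected unless the bound is raised.
* The contradiction vocabulary is class disjointness, interval arithmetic
  and declared inverses; domain contradictions outside it (e.g. dosage
  interactions) are invisible without bridging statements.
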