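---
title: "Typed validation of Relation Ontology models: the method and its design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typed validation of Relation Ontology models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oborel)
```

# The model

## Entity-class kinds as a meet-semilattice

The Relation Ontology classifies every biological entity class as
either a *process* (an occurrent: an activity or event with a
beginning, middle and end, such as a developmental stage) or a
*continuant* (a thing persisting through time), with continuants
subdivided into *material* (has matter: a cell, a protein) and
*immaterial* (no matter: a cavity, a lumen).  The two oppositions are
exclusive: nothing is both a process and a continuant, nothing both
material and immaterial.

`oborel` closes these four declarable kinds into a meet-semilattice by
adding a top element `UNKNOWN` (no information — the state of every
term in a plain OBO file, which has no slot for this classification)
and a bottom element `BOTTOM` (contradiction):

```
            UNKNOWN
           /       \
      PROCESS   CONTINUANT
          |     /        \
          | MATERIAL  IMMATERIAL
           \    |      /
             BOTTOM
```

The meet (`kindMeet`) is the greatest lower bound; mutual exclusivity
falls out of the order rather than being a special case: the meet of
two incomparable declarable kinds is `BOTTOM`.  "Class *C* must be
both *X* and *Y*" — the shape of every typing obligation in the system
— is then simply `kindMeet(X, Y)`, and a class is unsatisfiable
exactly when its accumulated meet is `BOTTOM`.  The lattice is tiny
(six members, height 4), so all algebraic laws (commutativity,
associativity, idempotence, identity of `UNKNOWN`) are verified
exhaustively in the test suite rather than sampled.

## The relation inventory

`relationRegistry()` holds the 22 relations, partitioned 8/5/5/4 into
foundational, spatial, temporal and participation categories.
`instance_of` is the single instance-to-class relation; the other 21
are class-to-class.  Nine relations form inverse pairs
(`part_of`/`has_part`, `located_in`/`location_of`,
`derives_from`/`derived_into`, `preceded_by`/`precedes`,
`has_participant`/`participates_in`, `has_agent`/`agent_in`, and the
proper/integral part variants); `is_a`, `instance_of`, `adjacent_to`
and `transformation_of` have no inverse in the inventory.  Relation
names are canonicalized to lowercase underscored form; the hyphenated
spellings (`part-of`) used in some listings are accepted on input and
never emitted.

The registry is deliberately closed: relations outside it (such as
`regulates`, or the `contributes_to` and `involved_in` relations that
the lint suggestions mention) are retained in models as *extension*
assertions — unconstrained, flagged in reports — rather than rejected,
because real ontology files contain them.

## Endpoint constraints

Each class-level relation carries a constraint row (`endpointRule()`):

| relation(s) | source | target | same branch | extra |
|---|---|---|---|---|
| `is_a` | — | — | yes | specification parity |
| `part_of` family | — | — | yes | material part ⇒ material whole; immaterial whole ⇒ immaterial part |
| `has_part` family | — | — | yes | mirrored conditionals |
| `located_in`, `location_of`, `adjacent_to` | continuant | continuant | — | |
| `contained_in` / `contains` | material / immaterial | immaterial / material | — | |
| `derives_from`, `derived_into`, `transformation_of` | material | material | — | |
| `preceded_by`, `precedes` | process | process | — | |
| `has_participant` / `participates_in` | process / continuant | continuant / process | — | |
| `has_agent` / `agent_in` | process / material | material / process | — | |

plus irreflexivity for `proper_part_of`/`has_proper_part` and an
expected reciprocal assertion for the integral variants.

Three design points deserve comment, because the design was genuinely
open:

* **Two checking modes.** In `STRICT` mode a declared kind must
  already satisfy its bound (`kindSatisfies`); `UNKNOWN` fails any
  real bound.  This is the profile's intended regime, where every
  class is stereotyped.  Real OBO inputs are untyped, so `LENIENT`
  mode only requires the kind to be *refinable* to the bound
  (`kindMeet` ≠ `BOTTOM`): an `UNKNOWN` or `CONTINUANT` source of
  `derives_from` passes leniently, a `PROCESS` source fails in both
  modes.  Strict issues are always a superset of lenient issues
  (property-tested).

* **`is_a` specification parity.** Between continuants we read the
  subtype rule literally: once either end is specified as material or
  immaterial, the other must carry the *same* specification, so the
  valid pairs over generic classes are exactly (process, process),
  (continuant, continuant), (material, material), (immaterial,
  immaterial).  The prose this comes from is not entirely conclusive —
  one could instead allow a specified subtype under an unspecified
  `continuant` supertype (ordinary subsumption).  We adopt parity as
  the default and expose the alternative as
  `checkRelation(..., isaParity = "subsumption")`, so the choice is a
  documented switch rather than a buried assumption.

* **`has_part` conditionals are the mirror image of `part_of`'s.**
  The conditional rules are stated for `part_of` (a material part
  forces a material whole; an immaterial whole forces immaterial
  parts); `has_part` is defined as its inverse, and mirroring the
  conditionals is the only reading under which the two validity
  matrices are transposes of each other — an invariant the tests
  enforce for all nine inverse pairs.  Likewise `part_of(continuant,
  material)` is valid: the literal conditionals do not exclude it, and
  excluding it would break transposition.

Also deliberate: `located_in`, `location_of` and `adjacent_to` carry
no material/immaterial constraint (only `contained_in`/`contains` are
material-specific), and the missing reciprocal of an integral part
assertion is a *warning*, not an error, because the reciprocal
association is part of the relation's semantics and may legitimately
be implicit.  Equally, `UNTYPED_CLASS` is a warning from the
validator, not a construction error: unstereotyped OBO terms must be
loadable.

The validity matrix of a relation (`validKindPairs`) is computed by
brute force: all 16 ordered pairs of declarable kinds are materialized
as two-class models and checked.  An independently written evaluator
in the test suite — its own constraint table, its own lattice test —
recomputes all 21 × 16 cases, and the two must agree cell for cell.

## The all/some rule

Class-level relations are defined from instance-level ones by the
all/some rule: `R(C, C1)` holds iff **all** instances of `C` bear an
`R` link to **some** instance of `C1`.  `checkAllSome()` evaluates
this directly when a model carries instance data: for each class-level
assertion of an association-based kind, every instance of the source
class must have at least one matching outgoing link; each uncovered
instance is one `ALL_SOME` error.  Links are also endpoint-checked
against the declared kinds of their instances' classes.  Instance data
travels in a deliberately small versioned sidecar format (one
`instance` or `link` record per line) because the OBO term-stanza
format has no instance records.

## Kind inference and unsatisfiable concepts

`inferKinds()` starts from the declared kinds and propagates
constraints to a fixpoint: endpoint bounds are met into the endpoints;
same-branch coupling fires once one side has resolved to a branch;
conditionals fire once their antecedent holds; `is_a` parity meets
each end with the other's kind.  Propagation is synchronous
(Jacobi-style: each round reads only the previous round's kinds), which
makes the result provably independent of assertion order — meets on a
semilattice commute — and termination is immediate since kinds only
descend a finite lattice; the round count is bounded by the number of
classes times the lattice height, and asserted in tests.

Two asymmetries are intentional:

* **`BOTTOM` does not propagate.**  A class whose kind collapses to
  `BOTTOM` is reported as unsatisfiable, but its neighbours are not
  poisoned: the historical "Gene Ontology" root — `is_a` parent of
  both a process (Biological Process) and a continuant (Cellular
  Component) — is detected as the invalid concept, while its children
  keep their own consistent kinds.  Propagating the contradiction
  outward would turn one modeling error into a graph-wide alarm.

* **No case-splitting.**  Same-branch constraints are disjunctive
  ("both processes or both continuants"); the engine propagates them
  only once one side is resolved, so inference is polynomial but
  incomplete: a branch-ambiguous model stays `UNKNOWN` rather than
  being guessed.  This matches the advisory role of the tool; full
  satisfiability search is out of scope.

Each narrowing step records the assertion that caused it, giving short
human-readable provenance chains for unsatisfiable classes.  Inference
never writes kinds back into a model; `applyInferredKinds()` does so
only when explicitly called.

## Lint

Two advisory rules, both derived from recurring defects in real
ontologies: `MULTIPLE_INHERITANCE` (a class with two or more `is_a`
parents; the suggestion names `contributes_to` as a candidate
replacement for one of them) and `EMBEDDED_RELATION_NAME` (a term name
of the form "X involved in Y" where X and Y are themselves term names
in the model; the suggestion is to relate the two classes directly).
Name matching is exact after case and whitespace normalization — no
stemming, no fuzzy matching — because a wrong refactoring suggestion
is worse than a missed one; both name parts must resolve, so "MAPKKK
Cascade Involved in Osmosensory Signaling Pathway" yields no finding
unless the model also contains "Osmosensory Signaling Pathway".  Lint
output never mutates the model.

# The synthetic-model generator

`randomModel(nClasses, nRelations, violationRate, seed)` emulates the
structural situation the validator is built for: a fragment whose
classes are stereotyped (kinds drawn uniformly from the four
declarable kinds, each kind guaranteed present) and whose assertions
are either *conforming* — endpoint kinds drawn from the relation's
computed validity matrix — or, with the given probability, *planted
violations* drawn from templates that each trigger exactly one error
of a named rule (`ENDPOINT_KIND`, `SAME_BRANCH`, `CONDITIONAL_KIND`,
`IRREFLEXIVE`).  One violation per assertion keeps the ground truth
unambiguous, so validator precision and recall can be measured exactly
(`plantedRecovery`); both are 1 across seeds in the test suite.  The
integral part variants are excluded from generation because their
expected-reciprocity *warnings* would be noise against the
error-level ground truth.

What the generator does **not** emulate: the deep, sparse, DAG-shaped
topology of real ontologies (its edges are uniform over class pairs),
realistic kind frequencies (real ontologies are continuant- or
process-heavy, not uniform), term-name conventions, and untyped terms
(every generated class is stereotyped).  Passing the recovery test
therefore shows that the constraint engine is *exact* on ground-truth
violations of its own rule set; it says nothing about how often real
curation errors fall within that rule set.

The generator restores the caller's RNG state on exit, so embedding it
in analyses does not perturb their random streams.  Problem sizes used
in the packaged checks — 20 seeds of 50 classes / 200 assertions for
recovery, 100 models of 8 classes / 12 assertions for round-trip —
were chosen to exercise every template and code path many times over
while keeping the whole suite fast.

# I/O

The OBO reader covers the flat-file subset the typing discipline
needs: `[Term]` stanzas with `id`, `name`, `is_a`, `relationship`,
`is_obsolete`; other tags are preserved verbatim and uninterpreted;
other stanza types (`[Typedef]`) are skipped; trailing `! comments`
and `{qualifier}` blocks are stripped; hyphenated relation names are
normalized.  Kinds are serialized as reserved `property_value:
oborel:kind` lines — the format has no stereotype slot, which is
precisely the gap this package fills — so write∘parse is the identity
on models (property-tested on fixtures and random models).  Dangling
relationship targets and non-inventory relation names are collected as
load warnings rather than fatal errors, and no relationship line is
ever silently dropped: every input line becomes an assertion or a
warning.  Identifiers are opaque strings; no CURIE expansion is
attempted.  Obsolete classes are loaded, preserved on write, and
excluded from validation and inference.

# Numerical and degenerate-input choices

There is no floating-point numerics in the package; determinism
questions are combinatorial instead.  Validation reports are sorted by
rule id then subject, so reports are insertion-order independent; DOT
output sorts nodes by id and edges by (kind, source, target), so it is
byte-identical across runs; `writeObo` emits stanzas in sorted id
order.  Degenerate inputs are defined rather than accidental: an empty
model validates to an empty report, exports a valid empty digraph, and
writes a header-only document; an empty model's usage statistics
report fraction 0 with an explicit `defined = FALSE` flag rather than
0/0; the all/some check is vacuously satisfied without instances.

# The packaged fragments

Four worked fragments are built in code (and shipped as OBO files
under `inst/extdata/`): the TGF-Beta fragment of the PRotein Ontology
(6 material continuants, 4 `is_a` + 2 `derives_from`, strictly valid),
the Xenopus developmental-stage fragment (10 processes, 6 `is_a` + 3
`part_of` + 2 `preceded_by`, strictly valid), the historical Gene
Ontology root (the canonical unsatisfiable concept), and a GO
biological-process fragment exhibiting two multiple inheritances and
one relation-embedded name.  The fragments implement exactly the
relations enumerated in the running descriptions of these ontologies'
published excerpts; where the original figures may contain additional
edges, those are not reproduced.  Term ids are synthetic stable
strings (`PRO:FIX01`, ...) because the excerpts do not print
accessions; labels follow the source ontologies.

# Known limitations

* Instantiation is not indexed by time: the formal definitions of the
  relations carry a time parameter *t* ("instantiates C at a time t")
  which a static model cannot check; the temporal content of
  `preceded_by` etc. is reduced to its endpoint kinds.
* The spatial non-overlap semantics of `adjacent_to` is not
  structurally decidable from a graph and is not checked.
* Inference is deliberately incomplete (no case-splitting over
  branches), and the registry implements the classic 22-relation
  inventory only; newer, larger relation inventories would enter as
  extension kinds.
* OWL/RDF serializations and OBO logical definitions
  (`intersection_of`, `union_of`) are out of scope; input is the flat
  file subset described above.

```{r session}
sessionInfo()
```
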