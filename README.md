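# oborel

Typed validation, kind inference and lint for biomedical ontology
fragments that use the OBO Relation Ontology.

## The problem

OBO Foundry ontologies (GO, PRO, XAO, ...) connect their terms with a
standard inventory of 22 relations — `is_a`, `part_of`, `derives_from`,
`preceded_by`, `has_agent` and so on — whose formal semantics constrain
what kinds of entity classes each relation may connect.  Every entity
class is, ontologically, either a **process** (an event with a
beginning, middle and end: a developmental stage) or a **continuant**
(a thing persisting through time), and continuants are further
**material** (a protein) or **immaterial** (a lumen).  The OBO flat
file format has no slot for this classification, so in practice terms
are untyped, relations are asserted on tacit knowledge, and semantic
inconsistencies creep in: `has_agent` must connect a process to a
*material* continuant, a material part cannot sit in an immaterial
whole, and a term that would have to be both a process and a continuant
(as the historical "Gene Ontology" root concept) is simply an invalid
concept.

`oborel` makes this typing discipline executable for curators and
ontology engineers:

- **Kind lattice.** The four declarable kinds are closed into a
  meet-semilattice (`UNKNOWN` ⊐ {`PROCESS`, `CONTINUANT`},
  `CONTINUANT` ⊐ {`MATERIAL`, `IMMATERIAL`}, with `BOTTOM` marking
  contradiction), so "class *C* must be both *X* and *Y*" is a meet.
- **Constraint engine.** Every relation carries an endpoint rule
  (kind bounds, same-branch coupling, material/immaterial conditional
  rules, `is_a` specification parity, irreflexivity for the proper part
  variants).  Models are validated in *strict* mode (every class must
  already be stereotyped correctly) or *lenient* mode (kinds need only
  be refinable — for plain, untyped OBO inputs).
- **Inference engine.** A fixpoint propagation refines missing kinds
  over the graph and detects unsatisfiable concepts (classes whose
  inferred kind collapses to `BOTTOM`), with a provenance chain
  explaining each narrowing.
- **All/some semantics.** Class-level relations are defined by the
  all/some rule — `R(C, C1)` holds iff every instance of `C` bears an
  `R` link to some instance of `C1`; given instance data (a small
  sidecar format), uncovered instances are reported.
- **Lint.** Multiple inheritance (with a `contributes_to` replacement
  suggestion) and relation-embedded term names ("X involved in Y" where
  X and Y are themselves terms) are flagged, advisorily.
- **I/O and reporting.** OBO flat-file subset reader/writer
  (round-trip safe, kinds carried in reserved `property_value:
  oborel:kind` lines), versioned JSON reports, Graphviz DOT export
  using the profile's notation (hollow triangle for `is_a`, open
  diamond for the part family), and a command-line tool.

## Worked example

```r
library(oborel)

# the Xenopus developmental-stage fragment: 10 processes, 11 assertions
xao <- xaoFragment()
validateModel(xao, mode = "STRICT")
#> ValidationReport (STRICT mode): 0 error(s), 0 warning(s)

relationUsageStats(xao, subset = c("is_a", "part_of", "preceded_by"))$subset_fraction
#> [1] 1

# an invalid concept: the historical Gene Ontology root is the is_a
# parent of both a process and a continuant
unsatisfiableClasses(goRootFragment())
#> [1] "GO:FIX01"
provenance(inferKinds(goRootFragment()), "GO:FIX01")
#> [1] "is_a(GO:FIX02, GO:FIX01): same-branch with GO:FIX02 (process)"
#> [2] "is_a(GO:FIX03, GO:FIX01): same-branch with GO:FIX03 (continuant)"

# an incorrect relation: a process with an immaterial agent
m <- addClass(OntologyModel(), "p", "binding", "PROCESS")
m <- addClass(m, "x", "lumen", "IMMATERIAL")
checkRelation(addRelation(m, "has_agent", "p", "x"), "has_agent", "p", "x")
#>            rule severity         subject
#> 1 ENDPOINT_KIND    ERROR has_agent(p, x)
#>                                                          message
#> 1 target of has_agent must be material; x is declared immaterial
```

The validity matrix of a relation over generic classes is computed by
brute force over the 16 kind pairs: `nrow(validKindPairs("is_a"))` is 4
(both processes, or two equally specified continuants),
`nrow(validKindPairs("part_of"))` is 7, and `has_agent` admits exactly
`(PROCESS, MATERIAL)`.

From a shell:

```sh
Rscript inst/scripts/oborel validate --mode strict inst/extdata/pro_fragment.obo
Rscript inst/scripts/oborel lint inst/extdata/go_mi_fragment.obo
Rscript inst/scripts/oborel export-dot inst/extdata/xao_fragment.obo --out xao.dot
```

Exit codes: 0 clean, 1 errors found, 2 I/O/format failure.

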