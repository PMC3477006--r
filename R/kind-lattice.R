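## Entity-class kind lattice
##
## The Relation Ontology divides biological entity classes into two
## non-overlapping branches: continuants (things that persist through time)
## and processes (events with a beginning, middle and end).  Continuants are
## further divided into material (cell, DNA, hemoglobin) and immaterial
## (cavities, lumina) continuants.  We close these four declarable kinds
## into a meet-semilattice with a top element UNKNOWN (no information; an
## unstereotyped OBO term) and a bottom element BOTTOM (contradiction; an
## unsatisfiable concept):
##
##              UNKNOWN
##             /       \
##        PROCESS   CONTINUANT
##            |     /        \
##            | MATERIAL  IMMATERIAL
##             \    |      /
##               BOTTOM
##
## MATERIAL and IMMATERIAL are incomparable, as are PROCESS and CONTINUANT.

#' Entity-class kinds
#'
#' The six members of the kind lattice.  Only the first four are
#' *declarable* on an entity class; `UNKNOWN` marks an unstereotyped class
#' and `BOTTOM` a contradictory (unsatisfiable) one, and both are reserved
#' for internal bookkeeping by the validator and the inference engine.
#'
#' @return `entityKinds()` returns the six lattice members;
#'   `declarableKinds()` the four kinds a class may be declared with.
#' @examples
#' entityKinds()
#' declarableKinds()
#' @export
entityKinds <- function() {
    c("PROCESS", "CONTINUANT", "MATERIAL", "IMMATERIAL", "UNKNOWN", "BOTTOM")
}

#' @rdname entityKinds
#' @export
declarableKinds <- function() {
    c("PROCESS", "CONTINUANT", "MATERIAL", "IMMATERIAL")
}

## Upward closure of each kind (the kinds at or above it).  BOTTOM is below
## everything, UNKNOWN above everything.
.kind_up <- list(
    UNKNOWN    = c("UNKNOWN"),
    PROCESS    = c("PROCESS", "UNKNOWN"),
    CONTINUANT = c("CONTINUANT", "UNKNOWN"),
    MATERIAL   = c("MATERIAL", "CONTINUANT", "UNKNOWN"),
    IMMATERIAL = c("IMMATERIAL", "CONTINUANT", "UNKNOWN"),
    BOTTOM     = c("BOTTOM", "PROCESS", "CONTINUANT", "MATERIAL",
                   "IMMATERIAL", "UNKNOWN")
)

.assert_kind <- function(x, arg = deparse(substitute(x))) {
    if (!(is.character(x) && length(x) == 1L && x %in% names(.kind_up)))
        stop("'", arg, "' must be one of ",
             paste(entityKinds(), collapse = ", "), call. = FALSE)
    x
}

#' Lattice order and meet on entity-class kinds
#'
#' `kindLeq(a, b)` tests whether `a` lies at or below `b` in the kind
#' lattice.  `kindMeet(a, b)` returns the greatest lower bound of two
#' kinds; the disjointness of the process/continuant and
#' material/immaterial branches is realised by the meet collapsing to
#' `BOTTOM` for incomparable declarable kinds.  `kindSatisfies(declared,
#' bound)` is the strict-mode endpoint test: the declared kind must already
#' lie at or below the bound.
#'
#' The meet is commutative, associative and idempotent; `UNKNOWN` is its
#' identity and `BOTTOM` is absorbing.
#'
#' @param a,b,declared,bound A kind, one of [entityKinds()].
#' @return `kindMeet` a kind; `kindLeq` and `kindSatisfies` a logical.
#' @examples
#' kindMeet("CONTINUANT", "MATERIAL")   # "MATERIAL"
#' kindMeet("PROCESS", "CONTINUANT")    # "BOTTOM": branches are disjoint
#' kindMeet("MATERIAL", "IMMATERIAL")   # "BOTTOM"
#' kindSatisfies("MATERIAL", "CONTINUANT")  # TRUE
#' kindSatisfies("CONTINUANT", "MATERIAL")  # FALSE
#' @export
kindMeet <- function(a, b) {
    .assert_kind(a); .assert_kind(b)
    if (b %in% .kind_up[[a]]) return(a)   # a <= b
    if (a %in% .kind_up[[b]]) return(b)   # b <= a
    "BOTTOM"
}

#' @rdname kindMeet
#' @export
kindLeq <- function(a, b) {
    .assert_kind(a); .assert_kind(b)
    b %in% .kind_up[[a]]
}

#' @rdname kindMeet
#' @export
kindSatisfies <- function(declared, bound) {
    .assert_kind(declared); .assert_kind(bound)
    if (declared == "BOTTOM")
        stop("'declared' must not be BOTTOM", call. = FALSE)
    bound %in% .kind_up[[declared]]
}

## Branch membership helpers used by the same-branch rule and inference.
.in_continuant_branch <- function(k) {
    k %in% c("CONTINUANT", "MATERIAL", "IMMATERIAL")
}
.in_process_branch <- function(k) {
    k == "PROCESS"
}
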