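## Fixpoint kind inference.
##
## Starting from the declared kinds (UNKNOWN for unstereotyped classes),
## constraints are propagated until nothing changes:
##   (a) endpoint bounds — each endpoint's kind is met with the relation's
##       bound for that end;
##   (b) same-branch coupling — once one endpoint of a branch-coupled
##       relation resolves to a branch, the other endpoint is met with
##       that branch's top (PROCESS or CONTINUANT);
##   (c) material/immaterial conditionals whose antecedent holds;
##   (d) is_a specification parity — the endpoints of a subtype relation
##       are met with each other's kind, so specification flows both ways.
##
## Propagation is synchronous (Jacobi-style): each round computes every
## class's new kind from the previous round's kinds, so the result does
## not depend on assertion order.  Kinds only descend a finite lattice, so
## the fixpoint is reached in at most (number of classes x lattice height)
## rounds.  A class whose kind collapses to BOTTOM is unsatisfiable; a
## BOTTOM neighbour contributes nothing further (the contradiction is
## reported where it arose rather than cascading over the graph).

#' @title Inferred kind assignment
#'
#' @description Result of [inferKinds()]: the inferred kind of every
#' non-obsolete class and, per class, the provenance chain — the
#' assertions that narrowed its kind, in the order the narrowing happened.
#' For every class the inferred kind lies at or below its declared kind;
#' a declaration contradicted by the constraints yields `BOTTOM` rather
#' than being silently overridden.
#'
#' @slot kinds named character vector: class id to inferred kind.
#' @slot provenance named list: class id to character vector of narrowing
#'   explanations.
#' @slot rounds number of propagation rounds to the fixpoint.
#' @name KindAssignment-class
#' @aliases KindAssignment
#' @exportClass KindAssignment
setClass("KindAssignment",
    representation(kinds = "character", provenance = "list",
                   rounds = "integer"))

setMethod("show", "KindAssignment", function(object) {
    cat("KindAssignment for", length(object@kinds), "classes (",
        object@rounds, "propagation rounds )\n")
    bot <- names(object@kinds)[object@kinds == "BOTTOM"]
    if (length(bot))
        cat("  unsatisfiable:", paste(bot, collapse = ", "), "\n")
})

#' @rdname KindAssignment-class
#' @param assignment A `KindAssignment`.
#' @export
inferredKinds <- function(assignment) assignment@kinds

#' @rdname KindAssignment-class
#' @param id A class id.
#' @export
provenance <- function(assignment, id) {
    if (!id %in% names(assignment@provenance))
        stop("unknown class id: ", id, call. = FALSE)
    assignment@provenance[[id]]
}

## informative kinds: contribute to neighbours (UNKNOWN carries no
## information, BOTTOM is not propagated)
.informative <- function(k) !k %in% c("UNKNOWN", "BOTTOM")

#' Infer entity-class kinds by constraint propagation
#'
#' Computes the most specific kind each class must have for the model's
#' relation assertions to be satisfiable, starting from the declared
#' kinds.  Classes whose constraints are contradictory are assigned
#' `BOTTOM` — these are the model's unsatisfiable (invalid) concepts, as
#' with a root term that is the `is_a` parent of both a process and a
#' continuant.  Same-branch coupling is propagated only once one side has
#' resolved to a branch; no case-splitting is performed, so a
#' branch-ambiguous class keeps `UNKNOWN` rather than being guessed.
#'
#' @param model An [OntologyModel].  Obsolete classes and assertions
#'   touching them are ignored.
#' @return A [KindAssignment].
#' @examples
#' a <- inferKinds(goRootFragment())
#' inferredKinds(a)                 # the ontology root is BOTTOM
#' unsatisfiableClasses(goRootFragment())
#' @export
inferKinds <- function(model) {
    cl <- .active_classes(model)
    rel <- .active_relations(model)
    kinds <- stats::setNames(cl$kind, cl$id)
    prov <- stats::setNames(vector("list", nrow(cl)), cl$id)
    if (nrow(rel)) {
        ord <- order(rel$kind, rel$source, rel$target)
        rel <- rel[ord, , drop = FALSE]
    }
    rules <- lapply(stats::setNames(rel$kind, NULL),
                    function(k) if (k == "instance_of") NULL
                                else endpointRule(k))

    max_rounds <- max(1L, length(kinds)) * 4L   # lattice height bound
    rounds <- 0L
    repeat {
        rounds <- rounds + 1L
        prev <- kinds
        ## collect this round's contributions from the previous round's
        ## kinds; (class, new kind, explanation)
        narrow <- function(id, to, why) {
            if (to == kinds[[id]]) return()
            kinds[[id]] <<- to
            prov[[id]] <<- c(prov[[id]], why)
        }
        for (i in seq_len(nrow(rel))) {
            rl <- rules[[i]]
            if (is.null(rl)) next
            k <- rel$kind[i]; s <- rel$source[i]; t <- rel$target[i]
            sk <- prev[[s]]; tk <- prev[[t]]
            subj <- .subject_of(k, s, t)

            if (rl$source_bound != "UNKNOWN")
                narrow(s, kindMeet(kinds[[s]], rl$source_bound),
                       paste0(subj, ": source bound ",
                              tolower(rl$source_bound)))
            if (rl$target_bound != "UNKNOWN")
                narrow(t, kindMeet(kinds[[t]], rl$target_bound),
                       paste0(subj, ": target bound ",
                              tolower(rl$target_bound)))

            if (rl$same_branch) {
                if (.informative(tk)) {
                    br <- if (.in_process_branch(tk)) "PROCESS"
                          else "CONTINUANT"
                    narrow(s, kindMeet(kinds[[s]], br),
                           paste0(subj, ": same-branch with ", t, " (",
                                  tolower(br), ")"))
                }
                if (.informative(sk)) {
                    br <- if (.in_process_branch(sk)) "PROCESS"
                          else "CONTINUANT"
                    narrow(t, kindMeet(kinds[[t]], br),
                           paste0(subj, ": same-branch with ", s, " (",
                                  tolower(br), ")"))
                }
            }

            for (cd in rl$conditionals) {
                ante <- if (cd$role == "source") sk else tk
                other <- if (cd$role == "source") t else s
                if (ante == cd$antecedent)
                    narrow(other, kindMeet(kinds[[other]], cd$consequent),
                           paste0(subj, ": ", tolower(cd$antecedent), " ",
                                  cd$role, " forces ",
                                  tolower(cd$consequent)))
            }

            if (rl$parity) {
                ## subtype and supertype must carry the same
                ## specification: meet each with the other's kind
                if (.informative(tk))
                    narrow(s, kindMeet(kinds[[s]], tk),
                           paste0(subj, ": specification of supertype ",
                                  t, " (", tolower(tk), ")"))
                if (.informative(sk))
                    narrow(t, kindMeet(kinds[[t]], sk),
                           paste0(subj, ": specification of subtype ",
                                  s, " (", tolower(sk), ")"))
            }
        }
        if (identical(kinds, prev) || rounds >= max_rounds) break
    }
    new("KindAssignment", kinds = kinds, provenance = prov,
        rounds = rounds)
}

#' Unsatisfiable classes of a model
#'
#' The classes whose inferred kind is `BOTTOM` — concepts that cannot be
#' assigned any entity-class kind consistently with the model's relation
#' assertions.
#'
#' @param model An [OntologyModel].
#' @return Character vector of class ids (sorted; empty when the model is
#'   satisfiable).
#' @examples
#' unsatisfiableClasses(goRootFragment())  # the ontology root concept
#' unsatisfiableClasses(proFragment())     # none
#' @export
unsatisfiableClasses <- function(model) {
    a <- inferKinds(model)
    sort(names(a@kinds)[a@kinds == "BOTTOM"])
}

#' Write inferred kinds back into a model
#'
#' Returns a copy of the model whose class kinds are replaced by the
#' inferred assignment.  Classes inferred `BOTTOM` are left at their
#' declared kind (a contradiction cannot be declared); classes inferred
#' `UNKNOWN` stay unstereotyped.  Inference itself never mutates a model;
#' this explicit step applies it.
#'
#' @param model An [OntologyModel].
#' @param assignment Optionally a precomputed [KindAssignment].
#' @return The re-declared model.
#' @export
applyInferredKinds <- function(model, assignment = inferKinds(model)) {
    k <- assignment@kinds
    idx <- match(names(k), model@classes$id)
    ok <- !k %in% c("BOTTOM")
    model@classes$kind[idx[ok]] <- unname(k[ok])
    methods::validObject(model)
    model
}
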