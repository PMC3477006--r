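## Per-relation endpoint constraints and model validation.
##
## Each class-level relation carries a row in the constraint table:
##   - source_bound / target_bound: the kind each endpoint must satisfy
##     (UNKNOWN = unconstrained);
##   - same_branch: both endpoints must lie in the same branch of the
##     lattice (both processes or both continuants) — the foundational
##     relations connect "either two continuants or two processes";
##   - conditionals: material/immaterial propagation rules that fire only
##     when the antecedent endpoint is declared with exactly that kind
##     (for part_of: a material part forces a material whole; an
##     immaterial whole forces immaterial parts);
##   - parity: the is_a specification-parity rule — once either endpoint
##     of a subtype relation between continuants is specified as material
##     or immaterial, the other must carry the same specification;
##   - irreflexive: source and target classes must differ (the proper
##     part variants);
##   - reciprocal: the integral part variants expect the mirrored
##     has_part/part_of assertion (reported as a warning when absent).

## A conditional is (role of antecedent endpoint, antecedent kind,
## consequent kind required of the other endpoint).
.cond <- function(role, ante, cons) {
    list(role = role, antecedent = ante, consequent = cons)
}

.part_of_conds  <- list(.cond("source", "MATERIAL", "MATERIAL"),
                        .cond("target", "IMMATERIAL", "IMMATERIAL"))
.has_part_conds <- list(.cond("target", "MATERIAL", "MATERIAL"),
                        .cond("source", "IMMATERIAL", "IMMATERIAL"))

.constraint_row <- function(src = "UNKNOWN", tgt = "UNKNOWN",
                            same_branch = FALSE, conds = list(),
                            parity = FALSE, irreflexive = FALSE,
                            reciprocal = FALSE) {
    list(source_bound = src, target_bound = tgt, same_branch = same_branch,
         conditionals = conds, parity = parity, irreflexive = irreflexive,
         reciprocal = reciprocal)
}

.constraint_table <- list(
    is_a              = .constraint_row(same_branch = TRUE, parity = TRUE),
    part_of           = .constraint_row(same_branch = TRUE,
                                        conds = .part_of_conds),
    proper_part_of    = .constraint_row(same_branch = TRUE,
                                        conds = .part_of_conds,
                                        irreflexive = TRUE),
    integral_part_of  = .constraint_row(same_branch = TRUE,
                                        conds = .part_of_conds,
                                        reciprocal = TRUE),
    has_part          = .constraint_row(same_branch = TRUE,
                                        conds = .has_part_conds),
    has_proper_part   = .constraint_row(same_branch = TRUE,
                                        conds = .has_part_conds,
                                        irreflexive = TRUE),
    has_integral_part = .constraint_row(same_branch = TRUE,
                                        conds = .has_part_conds,
                                        reciprocal = TRUE),
    located_in        = .constraint_row("CONTINUANT", "CONTINUANT"),
    location_of       = .constraint_row("CONTINUANT", "CONTINUANT"),
    adjacent_to       = .constraint_row("CONTINUANT", "CONTINUANT"),
    contained_in      = .constraint_row("MATERIAL", "IMMATERIAL"),
    contains          = .constraint_row("IMMATERIAL", "MATERIAL"),
    derives_from      = .constraint_row("MATERIAL", "MATERIAL"),
    derived_into      = .constraint_row("MATERIAL", "MATERIAL"),
    transformation_of = .constraint_row("MATERIAL", "MATERIAL"),
    preceded_by       = .constraint_row("PROCESS", "PROCESS"),
    precedes          = .constraint_row("PROCESS", "PROCESS"),
    has_participant   = .constraint_row("PROCESS", "CONTINUANT"),
    participates_in   = .constraint_row("CONTINUANT", "PROCESS"),
    has_agent         = .constraint_row("PROCESS", "MATERIAL"),
    agent_in          = .constraint_row("MATERIAL", "PROCESS")
)

#' Endpoint constraint of a relation kind
#'
#' Returns the constraint attached to a class-level Relation Ontology
#' relation: the kind bound on each endpoint (`UNKNOWN` when
#' unconstrained), whether the endpoints must lie in the same lattice
#' branch, the material/immaterial conditional rules, the is_a
#' specification-parity flag, irreflexivity, and whether a reciprocal part
#' assertion is expected.  Relation kinds outside the registry (extension
#' relations such as `contributes_to`) are unconstrained.
#'
#' @param kind A relation name; hyphenated spellings are normalized.
#' @return A list with elements `source_bound`, `target_bound`,
#'   `same_branch`, `conditionals`, `parity`, `irreflexive`, `reciprocal`.
#' @examples
#' endpointRule("has_agent")[c("source_bound", "target_bound")]
#' endpointRule("proper_part_of")$irreflexive
#' endpointRule("integral_part_of")$reciprocal
#' @export
endpointRule <- function(kind) {
    kind <- normalizeRelationName(kind)
    if (kind == "instance_of")
        stop("instance_of is instance-level; it has no class-level ",
             "endpoint rule", call. = FALSE)
    if (.is_registry_kind(kind))
        return(.constraint_table[[kind]])
    ## extension relation: unconstrained
    .constraint_row()
}

## ---- single-assertion check ----------------------------------------------

.issue <- function(rule, severity, subject, message) {
    data.frame(rule = rule, severity = severity, subject = subject,
               message = message, stringsAsFactors = FALSE)
}
.no_issues <- function() .issue(character(), character(), character(),
                                character())

.subject_of <- function(kind, source, target) {
    paste0(kind, "(", source, ", ", target, ")")
}

## Does `declared` meet the bound under the given mode?  STRICT: the
## declared kind must already satisfy the bound (UNKNOWN fails any real
## bound).  LENIENT: the declared kind need only be refinable to the bound
## (meet != BOTTOM).
.bound_ok <- function(declared, bound, mode) {
    if (bound == "UNKNOWN") return(TRUE)
    if (mode == "STRICT") kindSatisfies(declared, bound)
    else kindMeet(declared, bound) != "BOTTOM"
}

.check_mode <- function(mode) {
    mode <- toupper(mode)
    if (!mode %in% c("STRICT", "LENIENT"))
        stop("mode must be \"STRICT\" or \"LENIENT\"", call. = FALSE)
    mode
}

#' Check one relation assertion against its endpoint constraint
#'
#' Evaluates a single class-level assertion of `model` against the
#' constraint table.  In `STRICT` mode every declared kind must already
#' satisfy its bound (the profile's intended use, where every class is
#' stereotyped; `UNKNOWN` endpoints fail).  In `LENIENT` mode a kind only
#' needs to be *refinable* to the bound, so unstereotyped OBO terms pass.
#'
#' Issue rules emitted here: `ENDPOINT_KIND` (an endpoint violates the
#' relation's kind bound), `SAME_BRANCH` (endpoints straddle the
#' process/continuant divide), `CONDITIONAL_KIND` (a material/immaterial
#' conditional, or the is_a specification-parity rule, is violated) and
#' `IRREFLEXIVE` (a proper part relation from a class to itself).  All are
#' `ERROR` severity.
#'
#' @param model An [OntologyModel].
#' @param kind,source,target The assertion to check; endpoints must
#'   resolve to classes of `model`.
#' @param mode `"STRICT"` or `"LENIENT"`.
#' @param isaParity `"parity"` (default) requires both endpoints of a
#'   continuant-branch `is_a` to carry the same specification;
#'   `"subsumption"` additionally accepts a specified subtype under an
#'   unspecified `CONTINUANT` supertype.
#' @return A data.frame of issues (zero rows when the assertion is clean)
#'   with columns `rule`, `severity`, `subject`, `message`.
#' @examples
#' m <- addClass(OntologyModel(), "p", "binding", "PROCESS")
#' m <- addClass(m, "x", "lumen", "IMMATERIAL")
#' m <- addRelation(m, "has_agent", "p", "x")
#' checkRelation(m, "has_agent", "p", "x")   # ENDPOINT_KIND error
#' @export
checkRelation <- function(model, kind, source, target, mode = "STRICT",
                          isaParity = c("parity", "subsumption")) {
    mode <- .check_mode(mode)
    isaParity <- match.arg(isaParity)
    kind <- normalizeRelationName(kind)
    missing_ids <- setdiff(c(source, target), model@classes$id)
    if (length(missing_ids))
        stop("assertion endpoint does not resolve: ",
             paste(missing_ids, collapse = ", "), call. = FALSE)
    rule <- endpointRule(kind)
    sk <- unname(classKind(model, source))
    tk <- unname(classKind(model, target))
    subj <- .subject_of(kind, source, target)
    issues <- .no_issues()

    if (!.bound_ok(sk, rule$source_bound, mode))
        issues <- rbind(issues, .issue("ENDPOINT_KIND", "ERROR", subj,
            paste0("source of ", kind, " must be ",
                   tolower(rule$source_bound), "; ", source,
                   " is declared ", tolower(sk))))
    if (!.bound_ok(tk, rule$target_bound, mode))
        issues <- rbind(issues, .issue("ENDPOINT_KIND", "ERROR", subj,
            paste0("target of ", kind, " must be ",
                   tolower(rule$target_bound), "; ", target,
                   " is declared ", tolower(tk))))

    if (rule$same_branch) {
        ok <- if (mode == "STRICT") {
            (.in_process_branch(sk) && .in_process_branch(tk)) ||
                (.in_continuant_branch(sk) && .in_continuant_branch(tk))
        } else {
            (kindMeet(sk, "PROCESS") != "BOTTOM" &&
                 kindMeet(tk, "PROCESS") != "BOTTOM") ||
                (kindMeet(sk, "CONTINUANT") != "BOTTOM" &&
                     kindMeet(tk, "CONTINUANT") != "BOTTOM")
        }
        if (!ok)
            issues <- rbind(issues, .issue("SAME_BRANCH", "ERROR", subj,
                paste0(kind, " must connect two continuants or two ",
                       "processes; got ", tolower(sk), " and ",
                       tolower(tk))))
    }

    for (cd in rule$conditionals) {
        ante_kind <- if (cd$role == "source") sk else tk
        other_id <- if (cd$role == "source") target else source
        other_kind <- if (cd$role == "source") tk else sk
        if (ante_kind == cd$antecedent &&
            !.bound_ok(other_kind, cd$consequent, mode))
            issues <- rbind(issues, .issue("CONDITIONAL_KIND", "ERROR",
                subj,
                paste0("with a ", tolower(cd$antecedent), " ", cd$role,
                       ", the other endpoint of ", kind, " must be ",
                       tolower(cd$consequent), "; ", other_id,
                       " is declared ", tolower(other_kind))))
    }

    if (rule$parity) {
        viol <- if (mode == "STRICT") {
            if (.in_continuant_branch(sk) && .in_continuant_branch(tk)) {
                if (isaParity == "parity") sk != tk
                else kindMeet(sk, tk) == "BOTTOM" ||
                    (sk == "CONTINUANT" && tk != "CONTINUANT")
            } else FALSE
        } else {
            ## refinable: only materially incompatible specifications fail
            .in_continuant_branch(sk) && .in_continuant_branch(tk) &&
                kindMeet(sk, tk) == "BOTTOM"
        }
        if (viol)
            issues <- rbind(issues, .issue("CONDITIONAL_KIND", "ERROR",
                subj,
                paste0("is_a between continuants requires matching ",
                       "material/immaterial specification; got ",
                       tolower(sk), " and ", tolower(tk))))
    }

    if (rule$irreflexive && source == target)
        issues <- rbind(issues, .issue("IRREFLEXIVE", "ERROR", subj,
            paste0(kind, " requires distinct source and target classes")))

    issues
}

## ---- ValidationReport -----------------------------------------------------

#' @title Validation report
#'
#' @description Result of [validateModel()]: the issues found (a
#' data.frame with columns `rule`, `severity`, `subject`, `message`), the
#' checking mode, and per-rule counts.  `issues()`, `issueCounts()`,
#' `nErrors()` and `nWarnings()` are the accessors.
#'
#' @slot issues data.frame of issues in deterministic order.
#' @slot mode `"STRICT"` or `"LENIENT"`.
#' @slot counts named integer vector of issues per rule id.
#' @name ValidationReport-class
#' @aliases ValidationReport
#' @exportClass ValidationReport
setClass("ValidationReport",
    representation(issues = "data.frame", mode = "character",
                   counts = "integer"))

setValidity("ValidationReport", function(object) {
    tab <- table(object@issues$rule)
    ok <- length(object@counts) == length(tab) &&
        all(names(object@counts) %in% names(tab)) &&
        all(object@counts[names(tab)] == as.integer(tab))
    if (ok) TRUE else "counts inconsistent with issues"
})

.make_report <- function(issues, mode) {
    ## deterministic ordering: rule id, then subject
    if (nrow(issues)) {
        issues <- issues[order(issues$rule, issues$subject,
                               issues$severity), , drop = FALSE]
        rownames(issues) <- NULL
    }
    tab <- table(issues$rule)
    new("ValidationReport", issues = issues, mode = mode,
        counts = stats::setNames(as.integer(tab), names(tab)))
}

#' @rdname ValidationReport-class
#' @param report A `ValidationReport`.
#' @export
issues <- function(report) report@issues

#' @rdname ValidationReport-class
#' @export
issueCounts <- function(report) report@counts

#' @rdname ValidationReport-class
#' @export
nErrors <- function(report) sum(report@issues$severity == "ERROR")

#' @rdname ValidationReport-class
#' @export
nWarnings <- function(report) sum(report@issues$severity == "WARNING")

setMethod("show", "ValidationReport", function(object) {
    cat("ValidationReport (", object@mode, " mode): ",
        nErrors(object), " error(s), ", nWarnings(object),
        " warning(s)\n", sep = "")
    if (nrow(object@issues)) {
        for (i in seq_len(nrow(object@issues)))
            cat(sprintf("  [%s] %s: %s\n", object@issues$severity[i],
                        object@issues$rule[i], object@issues$message[i]))
    }
})

#' Validate an ontology model
#'
#' Runs [checkRelation()] over every class-level assertion of the model
#' (assertions touching obsolete classes are skipped), adds
#' `UNTYPED_CLASS` warnings for non-obsolete classes declared `UNKNOWN`,
#' `RECIPROCITY` warnings for integral part assertions lacking the
#' mirrored part assertion, and — when the model carries instances — the
#' all/some findings of [checkAllSome()].  Issues are reported in a
#' deterministic order (rule id, then subject), so validation is
#' independent of assertion insertion order.
#'
#' @inheritParams checkRelation
#' @param checkInstances Include the instance-level all/some check
#'   (default TRUE).
#' @return A [ValidationReport].
#' @examples
#' validateModel(proFragment())            # clean
#' validateModel(goRootFragment())         # untyped root warning
#' @export
validateModel <- function(model, mode = "STRICT",
                          isaParity = c("parity", "subsumption"),
                          checkInstances = TRUE) {
    mode <- .check_mode(mode)
    isaParity <- match.arg(isaParity)
    rel <- .active_relations(model)
    issues <- .no_issues()
    for (i in seq_len(nrow(rel)))
        issues <- rbind(issues,
                        checkRelation(model, rel$kind[i], rel$source[i],
                                      rel$target[i], mode = mode,
                                      isaParity = isaParity))

    cl <- .active_classes(model)
    untyped <- cl$id[cl$kind == "UNKNOWN"]
    for (id in untyped)
        issues <- rbind(issues, .issue("UNTYPED_CLASS", "WARNING", id,
            paste0("class ", id, " (", className(model, id),
                   ") carries no continuant/process stereotype")))

    ## integral part variants expect the mirrored assertion
    mirror <- c(integral_part_of = "has_integral_part",
                has_integral_part = "integral_part_of")
    for (i in seq_len(nrow(rel))) {
        k <- rel$kind[i]
        if (!k %in% names(mirror)) next
        m <- mirror[[k]]
        ## the reciprocal may be asserted as the integral mirror or as the
        ## plain part_of/has_part association it is represented by
        plain <- if (m == "has_integral_part") c(m, "has_part")
                 else c(m, "part_of")
        has_recip <- any(rel$kind %in% plain &
                         rel$source == rel$target[i] &
                         rel$target == rel$source[i])
        if (!has_recip)
            issues <- rbind(issues, .issue("RECIPROCITY", "WARNING",
                .subject_of(k, rel$source[i], rel$target[i]),
                paste0(k, " expects the reciprocal ", m,
                       " (or plain part) assertion from ", rel$target[i],
                       " back to ", rel$source[i])))
    }

    if (checkInstances && nrow(model@instances))
        issues <- rbind(issues, checkAllSome(model))

    .make_report(issues, mode)
}

## ---- validity matrix ------------------------------------------------------

#' Valid endpoint-kind pairs of a relation
#'
#' Enumerates the 16 ordered pairs of declarable kinds, builds for each a
#' minimal two-class model carrying the assertion, and returns the pairs
#' that validate with no issues — the relation's validity matrix over
#' generic source/target classes.
#'
#' @param kind A class-level relation kind.
#' @param mode Checking mode, `"STRICT"` by default.
#' @return A data.frame with columns `source`, `target` (kinds), one row
#'   per valid pair, in fixed kind order.
#' @examples
#' nrow(validKindPairs("is_a"))       # 4
#' nrow(validKindPairs("part_of"))    # 7
#' nrow(validKindPairs("has_agent"))  # 1
#' @export
validKindPairs <- function(kind, mode = "STRICT") {
    kind <- normalizeRelationName(kind)
    if (kind == "instance_of")
        stop("instance_of has no class-level validity matrix",
             call. = FALSE)
    mode <- .check_mode(mode)
    key <- paste(kind, mode, sep = "/")
    cached <- .vkp_cache[[key]]
    if (!is.null(cached)) return(cached)
    kinds <- declarableKinds()
    out <- data.frame(source = character(), target = character(),
                      stringsAsFactors = FALSE)
    for (sk in kinds) for (tk in kinds) {
        m <- addClass(OntologyModel(), "A", "A", sk)
        m <- addClass(m, "B", "B", tk)
        iss <- checkRelation(m, kind, "A", "B", mode = mode)
        if (!nrow(iss))
            out <- rbind(out, data.frame(source = sk, target = tk,
                                         stringsAsFactors = FALSE))
    }
    if (.is_registry_kind(kind)) .vkp_cache[[key]] <- out
    out
}

## memo cache for validity matrices (42 keys at most)
.vkp_cache <- new.env(parent = emptyenv())

## ---- all/some -------------------------------------------------------------

#' Instance-level all/some check
#'
#' The Relation Ontology defines class-level relations by the all/some
#' rule: `R(C, C1)` holds iff *every* instance of `C` bears an
#' instance-level `R` link to *some* instance of `C1`.  For each
#' class-level assertion of an association-based kind (everything but
#' `is_a` and `instance_of`), every instance of the source class must have
#' at least one link of that kind to an instance of the target class; each
#' uncovered instance yields one `ALL_SOME` error.  Instance links are
#' also endpoint-checked: a link whose kind, applied to the linked
#' instances' classes, has no matching class-level assertion between those
#' classes is not used as coverage.
#'
#' With no instances the check is vacuous and returns no issues.
#'
#' @param model An [OntologyModel] with instances and links.
#' @return A data.frame of `ALL_SOME` issues (zero rows when satisfied).
#' @examples
#' m <- addClass(OntologyModel(), "A", "part", "MATERIAL")
#' m <- addClass(m, "B", "whole", "MATERIAL")
#' m <- addRelation(m, "part_of", "A", "B")
#' m <- addInstance(m, "a1", "A"); m <- addInstance(m, "a2", "A")
#' m <- addInstance(m, "b1", "B")
#' m <- addInstanceLink(m, "part_of", "a1", "b1")
#' checkAllSome(m)    # a2 is uncovered
#' @export
checkAllSome <- function(model) {
    issues <- .no_issues()
    inst <- model@instances
    if (!nrow(inst)) return(issues)
    lnk <- model@links
    rel <- .active_relations(model)
    inst_class <- stats::setNames(inst$class_id, inst$id)

    ## endpoint-check each link against the declared kinds of the linked
    ## instances' classes
    for (i in seq_len(nrow(lnk))) {
        iss <- checkRelation(model, lnk$kind[i],
                             inst_class[[lnk$source[i]]],
                             inst_class[[lnk$target[i]]], mode = "STRICT")
        ## at the instance level irreflexivity is about distinct
        ## instances, not distinct classes
        iss <- iss[iss$rule != "IRREFLEXIVE", , drop = FALSE]
        if (endpointRule(lnk$kind[i])$irreflexive &&
            lnk$source[i] == lnk$target[i])
            iss <- rbind(iss, .issue("IRREFLEXIVE", "ERROR", "",
                paste0(lnk$kind[i], " link from instance ", lnk$source[i],
                       " to itself")))
        if (nrow(iss)) {
            iss$subject <- paste0(lnk$kind[i], "(", lnk$source[i], ", ",
                                  lnk$target[i], ")")
            issues <- rbind(issues, iss)
        }
    }

    assoc <- rel[rel$kind != "is_a", , drop = FALSE]
    for (i in seq_len(nrow(assoc))) {
        k <- assoc$kind[i]; C <- assoc$source[i]; C1 <- assoc$target[i]
        members <- inst$id[inst$class_id == C]
        targets <- inst$id[inst$class_id == C1]
        for (c_i in members) {
            covered <- any(lnk$kind == k & lnk$source == c_i &
                           lnk$target %in% targets)
            if (!covered)
                issues <- rbind(issues, .issue("ALL_SOME", "ERROR",
                    paste0(k, "(", C, ", ", C1, ")/", c_i),
                    paste0("instance ", c_i, " of ", C, " has no ", k,
                           " link to any instance of ", C1,
                           " (all/some rule)")))
        }
    }
    issues
}
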