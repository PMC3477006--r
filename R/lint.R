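## Lint rules: advisory findings about ontology style defects that are
## not constraint violations.  Lint never mutates the model; every
## suggestion is a textual refactoring proposal.

.lint_finding <- function(rule, subject, suggestion) {
    data.frame(rule = rule, subject = subject, suggestion = suggestion,
               stringsAsFactors = FALSE)
}
.no_findings <- function() .lint_finding(character(), character(),
                                         character())

#' Detect multiple inheritance
#'
#' Flags every class with two or more outgoing `is_a` assertions.
#' Multiple inheritance overloads the meaning of `is_a` within one
#' ontology and hinders automatic concept alignment across ontologies; in
#' many cases one of the `is_a` assertions can be replaced by a
#' `contributes_to` relation (contribution to the achievement of an end),
#' which the suggestion proposes.  `contributes_to` is an extension
#' relation outside the Relation Ontology inventory.
#'
#' @param model An [OntologyModel].
#' @return A data.frame of findings with columns `rule`
#'   (`MULTIPLE_INHERITANCE`), `subject` (the class id) and `suggestion`;
#'   zero rows for a tree-shaped is_a hierarchy.
#' @examples
#' findMultipleInheritance(goMiFragment())   # two findings
#' findMultipleInheritance(proFragment())    # none
#' @export
findMultipleInheritance <- function(model) {
    rel <- .active_relations(model)
    isa <- rel[rel$kind == "is_a", , drop = FALSE]
    out <- .no_findings()
    if (!nrow(isa)) return(out)
    deg <- table(isa$source)
    multi <- sort(names(deg)[deg >= 2L])
    for (id in multi) {
        parents <- sort(isa$target[isa$source == id])
        out <- rbind(out, .lint_finding("MULTIPLE_INHERITANCE", id,
            paste0(className(model, id), " (", id, ") specializes ",
                   length(parents), " classes through separate is_a ",
                   "relations (",
                   paste(className(model, parents), collapse = "; "),
                   "); consider replacing one is_a with a contributes_to ",
                   "relation (non-Relation-Ontology extension)")))
    }
    out
}

.normalize_label <- function(x) {
    tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

#' Detect relation-embedded term names
#'
#' Flags classes whose name has the form `"<X> <pattern> <Y>"` where both
#' `X` and `Y` are (case- and whitespace-insensitively) the names of other
#' classes in the model — for example a term named
#' `"Cell-Cell Signaling Involved in Cell Fate Commitment"` in a model
#' that also contains `"Cell-Cell Signaling"` and
#' `"Cell Fate Commitment"`.  Such a name embeds a relation between two
#' existing concepts in a term label; the suggestion proposes relating the
#' two named classes directly (e.g. with an `involved_in` extension
#' relation) instead.  Both name parts must resolve to classes of the
#' model; matching is exact after case/whitespace normalization, so
#' partial matches never produce a finding.
#'
#' @param model An [OntologyModel].
#' @param patterns Non-empty character vector of connector phrases;
#'   default `"involved in"`.
#' @return A data.frame of findings with columns `rule`
#'   (`EMBEDDED_RELATION_NAME`), `subject` and `suggestion`.
#' @examples
#' findEmbeddedRelationNames(goMiFragment())
#' @export
findEmbeddedRelationNames <- function(model, patterns = "involved in") {
    if (!is.character(patterns) || !length(patterns) ||
        any(!nzchar(trimws(patterns))))
        stop("'patterns' must be a non-empty character vector of ",
             "non-blank phrases", call. = FALSE)
    cl <- .active_classes(model)
    out <- .no_findings()
    if (!nrow(cl)) return(out)
    norm <- .normalize_label(cl$name)
    for (i in seq_len(nrow(cl))) {
        for (pat in .normalize_label(patterns)) {
            sep <- paste0(" ", pat, " ")
            hit <- regexpr(sep, norm[i], fixed = TRUE)
            if (hit < 0L) next
            x <- substr(norm[i], 1L, hit - 1L)
            y <- substr(norm[i], hit + attr(hit, "match.length"),
                        nchar(norm[i]))
            xi <- which(norm == x & cl$id != cl$id[i])
            yi <- which(norm == y & cl$id != cl$id[i])
            if (length(xi) && length(yi)) {
                out <- rbind(out, .lint_finding("EMBEDDED_RELATION_NAME",
                    cl$id[i],
                    paste0("name of ", cl$id[i], " embeds the relation '",
                           pat, "' between ", cl$id[xi[1L]], " (",
                           cl$name[xi[1L]], ") and ", cl$id[yi[1L]], " (",
                           cl$name[yi[1L]], "); consider relating these ",
                           "two classes directly, e.g. with an ",
                           "involved_in extension relation")))
            }
        }
    }
    out
}

#' Relation usage statistics
#'
#' Counts the model's class-level assertions per relation kind and the
#' fraction of assertions whose kind falls in a caller-given subset (e.g.
#' the fraction of an ontology covered by `is_a` and `part_of`).
#'
#' @param model An [OntologyModel].
#' @param subset Character vector of relation kinds for the fraction;
#'   names are normalized.
#' @return A list with elements `counts` (named integer vector over the
#'   kinds present, plus total), `total`, `subset_fraction` (in `[0, 1]`;
#'   `0` for an empty model) and `defined` (`FALSE` when the model has no
#'   assertions, so the fraction is vacuous).
#' @examples
#' relationUsageStats(xaoFragment(), subset = c("is_a", "part_of"))
#' @export
relationUsageStats <- function(model, subset = character()) {
    rel <- modelRelations(model)
    subset <- normalizeRelationName(subset)
    tab <- table(rel$kind)
    counts <- stats::setNames(as.integer(tab), names(tab))
    if (length(counts)) counts <- counts[order(names(counts))]
    total <- nrow(rel)
    frac <- if (total) sum(rel$kind %in% subset) / total else 0
    list(counts = counts, total = total, subset_fraction = frac,
         defined = total > 0L)
}
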