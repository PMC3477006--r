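## JSON and text rendering of validation, inference and lint results.
## The JSON schema is versioned; rule ids are the stable, documented
## vocabulary of the constraint engine and lint advisor.

.REPORT_SCHEMA_VERSION <- "1"

#' Rule id vocabulary
#'
#' The closed set of rule identifiers that can appear in reports:
#' validation rules `ENDPOINT_KIND`, `SAME_BRANCH`, `CONDITIONAL_KIND`,
#' `IRREFLEXIVE` (errors), `UNTYPED_CLASS`, `RECIPROCITY` (warnings),
#' `ALL_SOME` (instance-level error), `UNSATISFIABLE_KIND` (inference
#' error), and lint rules `MULTIPLE_INHERITANCE`,
#' `EMBEDDED_RELATION_NAME`.
#'
#' @return Character vector of rule ids.
#' @export
ruleIds <- function() {
    c("ENDPOINT_KIND", "SAME_BRANCH", "CONDITIONAL_KIND", "IRREFLEXIVE",
      "UNTYPED_CLASS", "RECIPROCITY", "ALL_SOME", "UNSATISFIABLE_KIND",
      "MULTIPLE_INHERITANCE", "EMBEDDED_RELATION_NAME")
}

#' Render a validation report, lint findings and inference as JSON
#'
#' Builds a versioned JSON document combining any of: a
#' [ValidationReport] (issues and per-rule counts), lint findings (from
#' [findMultipleInheritance()] / [findEmbeddedRelationNames()], kept in a
#' section separate from validation issues), and a [KindAssignment]
#' (inferred kinds, unsatisfiable classes with their provenance chains).
#'
#' @param report Optional [ValidationReport].
#' @param lint Optional data.frame of lint findings.
#' @param assignment Optional [KindAssignment].
#' @param stats Optional list from [relationUsageStats()].
#' @param pretty Pretty-print the JSON.
#' @return A JSON string (class `json`).
#' @examples
#' reportJSON(report = validateModel(proFragment()))
#' @export
reportJSON <- function(report = NULL, lint = NULL, assignment = NULL,
                       stats = NULL, pretty = TRUE) {
    out <- list(schema_version = .REPORT_SCHEMA_VERSION)
    if (!is.null(report))
        out$validation <- list(
            mode = report@mode,
            n_errors = nErrors(report),
            n_warnings = nWarnings(report),
            counts = as.list(report@counts),
            issues = issues(report))
    if (!is.null(lint))
        out$lint <- list(n_findings = nrow(lint), findings = lint)
    if (!is.null(assignment)) {
        bot <- sort(names(assignment@kinds)[assignment@kinds == "BOTTOM"])
        out$inference <- list(
            kinds = as.list(assignment@kinds),
            unsatisfiable = lapply(stats::setNames(bot, bot), function(id)
                list(rule = "UNSATISFIABLE_KIND",
                     provenance = assignment@provenance[[id]])))
    }
    if (!is.null(stats))
        out$stats <- list(counts = as.list(stats$counts),
                          total = stats$total,
                          subset_fraction = stats$subset_fraction,
                          defined = stats$defined)
    jsonlite::toJSON(out, auto_unbox = TRUE, pretty = pretty, digits = NA)
}

#' Render a validation report as plain text
#'
#' @param report A [ValidationReport].
#' @return Character vector of lines.
#' @export
reportText <- function(report) {
    head <- sprintf("validation (%s mode): %d error(s), %d warning(s)",
                    tolower(report@mode), nErrors(report),
                    nWarnings(report))
    iss <- issues(report)
    c(head, sprintf("  [%s] %s %s: %s", iss$severity, iss$rule,
                    iss$subject, iss$message))
}
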