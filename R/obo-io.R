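## Reader/writer for a subset of the OBO flat file format (1.2-style
## syntax): header tag-value lines, [Term] stanzas with id, name, is_a,
## relationship and is_obsolete tags.  Other tags are preserved verbatim
## and uninterpreted so that unknown content round-trips.  Entity-class
## kinds, which the OBO format has no slot for, are carried in reserved
## "property_value: oborel:kind <KIND>" lines.

#' @title Parsed OBO document
#'
#' @description Intermediate representation of an OBO flat file: the
#' header tag-value pairs and one record per `[Term]` stanza (`id`,
#' `name`, `is_a` targets, `relationship` pairs, `is_obsolete`, declared
#' kind if annotated, and any other lines preserved verbatim in order).
#' Produced by [parseObo()] and consumed by [toModel()].
#'
#' @slot header named list of header tag values.
#' @slot terms list of term records.
#' @name OboDocument-class
#' @aliases OboDocument
#' @exportClass OboDocument
setClass("OboDocument",
    representation(header = "list", terms = "list"),
    prototype(header = list(), terms = list()))

setMethod("show", "OboDocument", function(object) {
    cat("OboDocument with", length(object@terms), "term stanza(s)\n")
})

#' @rdname OboDocument-class
#' @param doc An `OboDocument`.
#' @export
oboTerms <- function(doc) doc@terms

#' @rdname OboDocument-class
#' @export
oboHeader <- function(doc) doc@header

## strip trailing "! comment" and "{...}" qualifier blocks from a value
.strip_trailers <- function(x) {
    x <- sub("\\s*!.*$", "", x)
    x <- sub("\\s*\\{[^}]*\\}\\s*$", "", x)
    trimws(x)
}

.KIND_PROPERTY <- "oborel:kind"

#' Parse an OBO flat file
#'
#' Reads OBO text (a file path or a character vector of lines) into an
#' [OboDocument].  Recognized term tags are `id`, `name`, `is_a`,
#' `relationship`, `is_obsolete` and the reserved
#' `property_value: oborel:kind` annotation; all other lines are
#' preserved verbatim.  Relation names are normalized to lowercase
#' underscored form (`derives-from` to `derives_from`).  Trailing
#' `! comments` and `{qualifier}` blocks are stripped.  Stanza types
#' other than `[Term]` are ignored.
#'
#' @param x A file path, or a character vector of lines (anything of
#'   length > 1, or containing a newline, is treated as content).
#' @return An [OboDocument].
#' @examples
#' doc <- parseObo(c("[Term]", "id: X:1", "name: NF stage 7",
#'                   "relationship: part_of X:2"))
#' oboTerms(doc)[[1]]$relationships
#' @export
parseObo <- function(x) {
    if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
        lines <- readLines(x, warn = FALSE)
    else
        lines <- unlist(strsplit(x, "\r?\n"), use.names = FALSE)
    lines <- sub("\r$", "", lines)

    header <- list()
    terms <- list()
    cur <- NULL
    in_term <- FALSE
    in_other_stanza <- FALSE

    new_term <- function() {
        list(id = NA_character_, name = NA_character_,
             is_a = character(),
             relationships = data.frame(kind = character(),
                                        target = character(),
                                        stringsAsFactors = FALSE),
             obsolete = FALSE, kind = "UNKNOWN", other = character())
    }
    flush_term <- function() {
        if (!is.null(cur)) {
            if (is.na(cur$id))
                stop("OBO format error: [Term] stanza without an id line",
                     call. = FALSE)
            if (cur$id %in% vapply(terms, `[[`, "", "id"))
                stop("OBO format error: duplicate term id: ", cur$id,
                     call. = FALSE)
            terms[[length(terms) + 1L]] <<- cur
        }
        cur <<- NULL
    }

    for (raw in lines) {
        line <- trimws(raw)
        if (grepl("^\\[.*\\]$", line)) {
            flush_term()
            in_term <- identical(line, "[Term]")
            in_other_stanza <- !in_term
            if (in_term) cur <- new_term()
            next
        }
        if (!nzchar(line) || in_other_stanza) next
        if (!in_term) {
            ## header tag-value line
            m <- regexpr(":", line, fixed = TRUE)
            if (m > 0L)
                header[[substr(line, 1L, m - 1L)]] <-
                    trimws(substr(line, m + 1L, nchar(line)))
            next
        }
        m <- regexpr(":", line, fixed = TRUE)
        if (m < 0L) { cur$other <- c(cur$other, raw); next }
        tag <- substr(line, 1L, m - 1L)
        val <- trimws(substr(line, m + 1L, nchar(line)))
        if (tag == "id") {
            cur$id <- .strip_trailers(val)
        } else if (tag == "name") {
            cur$name <- .strip_trailers(val)
        } else if (tag == "is_a") {
            cur$is_a <- c(cur$is_a, .strip_trailers(val))
        } else if (tag == "relationship") {
            val <- .strip_trailers(val)
            parts <- strsplit(val, "[[:space:]]+")[[1]]
            if (length(parts) < 2L)
                stop("OBO format error: relationship line without a ",
                     "target: ", raw, call. = FALSE)
            cur$relationships <- rbind(cur$relationships, data.frame(
                kind = normalizeRelationName(parts[1L]),
                target = parts[2L], stringsAsFactors = FALSE))
        } else if (tag == "is_obsolete") {
            cur$obsolete <- identical(tolower(.strip_trailers(val)),
                                      "true")
        } else if (tag == "property_value" &&
                   startsWith(val, .KIND_PROPERTY)) {
            k <- toupper(.strip_trailers(sub(.KIND_PROPERTY, "", val,
                                             fixed = TRUE)))
            if (!k %in% c(declarableKinds(), "UNKNOWN"))
                stop("OBO format error: unknown kind annotation: ", k,
                     call. = FALSE)
            cur$kind <- k
        } else {
            cur$other <- c(cur$other, raw)
        }
    }
    flush_term()
    new("OboDocument", header = header, terms = terms)
}

#' Build an ontology model from a parsed OBO document
#'
#' Turns the `[Term]` stanzas of an [OboDocument] into an
#' [OntologyModel]: `is_a` lines become `is_a` assertions, `relationship`
#' lines with Relation Ontology names become typed assertions, and
#' relationship lines with names outside the inventory become extension
#' assertions accompanied by a warning note.  Kinds default to `UNKNOWN`
#' unless annotated in the file or supplied via `kindAnnotations`.
#' Assertions whose target id does not resolve are collected as
#' resolution warnings rather than failing the load; no relationship line
#' is ever silently dropped.
#'
#' @param doc An [OboDocument].
#' @param kindAnnotations Optional named character vector mapping term
#'   ids to kinds; overrides kinds annotated in the file.
#' @return An [OntologyModel]; load warnings (dangling targets,
#'   non-inventory relation names, duplicate triples) are in
#'   `modelMetadata(model)$load_warnings`.
#' @examples
#' doc <- parseObo(oboFixtureFile("xao_fragment.obo"))
#' m <- toModel(doc)
#' nRelations(m)
#' @export
toModel <- function(doc, kindAnnotations = NULL) {
    model <- OntologyModel(metadata = doc@header)
    warnings <- character()
    for (tm in doc@terms) {
        kind <- tm$kind
        if (!is.null(kindAnnotations) && tm$id %in% names(kindAnnotations))
            kind <- kindAnnotations[[tm$id]]
        model <- addClass(model, tm$id,
                          if (is.na(tm$name)) tm$id else tm$name,
                          kind = kind, obsolete = tm$obsolete)
    }
    ids <- classIds(model)
    for (tm in doc@terms) {
        edges <- rbind(
            if (length(tm$is_a))
                data.frame(kind = "is_a", target = tm$is_a,
                           stringsAsFactors = FALSE),
            tm$relationships[, c("kind", "target"), drop = FALSE])
        for (i in seq_len(NROW(edges))) {
            k <- edges$kind[i]; tgt <- edges$target[i]
            if (!tgt %in% ids) {
                warnings <- c(warnings, paste0(
                    "dangling target in ", k, " line of ", tm$id, ": ",
                    tgt))
                next
            }
            if (!.is_registry_kind(k))
                warnings <- c(warnings, paste0(
                    "non-Relation-Ontology relation '", k, "' on ",
                    tm$id, " kept as extension assertion"))
            rel <- model@relations
            if (any(rel$kind == k & rel$source == tm$id &
                    rel$target == tgt)) {
                warnings <- c(warnings, paste0(
                    "duplicate assertion ignored: ", k, "(", tm$id, ", ",
                    tgt, ")"))
                next
            }
            model <- addRelation(model, k, tm$id, tgt)
        }
    }
    model@metadata$load_warnings <- warnings
    model
}

#' @rdname model-accessors
#' @export
modelMetadata <- function(model) model@metadata

#' Read an OBO file straight into a model
#'
#' Convenience composition of [parseObo()] and [toModel()].
#'
#' @inheritParams parseObo
#' @inheritParams toModel
#' @return An [OntologyModel].
#' @export
readObo <- function(x, kindAnnotations = NULL) {
    toModel(parseObo(x), kindAnnotations = kindAnnotations)
}

#' Serialize a model to OBO text
#'
#' Writes the model as OBO flat-file text with one `[Term]` stanza per
#' class in sorted id order (so output is deterministic), `is_a` and
#' `relationship` lines in sorted order, and declared kinds emitted as
#' reserved `property_value: oborel:kind` annotation lines.  Parsing the
#' output back with [readObo()] reconstructs a structurally equal model.
#'
#' @param model An [OntologyModel].
#' @param file Optional path; when given the text is written there (LF
#'   line endings) and the path is returned invisibly.
#' @return Character vector of lines, or the path invisibly.
#' @examples
#' cat(head(writeObo(proFragment()), 8), sep = "\n")
#' @export
writeObo <- function(model, file = NULL) {
    lines <- c("format-version: 1.2")
    nm <- model@metadata[["ontology"]]
    if (!is.null(nm)) lines <- c(lines, paste0("ontology: ", nm))
    cl <- model@classes[order(model@classes$id), , drop = FALSE]
    rel <- model@relations
    for (i in seq_len(nrow(cl))) {
        id <- cl$id[i]
        lines <- c(lines, "", "[Term]", paste0("id: ", id),
                   paste0("name: ", cl$name[i]))
        isa <- sort(rel$target[rel$kind == "is_a" & rel$source == id])
        lines <- c(lines, if (length(isa)) paste0("is_a: ", isa))
        oth <- rel[rel$kind != "is_a" & rel$source == id, , drop = FALSE]
        if (nrow(oth)) {
            oth <- oth[order(oth$kind, oth$target), , drop = FALSE]
            lines <- c(lines, paste0("relationship: ", oth$kind, " ",
                                     oth$target))
        }
        if (cl$kind[i] != "UNKNOWN")
            lines <- c(lines, paste0("property_value: ", .KIND_PROPERTY,
                                     " ", cl$kind[i]))
        if (cl$obsolete[i]) lines <- c(lines, "is_obsolete: true")
    }
    if (!is.null(file)) {
        writeLines(lines, file, sep = "\n")
        return(invisible(file))
    }
    lines
}

## ---- instance sidecar -----------------------------------------------------

.SIDECAR_HEADER <- "# oborel-instances v1"

#' Read and write the instance sidecar format
#'
#' Instance-level data (instance declarations and instance links) travels
#' in a small tab-separated sidecar file, since the OBO term stanza
#' format has no instance records.  The format, version 1, is: a comment
#' header line `# oborel-instances v1`, then one record per line — either
#' `instance <TAB> <instance id> <TAB> <class id>` or
#' `link <TAB> <relation kind> <TAB> <source instance> <TAB> <target
#' instance>`.  Blank lines and `#` comments are ignored.
#'
#' `readInstances()` adds the records to an existing model (so class ids
#' can be resolved); `writeInstances()` serializes a model's instances
#' and links deterministically.
#'
#' @param model An [OntologyModel].
#' @param x A file path or character vector of lines.
#' @param file Optional output path.
#' @return `readInstances()` the extended model; `writeInstances()` lines
#'   or the path invisibly.
#' @examples
#' m <- addClass(OntologyModel(), "A", "part", "MATERIAL")
#' m <- addClass(m, "B", "whole", "MATERIAL")
#' m <- addInstance(m, "a1", "A"); m <- addInstance(m, "b1", "B")
#' m <- addInstanceLink(m, "part_of", "a1", "b1")
#' writeInstances(m)
#' @export
readInstances <- function(model, x) {
    if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
        lines <- readLines(x, warn = FALSE)
    else
        lines <- unlist(strsplit(x, "\r?\n"), use.names = FALSE)
    lines <- trimws(sub("\r$", "", lines))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (line in lines) {
        f <- strsplit(line, "\t", fixed = TRUE)[[1]]
        if (f[1L] == "instance" && length(f) == 3L)
            model <- addInstance(model, f[2L], f[3L])
        else if (f[1L] == "link" && length(f) == 4L)
            model <- addInstanceLink(model, f[2L], f[3L], f[4L])
        else
            stop("instance sidecar format error: ", line, call. = FALSE)
    }
    model
}

#' @rdname readInstances
#' @export
writeInstances <- function(model, file = NULL) {
    inst <- .sort_df(model@instances)
    lnk <- .sort_df(model@links)
    lines <- c(.SIDECAR_HEADER,
               if (nrow(inst)) paste("instance", inst$id, inst$class_id,
                                     sep = "\t"),
               if (nrow(lnk)) paste("link", lnk$kind, lnk$source,
                                    lnk$target, sep = "\t"))
    if (!is.null(file)) {
        writeLines(lines, file, sep = "\n")
        return(invisible(file))
    }
    lines
}

#' Path to a packaged ontology fixture file
#'
#' The worked ontology fragments are also shipped as OBO files (with kind
#' annotation lines) under the package's `extdata` directory, so the I/O
#' layer can be exercised on them.
#'
#' @param name File name, e.g. `"pro_fragment.obo"`; with no argument,
#'   lists the available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' oboFixtureFile()
#' readObo(oboFixtureFile("pro_fragment.obo"))
#' @export
oboFixtureFile <- function(name = NULL) {
    dir <- system.file("extdata", package = "oborel")
    if (is.null(name)) return(list.files(dir))
    path <- file.path(dir, name)
    if (!file.exists(path))
        stop("no packaged fixture file: ", name, call. = FALSE)
    path
}
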