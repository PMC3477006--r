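## OntologyModel: a directed multigraph of typed entity classes with
## class-level relation assertions and (optionally) instances and
## instance-level links.

.empty_classes <- function() {
    data.frame(id = character(), name = character(), kind = character(),
               obsolete = logical(), stringsAsFactors = FALSE)
}
.empty_relations <- function() {
    data.frame(kind = character(), source = character(),
               target = character(), stringsAsFactors = FALSE)
}
.empty_instances <- function() {
    data.frame(id = character(), class_id = character(),
               stringsAsFactors = FALSE)
}

#' @title Ontology model of typed entity classes and relation assertions
#'
#' @description An `OntologyModel` holds a fragment of a biomedical
#' ontology as a typed graph: entity classes (each with an identifier, a
#' label, a declared kind from the continuant/process lattice, and an
#' obsolescence flag), class-level relation assertions (directed
#' `kind(source, target)` triples with set semantics), and optionally
#' instance declarations plus instance-level links used by the all/some
#' check.
#'
#' Models are value objects: `addClass()` and friends return a modified
#' copy.  Relation direction follows the Relation Ontology reading:
#' `part_of(A, B)` states that every instance of `A` is part of some
#' instance of `B`.
#'
#' @slot classes data.frame with columns `id`, `name`, `kind`, `obsolete`.
#' @slot relations data.frame with columns `kind`, `source`, `target`.
#' @slot instances data.frame with columns `id`, `class_id`.
#' @slot links data.frame with columns `kind`, `source`, `target`
#'   (instance identifiers).
#' @slot metadata list of free-form header fields (e.g. from an OBO file).
#'
#' @examples
#' m <- OntologyModel()
#' m <- addClass(m, "X:1", "cell", "MATERIAL")
#' m <- addClass(m, "X:2", "cell part", "MATERIAL")
#' m <- addRelation(m, "part_of", "X:2", "X:1")
#' m
#' @name OntologyModel-class
#' @aliases OntologyModel
#' @export OntologyModel
#' @exportClass OntologyModel
setClass("OntologyModel",
    representation(classes = "data.frame", relations = "data.frame",
                   instances = "data.frame", links = "data.frame",
                   metadata = "list"),
    prototype(classes = .empty_classes(), relations = .empty_relations(),
              instances = .empty_instances(), links = .empty_relations(),
              metadata = list()))

setValidity("OntologyModel", function(object) {
    msg <- character()
    cl <- object@classes
    if (anyDuplicated(cl$id))
        msg <- c(msg, "duplicate class ids")
    if (any(!cl$kind %in% c(declarableKinds(), "UNKNOWN")))
        msg <- c(msg, "class kind must be declarable or UNKNOWN")
    rel <- object@relations
    if (nrow(rel)) {
        if (!all(c(rel$source, rel$target) %in% cl$id))
            msg <- c(msg, "relation endpoint does not resolve to a class")
        if (anyDuplicated(rel[c("kind", "source", "target")]))
            msg <- c(msg, "duplicate relation triple")
    }
    inst <- object@instances
    if (nrow(inst)) {
        if (anyDuplicated(inst$id))
            msg <- c(msg, "duplicate instance ids")
        if (!all(inst$class_id %in% cl$id))
            msg <- c(msg, "instance class_id does not resolve to a class")
    }
    lnk <- object@links
    if (nrow(lnk) && !all(c(lnk$source, lnk$target) %in% inst$id))
        msg <- c(msg, "instance link endpoint does not resolve")
    if (length(msg)) msg else TRUE
})

#' @rdname OntologyModel-class
#' @param metadata list of free-form header fields.
#' @export
OntologyModel <- function(metadata = list()) {
    new("OntologyModel", metadata = metadata)
}

setMethod("show", "OntologyModel", function(object) {
    cat("OntologyModel with", nrow(object@classes), "classes,",
        nrow(object@relations), "relation assertions,",
        nrow(object@instances), "instances,",
        nrow(object@links), "instance links\n")
    if (nrow(object@classes)) {
        tab <- table(object@classes$kind)
        cat("  kinds:", paste(names(tab), tab, sep = "=", collapse = ", "),
            "\n")
    }
    if (nrow(object@relations)) {
        tab <- sort(table(object@relations$kind), decreasing = TRUE)
        cat("  relations:",
            paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    }
})

## ---- accessors ------------------------------------------------------------

#' Accessors for OntologyModel components
#'
#' `modelClasses()`, `modelRelations()`, `modelInstances()` and
#' `modelLinks()` return the underlying data frames; `classIds()` the class
#' identifiers; `classKind()` the declared kind of one class; `className()`
#' its label; `nClasses()` and `nRelations()` the component sizes.
#'
#' @param model An [OntologyModel].
#' @param id A class identifier.
#' @return Data frames, character vectors or counts as described.
#' @examples
#' m <- proFragment()
#' nClasses(m)
#' classKind(m, classIds(m)[1])
#' head(modelRelations(m))
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
modelClasses <- function(model) model@classes

#' @rdname model-accessors
#' @export
modelRelations <- function(model) model@relations

#' @rdname model-accessors
#' @export
modelInstances <- function(model) model@instances

#' @rdname model-accessors
#' @export
modelLinks <- function(model) model@links

#' @rdname model-accessors
#' @export
classIds <- function(model) model@classes$id

#' @rdname model-accessors
#' @export
classKind <- function(model, id) {
    i <- match(id, model@classes$id)
    if (anyNA(i)) stop("unknown class id: ",
                       paste(id[is.na(i)], collapse = ", "), call. = FALSE)
    stats::setNames(model@classes$kind[i], id)
}

#' @rdname model-accessors
#' @export
className <- function(model, id) {
    i <- match(id, model@classes$id)
    if (anyNA(i)) stop("unknown class id: ",
                       paste(id[is.na(i)], collapse = ", "), call. = FALSE)
    stats::setNames(model@classes$name[i], id)
}

#' @rdname model-accessors
#' @export
nClasses <- function(model) nrow(model@classes)

#' @rdname model-accessors
#' @export
nRelations <- function(model) nrow(model@relations)

## ---- builders -------------------------------------------------------------

#' Extend an ontology model
#'
#' `addClass()` adds an entity class; the id must be fresh.  `addRelation()`
#' adds a class-level relation assertion; both endpoints must resolve and
#' the `(kind, source, target)` triple must not already be present
#' (assertions have set semantics).  `addInstance()` declares an instance of
#' a class and `addInstanceLink()` a link between two instances, reusing a
#' class-level relation kind at the instance level.
#'
#' @param model An [OntologyModel].
#' @param id Class or instance identifier (opaque string, e.g. a CURIE).
#' @param name Human-readable label.
#' @param kind Declared kind: one of [declarableKinds()], or `"UNKNOWN"`
#'   for an unstereotyped class.
#' @param obsolete Logical obsolescence flag; obsolete classes are kept in
#'   the model but skipped by validation and inference.
#' @param source,target Class identifiers (for `addRelation`) or instance
#'   identifiers (for `addInstanceLink`).
#' @param class_id Identifier of the class an instance instantiates.
#' @return The extended model.
#' @examples
#' m <- addClass(OntologyModel(), "T:1", "TGF-Beta", "MATERIAL")
#' m <- addClass(m, "T:2", "TGF-Beta 1", "MATERIAL")
#' m <- addRelation(m, "is_a", "T:2", "T:1")
#' @export
addClass <- function(model, id, name = id, kind = "UNKNOWN",
                     obsolete = FALSE) {
    stopifnot(is.character(id), length(id) == 1L, nzchar(id))
    if (id %in% model@classes$id)
        stop("class id already present: ", id, call. = FALSE)
    if (!kind %in% c(declarableKinds(), "UNKNOWN"))
        stop("kind must be a declarable kind or UNKNOWN, got: ", kind,
             call. = FALSE)
    model@classes <- rbind(model@classes, data.frame(
        id = id, name = name, kind = kind, obsolete = obsolete,
        stringsAsFactors = FALSE))
    methods::validObject(model)
    model
}

#' @rdname addClass
#' @export
addRelation <- function(model, kind, source, target) {
    kind <- normalizeRelationName(kind)
    if (kind == "instance_of")
        stop("instance_of links an instance to a class; use addInstance()",
             call. = FALSE)
    missing_ids <- setdiff(c(source, target), model@classes$id)
    if (length(missing_ids))
        stop("relation endpoint does not resolve: ",
             paste(missing_ids, collapse = ", "), call. = FALSE)
    rel <- model@relations
    if (any(rel$kind == kind & rel$source == source & rel$target == target))
        stop("duplicate relation triple: ", kind, "(", source, ", ", target,
             ")", call. = FALSE)
    model@relations <- rbind(rel, data.frame(
        kind = kind, source = source, target = target,
        stringsAsFactors = FALSE))
    methods::validObject(model)
    model
}

#' @rdname addClass
#' @export
addInstance <- function(model, id, class_id) {
    if (id %in% model@instances$id)
        stop("instance id already present: ", id, call. = FALSE)
    if (!class_id %in% model@classes$id)
        stop("instance class does not resolve: ", class_id, call. = FALSE)
    model@instances <- rbind(model@instances, data.frame(
        id = id, class_id = class_id, stringsAsFactors = FALSE))
    methods::validObject(model)
    model
}

#' @rdname addClass
#' @export
addInstanceLink <- function(model, kind, source, target) {
    kind <- normalizeRelationName(kind)
    missing_ids <- setdiff(c(source, target), model@instances$id)
    if (length(missing_ids))
        stop("link endpoint does not resolve to an instance: ",
             paste(missing_ids, collapse = ", "), call. = FALSE)
    model@links <- rbind(model@links, data.frame(
        kind = kind, source = source, target = target,
        stringsAsFactors = FALSE))
    methods::validObject(model)
    model
}

## Non-obsolete part of a model, used by validation and inference.
.active_classes <- function(model) {
    model@classes[!model@classes$obsolete, , drop = FALSE]
}
.active_relations <- function(model) {
    obs <- model@classes$id[model@classes$obsolete]
    rel <- model@relations
    rel[!(rel$source %in% obs | rel$target %in% obs), , drop = FALSE]
}

## Structural equality used by round-trip tests: same classes (id, name,
## kind, obsolete), same assertion set, same instances/links, order
## ignored.
.sort_df <- function(df) {
    if (!nrow(df)) return(df[order(numeric(0)), , drop = FALSE])
    df <- df[do.call(order, unname(as.list(df))), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Structural equality of two ontology models
#'
#' Compares classes (id, label, kind, obsolescence), relation assertions,
#' instances and links as sets, ignoring insertion order and metadata.
#'
#' @param a,b [OntologyModel] objects.
#' @return TRUE or FALSE.
#' @export
modelEqual <- function(a, b) {
    isTRUE(all.equal(.sort_df(a@classes), .sort_df(b@classes))) &&
        isTRUE(all.equal(.sort_df(a@relations), .sort_df(b@relations))) &&
        isTRUE(all.equal(.sort_df(a@instances), .sort_df(b@instances))) &&
        isTRUE(all.equal(.sort_df(a@links), .sort_df(b@links)))
}
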