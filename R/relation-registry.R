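## The Relation Ontology inventory: 22 relations in four categories.
## instance_of is the single instance-to-class relation; all others are
## class-to-class.  Nine relations come with an inverse partner; is_a,
## instance_of, adjacent_to and transformation_of have none in the
## inventory.

.registry <- local({
    df <- rbind(
        data.frame(
            name = c("instance_of", "is_a", "part_of", "has_part",
                     "integral_part_of", "has_integral_part",
                     "proper_part_of", "has_proper_part"),
            category = "FOUNDATIONAL",
            stringsAsFactors = FALSE),
        data.frame(
            name = c("located_in", "location_of", "contained_in",
                     "contains", "adjacent_to"),
            category = "SPATIAL",
            stringsAsFactors = FALSE),
        data.frame(
            name = c("transformation_of", "derives_from", "derived_into",
                     "preceded_by", "precedes"),
            category = "TEMPORAL",
            stringsAsFactors = FALSE),
        data.frame(
            name = c("has_participant", "participates_in", "has_agent",
                     "agent_in"),
            category = "PARTICIPATION",
            stringsAsFactors = FALSE)
    )
    inv <- c(part_of = "has_part", proper_part_of = "has_proper_part",
             integral_part_of = "has_integral_part",
             located_in = "location_of", contained_in = "contains",
             derives_from = "derived_into", preceded_by = "precedes",
             has_participant = "participates_in", has_agent = "agent_in")
    inv <- c(inv, stats::setNames(names(inv), inv))
    df$level <- ifelse(df$name == "instance_of", "INSTANCE_CLASS",
                       "CLASS_CLASS")
    df$inverse <- unname(inv[df$name])
    rownames(df) <- df$name
    df
})

## Relations the paper's refactoring guidance proposes but that sit outside
## the Relation Ontology proper; loaded unconstrained and flagged as
## extensions in reports.
.extension_kinds <- c("contributes_to", "involved_in")

#' The Relation Ontology registry
#'
#' Returns the canonical inventory of the 22 Relation Ontology relations as
#' a data frame with one row per relation: its canonical underscored
#' `name`, its `category` (`FOUNDATIONAL`, `SPATIAL`, `TEMPORAL`,
#' `PARTICIPATION`), its `level` (`CLASS_CLASS`, or `INSTANCE_CLASS` for
#' `instance_of` only), and its `inverse` partner (`NA` for the four
#' relations without one).  The inverse pairing is involutive.
#'
#' @return A data.frame with columns `name`, `category`, `level`,
#'   `inverse` and 22 rows.
#' @seealso [relationInverse()], [normalizeRelationName()]
#' @examples
#' nrow(relationRegistry())                       # 22
#' table(relationRegistry()$category)
#' relationInverse("has_agent")                   # "agent_in"
#' @export
relationRegistry <- function() {
    df <- .registry
    rownames(df) <- NULL
    df
}

#' @rdname relationRegistry
#' @param kind A relation name (canonical or hyphenated form).
#' @export
relationInverse <- function(kind) {
    kind <- normalizeRelationName(kind)
    if (!kind %in% .registry$name)
        stop("unknown relation kind: ", kind, call. = FALSE)
    .registry[kind, "inverse"]
}

#' Canonicalize a relation name
#'
#' The Relation Ontology prints hyphenated relation names (`part-of`) while
#' the stereotype notation uses underscores (`part_of`); both are accepted
#' on input and the lowercase underscored form is used everywhere
#' internally and on output.  Normalization is idempotent.
#'
#' @param name Character vector of relation names.
#' @return Character vector of canonical names.
#' @examples
#' normalizeRelationName("derives-from")  # "derives_from"
#' @export
normalizeRelationName <- function(name) {
    gsub("-", "_", tolower(trimws(name)), fixed = TRUE)
}

.is_registry_kind <- function(kind) kind %in% .registry$name

.is_class_level_kind <- function(kind) {
    kind %in% .registry$name[.registry$level == "CLASS_CLASS"]
}

#' Is a relation kind part of the Relation Ontology inventory?
#'
#' Relation assertions whose kind is outside the 22-relation inventory
#' (for example `regulates`, or the proposed `contributes_to` /
#' `involved_in` refactoring relations) are retained in models as
#' *extension* relations: they carry no endpoint constraints and are
#' flagged as non-Relation-Ontology kinds in reports.
#'
#' @param kind Character vector of relation names.
#' @return Logical vector.
#' @examples
#' isRegistryKind(c("part_of", "regulates", "contributes_to"))
#' @export
isRegistryKind <- function(kind) {
    .is_registry_kind(normalizeRelationName(kind))
}
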