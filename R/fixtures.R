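## Worked ontology fragments and a random model generator with planted
## violations.  The fragment builders reconstruct, relation by relation,
## the fragments used to demonstrate the profile: a PRotein Ontology
## TGF-Beta fragment (material continuants), a Xenopus developmental-stage
## fragment (processes), the historical Gene Ontology root concept (an
## unsatisfiable concept), and a GO fragment exhibiting multiple
## inheritance and a relation-embedded term name.  Term ids are synthetic
## stable strings; labels follow the source ontologies.

.fix_model <- function(ids, names, kinds, ontology) {
    m <- OntologyModel(metadata = list(ontology = ontology))
    for (i in seq_along(ids))
        m <- addClass(m, ids[i], names[i], kinds[i])
    m
}

#' PRotein Ontology TGF-Beta fragment
#'
#' Six protein classes, all material continuants: TGF-Beta; TGF-Beta 1 (a
#' translation product of the TGFB1 gene, a subtype of TGF-Beta);
#' Proteolytic Cleavage Product; TGF-Beta 1 Proteolytic Cleavage Product
#' (a subtype of the former that `derives_from` TGF-Beta 1); TGF-Beta 1
#' Isoform 1 (a subtype of TGF-Beta 1); and TGF-Beta 1 Isoform 1 Cleaved
#' 1 (a subtype of TGF-Beta 1 Proteolytic Cleavage Product that
#' `derives_from` TGF-Beta 1 Isoform 1).  Four `is_a` plus two
#' `derives_from` assertions; strictly valid.
#'
#' @return An [OntologyModel].
#' @examples
#' nErrors(validateModel(proFragment()))   # 0
#' @export
proFragment <- function() {
    m <- .fix_model(
        ids = paste0("PRO:FIX0", 1:6),
        names = c("TGF-Beta", "TGF-Beta 1", "Proteolytic Cleavage Product",
                  "TGF-Beta 1 Proteolytic Cleavage Product",
                  "TGF-Beta 1 Isoform 1",
                  "TGF-Beta 1 Isoform 1 Cleaved 1"),
        kinds = rep("MATERIAL", 6), ontology = "pro-fragment")
    m <- addRelation(m, "is_a", "PRO:FIX02", "PRO:FIX01")
    m <- addRelation(m, "is_a", "PRO:FIX04", "PRO:FIX03")
    m <- addRelation(m, "derives_from", "PRO:FIX04", "PRO:FIX02")
    m <- addRelation(m, "is_a", "PRO:FIX05", "PRO:FIX02")
    m <- addRelation(m, "is_a", "PRO:FIX06", "PRO:FIX04")
    m <- addRelation(m, "derives_from", "PRO:FIX06", "PRO:FIX05")
    m
}

#' Xenopus developmental-stage fragment
#'
#' Ten developmental-stage classes, all processes: Xenopus Developmental
#' Stage with subtypes Unfertilized Egg, Embryonic Stage, Adult and
#' Death; Blastula and Neurula as subtypes of Embryonic Stage; and NF
#' Stages 7, 8 and 9, each `part_of` Blastula, with NF Stage 8
#' `preceded_by` NF Stage 7 and NF Stage 9 `preceded_by` NF Stage 8.
#' Six `is_a`, three `part_of` and two `preceded_by` assertions; strictly
#' valid.
#'
#' @return An [OntologyModel].
#' @examples
#' nRelations(xaoFragment())   # 11
#' @export
xaoFragment <- function() {
    m <- .fix_model(
        ids = sprintf("XAO:FIX%02d", 1:10),
        names = c("Xenopus Developmental Stage", "Unfertilized Egg",
                  "Embryonic Stage", "Adult", "Death", "Blastula",
                  "Neurula", "NF Stage 7", "NF Stage 8", "NF Stage 9"),
        kinds = rep("PROCESS", 10), ontology = "xao-fragment")
    for (sub in c("XAO:FIX02", "XAO:FIX03", "XAO:FIX04", "XAO:FIX05"))
        m <- addRelation(m, "is_a", sub, "XAO:FIX01")
    m <- addRelation(m, "is_a", "XAO:FIX06", "XAO:FIX03")
    m <- addRelation(m, "is_a", "XAO:FIX07", "XAO:FIX03")
    for (nf in c("XAO:FIX08", "XAO:FIX09", "XAO:FIX10"))
        m <- addRelation(m, "part_of", nf, "XAO:FIX06")
    m <- addRelation(m, "preceded_by", "XAO:FIX09", "XAO:FIX08")
    m <- addRelation(m, "preceded_by", "XAO:FIX10", "XAO:FIX09")
    m
}

#' Historical Gene Ontology root fragment
#'
#' The Gene Ontology once contained a root concept "Gene Ontology" with
#' Biological Process, Cellular Component and Molecular Function as its
#' `is_a` children, marking them as terminological components of the
#' ontology.  Since processes and continuants both specialize the root,
#' the root cannot be assigned any kind: it is an unsatisfiable (invalid)
#' concept, which [inferKinds()] detects by collapsing it to `BOTTOM`.
#'
#' @return An [OntologyModel] (root `UNKNOWN`; Biological Process and
#'   Molecular Function `PROCESS`; Cellular Component `CONTINUANT`).
#' @examples
#' unsatisfiableClasses(goRootFragment())
#' @export
goRootFragment <- function() {
    m <- .fix_model(
        ids = paste0("GO:FIX0", 1:4),
        names = c("Gene Ontology", "Biological Process",
                  "Cellular Component", "Molecular Function"),
        kinds = c("UNKNOWN", "PROCESS", "CONTINUANT", "PROCESS"),
        ontology = "go-root-fragment")
    for (child in c("GO:FIX02", "GO:FIX03", "GO:FIX04"))
        m <- addRelation(m, "is_a", child, "GO:FIX01")
    m
}

#' Gene Ontology multiple-inheritance fragment
#'
#' A biological-process fragment (August 2011 structure) in which
#' Cellular Developmental Process specializes both Developmental Process
#' and Cellular Process, Cell-Cell Signaling specializes both Cell
#' Communication and Signaling, and the term "Cell-Cell Signaling
#' Involved in Cell Fate Commitment" specializes Cell-Cell Signaling and
#' is `part_of` Cell Fate Commitment.  All classes are processes; the
#' fragment is constraint-clean, but lint flags the two multiple
#' inheritances and the relation-embedded term name.
#'
#' @return An [OntologyModel].
#' @examples
#' findMultipleInheritance(goMiFragment())$subject
#' @export
goMiFragment <- function() {
    m <- .fix_model(
        ids = sprintf("GO:MI%02d", 1:8),
        names = c("Developmental Process", "Cellular Process",
                  "Cellular Developmental Process", "Cell Communication",
                  "Signaling", "Cell-Cell Signaling",
                  "Cell Fate Commitment",
                  "Cell-Cell Signaling Involved in Cell Fate Commitment"),
        kinds = rep("PROCESS", 8), ontology = "go-mi-fragment")
    m <- addRelation(m, "is_a", "GO:MI03", "GO:MI01")
    m <- addRelation(m, "is_a", "GO:MI03", "GO:MI02")
    m <- addRelation(m, "is_a", "GO:MI06", "GO:MI04")
    m <- addRelation(m, "is_a", "GO:MI06", "GO:MI05")
    m <- addRelation(m, "is_a", "GO:MI08", "GO:MI06")
    m <- addRelation(m, "part_of", "GO:MI08", "GO:MI07")
    m
}

## ---- random models with planted violations -------------------------------

#' @title Random model with planted violations
#'
#' @description Result of [randomModel()]: the generated model, the
#' ground-truth list of violations inserted by construction (a data.frame
#' with columns `rule`, `kind`, `source`, `target`), and the seed.  The
#' planted list exactly enumerates the ERROR-severity issues the
#' validator is expected to find.
#'
#' @slot model the generated [OntologyModel].
#' @slot planted data.frame of planted violations.
#' @slot seed integer seed used.
#' @name PlantedModel-class
#' @aliases PlantedModel
#' @exportClass PlantedModel
setClass("PlantedModel",
    representation(model = "OntologyModel", planted = "data.frame",
                   seed = "integer"))

setMethod("show", "PlantedModel", function(object) {
    cat("PlantedModel (seed ", object@seed, "): ",
        nClasses(object@model), " classes, ",
        nRelations(object@model), " assertions, ",
        nrow(object@planted), " planted violation(s)\n", sep = "")
})

#' @rdname PlantedModel-class
#' @param x A `PlantedModel`.
#' @export
plantedModel <- function(x) x@model

#' @rdname PlantedModel-class
#' @export
plantedIssues <- function(x) x@planted

## violation templates: for each plantable rule, (relation kind, source
## kind, target kind) combinations that trigger exactly one ERROR issue
## of that rule and nothing else.  Worked out from the constraint table:
##  - ENDPOINT_KIND: break exactly one bound of a bounded relation;
##  - SAME_BRANCH: straddle the branches with a branch-coupled relation,
##    choosing kinds that fire no conditional;
##  - CONDITIONAL_KIND: a material part of a non-material whole, an
##    immaterial whole with a non-immaterial part (and mirrored), or an
##    is_a between differently specified continuants (compatible branch,
##    so only parity fires);
##  - IRREFLEXIVE: a proper part relation from a class to itself.
.violation_templates <- list(
    ENDPOINT_KIND = rbind(
        data.frame(kind = "has_agent", src = "PROCESS", tgt = "IMMATERIAL",
                   stringsAsFactors = FALSE),
        data.frame(kind = "has_agent", src = "PROCESS", tgt = "CONTINUANT"),
        data.frame(kind = "derives_from", src = "IMMATERIAL",
                   tgt = "MATERIAL"),
        data.frame(kind = "derives_from", src = "MATERIAL",
                   tgt = "CONTINUANT"),
        data.frame(kind = "preceded_by", src = "PROCESS",
                   tgt = "CONTINUANT"),
        data.frame(kind = "has_participant", src = "CONTINUANT",
                   tgt = "MATERIAL"),
        data.frame(kind = "contained_in", src = "MATERIAL",
                   tgt = "MATERIAL"),
        data.frame(kind = "located_in", src = "PROCESS",
                   tgt = "CONTINUANT")),
    SAME_BRANCH = rbind(
        data.frame(kind = "part_of", src = "PROCESS", tgt = "CONTINUANT",
                   stringsAsFactors = FALSE),
        data.frame(kind = "part_of", src = "CONTINUANT", tgt = "PROCESS"),
        data.frame(kind = "part_of", src = "IMMATERIAL", tgt = "PROCESS"),
        data.frame(kind = "has_part", src = "PROCESS", tgt = "CONTINUANT"),
        data.frame(kind = "is_a", src = "PROCESS", tgt = "CONTINUANT"),
        data.frame(kind = "is_a", src = "CONTINUANT", tgt = "PROCESS")),
    CONDITIONAL_KIND = rbind(
        data.frame(kind = "part_of", src = "MATERIAL", tgt = "CONTINUANT",
                   stringsAsFactors = FALSE),
        data.frame(kind = "part_of", src = "CONTINUANT",
                   tgt = "IMMATERIAL"),
        data.frame(kind = "has_part", src = "CONTINUANT",
                   tgt = "MATERIAL"),
        data.frame(kind = "has_part", src = "IMMATERIAL",
                   tgt = "CONTINUANT"),
        data.frame(kind = "is_a", src = "MATERIAL", tgt = "CONTINUANT"),
        data.frame(kind = "is_a", src = "CONTINUANT", tgt = "IMMATERIAL")),
    IRREFLEXIVE = rbind(
        data.frame(kind = "proper_part_of", src = "MATERIAL",
                   tgt = "MATERIAL", stringsAsFactors = FALSE),
        data.frame(kind = "proper_part_of", src = "PROCESS",
                   tgt = "PROCESS"),
        data.frame(kind = "has_proper_part", src = "IMMATERIAL",
                   tgt = "IMMATERIAL"))
)

## relation kinds the generator draws conforming assertions from: all
## class-level kinds except the integral variants (whose missing
## reciprocal assertion would add warnings unrelated to the planted
## ground truth)
.generator_kinds <- function() {
    setdiff(.registry$name[.registry$level == "CLASS_CLASS"],
            c("integral_part_of", "has_integral_part"))
}

#' Generate a random model with planted violations
#'
#' Samples `nClasses` classes with kinds drawn uniformly from the four
#' declarable kinds (each kind is guaranteed at least one class), then
#' emits `nRelations` assertions.  Each assertion is either *conforming*
#' — its endpoint kinds are drawn from [validKindPairs()] of a random
#' relation kind, so it validates cleanly — or, with probability
#' `violationRate`, *violating*: built from a template that triggers
#' exactly one ERROR issue of a named rule (`ENDPOINT_KIND`,
#' `SAME_BRANCH`, `CONDITIONAL_KIND` or `IRREFLEXIVE`).  The planted
#' violations are recorded as ground truth, so validator precision and
#' recall can be measured exactly.  Generation is reproducible from the
#' seed.
#'
#' @param nClasses Number of classes (at least 4 so every kind occurs).
#' @param nRelations Number of relation assertions.
#' @param violationRate Probability in `[0, 1]` that an assertion is a
#'   planted violation.
#' @param seed Integer seed.
#' @return A [PlantedModel].
#' @examples
#' pm <- randomModel(20, 40, violationRate = 0.25, seed = 7)
#' nrow(plantedIssues(pm))
#' @export
randomModel <- function(nClasses, nRelations, violationRate, seed) {
    if (nClasses < 4L) stop("nClasses must be at least 4", call. = FALSE)
    if (violationRate < 0 || violationRate > 1)
        stop("violationRate must be in [0, 1]", call. = FALSE)
    seed <- as.integer(seed)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)

    kinds <- c(declarableKinds(),
               sample(declarableKinds(), nClasses - 4L, replace = TRUE))
    kinds <- sample(kinds)   # shuffle so the guaranteed four are anywhere
    ids <- sprintf("RND:%04d", seq_len(nClasses))
    m <- OntologyModel(metadata = list(ontology = "random-model"))
    for (i in seq_len(nClasses))
        m <- addClass(m, ids[i], paste("random class", i), kinds[i])
    by_kind <- split(ids, kinds)

    ## precompute validity matrices once
    gk <- .generator_kinds()
    vkp <- lapply(stats::setNames(gk, gk), validKindPairs)

    planted <- data.frame(rule = character(), kind = character(),
                          source = character(), target = character(),
                          stringsAsFactors = FALSE)
    rules <- names(.violation_templates)
    tries_left <- nRelations * 50L
    n_done <- 0L
    while (n_done < nRelations && tries_left > 0L) {
        tries_left <- tries_left - 1L
        violate <- stats::runif(1) < violationRate
        if (violate) {
            rule <- sample(rules, 1L)
            tpl <- .violation_templates[[rule]]
            row <- tpl[sample(nrow(tpl), 1L), ]
            if (rule == "IRREFLEXIVE") {
                src <- sample(by_kind[[row$src]], 1L)
                tgt <- src
            } else {
                src <- sample(by_kind[[row$src]], 1L)
                tgt <- sample(by_kind[[row$tgt]], 1L)
                if (src == tgt) next
            }
        } else {
            k <- sample(gk, 1L)
            pairs <- vkp[[k]]
            row <- cbind(kind = k, pairs[sample(nrow(pairs), 1L), ])
            names(row)[2:3] <- c("src", "tgt")
            src <- sample(by_kind[[row$src]], 1L)
            tgt <- sample(by_kind[[row$tgt]], 1L)
            if (src == tgt) next
        }
        rel <- m@relations
        if (any(rel$kind == row$kind & rel$source == src &
                rel$target == tgt)) next
        m <- addRelation(m, row$kind, src, tgt)
        if (violate)
            planted <- rbind(planted, data.frame(
                rule = rule, kind = row$kind, source = src, target = tgt,
                stringsAsFactors = FALSE))
        n_done <- n_done + 1L
    }
    if (n_done < nRelations)
        stop("could not place ", nRelations, " distinct assertions; ",
             "increase nClasses or decrease nRelations", call. = FALSE)
    new("PlantedModel", model = m, planted = planted, seed = seed)
}

.Random.seed_save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}
.Random.seed_restore <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}

#' Measure planted-violation recovery
#'
#' Validates a [PlantedModel] in STRICT mode and compares the
#' ERROR-severity issues against the planted ground truth, matching on
#' `(rule, kind, source, target)`.  Returns precision and recall; both
#' are 1 when the validator finds exactly the planted violations.
#'
#' @param pm A [PlantedModel].
#' @return A list with `precision`, `recall`, `n_planted`, `n_reported`.
#' @examples
#' plantedRecovery(randomModel(20, 40, 0.3, seed = 1))
#' @export
plantedRecovery <- function(pm) {
    rep <- validateModel(plantedModel(pm), mode = "STRICT",
                         checkInstances = FALSE)
    err <- issues(rep)
    err <- err[err$severity == "ERROR", , drop = FALSE]
    found <- paste(err$rule, err$subject)
    truth <- paste(pm@planted$rule,
                   .subject_of(pm@planted$kind, pm@planted$source,
                               pm@planted$target))
    tp <- sum(found %in% truth)
    list(precision = if (length(found)) tp / length(found) else 1,
         recall = if (length(truth)) tp / length(truth) else 1,
         n_planted = length(truth), n_reported = length(found))
}
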