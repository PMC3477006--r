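two_class_model <- function(sk, tk) {
    m <- addClass(OntologyModel(), "A", "A", sk)
    addClass(m, "B", "B", tk)
}

test_that("endpoint rules match the relation semantics", {
    r <- endpointRule("has_agent")
    expect_identical(r$source_bound, "PROCESS")
    expect_identical(r$target_bound, "MATERIAL")
    expect_true(endpointRule("proper_part_of")$irreflexive)
    expect_false(endpointRule("part_of")$irreflexive)
    expect_true(endpointRule("integral_part_of")$reciprocal)
    expect_true(endpointRule("is_a")$same_branch)
    expect_identical(endpointRule("contained_in")$source_bound, "MATERIAL")
    expect_identical(endpointRule("contained_in")$target_bound,
                     "IMMATERIAL")
    expect_identical(endpointRule("derives-from")$source_bound, "MATERIAL")
    # extension relations are unconstrained
    ext <- endpointRule("contributes_to")
    expect_identical(ext$source_bound, "UNKNOWN")
    expect_false(ext$same_branch)
    expect_error(endpointRule("instance_of"), "instance-level")
})

test_that("single-assertion checks flag the documented violations", {
    # a process with an immaterial agent: endpoint kind error
    m <- two_class_model("PROCESS", "IMMATERIAL")
    iss <- checkRelation(m, "has_agent", "A", "B")
    expect_identical(iss$rule, "ENDPOINT_KIND")
    expect_identical(iss$severity, "ERROR")
    # two material continuants under has_agent: source bound broken
    m <- two_class_model("MATERIAL", "MATERIAL")
    expect_identical(checkRelation(m, "has_agent", "A", "B")$rule,
                     "ENDPOINT_KIND")
    # a material part forces a material whole
    m <- two_class_model("MATERIAL", "IMMATERIAL")
    iss <- checkRelation(m, "part_of", "A", "B")
    expect_true("CONDITIONAL_KIND" %in% iss$rule)
    # but an immaterial part may sit in a material whole
    m <- two_class_model("IMMATERIAL", "MATERIAL")
    expect_identical(nrow(checkRelation(m, "part_of", "A", "B")), 0L)
    # self proper part
    m <- addClass(OntologyModel(), "A", "A", "MATERIAL")
    m <- addRelation(m, "proper_part_of", "A", "A")
    expect_identical(checkRelation(m, "proper_part_of", "A", "A")$rule,
                     "IRREFLEXIVE")
    # branch straddling
    m <- two_class_model("PROCESS", "CONTINUANT")
    expect_identical(checkRelation(m, "part_of", "A", "B")$rule,
                     "SAME_BRANCH")
})

test_that("strict mode rejects what lenient mode can still refine", {
    m <- two_class_model("UNKNOWN", "MATERIAL")
    expect_identical(checkRelation(m, "derives_from", "A", "B")$rule,
                     "ENDPOINT_KIND")
    expect_identical(
        nrow(checkRelation(m, "derives_from", "A", "B", mode = "LENIENT")),
        0L)
    # CONTINUANT source refinable to MATERIAL in lenient mode only
    m <- two_class_model("CONTINUANT", "MATERIAL")
    expect_identical(checkRelation(m, "derives_from", "A", "B")$rule,
                     "ENDPOINT_KIND")
    expect_identical(
        nrow(checkRelation(m, "derives_from", "A", "B", mode = "LENIENT")),
        0L)
    # but an incompatible kind fails both modes
    m <- two_class_model("PROCESS", "MATERIAL")
    for (mode in c("STRICT", "LENIENT"))
        expect_true("ENDPOINT_KIND" %in%
                        checkRelation(m, "derives_from", "A", "B",
                                      mode = mode)$rule)
})

test_that("is_a requires matching specification between continuants", {
    pairs_ok <- list(c("CONTINUANT", "CONTINUANT"),
                     c("MATERIAL", "MATERIAL"),
                     c("IMMATERIAL", "IMMATERIAL"),
                     c("PROCESS", "PROCESS"))
    for (p in pairs_ok)
        expect_identical(
            nrow(checkRelation(two_class_model(p[1], p[2]), "is_a",
                               "A", "B")), 0L, info = paste(p, collapse = "/"))
    pairs_bad <- list(c("MATERIAL", "CONTINUANT"),
                      c("CONTINUANT", "MATERIAL"),
                      c("MATERIAL", "IMMATERIAL"))
    for (p in pairs_bad)
        expect_true("CONDITIONAL_KIND" %in%
                        checkRelation(two_class_model(p[1], p[2]), "is_a",
                                      "A", "B")$rule,
                    info = paste(p, collapse = "/"))
    # the documented alternative reading accepts a specified subtype
    # under an unspecified supertype
    m <- two_class_model("MATERIAL", "CONTINUANT")
    expect_identical(
        nrow(checkRelation(m, "is_a", "A", "B",
                           isaParity = "subsumption")), 0L)
    m <- two_class_model("CONTINUANT", "MATERIAL")
    expect_true(nrow(checkRelation(m, "is_a", "A", "B",
                                   isaParity = "subsumption")) > 0L)
})

test_that("validity matrices match the independent brute-force oracle", {
    kinds <- setdiff(relationRegistry()$name, "instance_of")
    expect_length(kinds, 21L)
    for (k in kinds) {
        expect_identical(engine_matrix(k), oracle_matrix(k), info = k)
        vp <- validKindPairs(k)
        expect_identical(vp, oracle_valid_pairs(k), info = k)
    }
    # the derived counts
    counts <- vapply(c(is_a = "is_a", part_of = "part_of",
                       has_part = "has_part", has_agent = "has_agent",
                       has_participant = "has_participant",
                       located_in = "located_in"),
                     function(k) nrow(validKindPairs(k)), 1L)
    expect_identical(unname(counts), c(4L, 7L, 7L, 1L, 3L, 9L))
    expect_error(validKindPairs("instance_of"))
})

test_that("inverse relations have transposed validity matrices", {
    reg <- relationRegistry()
    paired <- reg$name[!is.na(reg$inverse)]
    for (k in paired)
        expect_identical(engine_matrix(k),
                         t(engine_matrix(relationInverse(k))), info = k)
})

test_that("model validation orders issues deterministically and is order-independent", {
    build <- function(perm) {
        m <- OntologyModel()
        m <- addClass(m, "p1", kind = "PROCESS")
        m <- addClass(m, "m1", kind = "MATERIAL")
        m <- addClass(m, "i1", kind = "IMMATERIAL")
        m <- addClass(m, "u1", kind = "UNKNOWN")
        asserts <- list(c("has_agent", "p1", "i1"),
                        c("part_of", "m1", "i1"),
                        c("proper_part_of", "m1", "m1"),
                        c("preceded_by", "p1", "p1"))
        for (a in asserts[perm])
            m <- addRelation(m, a[1], a[2], a[3])
        m
    }
    r1 <- validateModel(build(1:4))
    r2 <- validateModel(build(4:1))
    expect_identical(issues(r1), issues(r2))
    expect_identical(issueCounts(r1)[["ENDPOINT_KIND"]], 1L)
    # part_of(material, immaterial) breaks both conditional rules
    expect_identical(issueCounts(r1)[["CONDITIONAL_KIND"]], 2L)
    expect_identical(issueCounts(r1)[["IRREFLEXIVE"]], 1L)
    expect_identical(issueCounts(r1)[["UNTYPED_CLASS"]], 1L)
    # counts slot is consistent with the issue list
    expect_identical(sum(issueCounts(r1)), nrow(issues(r1)))
})

test_that("strict issues are a superset of lenient issues", {
    for (seed in 1:5) {
        pm <- randomModel(15, 30, violationRate = 0.4, seed = seed)
        s <- issues(validateModel(plantedModel(pm), mode = "STRICT"))
        l <- issues(validateModel(plantedModel(pm), mode = "LENIENT"))
        key <- function(d) paste(d$rule, d$subject, d$message)
        expect_true(all(key(l) %in% key(s)), info = seed)
    }
})

test_that("untyped and obsolete classes are handled as documented", {
    m <- addClass(OntologyModel(), "u", "untyped thing", "UNKNOWN")
    rep <- validateModel(m)
    expect_identical(issues(rep)$rule, "UNTYPED_CLASS")
    expect_identical(issues(rep)$severity, "WARNING")
    # obsolete classes are excluded from validation
    m2 <- addClass(m, "dead", "old term", "UNKNOWN", obsolete = TRUE)
    expect_identical(nrow(issues(validateModel(m2))), 1L)
    # empty model: empty report
    expect_identical(nrow(issues(validateModel(OntologyModel()))), 0L)
})

test_that("integral part variants warn when the reciprocal is missing", {
    m <- two_class_model("MATERIAL", "MATERIAL")
    m <- addRelation(m, "integral_part_of", "A", "B")
    rep <- validateModel(m)
    expect_identical(issues(rep)$rule, "RECIPROCITY")
    expect_identical(issues(rep)$severity, "WARNING")
    expect_identical(nErrors(rep), 0L)
    # the plain has_part assertion satisfies the expectation
    m2 <- addRelation(m, "has_part", "B", "A")
    expect_identical(nrow(issues(validateModel(m2))), 0L)
})
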