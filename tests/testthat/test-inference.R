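test_that("a root specialized by both branches is unsatisfiable", {
    m <- goRootFragment()
    a <- inferKinds(m)
    expect_identical(unname(inferredKinds(a)["GO:FIX01"]), "BOTTOM")
    expect_identical(unsatisfiableClasses(m), "GO:FIX01")
    # the children keep their declared kinds: the contradiction does not
    # cascade outward from the invalid concept
    expect_identical(unname(inferredKinds(a)["GO:FIX02"]), "PROCESS")
    expect_identical(unname(inferredKinds(a)["GO:FIX03"]), "CONTINUANT")
    expect_true(length(provenance(a, "GO:FIX01")) >= 1L)
})

test_that("dropping the continuant child makes the root a process", {
    m <- goRootFragment()
    m@relations <- m@relations[m@relations$source != "GO:FIX03", ,
                               drop = FALSE]
    a <- inferKinds(m)
    expect_identical(unname(inferredKinds(a)["GO:FIX01"]), "PROCESS")
    expect_identical(unsatisfiableClasses(m), character(0))
})

test_that("endpoint bounds refine untyped classes", {
    m <- addClass(OntologyModel(), "P1", kind = "PROCESS")
    m <- addClass(m, "X", kind = "UNKNOWN")
    m <- addRelation(m, "has_agent", "P1", "X")
    a <- inferKinds(m)
    expect_identical(unname(inferredKinds(a)["X"]), "MATERIAL")
    # a satisfied bound narrows nothing and flags nothing
    m2 <- addClass(OntologyModel(), "M", kind = "MATERIAL")
    m2 <- addClass(m2, "P", kind = "PROCESS")
    m2 <- addRelation(m2, "participates_in", "M", "P")
    expect_identical(unsatisfiableClasses(m2), character(0))
    expect_identical(unname(inferredKinds(inferKinds(m2))["M"]),
                     "MATERIAL")
})

test_that("a relation-free fully declared model infers its declarations", {
    m <- addClass(OntologyModel(), "a", kind = "PROCESS")
    m <- addClass(m, "b", kind = "IMMATERIAL")
    a <- inferKinds(m)
    expect_identical(inferredKinds(a), c(a = "PROCESS", b = "IMMATERIAL"))
    expect_identical(unname(vapply(c("a", "b"), function(id)
        length(provenance(a, id)), 1L)), c(0L, 0L))
})

test_that("same-branch and conditional rules propagate", {
    # part_of couples branches: an untyped part of a process is a process
    m <- addClass(OntologyModel(), "u", kind = "UNKNOWN")
    m <- addClass(m, "p", kind = "PROCESS")
    m <- addRelation(m, "part_of", "u", "p")
    expect_identical(unname(inferredKinds(inferKinds(m))["u"]), "PROCESS")
    # material part forces a material whole through a chain
    m <- addClass(OntologyModel(), "m", kind = "MATERIAL")
    m <- addClass(m, "w", kind = "UNKNOWN")
    m <- addRelation(m, "part_of", "m", "w")
    expect_identical(unname(inferredKinds(inferKinds(m))["w"]), "MATERIAL")
    # branch ambiguity is reported as UNKNOWN, never guessed
    m <- addClass(OntologyModel(), "x", kind = "UNKNOWN")
    m <- addClass(m, "y", kind = "UNKNOWN")
    m <- addRelation(m, "part_of", "x", "y")
    a <- inferKinds(m)
    expect_identical(unname(inferredKinds(a)[c("x", "y")]),
                     c("UNKNOWN", "UNKNOWN"))
})

test_that("inference is idempotent and order-independent", {
    for (seed in 1:5) {
        pm <- randomModel(12, 25, violationRate = 0.3, seed = seed)
        m <- plantedModel(pm)
        # blank half the declarations so there is something to infer
        set.seed(seed)
        blank <- sample(classIds(m), nClasses(m) %/% 2)
        m@classes$kind[m@classes$id %in% blank] <- "UNKNOWN"
        a1 <- inferKinds(m)
        # idempotence: re-declare with the inferred kinds, re-infer
        m2 <- applyInferredKinds(m, a1)
        expect_identical(inferredKinds(inferKinds(m2)),
                         inferredKinds(a1), info = seed)
        # order independence: shuffle assertion order
        m3 <- m
        m3@relations <- m3@relations[sample(nrow(m3@relations)), ,
                                     drop = FALSE]
        expect_identical(inferredKinds(inferKinds(m3)),
                         inferredKinds(a1), info = seed)
        # termination bound
        expect_lte(a1@rounds, nClasses(m) * 4L)
    }
})

test_that("a BOTTOM-free inferred assignment validates without kind errors", {
    for (seed in 1:5) {
        pm <- randomModel(12, 25, violationRate = 0, seed = seed)
        m <- plantedModel(pm)
        set.seed(seed + 100)
        blank <- sample(classIds(m), nClasses(m) %/% 3)
        m@classes$kind[m@classes$id %in% blank] <- "UNKNOWN"
        a <- inferKinds(m)
        if (any(inferredKinds(a) == "BOTTOM")) next
        rep <- validateModel(applyInferredKinds(m, a), mode = "STRICT")
        iss <- issues(rep)
        expect_identical(
            nrow(iss[iss$rule %in% c("ENDPOINT_KIND", "CONDITIONAL_KIND"), ]),
            0L, info = seed)
    }
})
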