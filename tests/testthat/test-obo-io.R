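test_that("term stanzas parse with normalization and flags", {
    doc <- parseObo(c("format-version: 1.2", "",
                      "[Term]", "id: X:1", "name: NF stage 7",
                      "relationship: part_of X:2 ! the blastula range",
                      "",
                      "[Term]", "id: X:2", "name: Blastula",
                      "relationship: derives-from X:1 {source=\"curator\"}",
                      "",
                      "[Term]", "id: X:3", "name: old term",
                      "is_obsolete: true"))
    terms <- oboTerms(doc)
    expect_length(terms, 3L)
    expect_identical(terms[[1]]$relationships$kind, "part_of")
    expect_identical(terms[[1]]$relationships$target, "X:2")
    expect_identical(terms[[2]]$relationships$kind, "derives_from")
    expect_identical(terms[[2]]$relationships$target, "X:1")
    expect_true(terms[[3]]$obsolete)
    expect_identical(oboHeader(doc)[["format-version"]], "1.2")
})

test_that("format errors are reported", {
    expect_error(parseObo(c("[Term]", "id: A", "[Term]", "id: A")),
                 "duplicate term id")
    expect_error(parseObo(c("[Term]", "id: A", "relationship: part_of")),
                 "without a target")
    expect_error(parseObo(c("[Term]", "name: anonymous")), "without an id")
})

test_that("unknown tags and other stanzas survive or are skipped verbatim", {
    doc <- parseObo(c("[Term]", "id: A", "name: a",
                      "def: \"something\" [ref]",
                      "subset: goslim_generic",
                      "[Typedef]", "id: regulates"))
    tm <- oboTerms(doc)[[1]]
    expect_identical(tm$other, c("def: \"something\" [ref]",
                                 "subset: goslim_generic"))
    expect_length(oboTerms(doc), 1L)
})

test_that("models are built with extension and dangling warnings", {
    doc <- parseObo(c("[Term]", "id: A", "name: a",
                      "relationship: regulates B",
                      "relationship: part_of MISSING",
                      "[Term]", "id: B", "name: b"))
    m <- toModel(doc)
    rel <- modelRelations(m)
    expect_identical(rel$kind, "regulates")   # kept as extension
    w <- modelMetadata(m)$load_warnings
    expect_true(any(grepl("non-Relation-Ontology", w)))
    expect_true(any(grepl("dangling", w)))
    # every relationship line is either an assertion or a warning
    expect_identical(nrow(rel) + sum(grepl("dangling", w)), 2L)
    # extension assertions are unconstrained but reported by validation
    expect_identical(nErrors(validateModel(m, mode = "LENIENT")), 0L)
})

test_that("kind annotations load, override and round-trip", {
    lines <- c("[Term]", "id: A", "name: a",
               "property_value: oborel:kind MATERIAL")
    m <- readObo(lines)
    expect_identical(unname(classKind(m, "A")), "MATERIAL")
    m2 <- readObo(lines, kindAnnotations = c(A = "IMMATERIAL"))
    expect_identical(unname(classKind(m2, "A")), "IMMATERIAL")
    expect_error(parseObo(c("[Term]", "id: A",
                            "property_value: oborel:kind WIBBLE")),
                 "unknown kind")
})

test_that("the packaged fixture files reproduce the in-code fixtures", {
    expect_true(modelEqual(readObo(oboFixtureFile("pro_fragment.obo")),
                           proFragment()))
    expect_true(modelEqual(readObo(oboFixtureFile("xao_fragment.obo")),
                           xaoFragment()))
    expect_true(modelEqual(readObo(oboFixtureFile("go_root_fragment.obo")),
                           goRootFragment()))
    expect_true(modelEqual(readObo(oboFixtureFile("go_mi_fragment.obo")),
                           goMiFragment()))
    # an unannotated XAO file plus an "all PROCESS" annotation map
    plain <- sub("^property_value.*$", "",
                 readLines(oboFixtureFile("xao_fragment.obo")))
    ids <- sub("^id: ", "", grep("^id: ", plain, value = TRUE))
    m <- readObo(plain, kindAnnotations = setNames(
        rep("PROCESS", length(ids)), ids))
    expect_true(modelEqual(m, xaoFragment()))
})

test_that("write/parse round-trips fixtures and random models", {
    for (m in list(proFragment(), xaoFragment(), goRootFragment(),
                   goMiFragment(), OntologyModel()))
        expect_true(modelEqual(m, readObo(writeObo(m))))
    # empty model: header-only document
    expect_identical(writeObo(OntologyModel()), "format-version: 1.2")
    for (seed in 1:20) {
        m <- plantedModel(randomModel(10, 20, violationRate = 0.3,
                                      seed = seed))
        expect_true(modelEqual(m, readObo(writeObo(m))), info = seed)
    }
    # deterministic output
    expect_identical(writeObo(xaoFragment()), writeObo(xaoFragment()))
    # file round-trip with an actual file
    f <- withr::local_tempfile(fileext = ".obo")
    writeObo(proFragment(), f)
    expect_true(modelEqual(readObo(f), proFragment()))
})
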