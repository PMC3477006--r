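test_that("the protein fragment matches its published structure", {
    m <- proFragment()
    expect_identical(nClasses(m), 6L)
    expect_identical(nRelations(m), 6L)
    expect_true(all(modelClasses(m)$kind == "MATERIAL"))
    st <- relationUsageStats(m)
    expect_identical(st$counts[["is_a"]], 4L)
    expect_identical(st$counts[["derives_from"]], 2L)
    # TGF-Beta 1 is a subtype of TGF-Beta
    rel <- modelRelations(m)
    n1 <- function(id) unname(className(m, id))
    isa <- rel[rel$kind == "is_a", ]
    expect_true(any(n1(isa$source) == "TGF-Beta 1" &
                    n1(isa$target) == "TGF-Beta"))
    # the cleavage product derives from TGF-Beta 1
    df <- rel[rel$kind == "derives_from", ]
    expect_true(any(
        n1(df$source) == "TGF-Beta 1 Proteolytic Cleavage Product" &
        n1(df$target) == "TGF-Beta 1"))
    expect_identical(nErrors(validateModel(m, "STRICT")), 0L)
    expect_identical(unsatisfiableClasses(m), character(0))
})

test_that("the developmental-stage fragment matches its published structure", {
    m <- xaoFragment()
    expect_identical(nClasses(m), 10L)
    expect_identical(nRelations(m), 11L)
    expect_true(all(modelClasses(m)$kind == "PROCESS"))
    st <- relationUsageStats(m)
    expect_identical(unname(st$counts[c("is_a", "part_of", "preceded_by")]),
                     c(6L, 3L, 2L))
    n1 <- function(id) unname(className(m, id))
    rel <- modelRelations(m)
    pb <- rel[rel$kind == "preceded_by", ]
    expect_true(any(n1(pb$source) == "NF Stage 8" &
                    n1(pb$target) == "NF Stage 7"))
    po <- rel[rel$kind == "part_of", ]
    expect_identical(sort(n1(po$source)),
                     c("NF Stage 7", "NF Stage 8", "NF Stage 9"))
    expect_true(all(n1(po$target) == "Blastula"))
    expect_identical(nErrors(validateModel(m, "STRICT")), 0L)
})

test_that("the multiple-inheritance fragment is constraint-clean", {
    m <- goMiFragment()
    rep <- validateModel(m, "STRICT")
    expect_identical(nErrors(rep), 0L)
    expect_identical(nrow(findMultipleInheritance(m)), 2L)
    expect_identical(nrow(findEmbeddedRelationNames(m)), 1L)
})

test_that("random models are reproducible and respect their rate", {
    pm1 <- randomModel(20, 40, violationRate = 0.5, seed = 42)
    pm2 <- randomModel(20, 40, violationRate = 0.5, seed = 42)
    expect_true(modelEqual(plantedModel(pm1), plantedModel(pm2)))
    expect_identical(plantedIssues(pm1), plantedIssues(pm2))
    pm3 <- randomModel(20, 40, violationRate = 0.5, seed = 43)
    expect_false(modelEqual(plantedModel(pm1), plantedModel(pm3)))
    # rate 0: clean; rate 1: every assertion planted
    pm0 <- randomModel(20, 40, violationRate = 0, seed = 7)
    expect_identical(nrow(plantedIssues(pm0)), 0L)
    expect_identical(nErrors(validateModel(plantedModel(pm0), "STRICT")),
                     0L)
    pmA <- randomModel(20, 50, violationRate = 1, seed = 7)
    expect_identical(nrow(plantedIssues(pmA)), 50L)
    expect_error(randomModel(2, 5, 0, seed = 1), "at least 4")
    expect_error(randomModel(10, 5, 2, seed = 1), "violationRate")
})

test_that("the validator recovers planted violations exactly", {
    pm <- randomModel(20, 50, violationRate = 1, seed = 11)
    rec <- plantedRecovery(pm)
    expect_identical(rec$precision, 1)
    expect_identical(rec$recall, 1)
    expect_identical(rec$n_reported, 50L)
    for (seed in 1:5) {
        rec <- plantedRecovery(randomModel(30, 80, violationRate = 0.3,
                                           seed = seed))
        expect_identical(c(rec$precision, rec$recall), c(1, 1),
                         info = seed)
    }
})

test_that("generation does not disturb the caller's RNG stream", {
    set.seed(99); before <- runif(3)
    set.seed(99); runif(1)
    invisible(randomModel(10, 10, 0.5, seed = 5))
    after <- runif(2)
    expect_identical(before[2:3], after)
})
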