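repGroup <- list(ids = c("F1", "F2", "F3"),
                 int = c(2000, 220, 1000),
                 mz = c(180.0634, 181.0667, 202.0453))

test_that("the four representative methods pick the documented members", {
    g <- repGroup
    expect_identical(
        chooseRepresentative(g$ids, g$int, g$mz, "highest_intensity"), "F1")
    expect_identical(
        chooseRepresentative(g$ids, g$int, g$mz, "highest_mass"), "F3")
    ## 180.0634^2 * 2000 ~ 6.48e7 beats 202.0453^2 * 1000 ~ 4.08e7
    expect_identical(
        chooseRepresentative(g$ids, g$int, g$mz, "mass2_x_intensity"), "F1")
    ## top 2 by intensity = {F1, F3}; highest mass among them = F3
    expect_identical(
        chooseRepresentative(g$ids, g$int, g$mz, "highest_mass_in_top_n",
                             topN = 2), "F3")
    expect_error(
        chooseRepresentative(g$ids, g$int, g$mz, "highest_mass_in_top_n"),
        "topN")
    expect_error(
        chooseRepresentative(g$ids, g$int, NULL, "highest_mass"), "m/z")
})

test_that("method identities hold over random groups", {
    set.seed(23)
    for (i in 1:120) {
        n <- sample(2:8, 1)
        ids <- sprintf("X%02d", sample(99, n))
        int <- round(rlnorm(n, 8, 1), 3)
        mzv <- round(runif(n, 100, 900), 4)
        ## top_n >= group size reduces method 4 to argmax mass (method 2)
        expect_identical(
            chooseRepresentative(ids, int, mzv, "highest_mass_in_top_n",
                                 topN = n),
            chooseRepresentative(ids, int, mzv, "highest_mass"))
        ## top_n = 1 reduces method 4 to argmax intensity (method 1)
        expect_identical(
            chooseRepresentative(ids, int, mzv, "highest_mass_in_top_n",
                                 topN = 1),
            chooseRepresentative(ids, int, mzv, "highest_intensity"))
    }
})

test_that("argmax ties break by higher mass, then lexicographic id", {
    ids <- c("B", "A", "C")
    expect_identical(
        chooseRepresentative(ids, c(10, 10, 5), c(100, 200, 300),
                             "highest_intensity"), "A")
    expect_identical(
        chooseRepresentative(ids, c(10, 10, 5), c(100, 100, 50),
                             "highest_intensity"), "A")
})

test_that("filter flags keep exactly one feature per group", {
    res <- toyResult()
    flags <- filterFlags(res)
    expect_identical(names(flags)[flags == 1L], c("F1", "F4", "F5"))
    expect_identical(names(flags)[flags == 0L], c("F2", "F3"))
    expect_identical(sum(flags), nGroups(res))

    ## all-singleton input: everything kept
    ids <- LETTERS[1:5]
    assignment <- setNames(1:5, ids)
    reps <- setNames(ids, 1:5)
    expect_identical(sum(assignFilterFlags(assignment, reps)), 5L)

    ## one group of n features: exactly one kept
    one <- setNames(rep(1L, 5), ids)
    oneRep <- c("1" = "C")
    expect_identical(sum(assignFilterFlags(one, oneRep)), 1L)
    ## property over random simulated runs: sum(flags) == #groups
    for (seed in 1:5) {
        sim <- simulateDataset(nAnalytes = 5, maxDerived = 3, nSamples = 8,
                               nNoiseFeatures = 8, seed = seed)
        res2 <- suppressMessages(acorFilter(sim$intensities, sim$features,
            simMethod = "pearson", corThreshold = 0.8, rtDelta = 10,
            deltas = defaultDeltaList(), massTol = 0.005,
            repMethod = "highest_mass"))
        expect_identical(sum(filterFlags(res2)), nGroups(res2))
    }
})

test_that("in-group annotations list labelled partners in ascending id order", {
    res <- toyResult()
    ann <- annotatedTable(res)$isotopes_adducts_fragments
    names(ann) <- featureIds(res)
    expect_identical(ann[["F1"]], "isotope_13C@F2;Na-H@F3")
    expect_identical(ann[["F2"]], "isotope_13C@F1")
    expect_identical(ann[["F3"]], "Na-H@F1")
    expect_identical(ann[["F5"]], "-")
    ## without the mass gate the column is all "-"
    toy <- toyObjects()
    resNoMass <- suppressMessages(acorFilter(toy$m, toy$ft, similarity = toy$s,
        corThreshold = 0.9, rtDelta = 6, repMethod = "highest_intensity"))
    expect_true(all(annotatedTable(resNoMass)$isotopes_adducts_fragments == "-"))
})

test_that("annotation vs representative carries a sign and handles unmatched", {
    res <- toyResult()
    ann <- annotatedTable(res)$annotation_relative_to_representative
    names(ann) <- featureIds(res)
    expect_identical(ann[["F1"]], "M (representative)")
    expect_identical(ann[["F2"]], "+isotope_13C")       # delta = +1.0033
    expect_identical(ann[["F3"]], "+Na-H")              # delta = +21.9819
    expect_identical(ann[["F4"]], "-")
    ## a member lighter than the representative gets a "-" prefix,
    ## an inexplicable offset is "unmatched"
    assignment <- setNames(c(1L, 1L, 1L), c("A", "B", "C"))
    reps <- c("1" = "A")
    mzv <- c(A = 200, B = 200 - 18.010565, C = 150.1234)
    out <- annotateVsRepresentative(assignment, reps, mzv,
                                    defaultDeltaList(), 0.005)
    expect_identical(out[["B"]], "-H2O_loss")
    expect_identical(out[["C"]], "unmatched")
})

test_that("representatives are invariant under sample permutation", {
    toy <- toyObjects()
    set.seed(9)
    perm <- sample(ncol(toy$m))
    resA <- toyResult()
    resB <- suppressMessages(acorFilter(toy$m[, perm], toy$ft,
        similarity = toy$s, corThreshold = 0.9, rtDelta = 6,
        deltas = defaultDeltaList(), massTol = 0.005,
        repMethod = "highest_intensity"))
    expect_identical(representatives(resA), representatives(resB))
})

test_that("assembled output follows the five-column contract", {
    res <- toyResult(repMethod = "highest_mass_in_top_n", topN = 2)
    out <- annotatedTable(res)
    expect_true("representative_highest_mass_in_top_n" %in% names(out))
    expect_true(all(nzchar(out$ACorF_groups)))
    expect_identical(sum(out$ACorF_filter == "0"), 2L)
    ## method 4, top 2 picks F3 for the multi-member group
    expect_identical(out$representative_highest_mass_in_top_n[1], "F3")
})
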