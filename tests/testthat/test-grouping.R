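test_that("pair selection is strict at the threshold and skips missing values", {
    toy <- toyObjects()
    p <- selectPairs(toy$s, 0.9)
    expect_identical(nrow(p), 6L)
    key <- paste(p$idA, p$idB)
    expect_setequal(key, c("F1 F2", "F1 F3", "F1 F5", "F2 F3", "F2 F5", "F3 F5"))

    s <- matrix(c(1, 0.75, 0.75, 1), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
    expect_identical(nrow(selectPairs(s, 0.75)), 0L)      # strict >
    expect_identical(nrow(selectPairs(s, 0.7499)), 1L)
    expect_identical(nrow(selectPairs(toy$s, 1.5)), 0L)

    s[1, 2] <- s[2, 1] <- NA
    expect_identical(nrow(selectPairs(s, -10)), 0L)

    ## absolute mode admits strong anti-correlations
    pAbs <- selectPairs(toy$s, 0.9, absolute = TRUE)
    expect_identical(nrow(pAbs), 10L)
})

test_that("the RT gate keeps co-eluting pairs with an inclusive boundary", {
    toy <- toyObjects()
    pairs <- data.frame(idA = c("F1", "F1"), idB = c("F2", "F4"),
                        similarity = c(1, 1))
    kept <- rtGate(pairs, toy$ft, 6)
    expect_identical(kept$idB, "F2")          # |120 - 120.5| <= 6; F4 at 400 s out

    eq <- data.frame(idA = "F1", idB = "F1b", similarity = 1)
    ft <- FeatureTable(data.frame(id = c("F1", "F1b"), rt = c("120", "120")),
                       rtColumn = "rt")
    expect_identical(nrow(rtGate(eq, ft, 0)), 1L)         # rtDelta 0, equal rt

    ftNoRt <- FeatureTable(data.frame(id = c("F1", "F1b"), rt = c("120", "")),
                           rtColumn = "rt")
    expect_error(rtGate(eq, ftNoRt, 6), "F1b")
})

test_that("the mass gate matches deltas within an inclusive tolerance", {
    dl <- DeltaList(c("isotope_13C", "Na-H"), c(1.00336, 21.98194))
    ft <- FeatureTable(data.frame(
        id = c("M292.0134T309", "M293.0167T309", "M180T120", "M300T120"),
        mz = c("292.0134", "293.0167", "180.0634", "300.1000")), mzColumn = "mz")
    pairs <- data.frame(idA = c("M292.0134T309", "M180T120"),
                        idB = c("M293.0167T309", "M300T120"),
                        similarity = c(0.99, 0.99))
    kept <- massGate(pairs, ft, dl, 0.002)
    expect_identical(kept$idA, "M292.0134T309")           # ||1.0033|-1.00336| = 6e-5
    expect_identical(kept$label, "isotope_13C")
    kept5 <- massGate(pairs, ft, dl, 0.005)
    expect_identical(nrow(kept5), 1L)                     # delta 120.0366 matches nothing

    ## inclusive boundary: deviation exactly equal to the tolerance is kept
    dlB <- DeltaList("d", 1.0)
    ftB <- FeatureTable(data.frame(id = c("A", "B"), mz = c("100", "101.5")),
                        mzColumn = "mz")
    pB <- data.frame(idA = "A", idB = "B", similarity = 1)
    expect_identical(nrow(massGate(pB, ftB, dlB, 0.5)), 1L)    # dev = 0.5 = tol
    expect_identical(nrow(massGate(pB, ftB, dlB, 0.4999)), 0L)

    ## ties go to the closest entry, then first in list order
    dlTie <- DeltaList(c("a", "b", "c"), c(1.0, 1.2, 1.0))
    ftT <- FeatureTable(data.frame(id = c("A", "B"), mz = c("100", "101")),
                        mzColumn = "mz")
    tied <- massGate(data.frame(idA = "A", idB = "B", similarity = 1),
                     ftT, dlTie, 0.5)
    expect_identical(tied$label, "a")
})

test_that("groups are connected components with first-appearance numbering", {
    g <- buildGroups(data.frame(idA = c("A", "B"), idB = c("B", "C")),
                     c("A", "B", "C", "D"))
    expect_identical(unname(g), c(1L, 1L, 1L, 2L))

    none <- buildGroups(data.frame(idA = character(0), idB = character(0)),
                        LETTERS[1:6])
    expect_identical(unname(none), 1:6)

    res <- toyResult()
    expect_identical(nGroups(res), 3L)
    expect_identical(unname(groups(res)), c(1L, 1L, 1L, 2L, 3L))

    expect_error(buildGroups(data.frame(idA = "A", idB = "Z"), c("A", "B")),
                 "Z")
})

test_that("groups equal an independent BFS on random graphs (partition property)", {
    set.seed(11)
    for (i in 1:60) {
        case <- randomGraphCase(sample(5:40, 1))
        got <- buildGroups(case$pairs, case$ids)
        want <- bfsComponents(case$pairs, case$ids)
        expect_identical(got, want)
        ## total partition: every feature in exactly one group
        expect_identical(sort(names(got)), sort(case$ids))
        expect_identical(sort(unique(unname(got))),
                         seq_len(max(got)))
    }
})

test_that("each gate only refines: toy progression 2 -> 2 -> 3 groups", {
    toy <- toyObjects()
    dl <- defaultDeltaList()
    simOnly <- suppressMessages(runFiltration(toy$ft, toy$s, 0.9))
    expect_identical(length(unique(simOnly$assignment)), 2L)
    expect_setequal(names(simOnly$assignment)[simOnly$assignment == 1L],
                    c("F1", "F2", "F3", "F5"))
    withRt <- suppressMessages(runFiltration(toy$ft, toy$s, 0.9, rtDelta = 6))
    expect_identical(length(unique(withRt$assignment)), 2L)
    full <- suppressMessages(runFiltration(toy$ft, toy$s, 0.9, rtDelta = 6,
                                           deltas = dl, massTol = 0.005))
    expect_identical(length(unique(full$assignment)), 3L)
    expect_setequal(names(full$assignment)[full$assignment == 1L],
                    c("F1", "F2", "F3"))      # F2-F3 bridged through F1
})

test_that("monotone refinement and threshold monotonicity hold on simulations", {
    for (seed in 1:15) {
        sim <- simulateDataset(nAnalytes = 6, maxDerived = 3, nSamples = 10,
                               nNoiseFeatures = 10, cvNoise = 0.2,
                               rtJitter = 5, seed = seed)
        s <- computeSimilarity(sim$intensities, "pearson")
        res <- suppressMessages(acorFilter(sim$intensities, sim$features,
            similarity = s, corThreshold = 0.8, rtDelta = 10,
            deltas = defaultDeltaList(), massTol = 0.005,
            repMethod = "highest_intensity"))
        counts <- stageGroupCounts(res)
        expect_true(counts[["similarity"]] <= counts[["rt"]])
        expect_true(counts[["rt"]] <= counts[["mass"]])

        nLow <- length(unique(suppressMessages(
            runFiltration(sim$features, s, 0.6))$assignment))
        nHigh <- length(unique(suppressMessages(
            runFiltration(sim$features, s, 0.9))$assignment))
        expect_true(nLow <= nHigh)
    }
})

test_that("grouping is invariant under feature permutation of the similarity matrix", {
    toy <- toyObjects()
    base <- suppressMessages(runFiltration(toy$ft, toy$s, 0.9))$assignment
    set.seed(3)
    perm <- sample(rownames(toy$s))
    sPerm <- toy$s[perm, perm]
    permuted <- suppressMessages(runFiltration(toy$ft, sPerm, 0.9))$assignment
    expect_identical(base, permuted[names(base)])
})

test_that("gate preconditions are enforced", {
    toy <- toyObjects()
    expect_error(suppressMessages(
        runFiltration(toy$ft, toy$s, 0.9, deltas = defaultDeltaList(),
                      massTol = 0.005)),
        "RT gate")
    expect_error(suppressMessages(
        runFiltration(toy$ft, toy$s, 0.9, rtDelta = 6,
                      deltas = defaultDeltaList())),
        "massTol")
    sBad <- toy$s[1:4, 1:4]
    expect_error(suppressMessages(runFiltration(toy$ft, sBad, 0.9)), "F5")
})
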