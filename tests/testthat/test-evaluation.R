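test_that("stratified folds partition indices with balanced class counts", {
    labels <- rep(c("a", "b"), each = 50)
    folds <- stratifiedKFold(labels, 10, seed = 4L)
    expect_length(folds, 10L)
    allTest <- sort(unlist(lapply(folds, `[[`, "test")))
    expect_identical(allTest, seq_along(labels))
    for (f in folds) {
        expect_length(f$test, 10L)
        expect_identical(as.integer(table(labels[f$test])), c(5L, 5L))
        expect_length(intersect(f$train, f$test), 0L)
        expect_identical(sort(c(f$train, f$test)), seq_along(labels))
    }
    expect_identical(stratifiedKFold(labels, 10, seed = 4L), folds)
    expect_false(identical(stratifiedKFold(labels, 10, seed = 5L), folds))
    expect_error(stratifiedKFold(rep(c("a", "b"), c(50, 3)), 10),
                 "'b' has 3")
})

test_that("accuracy is the fraction of concordant labels", {
    expect_identical(accuracyScore(c("a", "b"), c("a", "b")), 1)
    expect_identical(accuracyScore(c("a", "b"), c("b", "a")), 0)
    expect_identical(accuracyScore(c("a", "a", "b", "b"),
                                   c("a", "a", "b", "a")), 0.75)
    expect_error(accuracyScore("a", c("a", "b")), "length")
})

test_that("nested cross-validation selects q and never leaks outer-test samples", {
    ds <- smallDataset(seed = 47L, nGenes = 120L, samplesPerClass = 12L)
    cv <- twoLayerCV(ds, qGrid = 1:3, folds = 4L, seed = 2L)
    tab <- foldResults(cv)
    expect_identical(nrow(tab), 4L)
    expect_true(all(tab$chosenQ %in% 1:3))
    expect_equal(meanAccuracy(cv), mean(tab$accuracy))

    for (f in cv@audit) {
        expect_length(intersect(f$train, f$test), 0L)
        for (innerSplit in f$inner) {
            # inner selection must only ever touch the outer-training portion
            expect_true(all(innerSplit$train %in% f$train))
            expect_true(all(innerSplit$test %in% f$train))
            expect_length(intersect(innerSplit$test, f$test), 0L)
        }
    }
})

test_that("a singleton q grid reduces to plain stratified CV with that q", {
    ds <- smallDataset(seed = 53L, nGenes = 100L, samplesPerClass = 8L)
    cv <- twoLayerCV(ds, qGrid = 2L, folds = 4L, seed = 9L)
    folds <- stratifiedKFold(as.character(subclassLabels(ds)), 4L, seed = 9L)
    X <- exprsMatrix(ds)
    lab <- as.character(subclassLabels(ds))
    manual <- vapply(folds, function(f) {
        model <- mrrccFit(GEPSet(X[, f$train], labels = lab[f$train]), 2L)
        accuracyScore(predictedLabels(predict(model, X[, f$test])),
                      lab[f$test])
    }, numeric(1))
    expect_equal(foldResults(cv)$accuracy, manual)
    expect_true(all(foldResults(cv)$chosenQ == 2L))
})

test_that("balanced division draws q per class, disjoint and exhaustive", {
    ds <- smallDataset(seed = 59L, nClasses = 3L, samplesPerClass = 10L)
    sp <- bdmSplit(ds, 5, seed = 3L)
    expect_identical(as.integer(table(subclassLabels(sp$train))),
                     rep(5L, 3))
    expect_identical(nSamples(sp$test), 15L)
    expect_length(intersect(sampleIds(sp$train), sampleIds(sp$test)), 0L)
    expect_setequal(c(sampleIds(sp$train), sampleIds(sp$test)),
                    sampleIds(ds))
    expect_error(bdmSplit(ds, 10), "class01")

    # distinct seeded repetitions, each reproducible
    splits <- vapply(1:20, function(s)
        paste(sampleIds(bdmSplit(ds, 5, seed = s)$train), collapse = ","),
        character(1))
    expect_gt(length(unique(splits)), 15L)
    expect_identical(sampleIds(bdmSplit(ds, 5, seed = 11L)$train),
                     sampleIds(bdmSplit(ds, 5, seed = 11L)$train))
})

test_that("Kruskal-Wallis scoring matches hand ranks and keeps topN genes", {
    x <- matrix(c(1, 2, 3, 4,
                  5, 5, 5, 5,
                  4, 3, 2, 1), 3, 4, byrow = TRUE,
                dimnames = list(c("gSep", "gConst", "gRev"),
                                paste0("s", 1:4)))
    ds <- GEPSet(x, labels = c("u", "u", "v", "v"))
    out <- kruskalWallisFilter(ds, topN = 3)
    # groups {1,2} vs {3,4}: H = 2.4 by direct rank computation
    expect_equal(unname(out$scores["gSep"]), 2.4, tolerance = 1e-12)
    expect_equal(unname(out$scores["gConst"]), 0)
    expect_equal(unname(out$scores["gRev"]), 2.4, tolerance = 1e-12)
    # rows reordered by descending score, ties to the smaller gene index
    expect_identical(geneIds(out$dataset), c("gSep", "gRev", "gConst"))
    expect_error(kruskalWallisFilter(ds, topN = 4), "topN")

    out1 <- kruskalWallisFilter(ds, topN = 2)
    expect_identical(geneIds(out1$dataset), c("gSep", "gRev"))
})

test_that("the H statistic is invariant under strictly monotone transforms", {
    ds <- smallDataset(seed = 61L, nGenes = 25L, samplesPerClass = 6L)
    base <- kruskalWallisFilter(ds, topN = 25L)$scores
    X <- exprsMatrix(ds)
    mono <- GEPSet(exp(X / 2),
                   labels = as.character(subclassLabels(ds)))
    expect_equal(kruskalWallisFilter(mono, topN = 25L)$scores, base,
                 tolerance = 1e-10)
})

test_that("cross-validation reports serialize with a summary row", {
    ds <- smallDataset(seed = 67L, nGenes = 80L, samplesPerClass = 8L)
    cv <- twoLayerCV(ds, qGrid = 2L, folds = 2L, seed = 1L)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeCVReport(cv, path)
    lines <- readLines(path)
    expect_identical(lines[1], "fold\tchosen_q\taccuracy")
    expect_length(lines, 2L + 2L)
    expect_match(lines[length(lines)], "^mean\t")
})
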