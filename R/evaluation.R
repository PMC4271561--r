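#' Stratified k-fold partition
#'
#' Shuffles each subclass independently under the given seed and deals its
#' samples round-robin across folds, so per-class counts per fold differ by
#' at most one and the folds partition the index set exactly.
#'
#' @param labels character/factor label vector.
#' @param folds number of folds (>= 2); every class must have at least
#'   `folds` samples.
#' @param seed integer seed.
#' @return list of length `folds`, each element `list(train=, test=)` of
#'   integer indices.
#' @export
stratifiedKFold <- function(labels, folds, seed = 1L) {
    labels <- as.character(labels)
    folds <- as.integer(folds)
    if (folds < 2L) stopf("folds must be >= 2")
    tab <- table(labels)
    if (any(tab < folds))
        stopf("class '%s' has %d sample(s), fewer than %d folds",
              names(tab)[which.min(tab)], min(tab), folds)
    assign <- integer(length(labels))
    withSeed(seed, {
        for (cl in names(tab)) {
            idx <- sample(which(labels == cl))
            assign[idx] <- rep_len(seq_len(folds), length(idx))
        }
    })
    lapply(seq_len(folds), function(f)
        list(train = which(assign != f), test = which(assign == f)))
}

#' Classification accuracy
#'
#' @param predicted,truth equal-length label vectors.
#' @return fraction of agreeing positions.
#' @export
accuracyScore <- function(predicted, truth) {
    if (length(predicted) != length(truth))
        stopf("predicted and truth differ in length")
    if (length(truth) == 0L) return(NaN)
    mean(as.character(predicted) == as.character(truth))
}

fitPredictAccuracy <- function(dataset, trainIdx, testIdx, q, config) {
    X <- exprsMatrix(dataset)
    lab <- as.character(subclassLabels(dataset))
    model <- mrrccFit(GEPSet(X[, trainIdx, drop = FALSE],
                             labels = lab[trainIdx]), q, config)
    preds <- predict(model, X[, testIdx, drop = FALSE])
    accuracyScore(vapply(preds, predictedLabel, character(1)), lab[testIdx])
}

#' Nested cross-validation over the number of meta-samples
#'
#' Two-layer (nested) stratified cross-validation: for each outer fold, an
#' inner k-fold CV on the outer-training portion scores every candidate
#' meta-sample count in `qGrid`; the count with the highest inner mean
#' accuracy (ties to the smallest count) is used to refit on the full
#' outer-training portion, which is then scored on the outer-test portion.
#' The inner fold count is reduced automatically (with a warning) when a
#' class in the outer-training portion is smaller than `innerFolds`.
#'
#' @param dataset a labeled [GEPSet-class].
#' @param qGrid integer vector of candidate meta-sample counts.
#' @param config an [RRCConfig-class].
#' @param folds outer fold count (default 10).
#' @param innerFolds inner fold count (default `folds`).
#' @param seed integer seed for the fold assignments.
#' @return a [CVResult-class]; its `audit` slot records every index set used
#'   so leakage can be verified.
#' @export
twoLayerCV <- function(dataset, qGrid, config = rrcConfig(), folds = 10L,
                       innerFolds = folds, seed = 1L) {
    lab <- subclassLabels(dataset)
    if (is.null(lab)) stopf("dataset carries no subclass labels")
    if (length(qGrid) < 1L) stopf("qGrid must be nonempty")
    qGrid <- sort(unique(as.integer(qGrid)))
    lab <- as.character(lab)
    outer <- stratifiedKFold(lab, folds, seed)
    rows <- vector("list", length(outer))
    audit <- vector("list", length(outer))
    for (f in seq_along(outer)) {
        trainIdx <- outer[[f]]$train
        testIdx <- outer[[f]]$test
        innerAudit <- list()
        if (length(qGrid) == 1L) {
            chosenQ <- qGrid
        } else {
            innerF <- min(innerFolds, min(table(lab[trainIdx])))
            if (innerF < 2L)
                stopf("outer-training portion too small for inner CV")
            if (innerF < innerFolds)
                warning(sprintf(
                    "inner folds reduced to %d (smallest class in fold %d)",
                    innerF, f), call. = FALSE)
            inner <- stratifiedKFold(lab[trainIdx], innerF,
                                     seed + 1000L * f)
            innerAcc <- vapply(qGrid, function(q) {
                mean(vapply(inner, function(sp) {
                    innerAudit[[length(innerAudit) + 1L]] <<-
                        list(train = trainIdx[sp$train],
                             test = trainIdx[sp$test])
                    fitPredictAccuracy(dataset, trainIdx[sp$train],
                                       trainIdx[sp$test], q, config)
                }, numeric(1)))
            }, numeric(1))
            chosenQ <- qGrid[which.max(innerAcc)]
        }
        acc <- fitPredictAccuracy(dataset, trainIdx, testIdx, chosenQ,
                                  config)
        rows[[f]] <- data.frame(fold = f, chosenQ = chosenQ, accuracy = acc)
        audit[[f]] <- list(train = trainIdx, test = testIdx,
                           inner = innerAudit)
    }
    tab <- do.call(rbind, rows)
    new("CVResult", foldTable = tab, meanAccuracy = mean(tab$accuracy),
        seed = as.integer(seed), audit = audit)
}

#' @rdname CVResult-class
#' @export
setMethod("foldResults", "CVResult", function(x) x@foldTable)

#' @rdname CVResult-class
#' @export
setMethod("meanAccuracy", "CVResult", function(x) x@meanAccuracy)

setMethod("show", "CVResult", function(object) {
    cat(sprintf("CVResult: %d outer folds, mean accuracy %.4f (seed %d)\n",
                nrow(object@foldTable), object@meanAccuracy, object@seed))
    invisible(NULL)
})

#' Write a cross-validation report
#'
#' Tab-separated table with columns fold, chosen_q, accuracy and a trailing
#' summary row holding the mean accuracy.
#'
#' @param cv a [CVResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCVReport <- function(cv, path) {
    tab <- foldResults(cv)
    lines <- c("fold\tchosen_q\taccuracy",
               sprintf("%d\t%d\t%.17g", tab$fold, tab$chosenQ,
                       tab$accuracy),
               sprintf("mean\tNA\t%.17g", meanAccuracy(cv)))
    writeLines(lines, path)
    invisible(path)
}

#' Balanced train/test division
#'
#' Draws exactly `qTrain` samples per subclass uniformly at random into the
#' training set; all remaining samples form the test set. The published
#' evaluation protocol sweeps `qTrain` from 5 to the smallest class size
#' (capped at 20) over 100 seeded randomizations.
#'
#' @param dataset a labeled [GEPSet-class].
#' @param qTrain training samples per subclass; must be smaller than every
#'   class size.
#' @param seed integer seed.
#' @return `list(train=, test=)` of [GEPSet-class] objects (disjoint; union
#'   is the dataset).
#' @export
bdmSplit <- function(dataset, qTrain, seed = 1L) {
    lab <- subclassLabels(dataset)
    if (is.null(lab)) stopf("dataset carries no subclass labels")
    qTrain <- as.integer(qTrain)
    if (qTrain < 1L) stopf("qTrain must be positive")
    lab <- as.character(lab)
    tab <- table(lab)
    if (any(tab <= qTrain))
        stopf("class '%s' has only %d sample(s); cannot draw %d for training",
              names(tab)[which.min(tab)], min(tab), qTrain)
    trainIdx <- withSeed(seed, {
        sort(unlist(lapply(names(tab), function(cl)
            sample(which(lab == cl), qTrain))))
    })
    testIdx <- setdiff(seq_along(lab), trainIdx)
    X <- exprsMatrix(dataset)
    list(train = GEPSet(X[, trainIdx, drop = FALSE],
                        labels = lab[trainIdx]),
         test = GEPSet(X[, testIdx, drop = FALSE], labels = lab[testIdx]))
}

kwStatistic <- function(x, g) {
    h <- suppressWarnings(stats::kruskal.test(x, g)$statistic)
    if (!is.finite(h)) 0 else unname(h)
}

#' Kruskal-Wallis gene filter
#'
#' Scores every gene with the tie-corrected Kruskal-Wallis rank-sum
#' statistic H across the subclasses (a gene tied across all samples gets
#' H = 0) and keeps the `topN` genes with the largest H, ties resolved
#' toward the smaller gene index. The returned dataset's rows are ordered by
#' descending score.
#'
#' @param dataset a labeled [GEPSet-class].
#' @param topN number of genes to keep (default 300; must not exceed the
#'   gene count).
#' @return `list(scores=, dataset=)`: the named per-gene H vector (input
#'   order) and the reduced dataset.
#' @export
kruskalWallisFilter <- function(dataset, topN = 300L) {
    lab <- subclassLabels(dataset)
    if (is.null(lab)) stopf("dataset carries no subclass labels")
    X <- exprsMatrix(dataset)
    topN <- as.integer(topN)
    if (topN < 1L || topN > nrow(X))
        stopf("topN must lie in [1, %d], got %d", nrow(X), topN)
    g <- factor(as.character(lab))
    scores <- apply(X, 1L, kwStatistic, g = g)
    names(scores) <- rownames(X)
    ord <- order(-scores)   # stable: ties keep the smaller gene index first
    keep <- ord[seq_len(topN)]
    list(scores = scores,
         dataset = GEPSet(X[keep, , drop = FALSE],
                          labels = as.character(lab)))
}
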