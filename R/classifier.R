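#' Normalize a sample vector to unit l2 norm
#'
#' @param v numeric vector with at least one nonzero entry.
#' @return `v / ||v||_2`.
#' @examples
#' normalizeUnitL2(c(3, 4))   # 0.6 0.8
#' @export
normalizeUnitL2 <- function(v) {
    nv <- sqrt(sum(v^2))
    if (!is.finite(nv) || nv == 0) stopf("cannot normalize a zero vector")
    v / nv
}

#' Per-sample z-score normalization
#'
#' Centers and scales each sample (column) to mean 0 and standard deviation
#' 1 across genes. Applied to training and test sets before gene filtering
#' in the dimension-reduction evaluation protocol; it is not part of the
#' default classifier pipeline.
#'
#' @param dataset a [GEPSet-class].
#' @return the transformed dataset. A sample constant across genes is an
#'   error naming that sample.
#' @export
zscoreBySample <- function(dataset) {
    x <- exprsMatrix(dataset)
    mu <- colMeans(x)
    sdv <- apply(x, 2L, stats::sd)
    if (any(sdv == 0))
        stopf("constant sample(s) cannot be z-scored: %s",
              paste(colnames(x)[sdv == 0], collapse = ", "))
    xs <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
    out <- dataset
    SummarizedExperiment::assay(out, "exprs") <- xs
    out
}

#' Low-level model constructor
#'
#' Assembles an [MRRCCModel-class] from an existing dictionary; [mrrccFit()]
#' is the usual entry point.
#'
#' @param dictionary a [MetaSampleDictionary-class].
#' @param config an [RRCConfig-class].
#' @param labels character label set; defaults to the dictionary's class
#'   names.
#' @return an `MRRCCModel`.
#' @export
mrrccModel <- function(dictionary, config = rrcConfig(),
                       labels = names(perClassCounts(dictionary))) {
    new("MRRCCModel", dictionary = dictionary, config = config,
        labelSet = sort(labels))
}

#' Fit the meta-sample robust coding classifier
#'
#' Unit-l2-normalizes every training sample, extracts `q` meta-samples per
#' subclass by SVD ([buildDictionary()]), and stores the resulting
#' dictionary together with the coding configuration. No test information is
#' used; fitting is deterministic.
#'
#' @param train a labeled [GEPSet-class].
#' @param q meta-samples per subclass (scalar or named per-class vector);
#'   clamped per class to the class sample count.
#' @param config an [RRCConfig-class]; `beta = 2` (default) is the
#'   ridge-penalized variant ("MRRCC2"), `beta = 1` the lasso variant
#'   ("MRRCC1").
#' @return an [MRRCCModel-class].
#' @seealso [predict,MRRCCModel-method]
#' @export
mrrccFit <- function(train, q, config = rrcConfig()) {
    lab <- subclassLabels(train)
    if (is.null(lab)) stopf("training dataset carries no subclass labels")
    X <- exprsMatrix(train)
    norms <- sqrt(colSums(X^2))
    if (any(norms == 0))
        stopf("all-zero training sample(s): %s",
              paste(colnames(X)[norms == 0], collapse = ", "))
    Xn <- sweep(X, 2L, norms, "/")
    trainN <- GEPSet(Xn, labels = as.character(lab))
    dict <- buildDictionary(trainN, q)
    mrrccModel(dict, config)
}

predictVector <- function(model, y, uniformWeights = FALSE) {
    D <- model@dictionary@atoms
    if (length(y) != nrow(D))
        stopf("sample has %d genes but the model expects %d",
              length(y), nrow(D))
    y <- normalizeUnitL2(as.numeric(y))
    state <- ir3c(D, y, model@config, uniformWeights = uniformWeights)
    w <- state@weights
    alpha <- state@alpha
    cc <- model@dictionary@columnClass
    classes <- sort(names(model@dictionary@perClassCounts))
    resid <- vapply(classes, function(d) {
        blk <- cc == d
        rd <- y - drop(D[, blk, drop = FALSE] %*% alpha[blk])
        sqrt(sum(w * rd^2))
    }, numeric(1))
    best <- argminLabel(resid)
    new("MRRCCPrediction", predictedLabel = best, residuals = resid,
        alpha = alpha, weights = w, iterations = state@iterations,
        converged = state@converged)
}

#' Predict subclasses with a fitted model
#'
#' Codes each (internally unit-normalized) sample against the full
#' meta-sample dictionary with [ir3c()], then assigns the subclass `d`
#' minimizing the weighted block-restricted reconstruction residual
#' `l_d = ||W^{1/2}(y - D_d alpha_d)||_2`, where `alpha_d` zeroes all
#' coefficients outside subclass `d`'s block and `W` is the final weight
#' matrix of the converged coding. Ties — residuals equal up to a tiny
#' relative tolerance (1e-9) that merges float-level differences — go to the
#' lexicographically smallest label.
#'
#' @param object an [MRRCCModel-class].
#' @param newdata a numeric vector (one sample), a genes x samples matrix,
#'   or a [GEPSet-class].
#' @param uniformWeights logical; force all gene weights to 1 (ablation of
#'   the robust reweighting).
#' @param ... ignored.
#' @return an [MRRCCPrediction-class] for a single vector; otherwise a named
#'   list of predictions in sample order (see [predictionTable()]).
#' @export
setMethod("predict", "MRRCCModel",
    function(object, newdata, uniformWeights = FALSE, ...) {
        if (is(newdata, "GEPSet")) newdata <- exprsMatrix(newdata)
        if (is.numeric(newdata) && is.null(dim(newdata)))
            return(predictVector(object, newdata, uniformWeights))
        newdata <- as.matrix(newdata)
        ids <- colnames(newdata)
        if (is.null(ids)) ids <- sprintf("sample%d", seq_len(ncol(newdata)))
        out <- stats::setNames(vector("list", ncol(newdata)), ids)
        for (j in seq_len(ncol(newdata))) {
            out[[j]] <- tryCatch(
                predictVector(object, newdata[, j], uniformWeights),
                error = function(err) stopf(
                    "prediction failed for sample '%s': %s",
                    ids[j], conditionMessage(err)))
        }
        out
    })

#' @rdname MRRCCModel-class
#' @export
setMethod("modelDictionary", "MRRCCModel", function(x) x@dictionary)

#' @rdname MRRCCModel-class
#' @export
setMethod("modelConfig", "MRRCCModel", function(x) x@config)

#' @rdname MRRCCModel-class
#' @export
setMethod("labelSet", "MRRCCModel", function(x) x@labelSet)

setMethod("show", "MRRCCModel", function(object) {
    cat(sprintf(
        "MRRCCModel (beta=%d): %d genes, %d dictionary atoms, %d subclasses\n",
        object@config@beta, nrow(object@dictionary@atoms),
        ncol(object@dictionary@atoms), length(object@labelSet)))
    invisible(NULL)
})

#' @rdname MRRCCPrediction-class
#' @export
setMethod("predictedLabel", "MRRCCPrediction", function(x) x@predictedLabel)

#' @rdname MRRCCPrediction-class
#' @export
setMethod("classResiduals", "MRRCCPrediction", function(x) x@residuals)

#' @rdname MRRCCPrediction-class
#' @export
setMethod("codingCoefficients", "MRRCCPrediction", function(x) x@alpha)

#' @rdname MRRCCPrediction-class
#' @export
setMethod("geneWeights", "MRRCCPrediction", function(x) x@weights)

setMethod("show", "MRRCCPrediction", function(object) {
    cat(sprintf("MRRCCPrediction: '%s'\n", object@predictedLabel))
    r <- sort(object@residuals)
    cat("  residuals:",
        paste(sprintf("%s=%.4g", names(r), r), collapse = ", "), "\n")
    invisible(NULL)
})
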