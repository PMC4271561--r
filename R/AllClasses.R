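#' @import methods
NULL

#' Gene-expression dataset container
#'
#' `GEPSet` is a thin [SummarizedExperiment::SummarizedExperiment] carrying a
#' genes x samples expression matrix in the `"exprs"` assay and, optionally,
#' per-sample subclass labels in `colData(x)$subclass`. The canonical
#' orientation throughout the package is genes in rows, samples in columns.
#'
#' Validity requires finite values, unique gene and sample identifiers, and,
#' when labels are present, a label set with at least two subclasses and no
#' unlabeled sample.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [GEPSet()], [readExpressionMatrix()], [simulateExpression()]
#' @export
setClass("GEPSet", contains = "SummarizedExperiment")

setValidity("GEPSet", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        return("assay 'exprs' is missing")
    x <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(x))
        msg <- c(msg, "expression values must be numeric")
    else if (length(x) && any(!is.finite(x)))
        msg <- c(msg, "expression values contain missing or non-finite entries")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    if ("subclass" %in% colnames(cd)) {
        lab <- cd$subclass
        if (!is.factor(lab))
            msg <- c(msg, "subclass labels must be a factor")
        else {
            if (anyNA(lab))
                msg <- c(msg, "every sample must carry a subclass label")
            if (nlevels(lab) < 2L)
                msg <- c(msg, "at least 2 subclasses required")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Meta-sample coding dictionary
#'
#' The concatenation `D = [M_1, ..., M_k]` of per-subclass meta-sample blocks.
#' Each block holds the leading left singular vectors of that subclass's
#' training submatrix, in descending singular-value order, so that within a
#' block the columns are orthonormal. The optional `patterns` slot keeps each
#' block's expression-pattern matrix `V_i` (singular values times right
#' singular vectors), so that `M_i %*% V_i` is the best rank-`q_i`
#' approximation of the class submatrix.
#'
#' @slot atoms numeric matrix, genes x Q dictionary columns.
#' @slot columnClass character vector mapping each column to its subclass.
#' @slot perClassCounts named integer vector, meta-samples per subclass.
#' @slot patterns named list of per-class `V_i` matrices (may be empty).
#' @seealso [buildDictionary()], [extractMetaSamples()]
#' @export
setClass("MetaSampleDictionary",
    representation(
        atoms = "matrix",
        columnClass = "character",
        perClassCounts = "integer",
        patterns = "list"
    )
)

setValidity("MetaSampleDictionary", function(object) {
    msg <- character()
    D <- object@atoms
    cc <- object@columnClass
    qs <- object@perClassCounts
    if (ncol(D) != length(cc))
        msg <- c(msg, "one class assignment per dictionary column required")
    if (!identical(cc, rep(names(qs), qs)))
        msg <- c(msg, "class blocks must be contiguous and match perClassCounts")
    if (any(qs < 1L))
        msg <- c(msg, "every subclass needs at least one meta-sample")
    if (any(qs > min(nrow(D), ncol(D))) && nrow(D) < max(qs))
        msg <- c(msg, "block size exceeds gene dimension")
    if (length(msg) == 0L && ncol(D) > 0L) {
        for (cl in names(qs)) {
            B <- D[, cc == cl, drop = FALSE]
            G <- crossprod(B)
            if (max(abs(G - diag(ncol(B)))) > 1e-8) {
                msg <- c(msg, sprintf(
                    "meta-sample block '%s' is not orthonormal", cl))
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' Tunables of the regularized robust coding model
#'
#' @slot beta integer, 1 or 2; exponent of the generalized-Gaussian
#'   coefficient prior. `beta = 1` gives a lasso (l1) coefficient penalty,
#'   `beta = 2` a ridge (l2) penalty.
#' @slot tau quantile fraction in (0,1) used to estimate the residual scale
#'   `delta` (the `max(1, floor(tau*n))`-th largest squared residual).
#' @slot s positive constant; the weight-function sharpness is `mu = s/delta`.
#' @slot lambda nonnegative regularization weight on the coefficients.
#' @slot phi positive convergence tolerance on the relative change of the
#'   weight vector between iterations.
#' @slot maxIter positive iteration cap of the reweighting loop.
#' @slot deltaFloor tiny positive floor on `delta` keeping `mu` finite on
#'   near-perfect reconstructions.
#' @seealso [rrcConfig()]
#' @export
setClass("RRCConfig",
    representation(
        beta = "integer",
        tau = "numeric",
        s = "numeric",
        lambda = "numeric",
        phi = "numeric",
        maxIter = "integer",
        deltaFloor = "numeric"
    )
)

setValidity("RRCConfig", function(object) {
    msg <- character()
    if (!(length(object@beta) == 1L && object@beta %in% c(1L, 2L)))
        msg <- c(msg, "beta must be 1 or 2")
    if (!(length(object@tau) == 1L && object@tau > 0 && object@tau < 1))
        msg <- c(msg, "tau must lie in (0, 1)")
    if (!(length(object@s) == 1L && object@s > 0))
        msg <- c(msg, "s must be positive")
    if (!(length(object@lambda) == 1L && object@lambda >= 0))
        msg <- c(msg, "lambda must be nonnegative")
    if (!(length(object@phi) == 1L && object@phi > 0))
        msg <- c(msg, "phi must be positive")
    if (!(length(object@maxIter) == 1L && object@maxIter >= 1L))
        msg <- c(msg, "maxIter must be a positive integer")
    if (!(length(object@deltaFloor) == 1L && object@deltaFloor > 0))
        msg <- c(msg, "deltaFloor must be positive")
    if (length(msg)) msg else TRUE
})

#' Solver state of the iteratively reweighted robust coding loop
#'
#' Returned by [ir3c()]. `residual` always equals `y - D %*% alpha` for the
#' final coefficients; `weights` is the diagonal of the final per-gene weight
#' matrix; `objectiveTrace` records, per iteration, the residual scale
#' `delta`, the sharpness `mu`, the accepted line-search step and the
#' surrogate objective before and after the coefficient update.
#'
#' @slot alpha numeric coefficient vector (length Q).
#' @slot residual numeric per-gene residual (length n).
#' @slot weights numeric per-gene weights in (0, 1].
#' @slot delta,mu numeric; final scale and sharpness of the weight function.
#' @slot step numeric; last accepted line-search step size.
#' @slot iterations integer iteration count.
#' @slot converged logical; whether the weight-change criterion was met.
#' @slot objectiveTrace data.frame with columns iter, delta, mu, step,
#'   objBefore, objAfter.
#' @export
setClass("RRCState",
    representation(
        alpha = "numeric",
        residual = "numeric",
        weights = "numeric",
        delta = "numeric",
        mu = "numeric",
        step = "numeric",
        iterations = "integer",
        converged = "logical",
        objectiveTrace = "data.frame"
    )
)

#' Fitted meta-sample robust coding classifier
#'
#' @slot dictionary a [MetaSampleDictionary-class] built from unit-normalized
#'   training samples.
#' @slot config the [RRCConfig-class] used at fit time and for prediction.
#' @slot labelSet character vector of subclass names (sorted).
#' @seealso [mrrccFit()], [predict,MRRCCModel-method]
#' @export
setClass("MRRCCModel",
    representation(
        dictionary = "MetaSampleDictionary",
        config = "RRCConfig",
        labelSet = "character"
    )
)

setValidity("MRRCCModel", function(object) {
    msg <- character()
    if (!setequal(object@labelSet, names(object@dictionary@perClassCounts)))
        msg <- c(msg, "label set must match the dictionary's class blocks")
    if (is.unsorted(object@labelSet))
        msg <- c(msg, "label set must be sorted")
    if (length(msg)) msg else TRUE
})

#' Single-sample classification result
#'
#' The predicted subclass is the one whose block-restricted reconstruction of
#' the (unit-normalized) sample has the smallest weighted residual norm
#' `l_d = ||W^{1/2} (y - D_d alpha_d)||_2`; ties go to the lexicographically
#' smallest label.
#'
#' @slot predictedLabel character scalar.
#' @slot residuals named numeric vector of per-subclass weighted residuals.
#' @slot alpha final coding coefficients over all dictionary columns.
#' @slot weights final per-gene weights.
#' @slot iterations,converged solver diagnostics from [ir3c()].
#' @export
setClass("MRRCCPrediction",
    representation(
        predictedLabel = "character",
        residuals = "numeric",
        alpha = "numeric",
        weights = "numeric",
        iterations = "integer",
        converged = "logical"
    )
)

setValidity("MRRCCPrediction", function(object) {
    msg <- character()
    r <- object@residuals
    if (is.null(names(r)) || anyDuplicated(names(r)))
        msg <- c(msg, "residuals must be uniquely named by subclass")
    if (any(r < 0))
        msg <- c(msg, "residuals must be nonnegative")
    if (length(r) && !identical(object@predictedLabel, argminLabel(r)))
        msg <- c(msg, "predictedLabel must be the argmin residual label")
    if (length(msg)) msg else TRUE
})

#' Nested cross-validation result
#'
#' @slot foldTable data.frame with one row per outer fold: fold, chosenQ
#'   (meta-sample count selected by the inner layer), accuracy.
#' @slot meanAccuracy mean of the outer-fold accuracies.
#' @slot seed integer seed the fold assignment derives from.
#' @slot audit list, one element per outer fold, recording the outer
#'   train/test indices and every inner train/test index set used during
#'   model selection (for leakage checks).
#' @seealso [twoLayerCV()]
#' @export
setClass("CVResult",
    representation(
        foldTable = "data.frame",
        meanAccuracy = "numeric",
        seed = "integer",
        audit = "list"
    )
)
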