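#' Simulate multi-subclass expression data with low-rank class structure
#'
#' Emulates the structural premise of meta-sample coding: each subclass's
#' samples lie near a low-dimensional linear subspace. Per subclass,
#' `factorsPerClass` latent gene profiles are drawn with standard-normal
#' entries; each sample is a random positive mixture of its class's factors
#' (mixing weights uniform on [0.5, 1.5], renormalized to sum to one, which
#' keeps samples away from the origin so unit normalization is stable) plus
#' gene-wise Gaussian noise. Optional outlier-gene contamination replaces a
#' random subset of genes per sample with large-variance noise (see
#' [contaminateSamples()]).
#'
#' No attempt is made to imitate real microarray/RNA-seq marginal
#' distributions; the linear-subspace structure is what the classifier
#' assumes and what its tests need.
#'
#' @param nGenes number of genes (rows).
#' @param nClasses number of subclasses `k >= 2`.
#' @param samplesPerClass samples per subclass.
#' @param factorsPerClass latent rank of each subclass
#'   (`<= samplesPerClass`).
#' @param noiseSd standard deviation of the additive gene-wise noise.
#' @param outlierGeneFraction fraction in [0, 1) of genes contaminated per
#'   sample (0 = none).
#' @param outlierMagnitude contamination noise scale, in multiples of each
#'   sample's value standard deviation.
#' @param seed integer seed; generation is fully reproducible.
#' @return `list(dataset=, truth=)` where `truth` records the per-class
#'   factor matrices, per-sample mixing weights, and the contamination mask
#'   (NULL when no contamination was applied).
#' @export
simulateExpression <- function(nGenes = 500L, nClasses = 3L,
                               samplesPerClass = 40L, factorsPerClass = 3L,
                               noiseSd = 0.1, outlierGeneFraction = 0,
                               outlierMagnitude = 5, seed = 1L) {
    nGenes <- as.integer(nGenes)
    nClasses <- as.integer(nClasses)
    samplesPerClass <- as.integer(samplesPerClass)
    factorsPerClass <- as.integer(factorsPerClass)
    if (min(nGenes, nClasses, samplesPerClass, factorsPerClass) < 1L)
        stopf("all counts must be positive")
    if (nClasses < 2L) stopf("at least 2 subclasses required")
    if (factorsPerClass > samplesPerClass)
        stopf("factorsPerClass (%d) exceeds samplesPerClass (%d)",
              factorsPerClass, samplesPerClass)
    if (noiseSd < 0) stopf("noiseSd must be nonnegative")
    if (outlierGeneFraction < 0 || outlierGeneFraction >= 1)
        stopf("outlierGeneFraction must lie in [0, 1)")
    classes <- sprintf("class%02d", seq_len(nClasses))
    m <- nClasses * samplesPerClass
    out <- withSeed(seed, {
        X <- matrix(0, nGenes, m)
        factors <- stats::setNames(vector("list", nClasses), classes)
        mixings <- stats::setNames(vector("list", nClasses), classes)
        col <- 0L
        for (cl in classes) {
            Fc <- matrix(stats::rnorm(nGenes * factorsPerClass),
                         nGenes, factorsPerClass)
            W <- matrix(stats::runif(factorsPerClass * samplesPerClass,
                                     0.5, 1.5),
                        factorsPerClass, samplesPerClass)
            W <- sweep(W, 2L, colSums(W), "/")
            S <- Fc %*% W
            if (noiseSd > 0)
                S <- S + matrix(stats::rnorm(length(S), sd = noiseSd),
                                nrow(S), ncol(S))
            X[, col + seq_len(samplesPerClass)] <- S
            factors[[cl]] <- Fc
            mixings[[cl]] <- W
            col <- col + samplesPerClass
        }
        list(X = X, factors = factors, mixings = mixings)
    })
    labels <- rep(classes, each = samplesPerClass)
    ids <- sprintf("%s.s%02d", labels, rep(seq_len(samplesPerClass),
                                           nClasses))
    dataset <- GEPSet(out$X, geneIds = sprintf("g%04d", seq_len(nGenes)),
                      sampleIds = ids, labels = labels)
    mask <- NULL
    if (outlierGeneFraction > 0) {
        cont <- contaminateSamples(dataset, outlierGeneFraction,
                                   outlierMagnitude, seed = seed + 1L)
        dataset <- cont$dataset
        mask <- cont$mask
    }
    list(dataset = dataset,
         truth = list(factors = out$factors, mixings = out$mixings,
                      contaminationMask = mask))
}

#' Contaminate samples with outlier genes
#'
#' For each sample independently, `floor(fraction * nGenes)` randomly chosen
#' genes are replaced by Gaussian draws whose standard deviation is
#' `magnitude` times that sample's (pre-contamination) value standard
#' deviation — the gross per-gene corruption the robust weight function is
#' designed to downweight.
#'
#' @param dataset a [GEPSet-class].
#' @param fraction fraction of genes to corrupt per sample, in [0, 1).
#' @param magnitude positive noise scale multiplier.
#' @param seed integer seed.
#' @return `list(dataset=, mask=)`; `mask` is a logical genes x samples
#'   matrix marking the replaced entries.
#' @export
contaminateSamples <- function(dataset, fraction, magnitude = 5,
                               seed = 1L) {
    if (fraction < 0 || fraction >= 1)
        stopf("fraction must lie in [0, 1)")
    if (magnitude <= 0) stopf("magnitude must be positive")
    X <- exprsMatrix(dataset)
    mask <- matrix(FALSE, nrow(X), ncol(X), dimnames = dimnames(X))
    nAlter <- floor(fraction * nrow(X))
    if (nAlter > 0L) {
        withSeed(seed, {
            for (j in seq_len(ncol(X))) {
                idx <- sample(nrow(X), nAlter)
                X[idx, j] <- stats::rnorm(nAlter,
                                          sd = magnitude * stats::sd(X[, j]))
                mask[idx, j] <- TRUE
            }
        })
    }
    lab <- subclassLabels(dataset)
    out <- GEPSet(X, labels = if (is.null(lab)) NULL
                  else as.character(lab))
    list(dataset = out, mask = mask)
}
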