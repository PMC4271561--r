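# Small seeded fixtures shared across test files. Everything is generated
# in code; nothing is read from disk.

# compact labeled dataset with low-rank class structure
smallDataset <- function(seed = 42L, nGenes = 150L, nClasses = 3L,
                         samplesPerClass = 15L, factorsPerClass = 3L,
                         noiseSd = 0.1) {
    simulateExpression(nGenes = nGenes, nClasses = nClasses,
                       samplesPerClass = samplesPerClass,
                       factorsPerClass = factorsPerClass,
                       noiseSd = noiseSd, seed = seed)$dataset
}

# random weighted-coding instance for solver tests
randomInstance <- function(seed, n = 30L, Q = 6L) {
    set.seed(seed)
    list(D = matrix(rnorm(n * Q), n, Q),
         y = rnorm(n),
         w = runif(n, 0.1, 1))
}

objL2 <- function(D, y, w, lambda, a)
    sum(w * (y - drop(D %*% a))^2) + lambda * sum(a^2)

objL1 <- function(D, y, w, lambda, a)
    sum(w * (y - drop(D %*% a))^2) + lambda * sum(abs(a))

# generic black-box minimizer of the weighted ridge objective
oracleL2 <- function(D, y, w, lambda) {
    fit <- optim(rep(0, ncol(D)), function(a) objL2(D, y, w, lambda, a),
                 method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    fit$par
}

# proximal-gradient (ISTA) oracle for the weighted lasso objective
oracleL1 <- function(D, y, w, lambda, iters = 50000L) {
    Dt <- sqrt(w) * D
    yt <- sqrt(w) * y
    L <- 2 * (svd(Dt, nu = 0, nv = 0)$d[1])^2
    step <- 1 / L
    a <- rep(0, ncol(Dt))
    soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
    for (i in seq_len(iters)) {
        grad <- 2 * drop(crossprod(Dt, drop(Dt %*% a) - yt))
        aNew <- soft(a - step * grad, step * lambda)
        if (max(abs(aNew - a)) < 1e-12) { a <- aNew; break }
        a <- aNew
    }
    a
}

# stratified per-class split used by the label-recovery checks
splitPerClass <- function(dataset, trainPerClass, seed)
    bdmSplit(dataset, trainPerClass, seed = seed)

predictedLabels <- function(preds)
    vapply(preds, predictedLabel, character(1))
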