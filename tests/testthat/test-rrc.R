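test_that("logistic weights hit their anchor values and bounds", {
    # omega(0) with mu*delta = 8
    expect_equal(weightFn(0, mu = 8, delta = 1), 1 / (1 + exp(-8)),
                 tolerance = 1e-12)
    # logistic midpoint at e^2 = delta (exactly representable values)
    expect_identical(weightFn(0.5, mu = 5, delta = 0.25), 0.5)
    # two demarcation widths out with mu = 8/delta
    d <- 0.07
    expect_equal(weightFn(sqrt(2 * d), mu = 8 / d, delta = d),
                 1 / (1 + exp(8)), tolerance = 1e-12)
    expect_error(weightFn(c(1, 2), mu = -1, delta = 1), "positive")
    expect_error(weightFn(c(1, 2), mu = 1, delta = 0), "positive")
})

test_that("weights decrease strictly in |e| and are sign-symmetric", {
    e <- seq(0.01, 3, length.out = 60)
    w <- weightFn(e, mu = 4, delta = 0.5)
    expect_true(all(diff(w) < 0))
    expect_true(all(w > 0 & w <= 1))
    expect_equal(weightFn(-e, 4, 0.5), w)
})

test_that("the residual scale is the floor(tau*n)-th order statistic of e^2", {
    expect_equal(estimateDelta(c(1, 2, 3), tau = 0.8), 4)   # l = 2, middle
    # l clamps to 1 when floor(tau*n) = 0 -> smallest squared residual
    expect_equal(estimateDelta(c(3, 1, 2), tau = 0.2), 1)
    # constant residuals give c^2 for any tau
    for (tau in c(0.1, 0.5, 0.9))
        expect_equal(estimateDelta(rep(2.5, 7), tau), 6.25)
    expect_error(estimateDelta(numeric(0), 0.5), "empty")
    # floored on perfect reconstructions
    expect_equal(estimateDelta(rep(0, 5), 0.9, deltaFloor = 1e-12), 1e-12)
})

test_that("the induced loss is zero at zero, even, and monotone in |e|", {
    mu <- 3; d <- 0.4
    expect_identical(rhoTheta(0, mu, d), 0)
    z <- seq(0.05, 2, length.out = 25)
    expect_equal(rhoTheta(-z, mu, d), rhoTheta(z, mu, d))
    expect_true(all(diff(rhoTheta(z, mu, d)) > 0))
    # extreme sharpness must not overflow
    expect_true(all(is.finite(rhoTheta(z, mu = 1e8, delta = 1e-9))))
})

test_that("weighted ridge solve matches closed forms and a black-box minimizer", {
    # orthonormal square D, identity weights, lambda 0 -> alpha = D'y
    Dq <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
    y <- c(1, -2, 0.5, 3)
    expect_equal(solveWeightedL2(Dq, y, rep(1, 4), 0), drop(crossprod(Dq, y)),
                 tolerance = 1e-10)
    # zero target -> zero coefficients
    inst <- randomInstance(1, n = 10L, Q = 4L)
    expect_equal(solveWeightedL2(inst$D, rep(0, 10), inst$w, 0.5),
                 rep(0, 4), tolerance = 1e-12)
    # random instances against optim
    for (seed in 1:5) {
        inst <- randomInstance(seed, n = 12L, Q = 5L)
        for (lam in c(0, 0.1, 1)) {
            a <- solveWeightedL2(inst$D, inst$y, inst$w, lam)
            ao <- oracleL2(inst$D, inst$y, inst$w, lam)
            expect_lt(abs(objL2(inst$D, inst$y, inst$w, lam, a) -
                          objL2(inst$D, inst$y, inst$w, lam, ao)), 1e-6)
        }
    }
})

test_that("rank-deficient unpenalized ridge needs an explicit minimum-norm opt-in", {
    D <- cbind(c(1, 0), c(2, 0))   # rank 1
    y <- c(3, 1)
    w <- c(1, 1)
    expect_error(solveWeightedL2(D, y, w, 0), "singular")
    a <- solveWeightedL2(D, y, w, 0, minNorm = TRUE)
    expect_equal(drop(D %*% a), c(3, 0), tolerance = 1e-10)
    # minimum-norm solution among minimizers
    expect_equal(a, c(3, 6) / 5, tolerance = 1e-10)
})

test_that("weighted ridge equals a conjugate-gradient solve of the normal equations", {
    for (seed in 1:3) {
        inst <- randomInstance(seed + 100, n = 25L, Q = 6L)
        lam <- 0.05
        A <- crossprod(inst$D, inst$w * inst$D) + lam * diag(6)
        b <- drop(crossprod(inst$D, inst$w * inst$y))
        # plain conjugate gradient on the SPD system
        x <- rep(0, 6); r <- b; p <- r; rs <- sum(r^2)
        for (i in 1:50) {
            Ap <- drop(A %*% p)
            a_ <- rs / sum(p * Ap)
            x <- x + a_ * p
            r <- r - a_ * Ap
            rsNew <- sum(r^2)
            if (sqrt(rsNew) < 1e-14) break
            p <- r + (rsNew / rs) * p
            rs <- rsNew
        }
        expect_equal(solveWeightedL2(inst$D, inst$y, inst$w, lam), x,
                     tolerance = 1e-8, ignore_attr = TRUE)
    }
})

test_that("weighted lasso solve matches hand solutions and the KKT zero rule", {
    # single-column: minimize (2-a)^2 + |a| -> a = 1.5
    a <- solveWeightedL1(matrix(c(1, 0), 2, 1), c(2, 0), c(1, 1), 1)
    expect_equal(a, 1.5, tolerance = 1e-9)

    # lambda at the zero-solution boundary: alpha = 0 iff
    # lambda >= 2 * max |Dtilde' ytilde|
    inst <- randomInstance(7, n = 8L, Q = 3L)
    Dt <- sqrt(inst$w) * inst$D
    yt <- sqrt(inst$w) * inst$y
    lamStar <- 2 * max(abs(crossprod(Dt, yt)))
    expect_identical(solveWeightedL1(inst$D, inst$y, inst$w, lamStar),
                     rep(0, 3))
    expect_identical(solveWeightedL1(inst$D, inst$y, inst$w, 1.01 * lamStar),
                     rep(0, 3))
    expect_gt(max(abs(solveWeightedL1(inst$D, inst$y, inst$w,
                                      0.95 * lamStar))), 0)

    # lambda -> 0+ approaches the exact interpolation for square invertible D
    set.seed(8)
    Ds <- matrix(rnorm(9), 3, 3)
    ys <- rnorm(3)
    aSmall <- solveWeightedL1(Ds, ys, rep(1, 3), 1e-9)
    expect_equal(aSmall, drop(solve(Ds, ys)), tolerance = 1e-4)
})

test_that("weighted lasso matches the proximal-gradient oracle on random instances", {
    for (seed in 1:6) {
        inst <- randomInstance(seed + 50, n = 20L, Q = 6L)
        lam <- c(0.05, 0.2, 1)[(seed %% 3) + 1]
        a <- solveWeightedL1(inst$D, inst$y, inst$w, lam)
        ao <- oracleL1(inst$D, inst$y, inst$w, lam)
        expect_lt(abs(objL1(inst$D, inst$y, inst$w, lam, a) -
                      objL1(inst$D, inst$y, inst$w, lam, ao)), 1e-5)
    }
})

test_that("the surrogate objective decomposes as loss plus penalty", {
    inst <- randomInstance(4, n = 10L, Q = 4L)
    mu <- 6; d <- 0.2; lam <- 0.3
    a <- rnorm(4)
    for (beta in c(1L, 2L)) {
        manual <- sum(rhoTheta(inst$y - drop(inst$D %*% a), mu, d)) +
            lam * sum(abs(a)^beta)
        expect_equal(surrogateObjective(inst$D, inst$y, a, mu, d, lam, beta),
                     manual)
    }
    # exact reconstruction leaves only the penalty
    yExact <- drop(inst$D %*% a)
    expect_equal(
        surrogateObjective(inst$D, yExact, a, mu, d, lam, 2L) /
            (lam * sum(a^2)), 1, tolerance = 1e-12)
    # alpha = 0 leaves only the loss
    expect_equal(surrogateObjective(inst$D, inst$y, rep(0, 4), mu, d,
                                    lam, 2L),
                 sum(rhoTheta(inst$y, mu, d)))
})

test_that("the reweighting loop starts at the dictionary mean and respects maxIter", {
    ds <- smallDataset(seed = 17L)
    dict <- buildDictionary(ds, 3)
    D <- dictionaryAtoms(dict)
    y <- normalizeUnitL2(exprsMatrix(ds)[, 1])

    # a single capped iteration performs one weighted solve, unconverged
    st1 <- ir3c(dict, y, rrcConfig(maxIter = 1L))
    expect_identical(st1@iterations, 1L)
    expect_false(st1@converged)
    # that solve used weights from the residual of the uniform start,
    # whose reconstruction is the mean of all meta-samples
    e0 <- y - rowMeans(D)
    d0 <- estimateDelta(e0, 0.9)
    w0 <- weightFn(e0, 8 / d0, d0)
    expect_equal(st1@alpha, solveWeightedL2(D, y, w0, 1e-3,
                                            minNorm = TRUE),
                 tolerance = 1e-12, ignore_attr = TRUE)

    st <- ir3c(dict, y, rrcConfig())
    expect_true(st@converged)
    expect_lte(st@iterations, 100L)
    expect_equal(st@residual, y - drop(D %*% st@alpha))
    expect_true(all(st@weights > 0 & st@weights <= 1))
})

test_that("the surrogate objective never increases across accepted steps", {
    ds <- smallDataset(seed = 23L)
    dict <- buildDictionary(ds, 3)
    X <- exprsMatrix(ds)
    for (j in c(1L, 10L, 25L, 40L)) {
        for (beta in c(1L, 2L)) {
            st <- ir3c(dict, normalizeUnitL2(X[, j]),
                       rrcConfig(beta = beta))
            tr <- st@objectiveTrace
            expect_true(all(tr$objAfter <= tr$objBefore + 1e-12))
            expect_true(all(tr$step > 0 & tr$step <= 1))
        }
    }
})

test_that("a noiseless dictionary atom is recovered with near-zero residual", {
    ds <- smallDataset(seed = 29L)
    dict <- buildDictionary(ds, 3)
    y <- dictionaryAtoms(dict)[, 4]
    st <- ir3c(dict, y, rrcConfig(lambda = 0))
    expect_true(st@converged)
    expect_lt(sqrt(sum(st@residual^2)), 1e-6)
    expect_true(all(st@weights > 0.99))
    expect_equal(unname(st@alpha[4]), 1, tolerance = 1e-6)
})

test_that("coding cost scales roughly linearly in the gene dimension", {
    cfg <- rrcConfig(maxIter = 4L, phi = 1e-9)
    timeFor <- function(n) {
        ds <- smallDataset(seed = 31L, nGenes = n, samplesPerClass = 10L)
        dict <- buildDictionary(ds, 3)
        y <- normalizeUnitL2(exprsMatrix(ds)[, 2])
        ir3c(dict, y, cfg)  # warm the path once
        median(vapply(1:5, function(i)
            system.time(ir3c(dict, y, cfg))[["elapsed"]], numeric(1)))
    }
    tSmall <- timeFor(200L)
    tBig <- timeFor(3200L)
    # 16x the genes should cost far less than a quadratic blow-up (256x);
    # allow generous slack around the linear trend
    expect_lt(tBig, 64 * max(tSmall, 1e-3))
})
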