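#' Configure the regularized robust coding model
#'
#' Defaults follow the method's published operating point: the weight
#' sharpness constant `s = 8` (so `mu = s/delta`), residual-scale quantile
#' `tau = 0.9`, an l2 coefficient penalty (`beta = 2`), and a small ridge
#' weight `lambda = 1e-3`.
#'
#' @param beta 1 (lasso coefficient penalty, "MRRCC1") or 2 (ridge,
#'   "MRRCC2").
#' @param tau residual quantile fraction in (0,1).
#' @param s positive sharpness constant; `mu = s/delta`.
#' @param lambda nonnegative coefficient penalty weight.
#' @param phi convergence tolerance on the relative weight change.
#' @param maxIter iteration cap of the reweighting loop.
#' @param deltaFloor positive floor on the residual scale `delta`.
#' @return an [RRCConfig-class].
#' @export
rrcConfig <- function(beta = 2L, tau = 0.9, s = 8, lambda = 1e-3,
                      phi = 1e-2, maxIter = 100L, deltaFloor = 1e-12) {
    new("RRCConfig", beta = as.integer(beta), tau = as.numeric(tau),
        s = as.numeric(s), lambda = as.numeric(lambda),
        phi = as.numeric(phi), maxIter = as.integer(maxIter),
        deltaFloor = as.numeric(deltaFloor))
}

setMethod("show", "RRCConfig", function(object) {
    cat(sprintf(
        "RRCConfig: beta=%d tau=%g s=%g lambda=%g phi=%g maxIter=%d\n",
        object@beta, object@tau, object@s, object@lambda, object@phi,
        object@maxIter))
    invisible(NULL)
})

#' Logistic gene-weight function
#'
#' `omega(e_i) = exp(mu*delta - mu*e_i^2) / (1 + exp(mu*delta - mu*e_i^2))`,
#' evaluated in the overflow-safe form `1 / (1 + exp(mu*e_i^2 - mu*delta))`.
#' Weights lie in (0, 1], equal 0.5 exactly at `e_i^2 = delta`, and decrease
#' strictly in `|e_i|`.
#'
#' @param e numeric residual vector.
#' @param mu,delta positive scalars: decreasing rate and demarcation point.
#' @return weight vector of `length(e)`.
#' @export
weightFn <- function(e, mu, delta) {
    if (!(is.numeric(mu) && length(mu) == 1L && mu > 0))
        stopf("mu must be a positive scalar")
    if (!(is.numeric(delta) && length(delta) == 1L && delta > 0))
        stopf("delta must be a positive scalar")
    w <- 1 / (1 + exp(mu * e^2 - mu * delta))
    pmax(w, .Machine$double.xmin)
}

#' Adaptive residual-scale estimate
#'
#' `delta` is the `l`-th order statistic (l-th smallest) of the squared
#' residuals with `l = max(1, floor(tau * n))` — i.e. essentially their
#' `tau`-quantile — floored at `deltaFloor` so that the weight sharpness
#' `mu = s/delta` stays finite on near-perfect reconstructions. With the
#' default `tau = 0.9` the worst-fitting ~10% of genes fall beyond the
#' demarcation point `e^2 = delta` and are downweighted as outliers; larger
#' `tau` treats fewer genes as outliers.
#'
#' @param e numeric residual vector (length n >= 1).
#' @param tau fraction in (0,1).
#' @param deltaFloor positive floor.
#' @return scalar `delta`.
#' @export
estimateDelta <- function(e, tau, deltaFloor = 1e-12) {
    n <- length(e)
    if (n < 1L) stopf("empty residual vector")
    if (!(tau > 0 && tau < 1)) stopf("tau must lie in (0, 1)")
    l <- max(1L, floor(tau * n))
    sq <- sort(e^2)
    max(sq[l], deltaFloor)
}

#' Robust residual loss induced by the logistic weight
#'
#' `rho(e_i) = -(1/(2*mu)) * (log(1 + exp(mu*delta - mu*e_i^2))
#'   - log(1 + exp(mu*delta)))`; it is even, zero at zero, and strictly
#' increasing in `|e_i|`. Used for objective monitoring and line search.
#'
#' @inheritParams weightFn
#' @return loss vector of `length(e)`.
#' @export
rhoTheta <- function(e, mu, delta) {
    if (!(mu > 0 && delta > 0)) stopf("mu and delta must be positive")
    -(log1pexp(mu * delta - mu * e^2) - log1pexp(mu * delta)) / (2 * mu)
}

#' Weighted ridge coding solve
#'
#' Minimizes `||W^{1/2}(y - D a)||_2^2 + lambda ||a||_2^2` through the normal
#' equations `(D' W D + lambda I) a = D' W y`; the solution is unique for
#' `lambda > 0`. With `lambda = 0` and a rank-deficient system, either an
#' error is raised or (with `minNorm = TRUE`) the minimum-norm least-squares
#' solution is returned.
#'
#' @param D numeric matrix (n x Q).
#' @param y numeric vector (length n).
#' @param w nonnegative weight vector (length n; diagonal of W).
#' @param lambda nonnegative scalar.
#' @param minNorm logical; fall back to the pseudoinverse solution when
#'   `lambda = 0` and `D' W D` is singular.
#' @return coefficient vector of length Q.
#' @export
solveWeightedL2 <- function(D, y, w, lambda, minNorm = FALSE) {
    stopifnot(nrow(D) == length(y), length(w) == length(y), lambda >= 0,
              all(w >= 0))
    wD <- w * D
    A <- crossprod(D, wD)
    b <- crossprod(D, w * y)
    if (lambda > 0) {
        diag(A) <- diag(A) + lambda
        return(unname(drop(solve(A, b))))
    }
    sol <- tryCatch(unname(drop(solve(A, b))), error = function(e) NULL)
    if (!is.null(sol)) return(sol)
    if (!minNorm)
        stopf(paste("D' W D is singular with lambda = 0;",
                    "set minNorm = TRUE for the minimum-norm solution"))
    Dt <- sqrt(w) * D
    sv <- svd(Dt)
    pos <- sv$d > max(dim(Dt)) * .Machine$double.eps * max(sv$d, 0)
    unname(drop(sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], sqrt(w) * y)) / sv$d[pos])))
}

softThreshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Weighted lasso coding solve
#'
#' Minimizes `||W^{1/2}(y - D a)||_2^2 + lambda ||a||_1` by cyclic
#' coordinate descent on the transformed problem `ytilde = W^{1/2} y`,
#' `Dtilde = W^{1/2} D`. Convergence is declared when the subgradient (KKT)
#' conditions hold within `tol`: `|2 Dtilde_j' r| <= lambda + tol` for zero
#' coefficients and `|2 Dtilde_j' r - lambda sign(a_j)| <= tol` otherwise.
#' In particular `a = 0` is optimal iff `lambda >= 2 max_j |Dtilde_j' ytilde|`.
#'
#' @inheritParams solveWeightedL2
#' @param lambda positive scalar.
#' @param tol KKT tolerance.
#' @param maxSweeps coordinate-descent sweep cap; exceeding it is an error
#'   reporting the residual KKT gap.
#' @return coefficient vector of length Q.
#' @export
solveWeightedL1 <- function(D, y, w, lambda, tol = 1e-6, maxSweeps = 20000L) {
    stopifnot(nrow(D) == length(y), length(w) == length(y), lambda > 0,
              all(w >= 0))
    sw <- sqrt(w)
    Dt <- sw * D
    yt <- sw * y
    Q <- ncol(Dt)
    cn <- colSums(Dt^2)
    a <- numeric(Q)
    r <- yt
    kktGap <- function() {
        g <- 2 * crossprod(Dt, r)      # = -gradient of ||r||^2 wrt a
        zero <- a == 0
        gap <- numeric(Q)
        gap[zero] <- pmax(abs(g[zero]) - lambda, 0)
        gap[!zero] <- abs(g[!zero] - lambda * sign(a[!zero]))
        max(gap, 0)
    }
    for (sweep in seq_len(maxSweeps)) {
        for (j in seq_len(Q)) {
            if (cn[j] == 0) next
            zj <- sum(Dt[, j] * r) + cn[j] * a[j]
            aj <- softThreshold(zj, lambda / 2) / cn[j]
            if (aj != a[j]) {
                r <- r - Dt[, j] * (aj - a[j])
                a[j] <- aj
            }
        }
        if (sweep %% 5L == 0L || sweep <= 2L) {
            if (kktGap() <= tol) return(a)
        }
    }
    if (kktGap() <= tol) return(a)
    stopf("weighted l1 solve did not converge: KKT gap %.3e after %d sweeps",
          kktGap(), maxSweeps)
}

#' Surrogate coding objective
#'
#' `sum_i rho(y_i - r_i a) + lambda * ||a||_beta^beta`, the robust residual
#' loss plus the generalized-Gaussian coefficient penalty (distribution
#' constants absorbed into `lambda`). Monitored across the reweighting loop
#' and used by its line search.
#'
#' @inheritParams solveWeightedL2
#' @param alpha coefficient vector.
#' @param mu,delta current weight-function parameters.
#' @param beta penalty exponent, 1 or 2.
#' @return scalar objective value.
#' @export
surrogateObjective <- function(D, y, alpha, mu, delta, lambda, beta) {
    e <- y - drop(D %*% alpha)
    sum(rhoTheta(e, mu, delta)) + lambda * sum(abs(alpha)^beta)
}

#' Iteratively reweighted regularized robust coding
#'
#' Codes a unit-norm sample `y` against the meta-sample dictionary under the
#' robust logistic-weight loss. Each iteration (i) computes the per-gene
#' residual `e = y - D alpha`, (ii) re-estimates the scale
#' `delta = ` [estimateDelta()] and sharpness `mu = s/delta`, (iii) computes
#' logistic weights, (iv) solves the weighted ridge (`beta = 2`) or lasso
#' (`beta = 1`) subproblem, and (v) moves `alpha` toward the subproblem
#' solution by a backtracking line search
#' (`v in {1, 1/2, ..., 2^-10}`; the first iteration takes the subproblem
#' solution directly) accepting the first step that does not increase the
#' surrogate objective; if no step is accepted the iterate is kept and the
#' loop stops. Iterations end when the relative change of the weight vector
#' falls below `phi`, or at `maxIter`.
#'
#' The initial coefficients are `alpha = (1/Q, ..., 1/Q)`, so the first
#' reconstruction `D alpha` is the mean of all meta-samples.
#'
#' @param D a [MetaSampleDictionary-class] or numeric dictionary matrix.
#' @param y numeric sample vector with unit l2 norm.
#' @param config an [RRCConfig-class].
#' @param uniformWeights logical; force every gene weight to 1 (disables the
#'   robust reweighting, leaving a plain regularized coding — mainly for
#'   ablation studies).
#' @return an [RRCState-class].
#' @export
ir3c <- function(D, y, config = rrcConfig(), uniformWeights = FALSE) {
    if (is(D, "MetaSampleDictionary")) D <- D@atoms
    if (ncol(D) == 0L) stopf("empty dictionary")
    if (nrow(D) != length(y))
        stopf("sample length %d does not match dictionary gene dimension %d",
              length(y), nrow(D))
    if (abs(sum(y^2) - 1) > 1e-6)
        stopf("y must be normalized to unit l2 norm (see normalizeUnitL2)")
    validObject(config)
    Q <- ncol(D)
    n <- nrow(D)
    alpha <- rep(1 / Q, Q)
    wPrev <- NULL
    w <- rep(1, n)
    delta <- config@deltaFloor
    mu <- config@s / delta
    step <- 1
    converged <- FALSE
    trace <- vector("list", config@maxIter)
    solveStep <- function(w) {
        if (config@beta == 2L) {
            solveWeightedL2(D, y, w, config@lambda, minNorm = TRUE)
        } else {
            solveWeightedL1(D, y, w, max(config@lambda,
                                         .Machine$double.eps))
        }
    }
    t <- 0L
    while (t < config@maxIter) {
        t <- t + 1L
        e <- y - drop(D %*% alpha)
        delta <- max(estimateDelta(e, config@tau, config@deltaFloor),
                     config@deltaFloor)
        mu <- config@s / delta
        w <- if (uniformWeights) rep(1, n) else weightFn(e, mu, delta)
        if (!is.null(wPrev)) {
            rel <- sqrt(sum((w - wPrev)^2)) / sqrt(sum(wPrev^2))
            if (rel < config@phi) {
                converged <- TRUE
                t <- t - 1L   # no update performed this pass
                break
            }
        }
        wPrev <- w
        alphaStar <- solveStep(w)
        objBefore <- surrogateObjective(D, y, alpha, mu, delta,
                                        config@lambda, config@beta)
        if (t == 1L) {
            alphaNew <- alphaStar
            step <- 1
            objAfter <- surrogateObjective(D, y, alphaNew, mu, delta,
                                           config@lambda, config@beta)
        } else {
            accepted <- FALSE
            for (v in 2^(-(0:10))) {
                cand <- alpha + v * (alphaStar - alpha)
                objCand <- surrogateObjective(D, y, cand, mu, delta,
                                              config@lambda, config@beta)
                if (objCand <= objBefore) {
                    alphaNew <- cand
                    step <- v
                    objAfter <- objCand
                    accepted <- TRUE
                    break
                }
            }
            if (!accepted) {
                # no admissible step: keep the iterate and stop
                converged <- TRUE
                t <- t - 1L
                break
            }
        }
        if (any(!is.finite(alphaNew)))
            stopf("non-finite coefficients in reweighting loop")
        alpha <- alphaNew
        trace[[t]] <- data.frame(iter = t, delta = delta, mu = mu,
                                 step = step, objBefore = objBefore,
                                 objAfter = objAfter)
    }
    e <- y - drop(D %*% alpha)
    trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
    if (is.null(trace))
        trace <- data.frame(iter = integer(), delta = numeric(),
                            mu = numeric(), step = numeric(),
                            objBefore = numeric(), objAfter = numeric())
    new("RRCState", alpha = alpha, residual = e, weights = w,
        delta = delta, mu = mu, step = step, iterations = max(t, 1L),
        converged = converged, objectiveTrace = trace)
}

#' @rdname MRRCCPrediction-class
#' @export
setMethod("codingCoefficients", "RRCState", function(x) x@alpha)

#' @rdname MRRCCPrediction-class
#' @export
setMethod("geneWeights", "RRCState", function(x) x@weights)

setMethod("show", "RRCState", function(object) {
    cat(sprintf(
        "RRCState: %d iteration(s), %sconverged, delta=%.3g, |alpha|=%d\n",
        object@iterations, if (object@converged) "" else "NOT ",
        object@delta, length(object@alpha)))
    invisible(NULL)
})
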