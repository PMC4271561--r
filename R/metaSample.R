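#' Extract meta-samples from one subclass's expression submatrix
#'
#' Decomposes a genes x samples class submatrix `A` by singular value
#' decomposition and keeps the `q` leading components: the meta-samples `M`
#' are the first `q` left singular vectors (unit norm, descending singular
#' value), and the expression patterns `V` carry the singular values times
#' the right singular vectors, so `M %*% V` is the best rank-`q`
#' approximation of `A` (Eckart-Young).
#'
#' A deterministic sign convention is applied: each singular vector is
#' flipped so its largest-magnitude entry (first such entry on ties) is
#' positive, with the corresponding row of `V` flipped to preserve the
#' product.
#'
#' @param classMatrix numeric matrix, genes x class samples, all finite.
#' @param q number of meta-samples, `1 <= q <= min(dim(classMatrix))`.
#' @return list with elements `M` (n x q) and `V` (q x m_i).
#' @examples
#' A <- outer(c(3, 0, 4), c(1, 1))
#' extractMetaSamples(A, 1)$M   # (0.6, 0, 0.8)
#' @export
extractMetaSamples <- function(classMatrix, q) {
    A <- as.matrix(classMatrix)
    if (any(!is.finite(A))) stopf("class matrix contains non-finite values")
    r <- min(dim(A))
    if (length(q) != 1L || q < 1L || q != round(q) || q > r)
        stopf("q must be an integer in [1, %d], got %s", r, format(q))
    if (all(A == 0)) stopf("class matrix is all zero (rank 0)")
    sv <- svd(A, nu = q, nv = q)
    M <- sv$u
    V <- sv$d[seq_len(q)] * t(sv$v)   # diag(d_q) %*% t(v_q)
    for (j in seq_len(q)) {
        top <- which.max(abs(M[, j]))
        if (M[top, j] < 0) {
            M[, j] <- -M[, j]
            V[j, ] <- -V[j, ]
        }
    }
    V <- matrix(V, nrow = q, dimnames = list(NULL, colnames(A)))
    rownames(M) <- rownames(A)
    list(M = M, V = V)
}

#' Build the meta-sample dictionary from labeled training data
#'
#' Runs [extractMetaSamples()] on each subclass's submatrix and concatenates
#' the blocks `D = [M_1, ..., M_k]` in lexicographic label order. A subclass
#' with fewer samples than the requested number of meta-samples has its
#' count clamped to its sample count, with a warning.
#'
#' @param train a labeled [GEPSet-class].
#' @param qPerClass a single positive integer, or a named vector/list giving
#'   a count per subclass.
#' @return a [MetaSampleDictionary-class] whose `patterns` slot carries the
#'   per-class `V_i` matrices.
#' @export
buildDictionary <- function(train, qPerClass) {
    lab <- subclassLabels(train)
    if (is.null(lab)) stopf("training dataset carries no subclass labels")
    classes <- sort(unique(as.character(lab)))
    X <- exprsMatrix(train)
    qMap <- if (length(qPerClass) == 1L && is.null(names(qPerClass))) {
        stats::setNames(rep(as.integer(qPerClass), length(classes)), classes)
    } else {
        if (!all(classes %in% names(qPerClass)))
            stopf("qPerClass must name every subclass")
        stats::setNames(as.integer(unlist(qPerClass)[classes]), classes)
    }
    if (any(qMap < 1L)) stopf("meta-sample counts must be positive")
    blocks <- vector("list", length(classes))
    patterns <- stats::setNames(vector("list", length(classes)), classes)
    counts <- stats::setNames(integer(length(classes)), classes)
    for (i in seq_along(classes)) {
        cl <- classes[i]
        A <- X[, as.character(lab) == cl, drop = FALSE]
        qi <- qMap[[cl]]
        cap <- min(nrow(A), ncol(A))
        if (qi > cap) {
            warning(sprintf(
                "subclass '%s' has only %d sample(s); clamping q from %d to %d",
                cl, ncol(A), qi, cap), call. = FALSE)
            qi <- cap
        }
        ms <- extractMetaSamples(A, qi)
        colnames(ms$M) <- sprintf("%s.ms%d", cl, seq_len(qi))
        blocks[[i]] <- ms$M
        patterns[[cl]] <- ms$V
        counts[cl] <- qi
    }
    new("MetaSampleDictionary",
        atoms = do.call(cbind, blocks),
        columnClass = rep(classes, counts),
        perClassCounts = counts,
        patterns = patterns)
}

#' @rdname MetaSampleDictionary-class
#' @export
setMethod("dictionaryAtoms", "MetaSampleDictionary", function(x) x@atoms)

#' @rdname MetaSampleDictionary-class
#' @export
setMethod("columnClasses", "MetaSampleDictionary", function(x) x@columnClass)

#' @rdname MetaSampleDictionary-class
#' @export
setMethod("perClassCounts", "MetaSampleDictionary",
    function(x) x@perClassCounts)

#' @rdname MetaSampleDictionary-class
#' @export
setMethod("metaPatterns", "MetaSampleDictionary", function(x) x@patterns)

setMethod("show", "MetaSampleDictionary", function(object) {
    q <- object@perClassCounts
    cat(sprintf("MetaSampleDictionary: %d genes x %d atoms, %d subclasses\n",
                nrow(object@atoms), ncol(object@atoms), length(q)))
    cat("  meta-samples per subclass:",
        paste(sprintf("%s=%d", names(q), q), collapse = ", "), "\n")
    invisible(NULL)
})
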