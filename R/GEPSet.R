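#' Construct a gene-expression dataset
#'
#' Builds a [GEPSet-class] from a numeric genes x samples matrix, optionally
#' attaching per-sample subclass labels. This is the container every other
#' function in the package consumes.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param geneIds character vector of unique gene identifiers; defaults to
#'   `rownames(values)`.
#' @param sampleIds character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @param labels optional character/factor vector of subclass labels, one per
#'   sample; at least two distinct subclasses are required when given.
#' @return a `GEPSet`.
#' @examples
#' x <- matrix(rnorm(12), 4, 3,
#'     dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' gep <- GEPSet(x, labels = c("A", "A", "B"))
#' nSamples(gep)
#' @export
GEPSet <- function(values, geneIds = rownames(values),
                   sampleIds = colnames(values), labels = NULL) {
    values <- as.matrix(values)
    if (is.null(geneIds))
        geneIds <- paste0("gene", seq_len(nrow(values)))
    if (is.null(sampleIds))
        sampleIds <- paste0("sample", seq_len(ncol(values)))
    dimnames(values) <- list(as.character(geneIds), as.character(sampleIds))
    cd <- S4Vectors::DataFrame(row.names = colnames(values))
    if (!is.null(labels)) {
        if (length(labels) != ncol(values))
            stopf("expected %d labels, got %d", ncol(values), length(labels))
        cd$subclass <- factor(as.character(labels),
                              levels = sort(unique(as.character(labels))))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values), colData = cd)
    new("GEPSet", se)
}

#' @rdname GEPSet
#' @export
setMethod("geneIds", "GEPSet", function(x) rownames(x))

#' @rdname GEPSet
#' @export
setMethod("sampleIds", "GEPSet", function(x) colnames(x))

#' @rdname GEPSet
#' @export
setMethod("exprsMatrix", "GEPSet",
    function(x) SummarizedExperiment::assay(x, "exprs"))

#' @rdname GEPSet
#' @export
setMethod("subclassLabels", "GEPSet", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("subclass" %in% colnames(cd)) cd$subclass else NULL
})

#' @rdname GEPSet
#' @export
setReplaceMethod("subclassLabels", "GEPSet", function(x, value) {
    if (is.null(value)) {
        SummarizedExperiment::colData(x)$subclass <- NULL
        return(x)
    }
    if (length(value) != ncol(x))
        stopf("expected %d labels, got %d", ncol(x), length(value))
    SummarizedExperiment::colData(x)$subclass <-
        factor(as.character(value), levels = sort(unique(as.character(value))))
    validObject(x)
    x
})

#' @rdname GEPSet
#' @export
setMethod("labelSet", "GEPSet", function(x) {
    lab <- subclassLabels(x)
    if (is.null(lab)) character() else levels(lab)
})

#' @rdname GEPSet
#' @export
nGenes <- function(x) nrow(x)

#' @rdname GEPSet
#' @export
nSamples <- function(x) ncol(x)

#' @rdname GEPSet
#' @export
nSubclasses <- function(x) length(labelSet(x))

setMethod("show", "GEPSet", function(object) {
    cat(sprintf("GEPSet: %d genes x %d samples\n",
                nrow(object), ncol(object)))
    lab <- subclassLabels(object)
    if (is.null(lab)) {
        cat("  unlabeled\n")
    } else {
        tab <- table(lab)
        cat(sprintf("  %d subclasses: %s\n", length(tab),
                    paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", ")))
    }
    invisible(NULL)
})
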