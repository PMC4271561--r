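MODEL_FORMAT_VERSION <- "1"

sepForPath <- function(path, sep = NULL) {
    if (!is.null(sep)) return(sep)
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited expression matrix
#'
#' Reads a plain-text expression table with one header row of identifiers and
#' one leading identifier column, returning a [GEPSet-class] in the canonical
#' genes x samples orientation. The delimiter is inferred from the file
#' extension (`.csv` comma, anything else tab) unless given explicitly.
#'
#' @param path file path.
#' @param orientation `"genes_in_rows"` (default) if rows are genes, or
#'   `"samples_in_rows"`, in which case the table is transposed after
#'   reading.
#' @param sep optional delimiter overriding the extension-based choice.
#' @return an unlabeled `GEPSet`. Non-numeric or missing cells are rejected
#'   with an error naming the offending gene and sample; duplicate
#'   identifiers and empty matrices are errors.
#' @seealso [readLabels()], [writeExpressionMatrix()]
#' @export
readExpressionMatrix <- function(path,
        orientation = c("genes_in_rows", "samples_in_rows"), sep = NULL) {
    orientation <- match.arg(orientation)
    if (!file.exists(path)) stopf("file not found: %s", path)
    sep <- sepForPath(path, sep)
    raw <- utils::read.table(path, header = TRUE, sep = sep,
        colClasses = "character", check.names = FALSE, row.names = NULL,
        quote = "", comment.char = "")
    if (nrow(raw) == 0L || ncol(raw) < 2L)
        stopf("empty expression matrix in %s", path)
    rowIds <- raw[[1L]]
    colIds <- colnames(raw)[-1L]
    if (anyDuplicated(rowIds))
        stopf("duplicate row identifiers in %s: %s", path,
              paste(unique(rowIds[duplicated(rowIds)]), collapse = ", "))
    if (anyDuplicated(colIds))
        stopf("duplicate column identifiers in %s: %s", path,
              paste(unique(colIds[duplicated(colIds)]), collapse = ", "))
    vals <- suppressWarnings(
        vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
    vals <- matrix(vals, nrow = nrow(raw),
                   dimnames = list(rowIds, colIds))
    bad <- which(!is.finite(vals), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
        i <- bad[1L, 1L]; j <- bad[1L, 2L]
        stopf("non-numeric value '%s' at row '%s', column '%s' in %s",
              raw[i, j + 1L], rowIds[i], colIds[j], path)
    }
    if (orientation == "samples_in_rows") vals <- t(vals)
    GEPSet(vals)
}

#' Write an expression matrix
#'
#' Writes the `GEPSet` expression values as delimited text (header = sample
#' identifiers, first column = gene identifiers). Values are printed with 17
#' significant digits so that a read/write round trip reproduces them
#' exactly.
#'
#' @param dataset a [GEPSet-class].
#' @param path output path; delimiter inferred from the extension unless
#'   `sep` is given.
#' @param sep optional delimiter.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(dataset, path, sep = NULL) {
    sep <- sepForPath(path, sep)
    x <- exprsMatrix(dataset)
    txt <- matrix(sprintf("%.17g", x), nrow = nrow(x))
    lines <- c(
        paste(c("gene_id", colnames(x)), collapse = sep),
        vapply(seq_len(nrow(x)), function(i)
            paste(c(rownames(x)[i], txt[i, ]), collapse = sep), character(1)))
    writeLines(lines, path)
    invisible(path)
}

#' Attach subclass labels from a two-column file
#'
#' Reads `sample_id<sep>label` pairs (an optional header whose first token is
#' `sample_id` is tolerated) and attaches them to the dataset. Every sample
#' in the dataset must receive exactly one label, every label-file sample
#' must exist in the dataset, and at least two distinct subclasses are
#' required.
#'
#' @param path label file path.
#' @param dataset the [GEPSet-class] the labels belong to.
#' @param sep optional delimiter (default inferred from extension).
#' @return the dataset with labels attached.
#' @export
readLabels <- function(path, dataset, sep = NULL) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    sep <- sepForPath(path, sep)
    tab <- utils::read.table(path, header = FALSE, sep = sep,
        colClasses = "character", quote = "", comment.char = "")
    if (ncol(tab) != 2L)
        stopf("label file %s must have exactly two columns", path)
    if (nrow(tab) > 0L && tab[1L, 1L] == "sample_id")
        tab <- tab[-1L, , drop = FALSE]
    ids <- tab[[1L]]
    labs <- tab[[2L]]
    if (anyDuplicated(ids))
        stopf("duplicate sample_id in label file: %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
    unknown <- setdiff(ids, sampleIds(dataset))
    if (length(unknown))
        stopf("label file mentions unknown sample(s): %s",
              paste(unknown, collapse = ", "))
    missing <- setdiff(sampleIds(dataset), ids)
    if (length(missing))
        stopf("unlabeled sample(s): %s", paste(missing, collapse = ", "))
    labs <- labs[match(sampleIds(dataset), ids)]
    if (length(unique(labs)) < 2L)
        stopf("at least 2 subclasses required, found %d",
              length(unique(labs)))
    subclassLabels(dataset) <- labs
    dataset
}

#' Write subclass labels
#'
#' @param dataset a labeled [GEPSet-class].
#' @param path output path (two tab-separated columns, with a
#'   `sample_id`/`label` header).
#' @return `path`, invisibly.
#' @export
writeLabels <- function(dataset, path) {
    lab <- subclassLabels(dataset)
    if (is.null(lab)) stopf("dataset carries no labels")
    writeLines(c("sample_id\tlabel",
                 paste(sampleIds(dataset), as.character(lab), sep = "\t")),
               path)
    invisible(path)
}

hexNum <- function(x) sprintf("%a", x)

#' Save a fitted classifier to a plain-text container
#'
#' The model (dictionary, configuration, label set) is written to a single
#' sectioned text file tagged with a format-version string. Floating-point
#' values are serialized as C99 hexadecimal literals, so a save/load round
#' trip reproduces the dictionary bit for bit.
#'
#' @param model an [MRRCCModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [loadModel()]
#' @export
saveModel <- function(model, path) {
    stopifnot(is(model, "MRRCCModel"))
    cfg <- model@config
    D <- model@dictionary@atoms
    lines <- c(
        paste("mrrcc-model", MODEL_FORMAT_VERSION, sep = "\t"),
        "[config]",
        paste("beta", cfg@beta, sep = "\t"),
        paste("tau", hexNum(cfg@tau), sep = "\t"),
        paste("s", hexNum(cfg@s), sep = "\t"),
        paste("lambda", hexNum(cfg@lambda), sep = "\t"),
        paste("phi", hexNum(cfg@phi), sep = "\t"),
        paste("maxIter", cfg@maxIter, sep = "\t"),
        paste("deltaFloor", hexNum(cfg@deltaFloor), sep = "\t"),
        "[labels]",
        model@labelSet,
        "[columns]",
        paste(colnames(D), model@dictionary@columnClass, sep = "\t"),
        "[dictionary]",
        vapply(seq_len(nrow(D)), function(i)
            paste(c(rownames(D)[i], hexNum(D[i, ])), collapse = "\t"),
            character(1)))
    writeLines(lines, path)
    invisible(path)
}

#' Load a fitted classifier
#'
#' @param path path written by [saveModel()]. An unknown format version or a
#'   corrupted container is an error.
#' @return an [MRRCCModel-class].
#' @export
loadModel <- function(path) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    lines <- readLines(path)
    if (length(lines) < 1L)
        stopf("corrupted model container: %s is empty", path)
    head <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(head) != 2L || head[1L] != "mrrcc-model")
        stopf("corrupted model container: missing header in %s", path)
    if (head[2L] != MODEL_FORMAT_VERSION)
        stopf("unsupported model format version '%s' (expected '%s')",
              head[2L], MODEL_FORMAT_VERSION)
    secAt <- function(name) {
        i <- which(lines == paste0("[", name, "]"))
        if (length(i) != 1L)
            stopf("corrupted model container: section [%s] missing", name)
        i
    }
    iCfg <- secAt("config"); iLab <- secAt("labels")
    iCol <- secAt("columns"); iDic <- secAt("dictionary")
    if (!(iCfg < iLab && iLab < iCol && iCol < iDic))
        stopf("corrupted model container: sections out of order")
    kv <- strsplit(lines[(iCfg + 1L):(iLab - 1L)], "\t", fixed = TRUE)
    cfgMap <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                              vapply(kv, `[`, character(1), 1L))
    need <- c("beta", "tau", "s", "lambda", "phi", "maxIter", "deltaFloor")
    if (!all(need %in% names(cfgMap)))
        stopf("corrupted model container: incomplete [config] section")
    cfg <- rrcConfig(
        beta = as.integer(cfgMap[["beta"]]),
        tau = as.numeric(cfgMap[["tau"]]),
        s = as.numeric(cfgMap[["s"]]),
        lambda = as.numeric(cfgMap[["lambda"]]),
        phi = as.numeric(cfgMap[["phi"]]),
        maxIter = as.integer(cfgMap[["maxIter"]]),
        deltaFloor = as.numeric(cfgMap[["deltaFloor"]]))
    labels <- lines[(iLab + 1L):(iCol - 1L)]
    colLines <- strsplit(lines[(iCol + 1L):(iDic - 1L)], "\t", fixed = TRUE)
    colIds <- vapply(colLines, `[`, character(1), 1L)
    colClass <- vapply(colLines, `[`, character(1), 2L)
    dicLines <- strsplit(lines[(iDic + 1L):length(lines)], "\t", fixed = TRUE)
    nGene <- length(dicLines)
    if (nGene == 0L)
        stopf("corrupted model container: empty [dictionary] section")
    geneIds <- vapply(dicLines, `[`, character(1), 1L)
    D <- t(vapply(dicLines,
                  function(v) as.numeric(v[-1L]), numeric(length(colIds))))
    if (length(colIds) == 1L) D <- matrix(D, ncol = 1L)
    dimnames(D) <- list(geneIds, colIds)
    qs <- vapply(split(seq_along(colClass), colClass), length, integer(1))
    qs <- qs[unique(colClass)]
    dict <- new("MetaSampleDictionary", atoms = D, columnClass = colClass,
                perClassCounts = stats::setNames(as.integer(qs), names(qs)),
                patterns = list())
    new("MRRCCModel", dictionary = dict, config = cfg, labelSet = labels)
}

#' Tabulate and write batch predictions
#'
#' `predictionTable` flattens a list of [MRRCCPrediction-class] objects into
#' a data.frame with columns `sample_id`, `predicted_label`, then one
#' `residual_<class>` column per subclass; `writePredictions` writes that
#' table as tab-separated text.
#'
#' @param predictions named list of `MRRCCPrediction` objects (names are
#'   sample identifiers), as returned by [predict,MRRCCModel-method] on a
#'   dataset.
#' @return a data.frame.
#' @export
predictionTable <- function(predictions) {
    stopifnot(length(predictions) == 0L || !is.null(names(predictions)))
    if (length(predictions) == 0L)
        return(data.frame(sample_id = character(),
                          predicted_label = character()))
    classes <- names(predictions[[1L]]@residuals)
    res <- t(vapply(predictions, function(p) p@residuals[classes],
                    numeric(length(classes))))
    out <- data.frame(
        sample_id = names(predictions),
        predicted_label = vapply(predictions, predictedLabel, character(1)),
        res, row.names = NULL, check.names = FALSE)
    colnames(out)[-(1:2)] <- paste0("residual_", classes)
    out
}

#' @rdname predictionTable
#' @param table data.frame from `predictionTable`.
#' @param path output path.
#' @export
writePredictions <- function(table, path) {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
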