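#' @rdname GEPSet
#' @param x,object an object.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GEPSet
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GEPSet
#' @export
setGeneric("exprsMatrix", function(x) standardGeneric("exprsMatrix"))

#' @rdname GEPSet
#' @export
setGeneric("subclassLabels", function(x) standardGeneric("subclassLabels"))

#' @rdname GEPSet
#' @param value replacement value.
#' @export
setGeneric("subclassLabels<-",
    function(x, value) standardGeneric("subclassLabels<-"))

#' @rdname GEPSet
#' @export
setGeneric("labelSet", function(x) standardGeneric("labelSet"))

#' @rdname MetaSampleDictionary-class
#' @param x a `MetaSampleDictionary`.
#' @export
setGeneric("dictionaryAtoms", function(x) standardGeneric("dictionaryAtoms"))

#' @rdname MetaSampleDictionary-class
#' @export
setGeneric("columnClasses", function(x) standardGeneric("columnClasses"))

#' @rdname MetaSampleDictionary-class
#' @export
setGeneric("perClassCounts", function(x) standardGeneric("perClassCounts"))

#' @rdname MetaSampleDictionary-class
#' @export
setGeneric("metaPatterns", function(x) standardGeneric("metaPatterns"))

#' @rdname MRRCCModel-class
#' @param x an `MRRCCModel`.
#' @export
setGeneric("modelDictionary", function(x) standardGeneric("modelDictionary"))

#' @rdname MRRCCModel-class
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname MRRCCPrediction-class
#' @param x a prediction or solver-state object.
#' @export
setGeneric("predictedLabel", function(x) standardGeneric("predictedLabel"))

#' @rdname MRRCCPrediction-class
#' @export
setGeneric("classResiduals", function(x) standardGeneric("classResiduals"))

#' @rdname MRRCCPrediction-class
#' @export
setGeneric("codingCoefficients",
    function(x) standardGeneric("codingCoefficients"))

#' @rdname MRRCCPrediction-class
#' @export
setGeneric("geneWeights", function(x) standardGeneric("geneWeights"))

#' @rdname CVResult-class
#' @param x a `CVResult`.
#' @export
setGeneric("foldResults", function(x) standardGeneric("foldResults"))

#' @rdname CVResult-class
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))
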