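#' @rdname instruments
#' @export
setGeneric("instruments", function(x) standardGeneric("instruments"))

#' @rdname instruments
#' @export
setGeneric("nInstruments", function(x) standardGeneric("nInstruments"))

#' @rdname instruments
#' @export
setGeneric("instrumentName", function(x) standardGeneric("instrumentName"))

#' @rdname instruments
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))

#' @rdname instruments
#' @export
setGeneric("filterLog", function(x) standardGeneric("filterLog"))

#' @rdname instruments
#' @export
setGeneric("covariateTraits", function(x) standardGeneric("covariateTraits"))

#' @rdname instruments
#' @export
setGeneric("covariateStats", function(x, trait) standardGeneric("covariateStats"))

#' @rdname mrEstimate-accessors
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))

#' @rdname mrEstimate-accessors
#' @export
setGeneric("mrSE", function(x) standardGeneric("mrSE"))

#' @rdname mrEstimate-accessors
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))

#' @rdname mrEstimate-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname mrEstimate-accessors
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' @rdname mrEstimate-accessors
#' @export
setGeneric("extras", function(x) standardGeneric("extras"))

#' @rdname heterogeneity-accessors
#' @export
setGeneric("qStatistic", function(x) standardGeneric("qStatistic"))

#' @rdname heterogeneity-accessors
#' @export
setGeneric("perSNPQ", function(x) standardGeneric("perSNPQ"))

#' @rdname heterogeneity-accessors
#' @export
setGeneric("flaggedSNPs", function(x, method) standardGeneric("flaggedSNPs"))

#' @rdname summaryStats
#' @export
setGeneric("summaryData", function(x) standardGeneric("summaryData"))

#' @rdname summaryStats
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' @rdname summaryStats
#' @export
setGeneric("traitKind", function(x) standardGeneric("traitKind"))
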