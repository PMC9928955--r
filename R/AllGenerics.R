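#' @rdname diffCounts
#' @export
setGeneric("diffCounts", function(x) standardGeneric("diffCounts"))

#' @rdname significantFeatures
#' @export
setGeneric("significantFeatures", function(x, ...)
  standardGeneric("significantFeatures"))

#' @rdname punctaCentroids
#' @export
setGeneric("punctaCentroids", function(x) standardGeneric("punctaCentroids"))

#' @rdname kseaTable
#' @export
setGeneric("kseaTable", function(x) standardGeneric("kseaTable"))

#' @rdname clusterSizes
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname reportSections
#' @export
setGeneric("reportSections", function(x) standardGeneric("reportSections"))
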