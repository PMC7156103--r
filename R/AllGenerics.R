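#' @rdname computeD
#' @export
setGeneric("computeD", function(x, ...) standardGeneric("computeD"))

#' @rdname computeDp
#' @export
setGeneric("computeDp", function(x, ...) standardGeneric("computeDp"))

#' @rdname countPatterns
#' @export
setGeneric("countPatterns", function(x, ...) standardGeneric("countPatterns"))

#' Number of sites in an object
#' @param x a `SiteMatrix` or `PolarizedSites`.
#' @return integer site count.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' Sample identifiers of an object
#' @param x a `SiteMatrix`.
#' @return character vector of sample identifiers, in stored order.
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' Genomic positions of the stored sites
#' @param x a `SiteMatrix` or `PolarizedSites`.
#' @return a `GRanges` of width-1 site positions.
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))
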