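#' @rdname F2Population-class
#' @param x an object.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname F2Population-class
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname VariantSet-class
#' @param x an object.
#' @export
setGeneric("variantSites", function(x) standardGeneric("variantSites"))

#' @rdname PooledCounts-class
#' @param x an object.
#' @export
setGeneric("altCounts", function(x) standardGeneric("altCounts"))

#' @rdname PooledCounts-class
#' @export
setGeneric("totalDepth", function(x) standardGeneric("totalDepth"))

#' True pooled alt-allele frequency per site and pool
#'
#' @param x an \linkS4class{F2Pools} object.
#' @return numeric matrix, sites x pools (WP, MP).
#' @export
setGeneric("poolFrequencies", function(x) standardGeneric("poolFrequencies"))

#' @rdname ProgenyDistribution-class
#' @param x an object.
#' @export
setGeneric("ratioOf", function(x) standardGeneric("ratioOf"))

#' @rdname ProgenyDistribution-class
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))
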