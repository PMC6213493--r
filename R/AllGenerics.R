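#' @rdname Genome-accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname Genome-accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname Genome-accessors
#' @export
setGeneric("features", function(x, ...) standardGeneric("features"))

#' @rdname GenomeSet-accessors
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))

#' @rdname GenomeSet-accessors
#' @export
setGeneric("nGenomes", function(x) standardGeneric("nGenomes"))

#' @rdname GenomeSet-accessors
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @rdname GenomeSet-accessors
#' @export
setGeneric("clusterMap", function(x) standardGeneric("clusterMap"))

#' @rdname gang-accessors
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname gang-accessors
#' @export
setGeneric("gangId", function(x) standardGeneric("gangId"))

#' @rdname gang-accessors
#' @export
setGeneric("ruliness", function(x) standardGeneric("ruliness"))

#' @rdname gang-accessors
#' @export
setGeneric("gangFlags", function(x) standardGeneric("gangFlags"))
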