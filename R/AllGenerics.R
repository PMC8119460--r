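#' @rdname CodonAlignment-class
#' @param object,x A package object.
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname CodonAlignment-class
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname CodonAlignment-class
#' @export
setGeneric("nsites", function(x) standardGeneric("nsites"))

#' @rdname LabeledTree-class
#' @export
setGeneric("edgeLabels", function(x) standardGeneric("edgeLabels"))

#' @rdname LabeledTree-class
#' @export
setGeneric("foregroundEdges", function(x) standardGeneric("foregroundEdges"))

#' @rdname PathwayProfile-class
#' @export
setGeneric("pathwayCounts", function(x) standardGeneric("pathwayCounts"))

#' @rdname DietCall-class
#' @export
setGeneric("dietCategory", function(x) standardGeneric("dietCategory"))

#' @rdname DietCall-class
#' @export
setGeneric("evidenceTrail", function(x) standardGeneric("evidenceTrail"))
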