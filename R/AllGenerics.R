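# Accessor generics. Slot access from user code is discouraged; these are
# the supported surface.

#' @name accessors
#' @title Accessors for lncDiscover S4 containers
#' @param x an object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("modulatedGenes", function(x) standardGeneric("modulatedGenes"))
#' @rdname accessors
#' @export
setMethod("modulatedGenes", "GroundTruth", function(x) x@modulatedGenes)

#' @rdname accessors
#' @export
setGeneric("plantedCisPairs", function(x) standardGeneric("plantedCisPairs"))
#' @rdname accessors
#' @export
setMethod("plantedCisPairs", "GroundTruth", function(x) x@cisPairs)

#' @rdname accessors
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))
#' @rdname accessors
#' @export
setMethod("signatureGenes", "GroundTruth", function(x) x@signatureGenes)

#' @rdname accessors
#' @export
setGeneric("nrirLikeId", function(x) standardGeneric("nrirLikeId"))
#' @rdname accessors
#' @export
setMethod("nrirLikeId", "GroundTruth", function(x) x@nrirLikeId)

#' @rdname accessors
#' @export
setGeneric("plantedModule", function(x) standardGeneric("plantedModule"))
#' @rdname accessors
#' @export
setMethod("plantedModule", "GroundTruth", function(x) x@plantedModule)

#' @rdname accessors
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))
#' @rdname accessors
#' @export
setMethod("termIds", "TermMap", function(x) x@ids)

#' @rdname accessors
#' @export
setGeneric("termNames", function(x) standardGeneric("termNames"))
#' @rdname accessors
#' @export
setMethod("termNames", "TermMap", function(x) setNames(x@termNames, x@ids))

#' @rdname accessors
#' @export
setGeneric("termGenes", function(x) standardGeneric("termGenes"))
#' @rdname accessors
#' @export
setMethod("termGenes", "TermMap", function(x) setNames(x@genes, x@ids))

#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))
#' @rdname accessors
#' @export
setMethod("adjacencyMatrix", "CoexpressionNetwork", function(x) x@adjacency)

#' @rdname accessors
#' @export
setGeneric("tomMatrix", function(x) standardGeneric("tomMatrix"))
#' @rdname accessors
#' @export
setMethod("tomMatrix", "CoexpressionNetwork", function(x) x@tom)

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))
#' @rdname accessors
#' @export
setMethod("moduleLabels", "CoexpressionNetwork", function(x) {
  setNames(x@moduleLabels, x@geneIds)
})

#' @rdname accessors
#' @export
setGeneric("networkBeta", function(x) standardGeneric("networkBeta"))
#' @rdname accessors
#' @export
setMethod("networkBeta", "CoexpressionNetwork", function(x) x@beta)

#' @rdname accessors
#' @export
setGeneric("commonGenes", function(x) standardGeneric("commonGenes"))
#' @rdname accessors
#' @export
setMethod("commonGenes", "ModuleIntersection", function(x) x@common)

#' @rdname accessors
#' @export
setGeneric("commonPCG", function(x) standardGeneric("commonPCG"))
#' @rdname accessors
#' @export
setMethod("commonPCG", "ModuleIntersection", function(x) x@commonPCG)

#' @rdname accessors
#' @export
setGeneric("commonNcRNA", function(x) standardGeneric("commonNcRNA"))
#' @rdname accessors
#' @export
setMethod("commonNcRNA", "ModuleIntersection", function(x) x@commonNcRNA)
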