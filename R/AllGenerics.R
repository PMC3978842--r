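#' Processing stage of an expression container
#' @param x a \linkS4class{TagCountExperiment}.
#' @return character scalar, one of \code{"counts"}, \code{"tpm"},
#'   \code{"log"}, \code{"log_centered"}.
#' @export
setGeneric("expressionStage", function(x) standardGeneric("expressionStage"))

#' @rdname expressionStage
#' @export
setMethod("expressionStage", "TagCountExperiment", function(x)
    S4Vectors::metadata(x)$stage)

#' TPM normalization of a tag-count matrix
#'
#' Scales each library to transcripts per million: value[g, s] =
#' counts[g, s] / total[s] * 1e6, so every column sums to 1e6 over the
#' mapped genes.
#'
#' @param x a counts-stage \linkS4class{TagCountExperiment} or a numeric
#'   count matrix (genes x libraries).
#' @return same shape as the input, at stage \code{"tpm"}.
#' @export
setGeneric("tpmNormalize", function(x) standardGeneric("tpmNormalize"))

#' Up-regulated gene calls of a SAM result
#' @param x a \linkS4class{SamResult}.
#' @return character vector of gene identifiers.
#' @export
setGeneric("upGenes", function(x) standardGeneric("upGenes"))

#' @rdname upGenes
#' @export
setMethod("upGenes", "SamResult", function(x) x@upGenes)

#' Down-regulated gene calls of a SAM result
#' @param x a \linkS4class{SamResult}.
#' @return character vector of gene identifiers.
#' @export
setGeneric("downGenes", function(x) standardGeneric("downGenes"))

#' @rdname downGenes
#' @export
setMethod("downGenes", "SamResult", function(x) x@downGenes)

#' Per-gene d-statistics of a SAM result
#' @param x a \linkS4class{SamResult}.
#' @return named numeric vector.
#' @export
setGeneric("dStatistics", function(x) standardGeneric("dStatistics"))

#' @rdname dStatistics
#' @export
setMethod("dStatistics", "SamResult", function(x)
    stats::setNames(x@d, x@genes))

#' Leaves of a dendrogram, in input order
#' @param x a \linkS4class{Dendrogram}.
#' @return character vector of item identifiers.
#' @export
setGeneric("leaves", function(x) standardGeneric("leaves"))

#' @rdname leaves
#' @export
setMethod("leaves", "Dendrogram", function(x) x@leaves)

#' Per-node merge similarities of a dendrogram
#' @param x a \linkS4class{Dendrogram}.
#' @return numeric vector, one similarity per merge, in merge order.
#' @export
setGeneric("nodeSimilarities", function(x) standardGeneric("nodeSimilarities"))

#' @rdname nodeSimilarities
#' @export
setMethod("nodeSimilarities", "Dendrogram", function(x) x@similarities)

#' Left-to-right leaf ordering of a dendrogram
#' @param x a \linkS4class{Dendrogram}.
#' @return character vector: the leaves in display order.
#' @export
setGeneric("leafOrder", function(x) standardGeneric("leafOrder"))

#' Samples called positive by a signature assignment
#' @param x a \linkS4class{SignatureAssignment}.
#' @return character vector of sample identifiers.
#' @export
setGeneric("positiveSamples", function(x) standardGeneric("positiveSamples"))

#' @rdname positiveSamples
#' @export
setMethod("positiveSamples", "SignatureAssignment", function(x)
    x@samples[x@positive])

#' Genes of a core signature
#' @param x a \linkS4class{CoreSignature}.
#' @return character vector of gene symbols.
#' @export
setGeneric("coreGenes", function(x) standardGeneric("coreGenes"))

#' @rdname coreGenes
#' @export
setMethod("coreGenes", "CoreSignature", function(x) x@genes)

setMethod("show", "SamResult", function(object) {
    cat("SamResult:", length(object@genes), "genes\n")
    cat(sprintf("  s0 = %.4g, delta = %.4g, FDR = %.4g, pi0 = %.3g\n",
                object@s0, object@delta, object@fdr, object@pi0))
    cat(sprintf("  calls: %d up, %d down (%s permutations: %d)\n",
                length(object@upGenes), length(object@downGenes),
                if (object@exact) "exact enumeration," else "sampled",
                object@nPerm))
})

setMethod("show", "Dendrogram", function(object) {
    cat("Dendrogram:", length(object@leaves), "leaves,",
        nrow(object@merges), "merge nodes\n")
    if (length(object@similarities))
        cat(sprintf("  node similarities in [%.3f, %.3f]\n",
                    min(object@similarities), max(object@similarities)))
})

setMethod("show", "SignatureAssignment", function(object) {
    cat(sprintf("SignatureAssignment '%s': %d/%d samples positive\n",
                object@signature, sum(object@positive),
                length(object@samples)))
    cat(sprintf("  volume = %.4g at node correlation %.3g (cut > %.3g)\n",
                object@volume, object@nodeCorrelation, object@threshold))
})

setMethod("show", "CoreSignature", function(object) {
    cat(sprintf("CoreSignature '%s': %d core genes (>%g correlation in >=%d datasets)\n",
                object@name, length(object@genes), object@corrThreshold,
                object@minDatasets))
})
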