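#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Tag-count / expression container
#'
#' A \linkS4class{SummarizedExperiment} carrying a single assay of 3'-end
#' tag counts or derived values, plus a processing-stage flag in
#' \code{metadata()$stage}. Stages: \code{"counts"} (non-negative integral
#' read counts), \code{"tpm"} (each column sums to 1e6 over mapped genes),
#' \code{"log"} and \code{"log_centered"} (Cluster 3.0-style adjusted data).
#'
#' @slot .  Inherits all slots from \code{SummarizedExperiment}.
#' @export
setClass("TagCountExperiment", contains = "SummarizedExperiment")

.validStages <- c("counts", "tpm", "log", "log_centered")

setValidity("TagCountExperiment", function(object) {
    msg <- NULL
    stage <- S4Vectors::metadata(object)$stage
    if (is.null(stage) || !stage %in% .validStages)
        msg <- c(msg, sprintf("metadata()$stage must be one of: %s",
                              paste(.validStages, collapse = ", ")))
    v <- SummarizedExperiment::assay(object)
    rn <- rownames(v); cn <- colnames(v)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(cn) || anyDuplicated(cn))
        msg <- c(msg, "sample identifiers must be present and unique")
    if (!is.null(stage) && identical(stage, "counts")) {
        if (any(v < 0) || any(abs(v - round(v)) > 1e-8))
            msg <- c(msg, "counts stage requires non-negative integral values")
    }
    if (!is.null(stage) && identical(stage, "tpm")) {
        cs <- colSums(v)
        if (any(abs(cs - 1e6) > 1e-6 * 1e6))
            msg <- c(msg, "tpm stage requires column sums of 1e6")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a TagCountExperiment
#'
#' @param values numeric matrix, genes in rows, libraries in columns; must
#'   carry unique dimnames.
#' @param stage processing stage, one of \code{"counts"}, \code{"tpm"},
#'   \code{"log"}, \code{"log_centered"}.
#' @param colData optional \code{DataFrame}/data.frame of per-sample
#'   annotation (e.g. diagnosis labels).
#' @return A \linkS4class{TagCountExperiment}.
#' @export
TagCountExperiment <- function(values, stage = c("counts", "tpm", "log",
                                                 "log_centered"),
                               colData = NULL) {
    stage <- match.arg(stage)
    values <- as.matrix(values)
    if (is.null(colData))
        colData <- S4Vectors::DataFrame(row.names = colnames(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(values = values), colData = colData)
    S4Vectors::metadata(se)$stage <- stage
    new("TagCountExperiment", se)
}

#' Two-class SAM result
#'
#' Holds the observed d-statistics, the fudge factor s0, the permutation
#' null (expected order statistics), the chosen delta with its estimated
#' FDR, and the up/down gene calls.
#'
#' @slot genes gene identifiers, in input order.
#' @slot d signed d-statistic per gene (class2 minus class1).
#' @slot s pooled standard error per gene.
#' @slot s0 fudge factor (scalar).
#' @slot dbar expected order statistics of d under permutation.
#' @slot delta threshold at which calls were made.
#' @slot fdr estimated false discovery rate at \code{delta}.
#' @slot pi0 estimated proportion of null genes.
#' @slot cutUp,cutLow d-value cut points implied by \code{delta}.
#' @slot upGenes,downGenes disjoint called gene lists.
#' @slot nPerm number of permutations used.
#' @slot exact TRUE when all distinct label assignments were enumerated.
#' @export
setClass("SamResult", representation(
    genes = "character", d = "numeric", s = "numeric", s0 = "numeric",
    dbar = "numeric", delta = "numeric", fdr = "numeric", pi0 = "numeric",
    cutUp = "numeric", cutLow = "numeric",
    upGenes = "character", downGenes = "character",
    nPerm = "integer", exact = "logical"))

setValidity("SamResult", function(object) {
    msg <- NULL
    n <- length(object@genes)
    if (length(object@d) != n)
        msg <- c(msg, "d must have one value per gene")
    if (length(object@dbar) != n)
        msg <- c(msg, "dbar must have the same length as d")
    if (length(intersect(object@upGenes, object@downGenes)) > 0)
        msg <- c(msg, "up and down calls must be disjoint")
    if (length(object@fdr) == 1 && object@fdr < 0)
        msg <- c(msg, "fdr must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' Binary merge tree with per-node similarity
#'
#' Agglomerative clustering result in Cluster 3.0 (GTR) semantics: n leaves,
#' n-1 merge nodes, each node recording the similarity at which its two
#' children joined. \code{merges} uses the \code{\link{hclust}} convention:
#' negative entries index leaves, positive entries earlier merge rows.
#'
#' @slot leaves item identifiers, in input order.
#' @slot merges integer matrix, (n-1) x 2.
#' @slot similarities similarity at each merge, in [-1, 1].
#' @export
setClass("Dendrogram", representation(
    leaves = "character", merges = "matrix", similarities = "numeric"))

setValidity("Dendrogram", function(object) {
    msg <- NULL
    n <- length(object@leaves)
    m <- object@merges
    if (!is.numeric(m) || ncol(m) != 2 || nrow(m) != n - 1)
        msg <- c(msg, "merges must be an (n-1) x 2 matrix")
    if (length(object@similarities) != n - 1)
        msg <- c(msg, "one similarity per merge node required")
    if (anyDuplicated(object@leaves))
        msg <- c(msg, "leaf identifiers must be unique")
    if (is.numeric(m) && ncol(m) == 2 && nrow(m) == n - 1 && n >= 2) {
        lf <- -m[m < 0]
        if (!setequal(lf, seq_len(n)) || length(lf) != n)
            msg <- c(msg, "every leaf must appear exactly once")
        for (i in seq_len(nrow(m))) {
            pos <- m[i, ][m[i, ] > 0]
            if (any(pos >= i))
                msg <- c(msg, "children must precede parents")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Per-sample signature call for one cohort
#'
#' Records, for one signature projected onto one cohort, the binary
#' positive/negative label per sample, the winning candidate group's volume
#' of expression, and the dendrogram node correlation at which that group
#' was cut.
#'
#' @slot signature signature name.
#' @slot samples cohort sample identifiers.
#' @slot positive logical per sample.
#' @slot volume volume of expression of the positive group.
#' @slot nodeCorrelation similarity of the positive cluster's root node
#'   (NA for a singleton).
#' @slot threshold sample-axis correlation threshold used for the cut.
#' @slot candidateVolumes volume of every candidate group, winner included.
#' @export
setClass("SignatureAssignment", representation(
    signature = "character", samples = "character", positive = "logical",
    volume = "numeric", nodeCorrelation = "numeric", threshold = "numeric",
    candidateVolumes = "numeric"))

setValidity("SignatureAssignment", function(object) {
    msg <- NULL
    if (length(object@samples) != length(object@positive))
        msg <- c(msg, "one label per sample required")
    if (anyDuplicated(object@samples))
        msg <- c(msg, "sample identifiers must be unique")
    if (length(object@candidateVolumes) &&
        object@volume < max(object@candidateVolumes) - 1e-12)
        msg <- c(msg, "positive group must have maximal volume of expression")
    if (is.null(msg)) TRUE else msg
})

#' Cross-cohort core gene set
#'
#' Genes of a signature that are coordinately expressed (cluster membership
#' at a node correlation above \code{corrThreshold}) in at least
#' \code{minDatasets} of the supplied cohorts.
#'
#' @slot name signature name.
#' @slot genes core gene symbols.
#' @slot provenance named list; per core gene, the cohort ids whose chosen
#'   gene cluster contained it.
#' @slot corrThreshold gene-axis correlation threshold used.
#' @slot minDatasets minimum number of supporting cohorts.
#' @export
setClass("CoreSignature", representation(
    name = "character", genes = "character", provenance = "list",
    corrThreshold = "numeric", minDatasets = "integer"))

setValidity("CoreSignature", function(object) {
    msg <- NULL
    if (length(object@provenance) != length(object@genes))
        msg <- c(msg, "provenance must have one entry per core gene")
    if (length(object@genes) &&
        any(vapply(object@provenance, length, 1L) < object@minDatasets))
        msg <- c(msg, "every core gene needs provenance of size >= minDatasets")
    if (is.null(msg)) TRUE else msg
})
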