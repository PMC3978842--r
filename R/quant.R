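## Gene-level quantification and QC of 3'-end tag-sequencing libraries.
## Input is a table of mapped-read records (one row per uniquely assigned
## read); alignment itself is upstream and out of scope.

.readCols <- c("library_id", "gene", "transcript_length", "start",
               "mismatches")

validateMappedReads <- function(reads) {
    if (!is.data.frame(reads) || !all(.readCols %in% names(reads)))
        stop("mapped reads need columns: ", paste(.readCols, collapse = ", "))
    if (nrow(reads) == 0L)
        stop("empty mapped-read set: no reads supplied")
    bad <- reads$start < 0 | reads$start >= reads$transcript_length
    if (any(bad))
        stop(sum(bad), " read(s) violate 0 <= start < transcript_length")
    if (any(reads$mismatches < 0))
        stop("negative mismatch counts")
    len <- tapply(reads$transcript_length, reads$gene,
                  function(v) length(unique(v)))
    if (any(len > 1L))
        stop("conflicting transcript lengths for gene(s): ",
             paste(names(len)[len > 1L], collapse = ", "))
    invisible(reads)
}

#' Read mapped-read records from TSV
#'
#' Expects a header line with columns \code{library_id}, \code{gene},
#' \code{transcript_length}, \code{start} (0-based offset of the read 5'
#' end on the transcript) and \code{mismatches}.
#'
#' @param path TSV file.
#' @return validated data.frame of mapped reads.
#' @export
readMappedReads <- function(path) {
    reads <- utils::read.delim(path, stringsAsFactors = FALSE,
                               comment.char = "#")
    validateMappedReads(reads)
}

#' Count tags per gene symbol and library
#'
#' Tallies uniquely assigned mapped reads into a gene x library count
#' matrix, discarding reads with more than \code{maxMismatches}
#' mismatches. Genes with zero counts everywhere are retained only when
#' they are part of a supplied gene universe.
#'
#' @param reads data.frame of mapped reads (see
#'   \code{\link{readMappedReads}}).
#' @param maxMismatches maximum tolerated mismatch count (default 2).
#' @param geneUniverse optional character vector of gene symbols to retain
#'   even at zero counts.
#' @return counts-stage \linkS4class{TagCountExperiment}.
#' @export
countTags <- function(reads, maxMismatches = 2, geneUniverse = NULL) {
    validateMappedReads(reads)
    stopifnot(maxMismatches >= 0)
    keep <- reads$mismatches <= maxMismatches
    genes <- sort(unique(c(reads$gene[keep], geneUniverse)))
    if (length(genes) == 0L)
        stop("no genes survive the mismatch filter and no gene universe given")
    libs <- sort(unique(reads$library_id))
    tab <- table(factor(reads$gene[keep], levels = genes),
                 factor(reads$library_id[keep], levels = libs))
    m <- matrix(as.integer(tab), nrow = length(genes),
                dimnames = list(genes, libs))
    TagCountExperiment(m, stage = "counts")
}

#' @rdname tpmNormalize
#' @export
setMethod("tpmNormalize", "matrix", function(x) {
    tot <- colSums(x)
    if (any(tot <= 0))
        stop("library with zero total count: ",
             paste(colnames(x)[tot <= 0], collapse = ", "))
    sweep(x, 2L, tot, "/") * 1e6
})

#' @rdname tpmNormalize
#' @export
setMethod("tpmNormalize", "TagCountExperiment", function(x) {
    if (!identical(expressionStage(x), "counts"))
        stop("tpmNormalize expects a counts-stage object, got stage '",
             expressionStage(x), "'")
    TagCountExperiment(tpmNormalize(SummarizedExperiment::assay(x)),
                       stage = "tpm",
                       colData = SummarizedExperiment::colData(x))
})

#' Library saturation curve
#'
#' Estimates how transcriptome detection saturates with sequencing depth:
#' for each requested fraction f of the library, reads are subsampled
#' without replacement \code{nRep} times and the number of distinct genes
#' detected is recorded. At f = 1 the full-depth detection count is
#' reported exactly (no resampling). The saturation fraction — detected
#' genes at full depth over \code{referenceSize} — is attached as attribute
#' \code{"saturation"}.
#'
#' @param reads mapped-read data.frame (a single library, or pooled reads;
#'   subsampling treats all rows as one library).
#' @param fractions sorted ascending fractions in (0, 1].
#' @param referenceSize size of the reference transcriptome; defaults to
#'   the number of distinct genes observed. Must be at least that number.
#' @param nRep subsampling replicates per fraction.
#' @param seed base seed; each (fraction, replicate) draws from its own
#'   substream.
#' @return data.frame with columns \code{fraction}, \code{reads},
#'   \code{mean_detected}, \code{sd_detected}; attribute
#'   \code{"saturation"}.
#' @export
saturationCurve <- function(reads, fractions = seq(0.1, 1, by = 0.1),
                            referenceSize = NULL, nRep = 20, seed = 1) {
    validateMappedReads(reads)
    if (any(fractions <= 0 | fractions > 1))
        stop("fractions must lie in (0, 1]")
    if (is.unsorted(fractions))
        stop("fractions must be sorted ascending")
    g <- reads$gene
    full <- length(unique(g))
    if (is.null(referenceSize)) referenceSize <- full
    if (referenceSize < full)
        stop("referenceSize must be >= number of distinct genes observed (",
             full, ")")
    N <- length(g)
    res <- lapply(seq_along(fractions), function(fi) {
        f <- fractions[fi]
        k <- round(f * N)
        if (k >= N) {
            det <- rep(full, 1L)
            c(k, full, 0)
        } else {
            det <- vapply(seq_len(nRep), function(r) {
                withSubstream(seed, "saturation", fi, r, expr = {
                    length(unique(g[sample.int(N, k)]))
                })
            }, 1L)
            c(k, mean(det), stats::sd(det))
        }
    })
    res <- do.call(rbind, res)
    out <- data.frame(fraction = fractions, reads = res[, 1],
                      mean_detected = res[, 2], sd_detected = res[, 3])
    attr(out, "saturation") <- full / referenceSize
    out
}

## Closed-form expectation of the saturation curve for small libraries:
## E[detected at k reads] = sum_g 1 - C(N - n_g, k) / C(N, k), the
## hypergeometric chance that gene g contributes at least one read.
expectedDetected <- function(geneCounts, k) {
    N <- sum(geneCounts)
    sum(1 - exp(lchoose(N - geneCounts, k) - lchoose(N, k)))
}

#' Distance-to-3'-end profile of mapped reads
#'
#' For each read the distance from its 5' end to the transcript 3' end is
#' \code{transcript_length - start} (0-based start), and the distances are
#' histogrammed in bins of \code{binWidth} nt. In a well-behaved 3'-end
#' tag library the modal bin sits around 100-200 nt, set by the fragment
#' length after shearing.
#'
#' @param reads mapped-read data.frame.
#' @param binWidth bin width in nt (>= 1).
#' @return list with \code{histogram} (data.frame: bin_start, bin_end,
#'   count) and \code{modal_bin} (length-2 numeric: start/end of the
#'   fullest bin; first such bin on ties).
#' @export
threePrimeDistanceProfile <- function(reads, binWidth = 50) {
    validateMappedReads(reads)
    stopifnot(binWidth >= 1)
    d <- reads$transcript_length - reads$start
    idx <- floor(d / binWidth)
    tab <- table(factor(idx, levels = 0:max(idx)))
    hist <- data.frame(bin_start = as.numeric(names(tab)) * binWidth,
                       bin_end = (as.numeric(names(tab)) + 1) * binWidth,
                       count = as.integer(tab))
    stopifnot(sum(hist$count) == nrow(reads))
    mb <- which.max(hist$count)
    list(histogram = hist,
         modal_bin = c(hist$bin_start[mb], hist$bin_end[mb]))
}
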