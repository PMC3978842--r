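## Projection of a derived signature onto an independent expression cohort:
## restrict the cohort to the signature's genes, cluster the samples,
## call the signature-positive group by volume of expression, pool gene
## clusters across cohorts into a core gene set, and cross two signatures
## into four strata.

#' Restrict a cohort matrix to a signature's genes
#'
#' Keeps the probes/rows mapping to the signature's gene symbols. When
#' several probes map to one symbol the probe with the highest sample
#' standard deviation is retained (the conventional most-variable-probe
#' collapse), and the returned rows are renamed to gene symbols.
#'
#' @param genes character vector of signature gene symbols.
#' @param cohort numeric matrix (probes/genes x samples). Rownames are
#'   gene symbols unless \code{probeMap} is given.
#' @param probeMap optional data.frame with columns \code{probe},
#'   \code{symbol} translating cohort rownames to gene symbols.
#' @param minGenes minimum number of signature genes that must be present
#'   on the platform (default 5); fewer is an error naming the missing.
#' @return submatrix with rownames = gene symbols; attribute
#'   \code{"missingGenes"} lists signature genes absent from the platform.
#' @export
mapSignatureToCohort <- function(genes, cohort, probeMap = NULL,
                                 minGenes = 5) {
    stopifnot(is.matrix(cohort), length(genes) >= 1)
    genes <- unique(as.character(genes))
    symbols <- if (is.null(probeMap)) rownames(cohort) else {
        stopifnot(all(c("probe", "symbol") %in% names(probeMap)))
        probeMap$symbol[match(rownames(cohort), probeMap$probe)]
    }
    hit <- which(symbols %in% genes)
    present <- unique(symbols[hit])
    missing <- setdiff(genes, present)
    if (length(present) < minGenes)
        stop("only ", length(present), " signature gene(s) present on the ",
             "platform (need >= ", minGenes, "); missing: ",
             paste(utils::head(missing, 25), collapse = ", "))
    sds <- rowSdSample(cohort[hit, , drop = FALSE])
    pick <- vapply(present, function(sym) {
        cand <- hit[symbols[hit] == sym]
        cand[which.max(sds[match(cand, hit)])]
    }, 1L)
    nDup <- length(hit) - length(present)
    if (nDup > 0)
        message(nDup, " duplicate probe(s) collapsed to the highest-SD probe")
    if (length(missing))
        message(length(missing), " signature gene(s) absent from platform")
    sub <- cohort[pick, , drop = FALSE]
    rownames(sub) <- present
    attr(sub, "missingGenes") <- missing
    sub
}

#' Volume of expression of a gene set in a sample group
#'
#' The mean of the strictly positive entries of the (centered) submatrix
#' restricted to \code{samples}; 0 when no entry is positive. Negative
#' entries never contribute, so the statistic measures only coordinate
#' over-expression.
#'
#' @param x centered numeric matrix (signature genes x cohort samples).
#' @param samples non-empty subset of column names (or indices).
#' @return non-negative scalar.
#' @export
volumeOfExpression <- function(x, samples = colnames(x)) {
    stopifnot(is.matrix(x), length(samples) >= 1)
    v <- x[, samples, drop = FALSE]
    pos <- v[v > 0]
    if (length(pos) == 0) 0 else mean(pos)
}

#' Identify the signature-positive sample group
#'
#' Cuts the cohort's sample dendrogram at the node-correlation threshold
#' (default > 0.2), scores every candidate cluster by volume of
#' expression of the signature genes, and labels the maximal-volume
#' cluster positive; all remaining samples are negative. Candidates must
#' contain at least two samples: the positive group stands in for a
#' visually identifiable block of cases in the clustered heatmap, which a
#' singleton is not, and the mean-based volume statistic is otherwise
#' selection-biased toward single extreme samples. Ties between equal
#' volumes break to the larger group, then the lower minimum leaf index.
#' If no multi-sample candidate exists, or the best one has zero volume,
#' the assignment is all-negative with a warning.
#'
#' @param x centered signature submatrix (genes x cohort samples), as from
#'   \code{\link{mapSignatureToCohort}}.
#' @param sampleTree \linkS4class{Dendrogram} over the cohort samples
#'   built from \code{x}; NULL builds one (Spearman similarity, centroid
#'   linkage).
#' @param threshold node-correlation cut for candidate groups (default
#'   0.2).
#' @param name signature name recorded in the assignment.
#' @return a \linkS4class{SignatureAssignment}.
#' @export
identifyPositiveGroup <- function(x, sampleTree = NULL, threshold = 0.2,
                                  name = "signature") {
    stopifnot(is.matrix(x))
    if (is.null(sampleTree))
        sampleTree <- hcluster(x, axis = "samples")
    if (!setequal(leaves(sampleTree), colnames(x)))
        stop("sample tree leaves do not match cohort samples")
    cl <- cutBySimilarity(sampleTree, threshold)
    rootSim <- attr(cl, "rootSimilarity")
    eligible <- which(lengths(cl) >= 2L)
    if (length(eligible) == 0L) {
        warning("only singleton candidate groups at this cut; ",
                "all samples labelled negative")
        return(new("SignatureAssignment", signature = name,
                   samples = colnames(x),
                   positive = rep(FALSE, ncol(x)), volume = 0,
                   nodeCorrelation = NA_real_, threshold = threshold,
                   candidateVolumes = numeric(0)))
    }
    cl <- cl[eligible]; rootSim <- rootSim[eligible]
    vols <- vapply(cl, function(g) volumeOfExpression(x, g), 1.0)
    sizes <- lengths(cl)
    minIdx <- vapply(cl, function(g) min(match(g, colnames(x))), 1.0)
    win <- order(-vols, -sizes, minIdx)[1]
    positive <- colnames(x) %in% cl[[win]]
    if (vols[win] <= 0) {
        warning("no candidate group with positive volume of expression; ",
                "all samples labelled negative")
        positive[] <- FALSE
    }
    new("SignatureAssignment", signature = name, samples = colnames(x),
        positive = positive, volume = vols[win],
        nodeCorrelation = rootSim[win], threshold = threshold,
        candidateVolumes = vols)
}

#' Permutation sanity check for a positive-group call
#'
#' Guards against calling a "positive" group on a cohort where the
#' signature shows no coordinate expression at all: each permutation
#' shuffles every gene's values across samples (destroying sample-level
#' coordination while keeping each gene's marginal distribution) and
#' reruns the positive-group identification. The test statistic is the
#' winning group's aggregate positive expression — the sum of its
#' strictly positive entries, i.e. volume times extent — because the mean
#' alone is selection-inflated for the tiny clusters that win on permuted
#' data. The reported p-value is the fraction of permutations whose
#' aggregate reaches the observed one; on a cohort without planted
#' structure it is large and the call should be treated as spurious.
#'
#' @param x centered signature submatrix (genes x samples).
#' @param threshold sample-axis node-correlation cut (default 0.2).
#' @param nPerm permutations (default 20; each reruns the clustering).
#' @param seed base seed.
#' @return list: \code{observed} aggregate positive expression of the
#'   called group, \code{permuted} the same under permutation, \code{p}
#'   permutation p-value (add-one corrected).
#' @export
volumeSignificance <- function(x, threshold = 0.2, nPerm = 20, seed = 1) {
    aggregate <- function(m) {
        a <- suppressWarnings(
            identifyPositiveGroup(m, threshold = threshold))
        if (!any(a@positive)) return(0)
        v <- m[, a@positive, drop = FALSE]
        sum(v[v > 0])
    }
    obs <- aggregate(x)
    perm <- vapply(seq_len(nPerm), function(k) {
        withSubstream(seed, "volperm", k, expr = {
            xp <- t(apply(x, 1L, sample))
            colnames(xp) <- colnames(x)
            aggregate(xp)
        })
    }, 1.0)
    list(observed = obs, permuted = perm,
         p = (1 + sum(perm >= obs)) / (1 + nPerm))
}

#' Derive a cross-cohort core gene set
#'
#' For each cohort, the signature's coordinately expressed gene cluster is
#' the cluster — from cutting that cohort's gene-axis dendrogram at
#' \code{corrThreshold} — with the highest volume of expression inside the
#' cohort's signature-positive sample group. Core genes are those present
#' in at least \code{minDatasets} of these per-cohort clusters.
#'
#' @param submatrices named list of centered signature submatrices, one
#'   per cohort (genes x samples).
#' @param assignments named list of \linkS4class{SignatureAssignment}
#'   objects (or character vectors of positive sample ids), parallel to
#'   \code{submatrices}.
#' @param corrThreshold gene-axis node-correlation cut (default 0.1).
#' @param minDatasets minimum supporting cohorts (default 3).
#' @param name signature name.
#' @param geneTrees optional named list of precomputed gene-axis
#'   \linkS4class{Dendrogram}s.
#' @return a \linkS4class{CoreSignature}.
#' @export
deriveCoreGenes <- function(submatrices, assignments, corrThreshold = 0.1,
                            minDatasets = 3, name = "signature",
                            geneTrees = NULL) {
    if (length(submatrices) < minDatasets)
        stop("need at least ", minDatasets, " cohorts, got ",
             length(submatrices))
    if (is.null(names(submatrices)))
        names(submatrices) <- sprintf("cohort%d", seq_along(submatrices))
    stopifnot(length(assignments) == length(submatrices))
    chosen <- lapply(seq_along(submatrices), function(k) {
        sub <- submatrices[[k]]
        pos <- assignments[[k]]
        if (is(pos, "SignatureAssignment")) pos <- positiveSamples(pos)
        if (length(pos) == 0) return(character(0))
        tree <- if (!is.null(geneTrees)) geneTrees[[k]]
                else hcluster(sub, axis = "genes")
        cl <- cutBySimilarity(tree, corrThreshold)
        vols <- vapply(cl, function(g)
            volumeOfExpression(sub[g, , drop = FALSE], pos), 1.0)
        sizes <- lengths(cl)
        minIdx <- vapply(cl, function(g) min(match(g, rownames(sub))), 1.0)
        cl[[order(-vols, -sizes, minIdx)[1]]]
    })
    names(chosen) <- names(submatrices)
    allGenes <- unique(unlist(chosen))
    prov <- lapply(allGenes, function(g)
        names(chosen)[vapply(chosen, function(cc) g %in% cc, TRUE)])
    names(prov) <- allGenes
    core <- allGenes[vapply(prov, length, 1L) >= minDatasets]
    new("CoreSignature", name = name, genes = core,
        provenance = prov[core], corrThreshold = corrThreshold,
        minDatasets = as.integer(minDatasets))
}

#' Cross two signature assignments into four strata
#'
#' Forms the per-sample 4-category label "A+/B+", "A+/B-", "A-/B+",
#' "A-/B-" from two assignments over the same cohort.
#'
#' @param a,b \linkS4class{SignatureAssignment} objects covering the same
#'   sample set.
#' @return named factor, one 4-level label per sample.
#' @export
combineSignatures <- function(a, b) {
    stopifnot(is(a, "SignatureAssignment"), is(b, "SignatureAssignment"))
    if (!setequal(a@samples, b@samples))
        stop("assignments cover different sample sets")
    bi <- match(a@samples, b@samples)
    lab <- paste0(a@signature, ifelse(a@positive, "+", "-"), "/",
                  b@signature, ifelse(b@positive[bi], "+", "-"))
    lv <- as.vector(outer(c("+", "-"), c("+", "-"), function(x, y)
        paste0(a@signature, x, "/", b@signature, y)))
    factor(stats::setNames(lab, a@samples), levels = lv)
}

#' Write a signature assignment table as TSV
#' @param assignments list of \linkS4class{SignatureAssignment} (or one).
#' @param path output file.
#' @param header optional comment lines.
#' @return \code{path}, invisibly.
#' @export
writeAssignments <- function(assignments, path, header = NULL) {
    if (is(assignments, "SignatureAssignment"))
        assignments <- list(assignments)
    rows <- do.call(rbind, lapply(assignments, function(a)
        data.frame(sample = a@samples, signature = a@signature,
                   label = ifelse(a@positive, "positive", "negative"),
                   volume = a@volume, threshold = a@threshold)))
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.table(rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a core signature as TSV
#' @param core a \linkS4class{CoreSignature}.
#' @param path output file.
#' @param header optional comment lines.
#' @return \code{path}, invisibly.
#' @export
writeCoreSignature <- function(core, path, header = NULL) {
    df <- data.frame(
        gene = core@genes,
        n_datasets = vapply(core@provenance, length, 1L),
        cohorts = vapply(core@provenance, paste, "", collapse = ","))
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
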