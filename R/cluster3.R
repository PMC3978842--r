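## The Stanford-lineage clustering recipe: SD filter, log transform + gene
## centering, Spearman-rank-correlation similarity, centroid-linkage
## agglomeration, dendrogram cuts by node similarity, and
## TreeView-compatible .cdt/.gtr/.atr output.
##
## Agglomeration maximizes SIMILARITY (not distance); centroid linkage
## recomputes a merged node's profile as the size-weighted mean of its
## member profiles and re-scores it against all active nodes, so similarity
## inversions toward the root are possible (as in Cluster 3.0).

#' Standard-deviation gene filter
#'
#' Retains genes whose row standard deviation — population SD, i.e.
#' divide-by-n, matching Cluster 3.0 — is at least \code{threshold}
#' (boundary inclusive). The "SD100" recipe is this filter at threshold
#' 100 on the TPM scale, applied before the log transform.
#'
#' @param x numeric matrix, genes x samples.
#' @param threshold non-negative SD cutoff.
#' @return the filtered matrix, row order preserved. Empty result warns.
#' @export
sdFilter <- function(x, threshold) {
    stopifnot(is.matrix(x), threshold >= 0)
    keep <- rowSdPop(x) >= threshold
    if (!any(keep))
        warning("SD filter at ", threshold, " removed every gene")
    x[keep, , drop = FALSE]
}

#' Log transform and center genes
#'
#' Cluster 3.0 "adjust data": x -> log_base(x + pseudocount), then
#' subtract each gene's center statistic (median by default). Set
#' \code{log = FALSE} for data already on a log/centered-ratio scale.
#'
#' @param x numeric matrix, genes x samples.
#' @param logBase base of the log transform (default 2).
#' @param pseudocount added before the log so zeros survive (default 1).
#' @param centerMode \code{"median"} (default) or \code{"mean"}.
#' @param log apply the log transform (default TRUE).
#' @return adjusted matrix; every row's center statistic is 0 within 1e-9.
#' @export
adjustMatrix <- function(x, logBase = 2, pseudocount = 1,
                         centerMode = c("median", "mean"), log = TRUE) {
    stopifnot(is.matrix(x))
    centerMode <- match.arg(centerMode)
    if (log) {
        bad <- which(x + pseudocount <= 0)
        if (length(bad)) {
            rc <- arrayInd(utils::head(bad, 10), dim(x))
            stop("non-positive values after pseudocount at e.g. ",
                 paste(sprintf("[%s, %s]", rownames(x)[rc[, 1]],
                               colnames(x)[rc[, 2]]), collapse = ", "))
        }
        x <- log(x + pseudocount, base = logBase)
    }
    ctr <- if (centerMode == "median")
        apply(x, 1L, stats::median) else rowMeans(x)
    x - ctr
}

#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of the average-ranked vectors (tie-corrected).
#' A vector with zero rank variance (all values tied) gets similarity 0
#' with a warning, so degenerate profiles join the tree last.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return rho in [-1, 1].
#' @export
spearmanSimilarity <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) >= 2)
    rx <- rank(x); ry <- rank(y)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
        warning("zero rank variance; similarity defined as 0")
        return(0)
    }
    stats::cor(rx, ry)
}

## Pairwise similarity among the rows of P, NA (constant rows) -> 0.
.rowSimilarity <- function(P, method) {
    S <- suppressWarnings(stats::cor(t(P), method = method))
    if (anyNA(S)) {
        warning("items with zero variance; their similarities set to 0")
        S[is.na(S)] <- 0
    }
    S
}

.profileSimilarity <- function(p, Q, method) {
    if (method == "spearman") {
        p <- rank(p)
        Q <- t(apply(Q, 1L, rank))
    }
    out <- suppressWarnings(as.vector(stats::cor(p, t(Q))))
    out[is.na(out)] <- 0
    out
}

#' Similarity-based agglomerative clustering
#'
#' Builds the merge tree the Cluster 3.0 way: at each step the pair of
#' active nodes with the highest similarity is merged and the similarity
#' of the merge is recorded. With centroid linkage the merged node's
#' profile is the size-weighted mean of its member profiles and is
#' re-scored against every active node with the chosen similarity; with
#' average linkage similarities combine as size-weighted means; with
#' complete linkage as the minimum. Ties between equal-similarity pairs
#' break to the lexicographically smallest pair of node creation indices,
#' so the merge sequence is fully deterministic.
#'
#' @param x numeric matrix, genes x samples.
#' @param axis cluster \code{"genes"} (rows) or \code{"samples"} (columns).
#' @param similarity \code{"spearman"} (default) or \code{"pearson"}.
#' @param linkage \code{"centroid"} (default), \code{"average"} or
#'   \code{"complete"}.
#' @return a \linkS4class{Dendrogram}.
#' @export
hcluster <- function(x, axis = c("genes", "samples"),
                     similarity = c("spearman", "pearson"),
                     linkage = c("centroid", "average", "complete")) {
    axis <- match.arg(axis)
    similarity <- match.arg(similarity)
    linkage <- match.arg(linkage)
    stopifnot(is.matrix(x))
    P <- if (axis == "genes") x else t(x)
    n <- nrow(P)
    if (n < 2L) stop("need at least 2 items to cluster")
    labels <- rownames(P)
    if (is.null(labels)) labels <- sprintf("item%d", seq_len(n))

    nTot <- 2L * n - 1L
    S <- matrix(-Inf, nTot, nTot)
    S[seq_len(n), seq_len(n)] <- .rowSimilarity(P, similarity)
    profiles <- matrix(NA_real_, nTot, ncol(P))
    profiles[seq_len(n), ] <- P
    size <- c(rep(1L, n), rep(0L, n - 1L))
    active <- c(rep(TRUE, n), rep(FALSE, n - 1L))

    merges <- matrix(0L, n - 1L, 2L)
    sims <- numeric(n - 1L)
    for (step in seq_len(n - 1L)) {
        act <- which(active)
        Ssub <- S[act, act, drop = FALSE]
        Ssub[lower.tri(Ssub, diag = TRUE)] <- -Inf
        best <- max(Ssub)
        hits <- which(Ssub == best, arr.ind = TRUE)
        # lexicographic tie-break on creation indices (i < j)
        cand <- cbind(act[hits[, 1]], act[hits[, 2]])
        pick <- order(cand[, 1], cand[, 2])[1]
        i <- cand[pick, 1]; j <- cand[pick, 2]

        newIdx <- n + step
        merges[step, ] <- c(if (i <= n) -i else i - n,
                            if (j <= n) -j else j - n)
        sims[step] <- best
        size[newIdx] <- size[i] + size[j]
        active[c(i, j)] <- FALSE
        others <- which(active)
        if (linkage == "centroid") {
            profiles[newIdx, ] <- (size[i] * profiles[i, ] +
                                   size[j] * profiles[j, ]) / size[newIdx]
            if (length(others)) {
                sNew <- .profileSimilarity(profiles[newIdx, ],
                                           profiles[others, , drop = FALSE],
                                           similarity)
                S[newIdx, others] <- sNew
                S[others, newIdx] <- sNew
            }
        } else if (linkage == "average") {
            sNew <- (size[i] * S[i, others] + size[j] * S[j, others]) /
                size[newIdx]
            S[newIdx, others] <- sNew
            S[others, newIdx] <- sNew
        } else {
            sNew <- pmin(S[i, others], S[j, others])
            S[newIdx, others] <- sNew
            S[others, newIdx] <- sNew
        }
        active[newIdx] <- TRUE
    }
    new("Dendrogram", leaves = labels, merges = merges, similarities = sims)
}

## Leaf indices under each merge node, bottom-up.
.subtreeLeaves <- function(dend) {
    m <- dend@merges
    out <- vector("list", nrow(m))
    childLeaves <- function(v) if (v < 0) -v else out[[v]]
    for (i in seq_len(nrow(m)))
        out[[i]] <- c(childLeaves(m[i, 1]), childLeaves(m[i, 2]))
    out
}

#' @rdname leafOrder
#' @export
setMethod("leafOrder", "Dendrogram", function(x) {
    sub <- .subtreeLeaves(x)
    x@leaves[sub[[length(sub)]]]
})

#' Cut a dendrogram by node similarity
#'
#' Clusters are the maximal subtrees whose root node joined at a
#' similarity strictly above \code{threshold}; a leaf whose parent joined
#' at or below the threshold forms a singleton. The clusters always
#' partition the leaves. This is the rule behind the paperless ">0.2"
#' sample-group and ">0.1" gene-cluster cuts of the projection stage.
#'
#' @param dend a \linkS4class{Dendrogram}.
#' @param threshold similarity threshold in [-1, 1].
#' @return list of character vectors (leaf ids per cluster), with
#'   attribute \code{"rootSimilarity"}: the root-node similarity of each
#'   cluster (NA for singletons).
#' @export
cutBySimilarity <- function(dend, threshold) {
    stopifnot(is(dend, "Dendrogram"), threshold >= -1, threshold <= 1)
    sub <- .subtreeLeaves(dend)
    nNodes <- nrow(dend@merges)
    clusters <- list()
    rootSim <- numeric(0)
    visit <- function(v) {
        if (v < 0) {
            clusters[[length(clusters) + 1L]] <<- dend@leaves[-v]
            rootSim[length(rootSim) + 1L] <<- NA_real_
        } else if (dend@similarities[v] > threshold) {
            clusters[[length(clusters) + 1L]] <<- dend@leaves[sub[[v]]]
            rootSim[length(rootSim) + 1L] <<- dend@similarities[v]
        } else {
            visit(dend@merges[v, 1])
            visit(dend@merges[v, 2])
        }
    }
    visit(nNodes)
    attr(clusters, "rootSimilarity") <- rootSim
    clusters
}

## ---- TreeView (.cdt/.gtr/.atr) dialect -----------------------------------

.gtrIds <- function(dend, prefix) {
    n <- length(dend@leaves)
    ref <- function(v) if (v < 0) sprintf("%s%dX", prefix, -v - 1L)
           else sprintf("NODE%dX", v)
    data.frame(node = sprintf("NODE%dX", seq_len(n - 1L)),
               left = vapply(dend@merges[, 1], ref, ""),
               right = vapply(dend@merges[, 2], ref, ""),
               correlation = dend@similarities)
}

#' Write a clustered matrix in Cluster 3.0 / Java TreeView format
#'
#' Emits \code{<pathStem>.cdt} plus \code{.gtr}/\code{.atr} for the
#' supplied trees, in the Cluster 3.0 dialect: GID/AID identifiers
#' \code{GENE\{n\}X}/\code{ARRY\{n\}X} assigned in input order, node lines
#' \code{NODE\{n\}X} with a correlation column, GWEIGHT/EWEIGHT written as
#' 1, and rows/columns of the .cdt ordered by the trees' left-to-right
#' leaf traversal. Values are written with 17 significant digits so the
#' files round-trip exactly through \code{\link{readTreeView}}.
#'
#' @param x numeric matrix, genes x samples.
#' @param geneTree,sampleTree \linkS4class{Dendrogram} over the rows /
#'   columns of \code{x}, or NULL to keep input order and skip the file.
#' @param pathStem output path without extension.
#' @return character vector of files written, invisibly.
#' @export
writeTreeView <- function(x, geneTree = NULL, sampleTree = NULL, pathStem) {
    stopifnot(is.matrix(x))
    if (!is.null(geneTree) && !setequal(leaves(geneTree), rownames(x)))
        stop("gene tree leaves do not match matrix rows")
    if (!is.null(sampleTree) && !setequal(leaves(sampleTree), colnames(x)))
        stop("sample tree leaves do not match matrix columns")
    files <- character(0)
    gidOf <- stats::setNames(sprintf("GENE%dX", seq_len(nrow(x)) - 1L),
                             rownames(x))
    aidOf <- stats::setNames(sprintf("ARRY%dX", seq_len(ncol(x)) - 1L),
                             colnames(x))
    rowOrd <- if (is.null(geneTree)) rownames(x) else leafOrder(geneTree)
    colOrd <- if (is.null(sampleTree)) colnames(x) else leafOrder(sampleTree)
    xo <- x[rowOrd, colOrd, drop = FALSE]

    cdt <- paste0(pathStem, ".cdt")
    con <- file(cdt, "w")
    writeLines(paste(c("GID", "UNIQID", "NAME", "GWEIGHT", colOrd),
                     collapse = "\t"), con)
    if (!is.null(sampleTree))
        writeLines(paste(c("AID", "", "", "", aidOf[colOrd]),
                         collapse = "\t"), con)
    writeLines(paste(c("EWEIGHT", "", "", "", rep("1", ncol(x))),
                     collapse = "\t"), con)
    body <- apply(xo, 1L, function(r) paste(fmtNum(r), collapse = "\t"))
    writeLines(paste(gidOf[rowOrd], rowOrd, rowOrd, "1", body, sep = "\t"),
               con)
    close(con)
    files <- c(files, cdt)

    writeTree <- function(tree, ids, ext) {
        path <- paste0(pathStem, ext)
        df <- .gtrIds(tree, sub("[0-9]+X$", "",
                                ids[1]))  # GENE / ARRY prefix
        writeLines(paste(df$node, df$left, df$right, fmtNum(df$correlation),
                         sep = "\t"), path)
        path
    }
    if (!is.null(geneTree))
        files <- c(files, writeTree(geneTree, gidOf, ".gtr"))
    if (!is.null(sampleTree))
        files <- c(files, writeTree(sampleTree, aidOf, ".atr"))
    invisible(files)
}

.parseTreeFile <- function(path, idsInOrder, prefix) {
    lines <- utils::read.delim(path, header = FALSE,
                               stringsAsFactors = FALSE)
    n <- nrow(lines) + 1L
    ref <- function(s) {
        if (startsWith(s, "NODE")) as.integer(sub("NODE([0-9]+)X", "\\1", s))
        else -(as.integer(sub(paste0(prefix, "([0-9]+)X"), "\\1", s)) + 1L)
    }
    merges <- cbind(vapply(lines[[2]], ref, 1L, USE.NAMES = FALSE),
                    vapply(lines[[3]], ref, 1L, USE.NAMES = FALSE))
    new("Dendrogram", leaves = idsInOrder, merges = merges,
        similarities = as.numeric(lines[[4]]))
}

#' Read Cluster 3.0 .cdt/.gtr/.atr files
#'
#' Inverse of \code{\link{writeTreeView}}: reconstructs the matrix (in
#' original gene/sample identifier space) and the dendrograms.
#'
#' @param pathStem path without extension; \code{.gtr}/\code{.atr} are
#'   read when present.
#' @return list with \code{matrix}, \code{geneTree}, \code{sampleTree}
#'   (trees NULL when the file is absent).
#' @export
readTreeView <- function(pathStem) {
    cdt <- utils::read.delim(paste0(pathStem, ".cdt"), header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    hasAid <- cdt[[1]][1] == "AID"
    aidRow <- if (hasAid) unlist(cdt[1, -(1:4)]) else NULL
    body <- cdt[cdt[[1]] != "AID" & cdt[[1]] != "EWEIGHT", , drop = FALSE]
    m <- as.matrix(body[, -(1:4), drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- body[[2]]
    gid <- stats::setNames(body[[1]], body[[2]])

    geneTree <- sampleTree <- NULL
    gtr <- paste0(pathStem, ".gtr")
    if (file.exists(gtr)) {
        # leaves in input order: GENE{i}X -> i-th gene
        ord <- order(as.integer(sub("GENE([0-9]+)X", "\\1", gid)))
        geneTree <- .parseTreeFile(gtr, names(gid)[ord], "GENE")
    }
    atr <- paste0(pathStem, ".atr")
    if (file.exists(atr) && hasAid) {
        ord <- order(as.integer(sub("ARRY([0-9]+)X", "\\1", aidRow)))
        sampleTree <- .parseTreeFile(atr, colnames(m)[ord], "ARRY")
    }
    list(matrix = m, geneTree = geneTree, sampleTree = sampleTree)
}
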