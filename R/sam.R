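## Two-class unpaired Significance Analysis of Microarrays: moderated
## d-statistic with fudge factor s0, permutation null of order statistics,
## and FDR-controlled up/down calls via the delta cut-point rule.

.twoClassLabels <- function(labels, n) {
    labels <- as.factor(labels)
    if (nlevels(labels) != 2L)
        stop("labels must define exactly two classes")
    if (length(labels) != n)
        stop("one label per sample required")
    cls2 <- labels == levels(labels)[2L]
    if (sum(!cls2) < 2L || sum(cls2) < 2L)
        stop("each class needs at least 2 samples")
    cls2
}

## Core vectorized computation; cls2 is a logical mask for class 2.
.dstat <- function(x, cls2, s0) {
    n1 <- sum(!cls2); n2 <- sum(cls2)
    x1 <- x[, !cls2, drop = FALSE]; x2 <- x[, cls2, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
    s <- sqrt((1 / n1 + 1 / n2) / (n1 + n2 - 2) * ss)
    r <- m2 - m1
    den <- s + s0
    d <- ifelse(den > 0, r / den, 0)
    list(d = d, s = s, numerator = r)
}

#' SAM d-statistic
#'
#' Computes the per-gene moderated test statistic
#' d = (mean2 - mean1) / (s + s0), where s is the pooled standard error
#' sqrt\{(1/n1 + 1/n2)/(n1 + n2 - 2) * [SS1 + SS2]\} and s0 is the fudge
#' factor stabilizing genes with tiny variance. Class 2 is the second
#' factor level of \code{labels}, so positive d means higher expression in
#' class 2.
#'
#' @param x numeric matrix, genes x samples.
#' @param labels two-class factor (or coercible), one per sample.
#' @param s0 non-negative fudge factor.
#' @return list with \code{d}, \code{s} and \code{numerator} (the mean
#'   difference), each named by gene. Genes with s + s0 = 0 get d = 0 and
#'   are counted in attribute \code{"nZeroDenominator"} with a warning.
#' @export
samDStatistic <- function(x, labels, s0 = 0) {
    stopifnot(is.matrix(x), s0 >= 0)
    cls2 <- .twoClassLabels(labels, ncol(x))
    out <- .dstat(x, cls2, s0)
    nzero <- sum(out$s + s0 == 0)
    if (nzero > 0)
        warning(nzero, " gene(s) with zero denominator; d set to 0")
    out <- lapply(out, function(v) stats::setNames(v, rownames(x)))
    attr(out, "nZeroDenominator") <- nzero
    out
}

#' Choose the SAM fudge factor s0
#'
#' Reference SAM recipe: candidate s0 values are the alpha-percentiles of
#' the per-gene standard errors s for alpha = 0, 0.05, ..., 1. For each
#' candidate the genes are split into up to 100 quantile windows of s, the
#' median absolute deviation of d = r/(s + s0) is taken within each
#' window, and the candidate minimizing the coefficient of variation of
#' those MADs wins. Ties break to the smallest alpha; constant s returns
#' s0 = 0 (all candidates equivalent).
#'
#' @param r per-gene numerators (mean differences).
#' @param s per-gene pooled standard errors (non-negative).
#' @param nWindows number of quantile windows (default 100, reduced when
#'   there are fewer genes than windows).
#' @return scalar s0.
#' @export
samChooseS0 <- function(r, s, nWindows = 100) {
    stopifnot(length(r) == length(s))
    if (length(s) < 10)
        stop("s0 selection needs at least 10 genes")
    if (stats::sd(s) == 0) return(0)
    alphas <- seq(0, 1, by = 0.05)
    cand <- stats::quantile(s, alphas, names = FALSE, type = 7)
    nw <- min(nWindows, max(2L, floor(length(s) / 2)))
    win <- ceiling(rank(s, ties.method = "first") / (length(s) / nw))
    cv <- vapply(cand, function(s0) {
        d <- r / (s + s0)
        mads <- tapply(d, win, stats::mad)
        mu <- mean(mads)
        if (!is.finite(mu) || mu == 0) return(Inf)
        stats::sd(mads) / mu
    }, 1.0)
    cand[which.min(cv)]   # which.min takes the first (smallest alpha) on ties
}

#' Permutation null of the SAM order statistics
#'
#' Recomputes the sorted d-statistics under permuted class labels. When
#' the number of distinct label assignments choose(n, n1) is at most
#' \code{nPerm}, all of them are enumerated exactly (deterministic,
#' seed-independent); otherwise \code{nPerm} random permutations are drawn
#' from a seeded stream. dbar_i is the mean of the i-th order statistic
#' across permutations.
#'
#' @param x numeric matrix, genes x samples.
#' @param labels two-class labels.
#' @param nPerm maximum number of permutations (default 1000).
#' @param seed seed for the sampled-permutation case.
#' @param s0 fudge factor used for every permuted d.
#' @return list: \code{dbar} (expected order statistics), \code{permD}
#'   (genes x permutations matrix of sorted permuted d), \code{exact}
#'   (logical), \code{nPerm} (permutations actually used).
#' @export
samPermutationNull <- function(x, labels, nPerm = 1000, seed = 1, s0 = 0) {
    stopifnot(nPerm >= 1)
    cls2 <- .twoClassLabels(labels, ncol(x))
    n <- ncol(x)
    n2 <- sum(cls2)
    nDistinct <- choose(n, n2)
    exact <- is.finite(nDistinct) && nDistinct <= nPerm
    if (exact) {
        sets <- utils::combn(n, n2)
        permD <- apply(sets, 2L, function(ix) {
            mask <- logical(n); mask[ix] <- TRUE
            sort(.dstat(x, mask, s0)$d)
        })
        used <- ncol(sets)
    } else {
        permD <- withSubstream(seed, "samperm", expr = {
            vapply(seq_len(nPerm), function(p) {
                mask <- logical(n); mask[sample.int(n, n2)] <- TRUE
                sort(.dstat(x, mask, s0)$d)
            }, numeric(nrow(x)))
        })
        used <- nPerm
    }
    list(dbar = rowMeans(permD), permD = permD, exact = exact,
         nPerm = as.integer(used))
}

## Cut points implied by delta on the sorted observed d: the smallest d
## among genes with d_(i) - dbar_i >= delta defines the upper cut, the
## largest among genes with dbar_i - d_(i) >= delta the lower cut. All
## genes at or beyond a cut are called (the standard slab refinement).
.samCuts <- function(dSorted, dbar, delta) {
    up <- dSorted - dbar >= delta
    lo <- dbar - dSorted >= delta
    cutUp <- if (any(up)) min(dSorted[up]) else Inf
    cutLow <- if (any(lo)) max(dSorted[lo]) else -Inf
    c(cutUp, cutLow)
}

## Median number of permuted d outside the cuts, using per-column binary
## search on the sorted permutation matrix.
.permOutside <- function(permD, cutUp, cutLow) {
    n <- nrow(permD)
    eps <- 1e-12
    apply(permD, 2L, function(col)
        findInterval(cutLow + eps, col) + n - findInterval(cutUp - eps, col))
}

.pi0FromPerm <- function(d, permD) {
    q <- stats::quantile(permD, c(0.25, 0.75), names = FALSE)
    min(1, sum(d > q[1] & d < q[2]) / (0.5 * length(d)))
}

#' Call significant genes at a delta threshold
#'
#' Applies the SAM plot rule: on the sorted observed statistics, genes
#' whose d exceeds its expected order statistic by at least delta anchor
#' the upper cut (and symmetrically for the lower cut); every gene at or
#' beyond a cut is called. The FDR at delta is pi0 times the median, over
#' permutations, of the number of permuted d outside the cuts, divided by
#' the number of genes called. When \code{delta} is NULL it is searched on
#' a grid as the smallest value with FDR <= \code{targetFdr}.
#'
#' @param d named numeric vector of observed d-statistics.
#' @param dbar expected order statistics (ascending), as from
#'   \code{\link{samPermutationNull}}.
#' @param permD sorted permuted d matrix from
#'   \code{\link{samPermutationNull}}.
#' @param delta fixed threshold, or NULL to search.
#' @param targetFdr target FDR for the delta search (default 0.05).
#' @param pi0 proportion of null genes; NULL estimates it from the central
#'   50\% of the permuted statistics, 1 disables the correction.
#' @param deltaGridSize grid resolution for the delta search.
#' @param s,s0 optional standard errors / fudge factor, stored in the
#'   result for provenance.
#' @param exact,nPerm provenance of the permutation null.
#' @return a \linkS4class{SamResult}.
#' @export
samCall <- function(d, dbar, permD, delta = NULL, targetFdr = 0.05,
                    pi0 = NULL, deltaGridSize = 200,
                    s = numeric(0), s0 = NA_real_,
                    exact = FALSE, nPerm = ncol(permD)) {
    genes <- names(d)
    if (is.null(genes)) genes <- sprintf("gene%d", seq_along(d))
    ord <- order(d)
    dSorted <- d[ord]
    if (is.null(pi0)) pi0 <- .pi0FromPerm(d, permD)

    fdrAt <- function(delta) {
        cuts <- .samCuts(dSorted, dbar, delta)
        nUp <- sum(d >= cuts[1])
        nLow <- sum(d <= cuts[2] & d < cuts[1])
        nCalled <- nUp + nLow
        if (nCalled == 0) return(c(0, cuts, 0))
        med <- stats::median(.permOutside(permD, cuts[1], cuts[2]))
        c(pi0 * med / nCalled, cuts, nCalled)
    }

    if (is.null(delta)) {
        stopifnot(!is.null(targetFdr), targetFdr > 0, targetFdr <= 1)
        grid <- seq(0, max(abs(dSorted - dbar)), length.out = deltaGridSize)
        delta <- Inf
        for (g in grid) {
            if (fdrAt(g)[1] <= targetFdr) { delta <- g; break }
        }
    }
    res <- fdrAt(delta)
    cutUp <- res[2]; cutLow <- res[3]
    upCalls <- genes[d >= cutUp]
    downCalls <- genes[d <= cutLow & d < cutUp]
    new("SamResult", genes = genes, d = unname(d), s = unname(s),
        s0 = s0, dbar = unname(dbar), delta = delta, fdr = res[1],
        pi0 = pi0, cutUp = cutUp, cutLow = cutLow,
        upGenes = upCalls, downGenes = downCalls,
        nPerm = as.integer(nPerm), exact = exact)
}

#' Two-class SAM analysis
#'
#' End-to-end moderated differential expression between two classes:
#' chooses the fudge factor s0 from the data, builds the permutation null
#' of order statistics, and calls up/down genes at the smallest delta whose
#' estimated FDR is at or below \code{targetFdr}.
#'
#' Genes with zero variance within both classes are excluded from the s0
#' selection (their standard error is exactly zero and would distort the
#' quantile windows); they remain in the test with d = r/s0.
#'
#' @param x numeric matrix, genes x samples.
#' @param labels two-class labels; class 2 (second level) minus class 1.
#' @param targetFdr target FDR for the delta search.
#' @param delta fixed threshold overriding the search, or NULL.
#' @param nPerm maximum permutations (exact enumeration when feasible).
#' @param seed seed for sampled permutations.
#' @param s0 fixed fudge factor, or NULL to choose it from the data.
#' @param pi0 proportion of null genes; NULL to estimate, 1 to disable.
#' @param deltaGridSize delta search grid resolution.
#' @return a \linkS4class{SamResult}.
#' @examples
#' set.seed(7)
#' x <- matrix(rnorm(200 * 12), 200, dimnames = list(sprintf("g%03d", 1:200),
#'             sprintf("s%02d", 1:12)))
#' x[1:10, 7:12] <- x[1:10, 7:12] + 3
#' res <- sam(x, rep(c("A", "B"), each = 6), targetFdr = 0.05, nPerm = 200)
#' upGenes(res)
#' @export
sam <- function(x, labels, targetFdr = 0.05, delta = NULL, nPerm = 1000,
                seed = 1, s0 = NULL, pi0 = NULL, deltaGridSize = 200) {
    stopifnot(is.matrix(x))
    cls2 <- .twoClassLabels(labels, ncol(x))
    base <- .dstat(x, cls2, 0)
    if (is.null(s0)) {
        usable <- base$s > 0
        nzv <- sum(!usable)
        if (nzv > 0)
            message(nzv, " gene(s) with zero variance in both classes ",
                    "excluded from s0 selection")
        s0 <- if (sum(usable) >= 10)
            samChooseS0(base$numerator[usable], base$s[usable]) else 0
    }
    d <- stats::setNames(ifelse(base$s + s0 > 0,
                                base$numerator / (base$s + s0), 0),
                         rownames(x))
    null <- samPermutationNull(x, labels, nPerm = nPerm, seed = seed, s0 = s0)
    samCall(d, null$dbar, null$permD, delta = delta, targetFdr = targetFdr,
            pi0 = pi0, deltaGridSize = deltaGridSize,
            s = base$s, s0 = s0, exact = null$exact, nPerm = null$nPerm)
}

#' Derive per-group signatures by one-vs-rest SAM
#'
#' Runs a two-class SAM of each diagnosis group against all remaining
#' samples and takes the up-regulated genes as that group's expression
#' signature. By default the input TPM values are variance-stabilized as
#' log2(TPM + 1) first.
#'
#' @param x TPM matrix (genes x samples) or a tpm-stage
#'   \linkS4class{TagCountExperiment}.
#' @param groups factor of diagnosis labels, one per sample; every group
#'   needs at least 3 samples.
#' @param targetFdr FDR for each one-vs-rest SAM (default 0.05).
#' @param nPerm,seed permutation settings passed to \code{\link{sam}}.
#' @param transform \code{"log2"} (default) applies log2(x + 1);
#'   \code{"none"} analyses the matrix as supplied.
#' @return list with \code{signatures} (per group: list of \code{up} and
#'   \code{down} gene vectors), \code{results} (per-group
#'   \linkS4class{SamResult}) and \code{summary} (data.frame: diagnosis,
#'   n_cases, n_up, n_down, delta, fdr).
#' @export
deriveSignatures <- function(x, groups, targetFdr = 0.05, nPerm = 1000,
                             seed = 1, transform = c("log2", "none")) {
    transform <- match.arg(transform)
    if (is(x, "TagCountExperiment")) x <- SummarizedExperiment::assay(x)
    stopifnot(is.matrix(x))
    groups <- as.factor(groups)
    if (nlevels(groups) < 2L)
        stop("at least two diagnosis groups required")
    sizes <- table(groups)
    if (any(sizes < 3L))
        stop("every group needs at least 3 samples; too small: ",
             paste(names(sizes)[sizes < 3L], collapse = ", "))
    if (transform == "log2") x <- log2(x + 1)
    res <- lapply(levels(groups), function(g) {
        labels <- factor(ifelse(groups == g, g, "rest"),
                         levels = c("rest", g))
        tryCatch(sam(x, labels, targetFdr = targetFdr, nPerm = nPerm,
                     seed = substreamSeed(seed, "group", g)),
                 error = function(e)
                     stop("SAM failed for group '", g, "': ",
                          conditionMessage(e)))
    })
    names(res) <- levels(groups)
    summary <- data.frame(
        diagnosis = levels(groups),
        n_cases = as.integer(sizes[levels(groups)]),
        n_up = vapply(res, function(r) length(upGenes(r)), 1L),
        n_down = vapply(res, function(r) length(downGenes(r)), 1L),
        delta = vapply(res, function(r) r@delta, 1.0),
        fdr = vapply(res, function(r) r@fdr, 1.0),
        row.names = NULL)
    sigs <- lapply(res, function(r)
        list(up = upGenes(r), down = downGenes(r)))
    list(signatures = sigs, results = res, summary = summary)
}
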