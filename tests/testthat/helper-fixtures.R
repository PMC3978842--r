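## Shared fixtures and independent oracles, all built in code.

## A tiny mapped-read table; defaults give one library over two genes.
makeReads <- function(gene = c("A", "A", "B"),
                      start = c(10, 20, 30),
                      len = c(500, 500, 800),
                      mism = c(0, 1, 0),
                      lib = "lib1") {
    data.frame(library_id = rep_len(lib, length(gene)), gene = gene,
               transcript_length = len, start = start, mismatches = mism,
               stringsAsFactors = FALSE)
}

randMatrix <- function(nr, nc, seed = 1, rowPrefix = "g", colPrefix = "s") {
    set.seed(seed)
    matrix(rnorm(nr * nc), nr, nc,
           dimnames = list(sprintf("%s%03d", rowPrefix, seq_len(nr)),
                           sprintf("%s%03d", colPrefix, seq_len(nc))))
}

## Independent O(n^3) re-scan agglomeration oracle: at every step all
## pairwise similarities are recomputed from scratch on the current
## cluster representatives. Centroid representative = plain mean of member
## leaf profiles; ties broken to the lexicographically smallest pair of
## creation indices, as documented for hcluster().
bruteCentroidTree <- function(P, similarity = "spearman") {
    n <- nrow(P)
    simFun <- function(a, b) {
        if (similarity == "spearman") { a <- rank(a); b <- rank(b) }
        if (sd(a) == 0 || sd(b) == 0) return(0)
        cor(a, b)
    }
    members <- lapply(seq_len(n), function(i) i)
    ids <- seq_len(n)
    merges <- matrix(0L, n - 1L, 2L)
    sims <- numeric(n - 1L)
    for (step in seq_len(n - 1L)) {
        best <- -Inf; bi <- NA; bj <- NA
        for (a in seq_along(members)) for (b in seq_along(members)) {
            if (a >= b) next
            pa <- colMeans(P[members[[a]], , drop = FALSE])
            pb <- colMeans(P[members[[b]], , drop = FALSE])
            s <- simFun(pa, pb)
            i <- min(ids[a], ids[b]); j <- max(ids[a], ids[b])
            if (s > best ||
                (s == best && (i < min(bi, bj) ||
                               (i == min(bi, bj) && j < max(bi, bj))))) {
                best <- s; bi <- ids[a]; bj <- ids[b]
            }
        }
        ka <- which(ids == min(bi, bj)); kb <- which(ids == max(bi, bj))
        merges[step, ] <- c(if (ids[ka] <= n) -ids[ka] else ids[ka] - n,
                            if (ids[kb] <= n) -ids[kb] else ids[kb] - n)
        sims[step] <- best
        members[[ka]] <- c(members[[ka]], members[[kb]])
        ids[ka] <- n + step
        members[[kb]] <- NULL
        ids <- ids[-kb]
    }
    list(merges = merges, similarities = sims)
}

## Left/right leaf-index sets under each merge node of a Dendrogram.
treeChildren <- function(tree) {
    subs <- vector("list", nrow(tree@merges))
    L <- list(); R <- list()
    get <- function(v) if (v < 0) -v else subs[[v]]
    for (i in seq_len(nrow(tree@merges))) {
        L[[i]] <- get(tree@merges[i, 1])
        R[[i]] <- get(tree@merges[i, 2])
        subs[[i]] <- c(L[[i]], R[[i]])
    }
    list(left = L, right = R)
}

## Hand log-rank for two groups: sum the 2x2 hypergeometric moments over
## distinct event times; statistic = (O - E)^2 / V.
handLogrank2 <- function(groupIsA, time, event) {
    ts <- sort(unique(time[event == 1]))
    O <- 0; E <- 0; V <- 0
    for (t in ts) {
        atRisk <- time >= t
        n <- sum(atRisk); nA <- sum(atRisk & groupIsA)
        d <- sum(event == 1 & time == t)
        dA <- sum(event == 1 & time == t & groupIsA)
        O <- O + dA
        E <- E + d * nA / n
        if (n > 1)
            V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
}
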