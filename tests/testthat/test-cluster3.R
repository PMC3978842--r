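test_that("SD filter is boundary-inclusive on the population SD and keeps order", {
    # rows with exactly representable population SDs 150, 90, 100
    m <- rbind(g1 = c(0, 0, 300, 300), g2 = c(0, 0, 180, 180),
               g3 = c(0, 0, 200, 200))
    colnames(m) <- sprintf("s%d", 1:4)
    got <- sdFilter(m, 100)
    expect_identical(rownames(got), c("g1", "g3"))
    expect_identical(sdFilter(m, 0), m)
    expect_warning(empty <- sdFilter(m, 1e6), "removed every gene")
    expect_identical(nrow(empty), 0L)
})

test_that("adjustMatrix log-transforms and centers genes as advertised", {
    m <- matrix(c(2, 8), 1, dimnames = list("g", c("s1", "s2")))
    expect_equal(unname(adjustMatrix(m, logBase = 2, pseudocount = 0,
                                     centerMode = "mean")[1, ]), c(-1, 1))
    const <- matrix(5, 2, 4, dimnames = list(c("a", "b"), sprintf("s%d", 1:4)))
    expect_true(all(adjustMatrix(const, centerMode = "mean") == 0))

    set.seed(6)
    r <- matrix(rexp(60), 6, 10,
                dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:10)))
    med <- adjustMatrix(r, centerMode = "median")
    expect_lt(max(abs(apply(med, 1, median))), 1e-9)
    mn <- adjustMatrix(r, centerMode = "mean")
    expect_lt(max(abs(rowMeans(mn))), 1e-9)

    neg <- matrix(c(-2, 1), 1, dimnames = list("g", c("s1", "s2")))
    expect_error(adjustMatrix(neg, pseudocount = 0), "non-positive")
})

test_that("Spearman similarity matches the rank formula and handles degenerate input", {
    expect_equal(spearmanSimilarity(1:3, c(10, 20, 30)), 1)
    expect_equal(spearmanSimilarity(1:3, c(3, 1, 2)), -0.5)
    set.seed(9)
    for (i in 1:5) {
        x <- rnorm(12); y <- rnorm(12)
        expect_equal(spearmanSimilarity(x, y), spearmanSimilarity(y, x))
        expect_equal(spearmanSimilarity(x, y),
                     cor(x, y, method = "spearman"))
    }
    # ties use average ranks
    expect_equal(spearmanSimilarity(c(1, 1, 2), c(1, 2, 3)),
                 cor(c(1, 1, 2), c(1, 2, 3), method = "spearman"))
    expect_warning(z <- spearmanSimilarity(c(1, 1, 1), 1:3), "zero rank")
    expect_equal(z, 0)
})

test_that("hcluster merges the most similar pair first and records node similarity", {
    m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
    colnames(m) <- sprintf("s%d", 1:4)
    d <- hcluster(m, axis = "genes")
    expect_identical(nrow(d@merges), 2L)
    # a and b are perfectly rank-correlated: they merge first at sim 1
    expect_identical(sort(d@merges[1, ]), c(-2L, -1L))
    expect_equal(nodeSimilarities(d)[1], 1)
    expect_error(hcluster(m[1, , drop = FALSE], axis = "genes"), "at least 2")
})

test_that("centroid, average and complete linkage agree with independent oracles on small instances", {
    for (seed in 1:6) {
        n <- sample(4:10, 1)
        P <- randMatrix(n, 8, seed = 600 + seed)
        got <- hcluster(P, axis = "genes", similarity = "spearman",
                        linkage = "centroid")
        want <- bruteCentroidTree(P)
        expect_identical(got@merges, want$merges)
        expect_equal(got@similarities, want$similarities, tolerance = 1e-12)
    }
    # average / complete linkage against the leaf-pair definitions
    P <- randMatrix(9, 7, seed = 77)
    S0 <- cor(t(P), method = "spearman")
    for (lk in c("average", "complete")) {
        got <- hcluster(P, axis = "genes", linkage = lk)
        sub <- treeChildren(got)
        for (i in seq_len(nrow(got@merges))) {
            l <- sub$left[[i]]; r <- sub$right[[i]]
            pairSims <- S0[l, r, drop = FALSE]
            want <- if (lk == "average") mean(pairSims) else min(pairSims)
            expect_equal(got@similarities[i], want, tolerance = 1e-12)
        }
    }
    # with average linkage, similarities never increase toward the root
    avg <- hcluster(P, axis = "genes", linkage = "average")
    for (i in seq_len(nrow(avg@merges))) for (ch in avg@merges[i, ]) {
        if (ch > 0)
            expect_lte(avg@similarities[i], avg@similarities[ch] + 1e-12)
    }
})

test_that("hcluster is invariant to input row order up to relabeling", {
    # long continuous profiles so similarity ties (where order may
    # legitimately matter) do not arise
    P <- randMatrix(12, 50, seed = 13)
    d1 <- hcluster(P, axis = "genes")
    set.seed(14)
    perm <- sample(nrow(P))
    d2 <- hcluster(P[perm, ], axis = "genes")
    expect_equal(sort(d1@similarities), sort(d2@similarities),
                 tolerance = 1e-12)
    for (th in c(-0.5, 0, 0.3)) {
        c1 <- vapply(cutBySimilarity(d1, th),
                     function(v) paste(sort(v), collapse = ","), "")
        c2 <- vapply(cutBySimilarity(d2, th),
                     function(v) paste(sort(v), collapse = ","), "")
        expect_setequal(c1, c2)
    }
})

test_that("similarity cuts partition the leaves at every threshold", {
    # hand-built chain: (1,2) join at 0.5, 3 joins at 0.15
    d <- new("Dendrogram", leaves = c("x", "y", "z"),
             merges = rbind(c(-1L, -2L), c(1L, -3L)),
             similarities = c(0.5, 0.15))
    cl <- cutBySimilarity(d, 0.2)
    expect_equal(cl, list(c("x", "y"), "z"), ignore_attr = TRUE)
    expect_equal(sum(is.na(attr(cl, "rootSimilarity"))), 1)

    expect_equal(cutBySimilarity(d, -1), list(c("x", "y", "z")),
                 ignore_attr = TRUE)
    expect_equal(cutBySimilarity(d, 1), list("x", "y", "z"),
                 ignore_attr = TRUE)

    P <- randMatrix(15, 5, seed = 15)
    dd <- hcluster(P, axis = "genes")
    for (th in seq(-1, 1, by = 0.25)) {
        cl <- cutBySimilarity(dd, th)
        expect_setequal(unlist(cl), rownames(P))
        expect_identical(anyDuplicated(unlist(cl)), 0L)
    }
})

test_that("TreeView files round-trip exactly and follow the Cluster 3.0 dialect", {
    m <- randMatrix(6, 4, seed = 16)
    gt <- hcluster(m, axis = "genes")
    at <- hcluster(m, axis = "samples")
    stem <- withr::local_tempfile()
    files <- writeTreeView(m, gt, at, pathStem = stem)
    expect_true(all(file.exists(paste0(stem, c(".cdt", ".gtr", ".atr")))))

    gtr <- readLines(paste0(stem, ".gtr"))
    expect_identical(length(gtr), nrow(m) - 1L)
    expect_true(all(grepl("^NODE[0-9]+X\t", gtr)))

    rt <- readTreeView(stem)
    expect_identical(rt$matrix[rownames(m), colnames(m)], m)
    expect_identical(rownames(rt$matrix), leafOrder(gt))
    expect_identical(rt$geneTree@merges, gt@merges)
    expect_equal(rt$geneTree@similarities, gt@similarities)
    expect_identical(rt$geneTree@leaves, gt@leaves)
    expect_identical(rt$sampleTree@merges, at@merges)

    # tiny 2x2 case
    m2 <- matrix(c(0.125, -1, 2, 3.5), 2,
                 dimnames = list(c("gA", "gB"), c("s1", "s2")))
    stem2 <- withr::local_tempfile()
    writeTreeView(m2, hcluster(m2, axis = "genes"), NULL, pathStem = stem2)
    rt2 <- readTreeView(stem2)
    expect_identical(rt2$matrix[rownames(m2), ], m2)
    expect_error(writeTreeView(m2, gt, NULL, stem2), "do not match")
})
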