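test_that("d-statistic matches the closed-form two-sample formula", {
    x <- matrix(1:6, nrow = 1,
                dimnames = list("g1", sprintf("s%d", 1:6)))
    r <- samDStatistic(x, rep(c("a", "b"), each = 3), s0 = 0.2)
    expect_equal(unname(r$s), 0.81650, tolerance = 1e-4)
    expect_equal(unname(r$d), 2.95130, tolerance = 1e-4)

    # identical class means -> d = 0
    y <- matrix(c(1, 2, 3, 1, 2, 3), nrow = 1)
    colnames(y) <- sprintf("s%d", 1:6)
    rownames(y) <- "g"
    expect_equal(unname(samDStatistic(y, rep(c("a", "b"), each = 3),
                                      s0 = 0.5)$d), 0)

    # label swap negates every d
    m <- randMatrix(50, 9, seed = 2)
    lab <- rep(c("a", "b"), c(4, 5))
    d1 <- samDStatistic(m, factor(lab, c("a", "b")), s0 = 0.3)$d
    d2 <- samDStatistic(m, factor(lab, c("b", "a")), s0 = 0.3)$d
    expect_equal(d1, -d2)
})

test_that("d-statistic agrees with a brute-force per-gene loop to 1e-10", {
    for (seed in 1:3) {
        m <- randMatrix(200, 11, seed = seed)
        n1 <- 5; n2 <- 6
        lab <- rep(c("a", "b"), c(n1, n2))
        s0 <- runif(1, 0, 0.5)
        got <- samDStatistic(m, lab, s0 = s0)
        for (g in sample(nrow(m), 20)) {
            x1 <- m[g, 1:n1]; x2 <- m[g, n1 + 1:n2]
            s <- sqrt((1 / n1 + 1 / n2) / (n1 + n2 - 2) *
                      (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)))
            d <- (mean(x2) - mean(x1)) / (s + s0)
            expect_equal(unname(got$d[g]), d, tolerance = 1e-10)
            expect_equal(unname(got$s[g]), s, tolerance = 1e-10)
        }
    }
})

test_that("s0 selection honours the tie rule, range contract, and responds to mean-variance dependence", {
    expect_identical(samChooseS0(rnorm(50), rep(2, 50)), 0)

    s <- seq(0.1, 1, length.out = 10)
    s0 <- samChooseS0(rnorm(10), s)
    expect_true(s0 == 0 || (s0 >= min(s) && s0 <= max(s)))

    # strong mean-variance dependence: low-s genes have wildly unstable d
    set.seed(8)
    n <- 2000
    s <- runif(n, 0.01, 1)
    r <- rnorm(n, sd = 0.2 + s)   # numerator noise not proportional to s
    expect_gt(samChooseS0(r, s), 0)
})

test_that("permutation null enumerates exactly when feasible and is seed-reproducible otherwise", {
    m <- randMatrix(30, 4, seed = 4)
    lab <- rep(c("a", "b"), each = 2)
    pn <- samPermutationNull(m, lab, nPerm = 1000, seed = 1, s0 = 0.1)
    expect_true(pn$exact)
    expect_identical(ncol(pn$permD), 6L)
    pn2 <- samPermutationNull(m, lab, nPerm = 1000, seed = 99, s0 = 0.1)
    expect_identical(pn$dbar, pn2$dbar)   # enumeration ignores the seed

    m2 <- randMatrix(40, 20, seed = 5)
    lab2 <- rep(c("a", "b"), each = 10)
    a <- samPermutationNull(m2, lab2, nPerm = 50, seed = 7, s0 = 0)
    b <- samPermutationNull(m2, lab2, nPerm = 50, seed = 7, s0 = 0)
    cc <- samPermutationNull(m2, lab2, nPerm = 50, seed = 8, s0 = 0)
    expect_false(a$exact)
    expect_identical(a$permD, b$permD)
    expect_false(identical(a$permD, cc$permD))
})

test_that("on null data the sorted observed d tracks its permutation expectation", {
    m <- randMatrix(500, 10, seed = 21)
    lab <- rep(c("a", "b"), each = 5)
    ds <- samDStatistic(m, lab, s0 = 0)
    pn <- samPermutationNull(m, lab, nPerm = 252, seed = 1, s0 = 0)
    expect_true(pn$exact)
    expect_lt(max(abs(sort(ds$d) - pn$dbar)), 1)
    expect_lt(mean(abs(sort(ds$d) - pn$dbar)), 0.3)
    expect_gt(cor(sort(ds$d), pn$dbar), 0.98)
})

test_that("delta = 0 calls every gene and increasing delta never increases calls", {
    m <- randMatrix(300, 10, seed = 31)
    m[1:30, 6:10] <- m[1:30, 6:10] + 2
    lab <- rep(c("a", "b"), each = 5)
    ds <- samDStatistic(m, lab, s0 = 0.2)
    pn <- samPermutationNull(m, lab, nPerm = 252, seed = 1, s0 = 0.2)
    r0 <- samCall(ds$d, pn$dbar, pn$permD, delta = 0)
    expect_identical(length(upGenes(r0)) + length(downGenes(r0)), 300L)

    nCalled <- vapply(seq(0, 3, length.out = 15), function(dl) {
        r <- samCall(ds$d, pn$dbar, pn$permD, delta = dl)
        length(upGenes(r)) + length(downGenes(r))
    }, 1L)
    expect_true(all(diff(nCalled) <= 0))
})

test_that("exchanging class labels mirrors up and down calls", {
    m <- randMatrix(200, 8, seed = 41)
    m[1:15, 5:8] <- m[1:15, 5:8] + 2.5
    m[16:25, 1:4] <- m[16:25, 1:4] + 2.5
    lab <- rep(c("a", "b"), each = 4)
    r1 <- sam(m, factor(lab, c("a", "b")), targetFdr = 0.1, nPerm = 70)
    r2 <- sam(m, factor(lab, c("b", "a")), targetFdr = 0.1, nPerm = 70)
    expect_true(r1@exact && r2@exact)
    expect_setequal(upGenes(r1), downGenes(r2))
    expect_setequal(downGenes(r1), upGenes(r2))
})

test_that("one-vs-rest signatures mirror for two groups and reject undersized groups", {
    m <- randMatrix(150, 8, seed = 51)
    m[1:10, 5:8] <- m[1:10, 5:8] + 3
    groups <- rep(c("g1", "g2"), each = 4)
    res <- suppressMessages(deriveSignatures(m, groups, targetFdr = 0.1,
                                             nPerm = 70, transform = "none"))
    expect_setequal(res$signatures$g1$up, res$signatures$g2$down)
    expect_setequal(res$signatures$g1$down, res$signatures$g2$up)
    expect_identical(res$summary$diagnosis, c("g1", "g2"))

    expect_error(suppressMessages(
        deriveSignatures(m, rep(c("g1", "g2"), c(2, 6)),
                         transform = "none")), "at least 3")
})
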