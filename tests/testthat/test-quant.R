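test_that("tag counting applies the mismatch cap at the boundary and honours the gene universe", {
    reads <- makeReads(gene = c("A", "A", "A", "A"),
                       start = c(1, 2, 3, 4), len = rep(500, 4),
                       mism = c(0, 1, 2, 3))
    tc <- countTags(reads, maxMismatches = 2)
    expect_identical(unname(SummarizedExperiment::assay(tc)["A", "lib1"]), 3L)
    expect_identical(expressionStage(tc), "counts")

    # zero-count gene retained only when the universe names it
    tcU <- countTags(reads, maxMismatches = 2, geneUniverse = c("A", "Z"))
    expect_setequal(rownames(tcU), c("A", "Z"))
    expect_identical(unname(SummarizedExperiment::assay(tcU)["Z", "lib1"]), 0L)

    # order invariance
    perm <- sample(nrow(reads))
    expect_identical(SummarizedExperiment::assay(countTags(reads[perm, ])),
                     SummarizedExperiment::assay(countTags(reads)))
})

test_that("mapped-read validation catches empty input and conflicting transcript lengths", {
    expect_error(countTags(makeReads()[0, ]), "empty")
    bad <- makeReads(gene = c("A", "A"), len = c(500, 600),
                     start = c(1, 2), mism = c(0, 0))
    expect_error(countTags(bad), "conflicting transcript length")
    expect_error(countTags(makeReads(start = c(-1, 20, 30))), "start")
})

test_that("counts match the generator's own tally on multinomial reads", {
    genes <- data.frame(gene = sprintf("g%02d", 1:50),
                        transcript_length = sample(800:2000, 50))
    reads <- genMappedReads(10000, genes, proportions = runif(50, 0.5, 2),
                            seed = 42)
    tc <- countTags(reads, maxMismatches = 2)
    kept <- reads[reads$mismatches <= 2, ]
    want <- table(kept$gene)
    got <- SummarizedExperiment::assay(tc)[names(want), "lib1"]
    expect_identical(unname(got), as.integer(want))
})

test_that("TPM normalization scales to 1e6 and preserves within-library ranks", {
    m <- matrix(c(5, 15, 0, 0, 0, 7), nrow = 3,
                dimnames = list(c("a", "b", "c"), c("s1", "s2")))
    tpm <- tpmNormalize(m)
    expect_equal(tpm["a", "s1"], 250000)
    expect_equal(tpm["c", "s2"], 1e6)     # single-gene library
    expect_equal(unname(colSums(tpm)), rep(1e6, 2))

    set.seed(3)
    r <- matrix(rpois(200, 20) + 1, 20, 10,
                dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10)))
    rt <- tpmNormalize(r)
    expect_equal(unname(colSums(rt)), rep(1e6, 10), tolerance = 1e-6)
    for (j in 1:10)
        expect_identical(order(rt[, j]), order(r[, j]))

    z <- m; z[, 1] <- 0
    expect_error(tpmNormalize(z), "s1")
})

test_that("saturation curve is exact at full depth, monotone, and matches the hypergeometric expectation", {
    genes <- data.frame(gene = sprintf("g%03d", 1:100),
                        transcript_length = 1000)
    reads <- do.call(rbind, lapply(1:100, function(i)
        makeReads(gene = rep(genes$gene[i], 10), start = 800 + 1:10,
                  len = rep(1000, 10), mism = rep(0, 10))))
    sat <- saturationCurve(reads, fractions = c(0.01, 0.1, 0.5, 1),
                           nRep = 200, seed = 7)
    expect_equal(sat$mean_detected[4], 100)   # full depth exact
    expect_equal(sat$sd_detected[4], 0)
    expect_true(all(diff(sat$mean_detected) >= 0))
    expect_equal(attr(sat, "saturation"), 1)

    # closed-form oracle: E[detected] = sum_g 1 - C(N-n_g, k)/C(N, k)
    k <- round(0.01 * 1000)
    exact <- 100 * (1 - exp(lchoose(1000 - 10, k) - lchoose(1000, k)))
    expect_equal(exact, 9.56, tolerance = 0.01)
    se <- sat$sd_detected[1] / sqrt(200)
    expect_lt(abs(sat$mean_detected[1] - exact), 4 * se + 0.05)

    expect_error(saturationCurve(reads, fractions = c(0, 0.5)), "fractions")
    expect_error(saturationCurve(reads, fractions = 1.2), "fractions")
    expect_error(saturationCurve(reads, referenceSize = 10), "referenceSize")
})

test_that("3'-distance profile follows the stated convention and finds the modal bin", {
    one <- makeReads(gene = "A", start = 900, len = 1000, mism = 0)
    prof <- threePrimeDistanceProfile(one, binWidth = 50)
    expect_equal(sum(prof$histogram$count), 1)
    hit <- prof$histogram[prof$histogram$count > 0, ]
    expect_true(hit$bin_start <= 100 && 100 < hit$bin_end)

    many <- makeReads(gene = rep("B", 40), start = rep(850, 40),
                      len = rep(1000, 40), mism = rep(0, 40))
    prof2 <- threePrimeDistanceProfile(many, binWidth = 50)
    expect_true(prof2$modal_bin[1] <= 150 && 150 < prof2$modal_bin[2])

    genes <- data.frame(gene = sprintf("g%d", 1:20),
                        transcript_length = sample(1000:3000, 20))
    reads <- genMappedReads(5000, genes, distanceMean = 150,
                            distanceSd = 30, seed = 5)
    prof3 <- threePrimeDistanceProfile(reads, binWidth = 50)
    expect_gte(prof3$modal_bin[1], 100)
    expect_lte(prof3$modal_bin[2], 200)
    expect_equal(sum(prof3$histogram$count), 5000)
})

test_that("expression TSV writer/reader round-trips bit-stably", {
    set.seed(11)
    m <- matrix(c(rpois(6, 50), runif(6)), 4, 3,
                dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:3)))
    p <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionTSV(m, p, header = "roundtrip test")
    expect_identical(readExpressionTSV(p), m)
})
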