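## Synthetic-data generators with planted structure. Every generator
## returns its ground truth alongside the data, and all randomness flows
## from a single seed through named substreams, so equal configs give
## bit-identical output.

#' Configuration for the multi-group discovery-cohort generator
#'
#' Defaults emulate the discovery setting: 53 libraries over 10 diagnosis
#' groups with the per-group case counts of the study design, a planted
#' 50-gene expression program per group elevated by 2 log2 units, and
#' overdispersed (negative binomial) tag counts at desk-scale depth.
#'
#' @param nGroups number of diagnosis groups.
#' @param samplesPerGroup integer vector of group sizes.
#' @param nGenes total genes.
#' @param programSize planted program genes per group (disjoint blocks).
#' @param effectLog2fc log2 fold elevation of a program in its group.
#' @param dispersion negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2); 0 gives Poisson counts.
#' @param librarySizeMean mean library size in reads (lognormal across
#'   libraries, sdlog 0.3).
#' @param groupNames group labels.
#' @param seed base seed.
#' @return validated config list of class \code{"FibrousSimConfig"}.
#' @export
fibrousSimConfig <- function(nGroups = 10,
                             samplesPerGroup = c(7, 5, 4, 6, 4, 3, 8, 6, 4, 6),
                             nGenes = 2000, programSize = 50,
                             effectLog2fc = 2, dispersion = 0.1,
                             librarySizeMean = 1e5,
                             groupNames = c("DTF", "SFT", "DFSP", "FC", "EF",
                                            "IF", "PF", "NPAF", "FOTS", "NF"),
                             seed = 1) {
    stopifnot(nGroups >= 2, length(samplesPerGroup) == nGroups,
              all(samplesPerGroup >= 2), nGenes >= nGroups * programSize,
              programSize >= 1, effectLog2fc >= 0, dispersion >= 0,
              librarySizeMean > 0)
    if (length(groupNames) != nGroups)
        groupNames <- sprintf("G%02d", seq_len(nGroups))
    structure(list(nGroups = nGroups,
                   samplesPerGroup = as.integer(samplesPerGroup),
                   nGenes = nGenes, programSize = programSize,
                   effectLog2fc = effectLog2fc, dispersion = dispersion,
                   librarySizeMean = librarySizeMean,
                   groupNames = groupNames, seed = seed),
              class = "FibrousSimConfig")
}

#' Generate a multi-group tag-count discovery cohort
#'
#' Counts are negative binomial around library-size-scaled gene
#' abundances; each group's planted program genes are elevated by
#' \code{effectLog2fc} log2 units in that group (abundances renormalized,
#' so library size is preserved).
#'
#' @param config a \code{\link{fibrousSimConfig}}.
#' @return list: \code{counts} (counts-stage
#'   \linkS4class{TagCountExperiment} with the diagnosis in
#'   \code{colData()$diagnosis}), \code{labels} (factor), \code{truth}
#'   (named list of planted program gene sets).
#' @export
genFibrousCounts <- function(config) {
    stopifnot(inherits(config, "FibrousSimConfig"))
    nG <- config$nGenes
    genes <- sprintf("gene%04d", seq_len(nG))
    labels <- factor(rep(config$groupNames,
                         times = config$samplesPerGroup),
                     levels = config$groupNames)
    nS <- length(labels)
    samples <- sprintf("lib%02d", seq_len(nS))

    w <- withSubstream(config$seed, "baseline",
                       expr = stats::rlnorm(nG, meanlog = 0, sdlog = 1))
    progIdx <- withSubstream(config$seed, "programs", expr =
        sample.int(nG, config$nGroups * config$programSize))
    truth <- split(genes[progIdx],
                   rep(config$groupNames, each = config$programSize))
    truth <- truth[config$groupNames]
    libSizes <- withSubstream(config$seed, "libsizes", expr =
        stats::rlnorm(nS, meanlog = log(config$librarySizeMean) - 0.3^2 / 2,
                      sdlog = 0.3))

    counts <- matrix(0L, nG, nS, dimnames = list(genes, samples))
    fc <- 2^config$effectLog2fc
    for (s in seq_len(nS)) {
        ws <- w
        ws[genes %in% truth[[as.character(labels[s])]]] <-
            ws[genes %in% truth[[as.character(labels[s])]]] * fc
        mu <- libSizes[s] * ws / sum(ws)
        counts[, s] <- withSubstream(config$seed, "counts", s, expr = {
            if (config$dispersion > 0)
                stats::rnbinom(nG, mu = mu, size = 1 / config$dispersion)
            else stats::rpois(nG, mu)
        })
    }
    tce <- TagCountExperiment(counts, stage = "counts",
                              colData = S4Vectors::DataFrame(
                                  diagnosis = labels,
                                  row.names = samples))
    list(counts = tce, labels = stats::setNames(labels, samples),
         truth = truth)
}

#' Configuration for the projection-cohort generator
#'
#' Defaults emulate one microarray cohort of the projection stage: 200
#' samples, a planted 40-gene signature block over-expressed by 1.5
#' centered log2 units in a 25\% latent subpopulation, unit background
#' noise, exponential survival with per-status proportional hazards and
#' independent exponential censoring tuned to a 20\% censoring fraction.
#'
#' @param nSamples cohort size.
#' @param nGenes total genes on the platform.
#' @param signatureBlocks list of blocks, each
#'   \code{list(size=, prevalence=, effect=)}. \code{effect} is the mean
#'   over-expression of the block in status-positive samples; individual
#'   genes get lognormal effect multipliers (mean 1, sdlog
#'   \code{effectHeterogeneity}), reproducing the graded coordinate
#'   over-expression of real signature blocks — without gene-to-gene
#'   variation in effect size, sample-sample correlation (which discards
#'   shared offsets) would be blind to the block by construction.
#' @param effectHeterogeneity sdlog of the per-gene effect multipliers
#'   (default 0.8; 0 gives a uniform effect).
#' @param noiseSd background noise SD (centered log2 units).
#' @param hazardRatio hazard multiplier per block for status-positive
#'   samples (recycled over blocks).
#' @param baselineHazard events per month for status-negative samples.
#' @param censoringRate target fraction of censored samples, in [0, 1).
#' @param seed base seed.
#' @return validated config list of class \code{"CohortSimConfig"}.
#' @export
cohortSimConfig <- function(nSamples = 200, nGenes = 1000,
                            signatureBlocks = list(
                                list(size = 40, prevalence = 0.25,
                                     effect = 1.5)),
                            effectHeterogeneity = 0.8,
                            noiseSd = 1, hazardRatio = 1,
                            baselineHazard = 0.01, censoringRate = 0.2,
                            seed = 1) {
    stopifnot(nSamples >= 4, nGenes >= 1,
              length(signatureBlocks) >= 1,
              censoringRate >= 0, censoringRate < 1,
              baselineHazard > 0, noiseSd > 0)
    for (b in signatureBlocks)
        stopifnot(b$size >= 1, b$prevalence > 0, b$prevalence < 1,
                  b$effect >= 0)
    totalBlock <- sum(vapply(signatureBlocks, `[[`, 1.0, "size"))
    stopifnot(nGenes >= totalBlock)
    hazardRatio <- rep_len(hazardRatio, length(signatureBlocks))
    stopifnot(all(hazardRatio > 0))
    stopifnot(effectHeterogeneity >= 0)
    structure(list(nSamples = nSamples, nGenes = nGenes,
                   signatureBlocks = signatureBlocks,
                   effectHeterogeneity = effectHeterogeneity,
                   noiseSd = noiseSd,
                   hazardRatio = hazardRatio,
                   baselineHazard = baselineHazard,
                   censoringRate = censoringRate, seed = seed),
              class = "CohortSimConfig")
}

## Censoring rate of an exponential censor with rate lc against subjects
## with event rates lambda: E[lc / (lc + lambda)].
.censorRateFor <- function(lc, lambda) mean(lc / (lc + lambda))

#' Generate a projection cohort with planted signature structure
#'
#' The expression matrix is built directly on the centered log scale the
#' projection stage consumes: background N(0, noiseSd), block genes of
#' latent-status-positive samples shifted up by the block effect, then
#' median-centered per gene. Survival times are exponential with the
#' baseline hazard multiplied by each block's hazard ratio for positive
#' samples; censoring is an independent exponential whose rate is solved
#' (on the known hazard mixture) to hit the target censoring fraction in
#' expectation.
#'
#' @param config a \code{\link{cohortSimConfig}}.
#' @return list: \code{expr} (centered genes x samples matrix),
#'   \code{survival} (data.frame from \code{\link{survivalTable}}),
#'   \code{truth} (list: \code{status} sample x block logical matrix,
#'   \code{blockGenes} list of planted gene sets).
#' @export
genCohort <- function(config) {
    stopifnot(inherits(config, "CohortSimConfig"))
    nS <- config$nSamples; nG <- config$nGenes
    genes <- sprintf("gene%04d", seq_len(nG))
    samples <- sprintf("case%03d", seq_len(nS))
    nB <- length(config$signatureBlocks)

    expr <- withSubstream(config$seed, "noise", expr =
        matrix(stats::rnorm(nG * nS, sd = config$noiseSd), nG, nS,
               dimnames = list(genes, samples)))
    sizes <- vapply(config$signatureBlocks, `[[`, 1.0, "size")
    stops <- cumsum(sizes)
    starts <- stops - sizes + 1
    blockGenes <- lapply(seq_len(nB), function(b)
        genes[starts[b]:stops[b]])
    names(blockGenes) <- sprintf("block%d", seq_len(nB))

    status <- matrix(FALSE, nS, nB,
                     dimnames = list(samples, names(blockGenes)))
    geneEffects <- vector("list", nB)
    names(geneEffects) <- names(blockGenes)
    sdl <- config$effectHeterogeneity
    for (b in seq_len(nB)) {
        st <- withSubstream(config$seed, "status", b, expr =
            stats::runif(nS) < config$signatureBlocks[[b]]$prevalence)
        status[, b] <- st
        eff <- config$signatureBlocks[[b]]$effect *
            withSubstream(config$seed, "effects", b, expr =
                stats::rlnorm(length(blockGenes[[b]]),
                              meanlog = -sdl^2 / 2, sdlog = sdl))
        geneEffects[[b]] <- stats::setNames(eff, blockGenes[[b]])
        expr[blockGenes[[b]], st] <- expr[blockGenes[[b]], st] + eff
    }
    expr <- expr - apply(expr, 1L, stats::median)

    lambda <- config$baselineHazard *
        apply(status, 1L, function(st) prod(config$hazardRatio^st))
    evt <- withSubstream(config$seed, "eventtimes", expr =
        stats::rexp(nS, rate = lambda))
    if (config$censoringRate > 0) {
        lc <- stats::uniroot(function(l)
            .censorRateFor(l, lambda) - config$censoringRate,
            interval = c(1e-10, 1e4 * max(lambda)))$root
        cens <- withSubstream(config$seed, "censortimes", expr =
            stats::rexp(nS, rate = lc))
    } else cens <- rep(Inf, nS)
    time <- pmin(evt, cens)
    event <- as.integer(evt <= cens)

    covs <- withSubstream(config$seed, "covariates", expr = data.frame(
        grade = sample(1:3, nS, replace = TRUE,
                       prob = c(0.3, 0.45, 0.25)),
        er_positive = as.integer(stats::runif(nS) < 0.75)))
    covs <- cbind(covs, as.data.frame(status))
    surv <- survivalTable(samples, time, event, endpoint = "OS",
                          covariates = covs)
    list(expr = expr, survival = surv,
         truth = list(status = status, blockGenes = blockGenes,
                      geneEffects = geneEffects))
}

#' Generate mapped-read records for a 3'-end tag library
#'
#' Reads are assigned to genes multinomially and placed so that the
#' distance from the read 5' end to the transcript 3' end follows a
#' truncated Normal (inverse-CDF truncation to [1, transcript length]),
#' emulating the 100-200 nt positioning of sheared poly(A)-anchored
#' fragments. Mismatch counts are drawn independently.
#'
#' @param nReads number of reads.
#' @param genes data.frame with columns \code{gene},
#'   \code{transcript_length}.
#' @param proportions per-gene sampling weights (default uniform).
#' @param distanceMean,distanceSd parameters of the 3'-distance Normal
#'   (nt).
#' @param mismatchProbs probabilities of 0, 1, 2, ... mismatches.
#' @param libraryId library identifier.
#' @param seed base seed.
#' @return data.frame of mapped reads (see \code{\link{readMappedReads}}).
#' @export
genMappedReads <- function(nReads, genes, proportions = NULL,
                           distanceMean = 150, distanceSd = 30,
                           mismatchProbs = c(0.9, 0.08, 0.02),
                           libraryId = "lib1", seed = 1) {
    stopifnot(nReads >= 1, is.data.frame(genes),
              all(c("gene", "transcript_length") %in% names(genes)),
              all(genes$transcript_length > 1))
    if (is.null(proportions))
        proportions <- rep(1, nrow(genes))
    stopifnot(length(proportions) == nrow(genes), all(proportions >= 0))
    gi <- withSubstream(seed, "geneassign", expr =
        sample.int(nrow(genes), nReads, replace = TRUE,
                   prob = proportions))
    len <- genes$transcript_length[gi]
    d <- withSubstream(seed, "distances", expr = {
        lo <- stats::pnorm(1, distanceMean, distanceSd)
        hi <- stats::pnorm(len, distanceMean, distanceSd)
        stats::qnorm(lo + stats::runif(nReads) * (hi - lo),
                     distanceMean, distanceSd)
    })
    start <- pmin(pmax(len - round(d), 0), len - 1)
    mm <- withSubstream(seed, "mismatches", expr =
        sample(seq_along(mismatchProbs) - 1L, nReads, replace = TRUE,
               prob = mismatchProbs))
    data.frame(library_id = libraryId, gene = genes$gene[gi],
               transcript_length = len, start = start, mismatches = mm,
               stringsAsFactors = FALSE)
}
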