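## Orchestration of the full workflow on files: simulate -> quantify ->
## signatures -> project/survive. Every output carries a provenance header
## (package version, seed, config fingerprint) and reruns with the same
## config and seed are byte-identical.

#' Pipeline configuration with the study's printed thresholds
#'
#' @param samFdr SAM target FDR (default 0.05).
#' @param sdFilter SD filter threshold on the TPM scale (default 100).
#' @param sampleCorr sample-axis node-correlation cut (default 0.2).
#' @param geneCorr gene-axis node-correlation cut for core genes
#'   (default 0.1).
#' @param minDatasets cohorts required for a core gene (default 3).
#' @param maxMismatches read-filter mismatch cap (default 2).
#' @param nPerm SAM permutations (default 1000).
#' @param seed base seed for all stages.
#' @return named list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(samFdr = 0.05, sdFilter = 100, sampleCorr = 0.2,
                           geneCorr = 0.1, minDatasets = 3,
                           maxMismatches = 2, nPerm = 1000, seed = 1) {
    stopifnot(samFdr > 0, samFdr <= 1, sdFilter >= 0,
              sampleCorr >= -1, sampleCorr <= 1,
              geneCorr >= -1, geneCorr <= 1,
              minDatasets >= 1, maxMismatches >= 0, nPerm >= 1)
    structure(list(samFdr = samFdr, sdFilter = sdFilter,
                   sampleCorr = sampleCorr, geneCorr = geneCorr,
                   minDatasets = minDatasets, maxMismatches = maxMismatches,
                   nPerm = nPerm, seed = seed),
              class = "PipelineConfig")
}

provenanceHeader <- function(config) {
    fp <- substreamSeed(0, paste(deparse(unclass(config)), collapse = ""))
    c(sprintf("stromalsig %s",
              as.character(utils::packageVersion("stromalsig"))),
      sprintf("seed=%d config=%d", config$seed, fp))
}

#' Run the quantification stage on a mapped-read file
#'
#' Composes tag counting, TPM normalization, the saturation curve and the
#' 3'-distance histogram, writing \code{counts.tsv}, \code{tpm.tsv},
#' \code{saturation.tsv} and \code{distance_histogram.tsv}.
#'
#' @param readsPath mapped-read TSV (see \code{\link{readMappedReads}}).
#' @param outDir output directory (created if needed).
#' @param config a \code{\link{pipelineConfig}}.
#' @param binWidth histogram bin width (nt).
#' @return named character vector of output files, invisibly.
#' @export
runQuantify <- function(readsPath, outDir, config = pipelineConfig(),
                        binWidth = 50) {
    if (!file.exists(readsPath)) stop("missing input: ", readsPath)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    hdr <- provenanceHeader(config)
    reads <- readMappedReads(readsPath)
    counts <- countTags(reads, maxMismatches = config$maxMismatches)
    tpm <- tpmNormalize(counts)
    message("quantify: ", nrow(reads), " reads -> ",
            nrow(counts), " genes x ", ncol(counts), " libraries")
    out <- c(counts = file.path(outDir, "counts.tsv"),
             tpm = file.path(outDir, "tpm.tsv"),
             saturation = file.path(outDir, "saturation.tsv"),
             histogram = file.path(outDir, "distance_histogram.tsv"))
    writeExpressionTSV(counts, out["counts"], header = hdr)
    writeExpressionTSV(tpm, out["tpm"], header = hdr)
    sat <- saturationCurve(reads, seed = config$seed)
    con <- file(out["saturation"], "w")
    writeLines(paste0("# ", c(hdr, sprintf("saturation=%.6f",
                                           attr(sat, "saturation")))), con)
    utils::write.table(sat, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    prof <- threePrimeDistanceProfile(reads, binWidth = binWidth)
    con <- file(out["histogram"], "w")
    writeLines(paste0("# ", c(hdr, sprintf("modal_bin=%g-%g",
                                           prof$modal_bin[1],
                                           prof$modal_bin[2]))), con)
    utils::write.table(prof$histogram, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    invisible(out)
}

#' Run signature derivation on a TPM matrix
#'
#' One-vs-rest SAM per diagnosis group at the configured FDR; writes one
#' up-gene list per group (\code{<group>_up.txt}) plus
#' \code{table1_summary.tsv} (diagnosis, n cases, n up, n down).
#'
#' @param tpmPath TPM matrix TSV.
#' @param labelsPath two-column TSV (sample, diagnosis).
#' @param outDir output directory.
#' @param config a \code{\link{pipelineConfig}}.
#' @return list as from \code{\link{deriveSignatures}}, with
#'   \code{$files}, invisibly.
#' @export
runSignatures <- function(tpmPath, labelsPath, outDir,
                          config = pipelineConfig()) {
    for (p in c(tpmPath, labelsPath))
        if (!file.exists(p)) stop("missing input: ", p)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    hdr <- provenanceHeader(config)
    tpm <- readExpressionTSV(tpmPath)
    lab <- utils::read.delim(labelsPath, stringsAsFactors = FALSE,
                             comment.char = "#")
    if (!all(colnames(tpm) %in% lab[[1]]))
        stop("labels file does not cover every sample")
    groups <- factor(lab[[2]][match(colnames(tpm), lab[[1]])])
    res <- deriveSignatures(tpm, groups, targetFdr = config$samFdr,
                            nPerm = config$nPerm, seed = config$seed)
    files <- character(0)
    for (g in names(res$signatures)) {
        p <- file.path(outDir, paste0(g, "_up.txt"))
        writeGeneList(res$signatures[[g]]$up, p)
        files <- c(files, p)
    }
    sump <- file.path(outDir, "table1_summary.tsv")
    con <- file(sump, "w")
    writeLines(paste0("# ", hdr), con)
    utils::write.table(res$summary, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    message("signatures: ", nrow(res$summary), " groups, ",
            sum(res$summary$n_up), " up calls in total")
    res$files <- c(files, sump)
    invisible(res)
}

#' Project a signature onto cohorts and test outcome association
#'
#' For each cohort: restricts the matrix to the signature genes, clusters
#' the samples, calls the signature-positive group; across cohorts derives
#' the core gene set; per cohort with survival data runs the log-rank test
#' between positive and negative cases and exports Kaplan-Meier curves.
#' Writes \code{assignments.tsv}, \code{core_signature.tsv},
#' \code{km_curves.tsv} and \code{tests.tsv}.
#'
#' @param cohortPaths named character vector of cohort matrix TSVs
#'   (centered log-scale values).
#' @param signaturePath gene-list file (one symbol per line).
#' @param survivalPaths named character vector of survival TSVs parallel
#'   to \code{cohortPaths} (columns sample, endpoint, time, event, ...),
#'   or NULL to skip outcome testing.
#' @param outDir output directory.
#' @param config a \code{\link{pipelineConfig}}.
#' @param name signature name (default: signature file stem).
#' @return list with \code{assignments}, \code{core}, \code{tests},
#'   invisibly.
#' @export
runProject <- function(cohortPaths, signaturePath, survivalPaths = NULL,
                       outDir, config = pipelineConfig(), name = NULL) {
    for (p in c(cohortPaths, signaturePath, survivalPaths))
        if (!file.exists(p)) stop("missing input: ", p)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    hdr <- provenanceHeader(config)
    if (is.null(name))
        name <- sub("\\.[^.]*$", "", basename(signaturePath))
    if (is.null(names(cohortPaths)))
        names(cohortPaths) <- sprintf("cohort%d", seq_along(cohortPaths))
    genes <- readGeneList(signaturePath)
    subs <- list(); assigns <- list()
    for (cid in names(cohortPaths)) {
        m <- readExpressionTSV(cohortPaths[[cid]])
        sub <- mapSignatureToCohort(genes, m)
        a <- identifyPositiveGroup(sub, threshold = config$sampleCorr,
                                   name = name)
        message("project[", cid, "]: ", sum(a@positive), "/",
                length(a@samples), " samples positive")
        subs[[cid]] <- sub; assigns[[cid]] <- a
    }
    core <- if (length(subs) >= config$minDatasets)
        deriveCoreGenes(subs, assigns, corrThreshold = config$geneCorr,
                        minDatasets = config$minDatasets, name = name)
    else NULL
    writeAssignments(assigns, file.path(outDir, "assignments.tsv"),
                     header = hdr)
    if (!is.null(core))
        writeCoreSignature(core, file.path(outDir, "core_signature.tsv"),
                           header = hdr)
    tests <- NULL; curves <- NULL
    if (!is.null(survivalPaths)) {
        for (cid in names(cohortPaths)) {
            sv <- utils::read.delim(survivalPaths[[cid]],
                                    comment.char = "#",
                                    stringsAsFactors = FALSE)
            a <- assigns[[cid]]
            ix <- match(sv$sample, a@samples)
            sv <- sv[!is.na(ix), , drop = FALSE]
            lab <- ifelse(a@positive[match(sv$sample, a@samples)],
                          "positive", "negative")
            if (length(unique(lab)) < 2) next
            lr <- logrankTest(lab, sv$time, sv$event)
            tests <- rbind(tests, data.frame(
                cohort = cid, signature = name, test = "logrank",
                statistic = lr$chisq, df = lr$df, p = lr$p))
            curves <- rbind(curves, cbind(cohort = cid,
                kmCurvesByGroup(lab, sv$time, sv$event)))
        }
        if (!is.null(tests)) {
            con <- file(file.path(outDir, "tests.tsv"), "w")
            writeLines(paste0("# ", hdr), con)
            utils::write.table(tests, con, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            close(con)
        }
        if (!is.null(curves)) {
            con <- file(file.path(outDir, "km_curves.tsv"), "w")
            writeLines(paste0("# ", hdr), con)
            utils::write.table(curves, con, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            close(con)
        }
    }
    invisible(list(assignments = assigns, core = core, tests = tests))
}

#' Simulate a full synthetic study to files
#'
#' Writes a discovery cohort (counts matrix + diagnosis labels + truth)
#' and \code{nCohorts} projection cohorts (centered matrix + survival
#' table + truth) under \code{outDir}, in the standard TSV/JSON formats
#' the other stages consume.
#'
#' @param outDir output directory.
#' @param nCohorts number of projection cohorts (default 4).
#' @param fibrousConfig a \code{\link{fibrousSimConfig}}; NULL for
#'   defaults.
#' @param cohortConfig a \code{\link{cohortSimConfig}} template; each
#'   cohort re-seeds it from the base seed. NULL for defaults.
#' @param config a \code{\link{pipelineConfig}} supplying the base seed.
#' @return named list of written files, invisibly.
#' @export
runSimulate <- function(outDir, nCohorts = 4, fibrousConfig = NULL,
                        cohortConfig = NULL, config = pipelineConfig()) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    hdr <- provenanceHeader(config)
    if (is.null(fibrousConfig))
        fibrousConfig <- fibrousSimConfig(seed = substreamSeed(
            config$seed, "fibrous"))
    fib <- genFibrousCounts(fibrousConfig)
    files <- c(discovery_counts = file.path(outDir, "discovery_counts.tsv"),
               discovery_labels = file.path(outDir, "discovery_labels.tsv"),
               discovery_truth = file.path(outDir, "discovery_truth.json"))
    writeExpressionTSV(fib$counts, files["discovery_counts"], header = hdr)
    utils::write.table(
        data.frame(sample = names(fib$labels),
                   diagnosis = as.character(fib$labels)),
        files["discovery_labels"], sep = "\t", quote = FALSE,
        row.names = FALSE)
    jsonlite::write_json(fib$truth, files["discovery_truth"])
    for (k in seq_len(nCohorts)) {
        cfg <- if (is.null(cohortConfig)) cohortSimConfig() else cohortConfig
        cfg$seed <- substreamSeed(config$seed, "cohort", k)
        ch <- genCohort(cfg)
        stem <- sprintf("cohort%d", k)
        fk <- c(file.path(outDir, paste0(stem, "_expr.tsv")),
                file.path(outDir, paste0(stem, "_survival.tsv")),
                file.path(outDir, paste0(stem, "_truth.json")))
        names(fk) <- paste0(stem, c("_expr", "_survival", "_truth"))
        writeExpressionTSV(ch$expr, fk[1], header = hdr)
        utils::write.table(ch$survival, fk[2], sep = "\t", quote = FALSE,
                           row.names = FALSE)
        jsonlite::write_json(
            list(status = as.data.frame(ch$truth$status),
                 blockGenes = ch$truth$blockGenes), fk[3])
        files <- c(files, fk)
    }
    invisible(files)
}
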