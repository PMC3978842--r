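## Internal helpers: reproducible substreams and TSV round-trips.

## Fold a base seed and a sequence of names/indices into a 31-bit seed, so
## each (seed, "purpose", index...) pair gets its own deterministic stream.
substreamSeed <- function(seed, ...) {
    parts <- as.character(unlist(list(...)))
    h <- as.double(seed %% 2147483647L)
    for (p in parts) {
        for (k in utf8ToInt(p)) h <- (h * 131 + k) %% 2147483647
    }
    as.integer(h)
}

withSubstream <- function(seed, ..., expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(substreamSeed(seed, ...))
    expr
}

## Population (divide-by-n) row standard deviation, Cluster 3.0 style.
rowSdPop <- function(x) {
    m <- rowMeans(x)
    sqrt(rowMeans((x - m)^2))
}

## Sample (divide-by-n-1) row standard deviation.
rowSdSample <- function(x) {
    n <- ncol(x)
    m <- rowMeans(x)
    sqrt(rowSums((x - m)^2) / (n - 1))
}

fmtNum <- function(x) {
    out <- sprintf("%.17g", x)
    ix <- abs(x - round(x)) < .Machine$double.eps & abs(x) < 1e15
    out[ix] <- sprintf("%d", as.integer(round(x[ix])))
    big <- ix & abs(x) > .Machine$integer.max
    out[big] <- sprintf("%.17g", x[big])
    out
}

#' Write an expression matrix as TSV
#'
#' First column holds the gene identifier, remaining columns one per
#' sample. Integer values are written as integers and numeric values with
#' 17 significant digits, so a write/read round trip is bit-stable.
#'
#' @param x numeric matrix with dimnames, or a
#'   \linkS4class{TagCountExperiment}.
#' @param path output file.
#' @param idColumn header of the identifier column.
#' @param header optional character vector of comment lines (without the
#'   leading \code{"#"}) written before the table.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTSV <- function(x, path, idColumn = "gene", header = NULL) {
    if (is(x, "TagCountExperiment")) x <- SummarizedExperiment::assay(x)
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header))
        writeLines(paste0("# ", header), con)
    writeLines(paste(c(idColumn, colnames(x)), collapse = "\t"), con)
    body <- apply(x, 1L, function(r) paste(fmtNum(r), collapse = "\t"))
    writeLines(paste(rownames(x), body, sep = "\t"), con)
    invisible(path)
}

#' Read an expression matrix from TSV
#'
#' @param path file written by \code{\link{writeExpressionTSV}} (or any TSV
#'   whose first column is the row identifier). Lines starting with
#'   \code{"#"} are skipped.
#' @return numeric matrix with dimnames.
#' @export
readExpressionTSV <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "double"
    m
}

#' Write a gene list, one symbol per line
#' @param genes character vector.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGeneList <- function(genes, path) {
    writeLines(as.character(genes), path)
    invisible(path)
}

#' Read a gene list written by \code{\link{writeGeneList}}
#' @param path input file.
#' @return character vector.
#' @export
readGeneList <- function(path) {
    x <- readLines(path)
    x[nzchar(x) & !startsWith(x, "#")]
}
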