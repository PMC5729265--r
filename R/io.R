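#' Read a beta-value matrix from TSV/CSV
#'
#' Expects a header row of sample IDs and a first column of probe IDs.
#' The field separator is sniffed from the header line (tab wins over
#' comma) unless given.
#'
#' @param path file path
#' @param sep field separator; \code{NULL} (default) sniffs tab vs comma
#' @return numeric matrix, probes by samples
#' @export
readBetaMatrix <- function(path, sep = NULL) {
    sep <- .sniffSep(path, sep)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("beta matrix needs a probe-ID column plus samples")
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("beta matrix contains non-numeric values")
    rownames(m) <- as.character(df[[1]])
    m
}

#' Read a CpG annotation table (TSV or BED)
#'
#' Accepts either a headered TSV with columns \code{probe_id},
#' \code{chromosome}, \code{position} (1-based) or a headerless 4-column
#' BED (\code{chrom start end name}); BED coordinates are 0-based
#' half-open and are converted so the probe position is \code{start + 1}.
#'
#' @param path file path
#' @return a named \code{GRanges} of width-1 probe positions
#' @export
readCpGAnnotation <- function(path) {
    first <- readLines(path, n = 1L)
    fields <- strsplit(first, "\t")[[1]]
    isBed <- length(fields) >= 4 &&
        suppressWarnings(!is.na(as.integer(fields[2])) &&
                         !is.na(as.integer(fields[3])))
    if (isBed) {
        df <- utils::read.table(path, header = FALSE, sep = "\t",
                                stringsAsFactors = FALSE)
        gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, width = 1L))
        names(gr) <- as.character(df[[4]])
    } else {
        df <- utils::read.table(path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
        need <- c("probe_id", "chromosome", "position")
        if (!all(need %in% colnames(df)))
            stop("annotation TSV needs columns: ",
                 paste(need, collapse = ", "))
        gr <- GRanges(df$chromosome, IRanges(as.integer(df$position),
                                             width = 1L))
        names(gr) <- as.character(df$probe_id)
    }
    if (anyDuplicated(names(gr))) stop("annotation probe IDs must be unique")
    gr
}

#' Read a sample phenotype table (TSV)
#'
#' First column holds sample IDs; remaining columns are variables.
#'
#' @param path file path
#' @return data.frame with sample IDs as rownames
#' @export
readPhenotypes <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 1) stop("phenotype table is empty")
    rownames(df) <- as.character(df[[1]])
    df[, -1, drop = FALSE]
}

#' Read beta matrix, annotation and phenotypes into a MethylExperiment
#'
#' @param betaPath,annotPath,phenoPath file paths; \code{phenoPath} may be
#'   \code{NULL}
#' @param epsilon clipping bound, see \code{\link{MethylExperiment}}
#' @return a \linkS4class{MethylExperiment}
#' @export
readMethylData <- function(betaPath, annotPath, phenoPath = NULL,
                           epsilon = 1e-6) {
    betas <- readBetaMatrix(betaPath)
    ann <- readCpGAnnotation(annotPath)
    pheno <- if (is.null(phenoPath)) NULL else readPhenotypes(phenoPath)
    MethylExperiment(betas, ann, pheno, epsilon = epsilon)
}

.sniffSep <- function(path, sep) {
    if (!is.null(sep)) return(sep)
    first <- readLines(path, n = 1L)
    if (grepl("\t", first)) "\t" else ","
}

#' Write a simulated dataset as standard input files
#'
#' Writes \code{betas.tsv}, \code{annotation.tsv}, \code{phenotypes.tsv}
#' and \code{truth.tsv} (target region plus ground-truth DMPs) under
#' \code{dir}, in the formats the package readers accept, so a simulated
#' dataset can be fed back through the full file-based pipeline.
#'
#' @param sim a \linkS4class{SimulatedDataset}
#' @param dir output directory (created if absent)
#' @return invisibly, the named vector of file paths written
#' @export
writeSimulatedDataset <- function(sim, dir) {
    stopifnot(is(sim, "SimulatedDataset"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    me <- sim@experiment
    rr <- SummarizedExperiment::rowRanges(me)

    paths <- c(betas = file.path(dir, "betas.tsv"),
               annotation = file.path(dir, "annotation.tsv"),
               phenotypes = file.path(dir, "phenotypes.tsv"),
               truth = file.path(dir, "truth.tsv"))

    b <- data.frame(probe_id = rownames(me),
                    format(betaValues(me), digits = 8, trim = TRUE),
                    check.names = FALSE)
    utils::write.table(b, paths["betas"], sep = "\t", quote = FALSE,
                       row.names = FALSE)

    ann <- data.frame(probe_id = names(rr),
                      chromosome = as.character(seqnames(rr)),
                      position = start(rr))
    utils::write.table(ann, paths["annotation"], sep = "\t", quote = FALSE,
                       row.names = FALSE)

    ph <- data.frame(sample_id = colnames(me),
                     as.data.frame(SummarizedExperiment::colData(me)))
    utils::write.table(ph, paths["phenotypes"], sep = "\t", quote = FALSE,
                       row.names = FALSE)

    truth <- data.frame(
        probe_id = rownames(me)[sim@dmpIndices],
        direction = sim@dmpDirections,
        region = formatRegion(sim@targetRegion),
        seed = sim@seed)
    utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(paths)
}
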