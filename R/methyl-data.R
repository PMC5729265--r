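#' Build a MethylExperiment from a beta matrix, annotation and phenotypes
#'
#' Aligns a beta-value matrix (CpGs in rows, samples in columns) with a CpG
#' annotation and an optional sample phenotype table, applies the
#' missing-data policy (rows containing any NA are dropped, with a
#' message), clips values into \code{(epsilon, 1 - epsilon)} and sorts rows
#' by chromosome and position.
#'
#' @param betas numeric matrix of beta values with probe IDs as rownames
#'   and sample IDs as colnames
#' @param annotation a \code{GRanges} named by probe ID (width-1 positions),
#'   or a data.frame with columns \code{probe_id}, \code{chromosome},
#'   \code{position} (1-based bp)
#' @param phenotypes optional data.frame of sample covariates; rownames (or
#'   a first column of sample IDs) must match the beta matrix columns
#' @param epsilon clipping bound applied to beta values; default
#'   \code{1e-6}
#' @return a \linkS4class{MethylExperiment}
#' @examples
#' b <- matrix(runif(12, 0.1, 0.9), 3,
#'             dimnames = list(paste0("cg", 1:3), paste0("S", 1:4)))
#' ann <- data.frame(probe_id = paste0("cg", 1:3), chromosome = "chr22",
#'                   position = c(100L, 300L, 200L))
#' me <- MethylExperiment(b, ann)
#' @export
MethylExperiment <- function(betas, annotation, phenotypes = NULL,
                             epsilon = 1e-6) {
    if (!is.matrix(betas) || !is.numeric(betas))
        stop("'betas' must be a numeric matrix")
    if (is.null(rownames(betas)) || is.null(colnames(betas)))
        stop("'betas' must carry probe IDs as rownames and sample IDs as ",
             "colnames")
    ann <- .asAnnotationGRanges(annotation)

    missing <- setdiff(rownames(betas), names(ann))
    if (length(missing) > 0)
        stop("annotation is missing ", length(missing), " probe(s), e.g. '",
             missing[1], "'")
    ann <- ann[rownames(betas)]

    drop <- rowSums(is.na(betas)) > 0
    if (any(drop)) {
        message("dropping ", sum(drop), " CpG row(s) containing missing ",
                "beta values")
        betas <- betas[!drop, , drop = FALSE]
        ann <- ann[!drop]
        if (nrow(betas) == 0L) stop("no CpG rows left after NA filtering")
    }
    betas <- pmin(pmax(betas, epsilon), 1 - epsilon)

    o <- order(as.character(seqnames(ann)), start(ann))
    betas <- betas[o, , drop = FALSE]
    ann <- ann[o]

    cd <- .alignPhenotypes(phenotypes, colnames(betas))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(beta = betas), rowRanges = ann, colData = cd)
    new("MethylExperiment", se)
}

.asAnnotationGRanges <- function(annotation) {
    if (is(annotation, "GRanges")) {
        if (is.null(names(annotation)) || anyDuplicated(names(annotation)))
            stop("annotation GRanges must have unique probe-ID names")
        return(annotation)
    }
    if (is.data.frame(annotation)) {
        need <- c("probe_id", "chromosome", "position")
        if (!all(need %in% colnames(annotation)))
            stop("annotation data.frame needs columns: ",
                 paste(need, collapse = ", "))
        if (anyDuplicated(annotation$probe_id))
            stop("annotation probe IDs must be unique")
        gr <- GRanges(annotation$chromosome,
                      IRanges(annotation$position, width = 1L))
        names(gr) <- annotation$probe_id
        return(gr)
    }
    stop("'annotation' must be a GRanges or a data.frame")
}

.alignPhenotypes <- function(phenotypes, sampleIds) {
    if (is.null(phenotypes))
        return(DataFrame(row.names = sampleIds))
    ph <- as.data.frame(phenotypes)
    if (!all(sampleIds %in% rownames(ph))) {
        # fall back to a first column of sample IDs
        if (ncol(ph) >= 1 && all(sampleIds %in% as.character(ph[[1]]))) {
            rownames(ph) <- as.character(ph[[1]])
            ph <- ph[, -1, drop = FALSE]
        } else {
            stop("phenotype table does not cover all sample IDs")
        }
    }
    DataFrame(ph[sampleIds, , drop = FALSE], row.names = sampleIds)
}

#' Beta values of a MethylExperiment
#' @param x a \linkS4class{MethylExperiment}
#' @return numeric matrix, CpGs by samples
#' @export
betaValues <- function(x) {
    stopifnot(is(x, "MethylExperiment"))
    SummarizedExperiment::assay(x, "beta")
}

#' M-values of a MethylExperiment
#' @param x a \linkS4class{MethylExperiment}
#' @param epsilon clipping bound passed to \code{\link{betaToM}}
#' @return numeric matrix of M-values, CpGs by samples
#' @export
mValues <- function(x, epsilon = 1e-6) {
    betaToM(betaValues(x), epsilon = epsilon)
}

#' CpG annotation of a MethylExperiment
#' @param x a \linkS4class{MethylExperiment}
#' @return a named \code{GRanges} of width-1 probe positions, in row order
#' @export
cpgAnnotation <- function(x) {
    stopifnot(is(x, "MethylExperiment"))
    SummarizedExperiment::rowRanges(x)
}

setMethod("show", "MethylExperiment", function(object) {
    cat("MethylExperiment with", nrow(object), "CpGs and", ncol(object),
        "samples\n")
    chr <- unique(as.character(seqnames(SummarizedExperiment::rowRanges(object))))
    cat("  chromosomes:", paste(chr, collapse = ", "), "\n")
    cd <- colnames(SummarizedExperiment::colData(object))
    if (length(cd))
        cat("  phenotypes:", paste(cd, collapse = ", "), "\n")
})
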