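#' Parse a genomic-region string
#'
#' Accepts \code{"chr17:37,700,000-38,000,000"} style strings (1-based,
#' inclusive on both ends; thousands separators tolerated and stripped).
#' A \code{GRanges} of length 1 passes through unchanged.
#'
#' @param region character scalar or \code{GRanges} of length 1
#' @return a \code{GRanges} of length 1
#' @examples
#' parseRegion("chr17:37,700,000-38,000,000")
#' @export
parseRegion <- function(region) {
    if (is(region, "GRanges")) {
        if (length(region) != 1L) stop("region must be a single range")
        return(region)
    }
    if (!is.character(region) || length(region) != 1L)
        stop("region must be a single string like 'chr1:100-200'")
    s <- gsub(",", "", region, fixed = TRUE)
    m <- regmatches(s, regexec("^([^:]+):([0-9]+)-([0-9]+)$", s))[[1]]
    if (length(m) != 4L)
        stop("cannot parse region string '", region,
             "'; expected 'chrom:start-end'")
    start <- as.numeric(m[3]); end <- as.numeric(m[4])
    if (start > end) stop("region start must not exceed end")
    GRanges(m[2], IRanges(start, end))
}

#' Format a GRanges region back to a string
#' @param region a \code{GRanges} of length 1
#' @return character scalar \code{"chrom:start-end"}
#' @export
formatRegion <- function(region) {
    stopifnot(is(region, "GRanges"), length(region) == 1L)
    sprintf("%s:%d-%d", as.character(seqnames(region)), start(region),
            end(region))
}

# row indices (in annotation order) of probes inside a 1-based inclusive
# region; errors if the region holds no probes
.regionIndices <- function(ann, region) {
    region <- parseRegion(region)
    chr <- as.character(seqnames(ann))
    pos <- start(ann)
    idx <- which(chr == as.character(seqnames(region)) &
                 pos >= start(region) & pos <= end(region))
    if (length(idx) == 0L)
        stop("empty region: no annotated CpGs in ", formatRegion(region))
    idx[order(pos[idx])]
}

#' Extract the M-value submatrix of a target region
#'
#' Resolves a region to the probes it contains (chromosome match and
#' 1-based inclusive position overlap), in genomic order, and returns
#' their M-values.
#'
#' @param x a \linkS4class{MethylExperiment}
#' @param region region string or \code{GRanges} of length 1
#' @param minCpgs minimum CpG count for an analyzable region (default 3)
#' @param epsilon clipping bound for the beta-to-M transform
#' @return list with \code{mvalues} (k CpGs by n samples matrix),
#'   \code{index} (row indices into \code{x}), \code{k}, and
#'   \code{region} (the parsed \code{GRanges})
#' @export
selectRegion <- function(x, region, minCpgs = 3L, epsilon = 1e-6) {
    stopifnot(is(x, "MethylExperiment"))
    region <- parseRegion(region)
    idx <- .regionIndices(cpgAnnotation(x), region)
    if (length(idx) < minCpgs)
        stop("region too small: ", length(idx), " CpG(s) in ",
             formatRegion(region), " but at least ", minCpgs,
             " are required")
    list(mvalues = mValues(x, epsilon = epsilon)[idx, , drop = FALSE],
         index = idx, k = length(idx), region = region)
}
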