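#' Sample random contiguous CpG windows of fixed probe count
#'
#' Enumerates every run of exactly \code{k} consecutive annotated CpGs
#' (genomic order within one chromosome; windows never cross chromosome
#' boundaries), removes windows overlapping an excluded region, and draws
#' \code{b} of them uniformly at random. Sampling is without replacement
#' while \code{b} does not exceed the number of eligible windows, and with
#' replacement (with a message) otherwise; set \code{replace = TRUE} to
#' force independent draws.
#'
#' @param ann a named \code{GRanges} of probe positions in row order of
#'   the methylation matrix (as from \code{\link{cpgAnnotation}})
#' @param k window CpG count
#' @param b number of windows to draw
#' @param exclude optional \code{GRanges} region; windows whose genomic
#'   span overlaps it are rejected
#' @param seed integer RNG seed; \code{NULL} uses the current state
#' @param replace logical or \code{NULL} (auto, see above)
#' @return list of integer vectors, each of length k, indexing rows of
#'   the annotation
#' @export
sampleRandomWindows <- function(ann, k, b, exclude = NULL, seed = NULL,
                                replace = NULL) {
    stopifnot(is(ann, "GRanges"), k >= 1, b >= 1)
    if (!is.null(seed)) set.seed(as.integer(seed))
    starts <- .eligibleWindowStarts(ann, k, exclude)
    if (length(starts) == 0L)
        stop("no eligible window of ", k, " consecutive CpGs exists",
             if (!is.null(exclude)) " outside the excluded region")
    if (is.null(replace)) {
        replace <- b > length(starts)
        if (replace)
            message("requested ", b, " windows but only ", length(starts),
                    " are eligible; sampling with replacement")
    }
    if (!replace && b > length(starts))
        stop("b exceeds the number of eligible windows; use replace = TRUE")
    drawn <- starts[sample.int(length(starts), b, replace = replace)]
    lapply(drawn, function(s) seq.int(s, s + k - 1L))
}

# start indices (into annotation row order) of every eligible k-window
.eligibleWindowStarts <- function(ann, k, exclude = NULL) {
    chr <- as.character(seqnames(ann))
    pos <- start(ann)
    if (is.unsorted(order(chr, pos)))
        stop("annotation must be sorted by chromosome and position")
    starts <- integer(0)
    for (c in unique(chr)) {
        idx <- which(chr == c)
        if (any(diff(pos[idx]) < 0))
            stop("annotation positions must be sorted within chromosomes")
        if (length(idx) < k) next
        s <- idx[seq_len(length(idx) - k + 1L)]
        if (!is.null(exclude)) {
            exclude <- parseRegion(exclude)
            if (as.character(seqnames(exclude)) == c) {
                wStart <- pos[s]
                wEnd <- pos[s + k - 1L]
                keep <- wEnd < start(exclude) | wStart > end(exclude)
                s <- s[keep]
            }
        }
        starts <- c(starts, s)
    }
    starts
}

#' Empirical random-region null for the target region's R-squared
#'
#' Answers the question: how unusual is the association observed in the
#' target region compared with the rest of the genome? The target R-squared
#' is compared against the R-squared of \code{nRegions} random regions with
#' the same number of CpGs (contiguous probe windows), fitted with the
#' identical design and code path, and the exceedance probability
#' \eqn{p = (1 + \#\{R^2_{null} \ge R^2_{obs}\}) / (nRegions + 1)}
#' is returned. Windows overlapping the target are excluded by default so
#' the null is not contaminated by the tested signal.
#'
#' @param x a \linkS4class{MethylExperiment}
#' @param design a \linkS4class{DesignMatrix}
#' @param region target region (string or \code{GRanges} of length 1)
#' @param nRegions number of random windows (default 10000)
#' @param seed integer RNG seed; \code{NULL} uses the current state
#' @param excludeTarget logical; reject windows overlapping the target
#' @param minCpgs minimum CpG count for the target region
#' @param scale,r2Denominator passed to \code{\link{fitRDA}}
#' @return a \linkS4class{RegionalNull}
#' @export
regionR2Null <- function(x, design, region, nRegions = 10000L,
                         seed = NULL, excludeTarget = TRUE, minCpgs = 3L,
                         scale = FALSE,
                         r2Denominator = c("total", "conditioned")) {
    r2Denominator <- match.arg(r2Denominator)
    nRegions <- as.integer(nRegions)
    if (nRegions < 1L) stop("'nRegions' must be at least 1")
    sel <- selectRegion(x, region, minCpgs = minCpgs)
    m <- mValues(x)
    fitObs <- fitRDA(sel$mvalues, design, scale = scale,
                     r2Denominator = r2Denominator, components = FALSE)

    windows <- sampleRandomWindows(
        cpgAnnotation(x), k = sel$k, b = nRegions,
        exclude = if (excludeTarget) sel$region else NULL,
        seed = seed, replace = TRUE)
    r2Null <- vapply(windows, function(w) {
        fitRDA(m[w, , drop = FALSE], design, scale = scale,
               r2Denominator = r2Denominator, components = FALSE)@r2
    }, numeric(1))

    p <- (1 + sum(r2Null >= fitObs@r2)) / (nRegions + 1)
    new("RegionalNull", r2Obs = fitObs@r2, r2Null = r2Null, pValue = p,
        nRegions = nRegions, k = as.integer(sel$k), region = sel$region,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

setMethod("pValue", "RegionalNull", function(object, ...) object@pValue)
setMethod("nullDraws", "RegionalNull", function(object, ...) object@r2Null)
setMethod("observedStat", "RegionalNull", function(object, ...)
    object@r2Obs)
setMethod("explainedR2", "RegionalNull", function(object, ...)
    object@r2Obs)

setMethod("show", "RegionalNull", function(object) {
    cat("RegionalNull:", object@nRegions, "random windows of",
        object@k, "CpGs\n")
    cat(sprintf("  target %s: R2 = %.4f\n", formatRegion(object@region),
                object@r2Obs))
    cat(sprintf("  exceedance p = %.4g (null mean R2 = %.4f)\n",
                object@pValue, mean(object@r2Null)))
})
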