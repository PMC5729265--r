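#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges
NULL

#' MethylExperiment: beta-value methylation data with CpG coordinates
#'
#' A \linkS4class{RangedSummarizedExperiment} holding one assay
#' (\code{"beta"}) of methylation proportions in the open interval (0, 1),
#' with per-CpG genomic positions as \code{rowRanges} (width-1 ranges named
#' by probe ID, sorted by chromosome and position) and sample phenotypes as
#' \code{colData}. Built with \code{\link{MethylExperiment}}.
#'
#' @seealso \code{\link{betaValues}}, \code{\link{mValues}},
#'   \code{\link{selectRegion}}
#' @export
setClass("MethylExperiment", contains = "RangedSummarizedExperiment")

setValidity("MethylExperiment", function(object) {
    msg <- NULL
    if (!"beta" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- SummarizedExperiment::assay(object, "beta")
        if (anyNA(b))
            msg <- c(msg, "beta values must not contain NA")
        else if (any(b <= 0 | b >= 1))
            msg <- c(msg, "beta values must lie strictly in (0, 1)")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "probe IDs (rownames) must be present and unique")
    rr <- SummarizedExperiment::rowRanges(object)
    if (length(rr) > 1L) {
        chr <- as.character(seqnames(rr))
        pos <- start(rr)
        o <- order(chr, pos)
        if (!identical(o, seq_along(rr)))
            msg <- c(msg, "rows must be sorted by chromosome and position")
    }
    if (is.null(msg)) TRUE else msg
})

#' Centered design matrix for redundancy analysis
#'
#' Holds the mean-centered predictor columns (outcomes of interest, slot
#' \code{predictors}, n samples by m columns) and an optional block of
#' conditioning covariates to be partialled out (slot \code{conditioning},
#' n by q). Rows align with the samples of the methylation matrix. Built by
#' \code{\link{encodeDesign}}.
#'
#' @slot predictors centered numeric matrix, samples by predictors
#' @slot conditioning centered numeric matrix, samples by covariates
#'   (zero columns when no conditioning is requested)
#' @export
setClass("DesignMatrix",
         representation(predictors = "matrix", conditioning = "matrix"))

setValidity("DesignMatrix", function(object) {
    msg <- NULL
    X <- object@predictors
    Z <- object@conditioning
    if (!is.numeric(X)) msg <- c(msg, "predictors must be numeric")
    if (nrow(Z) != nrow(X))
        msg <- c(msg, "conditioning rows must match predictor rows")
    if (ncol(X) > 0 && max(abs(colMeans(X))) > 1e-8)
        msg <- c(msg, "predictor columns must be mean-centered")
    if (ncol(Z) > 0 && max(abs(colMeans(Z))) > 1e-8)
        msg <- c(msg, "conditioning columns must be mean-centered")
    if (ncol(X) > 0 && qr(X)$rank < ncol(X))
        msg <- c(msg, "predictor columns must be linearly independent")
    if (is.null(msg)) TRUE else msg
})

#' Fitted redundancy analysis of a region
#'
#' Result of \code{\link{fitRDA}}: the variance decomposition of the
#' centered M-value matrix of a region into conditioned, fitted
#' (constrained) and residual sums of squares, the R-squared, and the RDA
#' components (PCA of the fitted matrix).
#'
#' @slot r2 proportion of variance explained by the predictors
#' @slot ssTotal,ssFitted,ssResidual,ssConditioned sums of squares of the
#'   centered outcome and its decomposition
#' @slot sampleScores n-by-c matrix of sample coordinates
#' @slot cpgLoadings k-by-c matrix of CpG coordinates
#' @slot eigenvalues c component eigenvalues (nonincreasing)
#' @slot n,k,m,q sample, CpG, predictor and conditioning-covariate counts
#' @slot r2Denominator \code{"total"} or \code{"conditioned"}; which
#'   variance the R-squared is referred to
#' @export
setClass("RDAFit",
         representation(r2 = "numeric", ssTotal = "numeric",
                        ssFitted = "numeric", ssResidual = "numeric",
                        ssConditioned = "numeric",
                        sampleScores = "matrix", cpgLoadings = "matrix",
                        eigenvalues = "numeric",
                        n = "integer", k = "integer", m = "integer",
                        q = "integer", r2Denominator = "character"))

setValidity("RDAFit", function(object) {
    msg <- NULL
    ss <- c(object@ssConditioned, object@ssFitted, object@ssResidual)
    if (any(ss < -1e-8)) msg <- c(msg, "sums of squares must be nonnegative")
    if (object@ssTotal > 0 &&
        abs(sum(ss) - object@ssTotal) > 1e-8 * object@ssTotal)
        msg <- c(msg, "sum-of-squares decomposition must conserve ssTotal")
    if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12)
        msg <- c(msg, "r2 must lie in [0, 1]")
    c <- length(object@eigenvalues)
    if (c > min(object@m, object@k, object@n - 1L))
        msg <- c(msg, "component count exceeds min(m, k, n - 1)")
    if (c > 1 && any(diff(object@eigenvalues) > 1e-8))
        msg <- c(msg, "eigenvalues must be nonincreasing")
    if (is.null(msg)) TRUE else msg
})

#' Permutation test of a fitted RDA
#'
#' Result of \code{\link{rdaPermTest}}: the observed pseudo-F, the null
#' pseudo-F draws obtained by permuting the sample-to-predictor pairing,
#' and the add-one permutation p-value.
#'
#' @slot fObs observed pseudo-F
#' @slot fNull null pseudo-F draws (length \code{nperm})
#' @slot pValue (1 + exceedances) / (nperm + 1)
#' @slot nperm permutation count
#' @slot seed RNG seed used (NA when none was set)
#' @slot fit the \linkS4class{RDAFit} of the observed data
#' @export
setClass("RDAPermutation",
         representation(fObs = "numeric", fNull = "numeric",
                        pValue = "numeric", nperm = "integer",
                        seed = "integer", fit = "RDAFit"))

setValidity("RDAPermutation", function(object) {
    msg <- NULL
    if (length(object@fNull) != object@nperm)
        msg <- c(msg, "fNull length must equal nperm")
    lo <- 1 / (object@nperm + 1)
    if (object@pValue < lo - 1e-12 || object@pValue > 1 + 1e-12)
        msg <- c(msg, "pValue must lie in [1/(nperm+1), 1]")
    if (is.null(msg)) TRUE else msg
})

#' Empirical random-region null for a region's R-squared
#'
#' Result of \code{\link{regionR2Null}}: the target-region R-squared
#' compared against random contiguous windows of the same CpG count drawn
#' genome-wide, with the add-one exceedance p-value.
#'
#' @slot r2Obs target-region R-squared
#' @slot r2Null R-squared of each sampled random window
#' @slot pValue (1 + exceedances) / (nRegions + 1)
#' @slot nRegions number of random windows
#' @slot k CpG count shared by the target and every window
#' @slot region the target region (GRanges of length 1)
#' @slot seed RNG seed used (NA when none was set)
#' @export
setClass("RegionalNull",
         representation(r2Obs = "numeric", r2Null = "numeric",
                        pValue = "numeric", nRegions = "integer",
                        k = "integer", region = "GRanges", seed = "integer"))

setValidity("RegionalNull", function(object) {
    msg <- NULL
    if (length(object@r2Null) != object@nRegions)
        msg <- c(msg, "r2Null length must equal nRegions")
    if (any(object@r2Null < -1e-12 | object@r2Null > 1 + 1e-12))
        msg <- c(msg, "null R-squared values must lie in [0, 1]")
    lo <- 1 / (object@nRegions + 1)
    if (object@pValue < lo - 1e-12 || object@pValue > 1 + 1e-12)
        msg <- c(msg, "pValue must lie in [1/(nRegions+1), 1]")
    if (is.null(msg)) TRUE else msg
})

#' Per-CpG Beta-distribution parameters for the simulator
#'
#' Shape pairs (a_j, b_j) of independent Beta distributions, one per CpG,
#' together with probe positions on a single pseudo-chromosome. Built by
#' \code{\link{defaultCpGParameters}} or \code{\link{fitCpGParameters}}.
#'
#' @slot shape1,shape2 positive Beta shape parameters, one pair per CpG
#' @slot positions strictly increasing 1-based bp positions
#' @slot chromosome chromosome name carried by simulated annotation
#' @slot chromLength pseudo-chromosome length in bp
#' @export
setClass("CpGParameterSet",
         representation(shape1 = "numeric", shape2 = "numeric",
                        positions = "integer", chromosome = "character",
                        chromLength = "numeric"))

setValidity("CpGParameterSet", function(object) {
    msg <- NULL
    n <- length(object@shape1)
    if (length(object@shape2) != n || length(object@positions) != n)
        msg <- c(msg, "shape1, shape2 and positions must have equal length")
    if (any(object@shape1 <= 0) || any(object@shape2 <= 0))
        msg <- c(msg, "Beta shapes must be strictly positive")
    if (n > 1 && any(diff(object@positions) <= 0))
        msg <- c(msg, "positions must be strictly increasing")
    if (n > 0 && object@positions[n] > object@chromLength)
        msg <- c(msg, "positions must not exceed chromLength")
    if (is.null(msg)) TRUE else msg
})

#' One cell of the simulation grid
#'
#' Describes a simulated two-group study: region width in bp, total sample
#' size (split into two equal groups), the difference in mean beta value
#' injected at differentially methylated probes (DMPs), the fraction of
#' region CpGs made DMPs, and the number of replicate datasets.
#'
#' @slot regionWidth target DMR width in bp
#' @slot nSamples total samples (even, split half/half)
#' @slot effect difference in mean beta at DMPs (0 simulates the null)
#' @slot dmpFraction fraction of region CpGs turned into DMPs
#' @slot nReplicates datasets to simulate for this cell
#' @export
setClass("ScenarioConfig",
         representation(regionWidth = "numeric", nSamples = "integer",
                        effect = "numeric", dmpFraction = "numeric",
                        nReplicates = "integer"))

setValidity("ScenarioConfig", function(object) {
    msg <- NULL
    if (object@regionWidth <= 0) msg <- c(msg, "regionWidth must be positive")
    if (object@nSamples < 4L || object@nSamples %% 2L != 0L)
        msg <- c(msg, "nSamples must be even and at least 4")
    if (object@effect < 0 || object@effect >= 1)
        msg <- c(msg, "effect must lie in [0, 1)")
    if (object@dmpFraction <= 0 || object@dmpFraction > 1)
        msg <- c(msg, "dmpFraction must lie in (0, 1]")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' A simulated methylation dataset with ground truth
#'
#' Output of \code{\link{simulateDataset}}: the simulated
#' \linkS4class{MethylExperiment} (with a two-level \code{group} column in
#' \code{colData}), the placed target region, the ground-truth DMP row
#' indices and shift directions, and full provenance (config, replicate
#' id, seed).
#'
#' @slot experiment the simulated \linkS4class{MethylExperiment}
#' @slot targetRegion GRanges of length 1
#' @slot dmpIndices row indices of the injected DMPs
#' @slot dmpDirections +1/-1 shift direction per DMP
#' @slot config the \linkS4class{ScenarioConfig} used
#' @slot replicateId replicate number within the scenario
#' @slot seed RNG seed used for this dataset
#' @export
setClass("SimulatedDataset",
         representation(experiment = "MethylExperiment",
                        targetRegion = "GRanges",
                        dmpIndices = "integer", dmpDirections = "integer",
                        config = "ScenarioConfig", replicateId = "integer",
                        seed = "integer"))

setValidity("SimulatedDataset", function(object) {
    msg <- NULL
    rr <- SummarizedExperiment::rowRanges(object@experiment)
    idx <- object@dmpIndices
    if (length(idx) > 0) {
        pos <- start(rr)[idx]
        chr <- as.character(seqnames(rr))[idx]
        inside <- chr == as.character(seqnames(object@targetRegion)) &
            pos >= start(object@targetRegion) &
            pos <= end(object@targetRegion)
        if (!all(inside))
            msg <- c(msg, "all DMP indices must lie inside the target region")
    }
    if (length(object@dmpDirections) != length(idx))
        msg <- c(msg, "dmpDirections must match dmpIndices in length")
    if (is.null(msg)) TRUE else msg
})
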