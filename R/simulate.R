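#' Default per-CpG Beta parameters emulating a 450K chromosome 22
#'
#' Builds a synthetic stand-in for per-CpG Beta-distribution parameters
#' estimated from a real cohort: 8432 CpGs on a 51 Mb pseudo-chromosome,
#' with per-CpG means drawn from a three-component mixture reproducing the
#' bimodal marginal of array methylation (hypomethylated: mean ~
#' Beta(2, 18), weight 0.45; hypermethylated: mean ~ Beta(18, 2), weight
#' 0.40; intermediate: mean ~ Beta(5, 5), weight 0.15) and per-CpG
#' precision \eqn{\nu = a + b} log-uniform on \[50, 500\]. Positions are
#' uniform over the pseudo-chromosome, sorted and unique.
#'
#' @param seed integer RNG seed
#' @param nCpgs number of CpGs (default 8432)
#' @param chromosome chromosome name for the simulated annotation
#' @param chromLength pseudo-chromosome length in bp (default 51e6)
#' @return a \linkS4class{CpGParameterSet}
#' @export
defaultCpGParameters <- function(seed = 1L, nCpgs = 8432L,
                                 chromosome = "chr22",
                                 chromLength = 51e6) {
    set.seed(as.integer(seed))
    nCpgs <- as.integer(nCpgs)
    comp <- sample.int(3L, nCpgs, replace = TRUE,
                       prob = c(0.45, 0.40, 0.15))
    mu <- numeric(nCpgs)
    mu[comp == 1L] <- stats::rbeta(sum(comp == 1L), 2, 18)
    mu[comp == 2L] <- stats::rbeta(sum(comp == 2L), 18, 2)
    mu[comp == 3L] <- stats::rbeta(sum(comp == 3L), 5, 5)
    mu <- pmin(pmax(mu, 0.01), 0.99)
    nu <- exp(stats::runif(nCpgs, log(50), log(500)))
    pos <- sort(sample.int(as.integer(chromLength), nCpgs))
    new("CpGParameterSet", shape1 = mu * nu, shape2 = (1 - mu) * nu,
        positions = as.integer(pos), chromosome = chromosome,
        chromLength = chromLength)
}

#' Fit per-CpG Beta parameters from reference beta values
#'
#' Method-of-moments fit per CpG: with sample mean \eqn{\hat\mu} and
#' variance \eqn{\hat v}, the precision is
#' \eqn{\hat\nu = \hat\mu(1 - \hat\mu)/\hat v - 1}, floored at
#' \code{nuFloor} (with a warning for floored CpGs, including
#' zero-variance ones), and \eqn{a = \hat\mu\hat\nu},
#' \eqn{b = (1 - \hat\mu)\hat\nu}.
#'
#' @param betas numeric matrix of beta values (CpGs by samples, at least
#'   3 samples) or a \linkS4class{MethylExperiment}
#' @param positions optional bp positions (taken from the annotation when
#'   \code{betas} is a MethylExperiment; defaults to a unit grid)
#' @param chromosome,chromLength annotation metadata for the result
#' @param nuFloor lower bound on the precision (default 2)
#' @return a \linkS4class{CpGParameterSet}
#' @export
fitCpGParameters <- function(betas, positions = NULL,
                             chromosome = "chr22", chromLength = NULL,
                             nuFloor = 2) {
    if (is(betas, "MethylExperiment")) {
        ann <- cpgAnnotation(betas)
        positions <- start(ann)
        chromosome <- as.character(seqnames(ann))[1]
        betas <- betaValues(betas)
    }
    stopifnot(is.matrix(betas), is.numeric(betas))
    if (ncol(betas) < 3) stop("at least 3 samples per CpG are required")
    mu <- rowMeans(betas)
    v <- apply(betas, 1, stats::var)
    nu <- ifelse(v > 0, mu * (1 - mu) / v - 1, -Inf)
    floored <- nu < nuFloor
    if (any(floored))
        warning(sum(floored), " CpG(s) with precision below ", nuFloor,
                " (or zero variance); precision floored")
    nu[floored] <- nuFloor
    mu <- pmin(pmax(mu, 0.005), 0.995)
    if (is.null(positions)) positions <- seq_len(nrow(betas)) * 1000L
    if (is.null(chromLength)) chromLength <- max(positions)
    new("CpGParameterSet", shape1 = mu * nu, shape2 = (1 - mu) * nu,
        positions = as.integer(positions), chromosome = chromosome,
        chromLength = as.numeric(chromLength))
}

#' Construct one simulation scenario
#'
#' @param regionWidth target DMR width in bp
#' @param nSamples total samples (even; split into two equal groups)
#' @param effect difference in mean beta at DMPs (0 gives null data)
#' @param dmpFraction fraction of region CpGs made differentially
#'   methylated
#' @param nReplicates datasets per cell (default 200)
#' @return a \linkS4class{ScenarioConfig}
#' @export
scenarioConfig <- function(regionWidth, nSamples, effect, dmpFraction,
                           nReplicates = 200L) {
    new("ScenarioConfig", regionWidth = as.numeric(regionWidth),
        nSamples = as.integer(nSamples), effect = as.numeric(effect),
        dmpFraction = as.numeric(dmpFraction),
        nReplicates = as.integer(nReplicates))
}

setMethod("show", "ScenarioConfig", function(object) {
    cat(sprintf(
        "ScenarioConfig: width %g bp, n = %d, effect %.2f, DMP fraction %.2f, %d replicates\n",
        object@regionWidth, object@nSamples, object@effect,
        object@dmpFraction, object@nReplicates))
})

#' The default benchmark grid
#'
#' The full factorial grid of the benchmark study: region widths 500, 300,
#' 100 and 50 kb; sample sizes 10, 40 and 100; mean-methylation
#' differences 0.3, 0.1 and 0.05; DMP fractions 30\% and 10\%; 200
#' replicate datasets per cell (72 cells).
#'
#' @param widths,nSamples,effects,dmpFractions,nReplicates grid axes;
#'   defaults as above
#' @return data.frame with one scenario per row (columns
#'   \code{regionWidth}, \code{nSamples}, \code{effect},
#'   \code{dmpFraction}, \code{nReplicates})
#' @export
scenarioGrid <- function(widths = c(5e5, 3e5, 1e5, 5e4),
                         nSamples = c(10L, 40L, 100L),
                         effects = c(0.3, 0.1, 0.05),
                         dmpFractions = c(0.30, 0.10),
                         nReplicates = 200L) {
    g <- expand.grid(regionWidth = widths, nSamples = nSamples,
                     effect = effects, dmpFraction = dmpFractions,
                     KEEP.OUT.ATTRS = FALSE)
    g$nReplicates <- as.integer(nReplicates)
    g
}

#' Simulate one methylation dataset with an injected DMR
#'
#' Places a target region of the configured width uniformly at random on
#' the pseudo-chromosome (anchored at an annotated CpG so the region is
#' never empty), selects the configured fraction of its CpGs as DMPs
#' (uniformly without replacement; count rounded half up), and draws beta
#' values for two equal groups from independent per-CpG Beta
#' distributions. Group 2 differs from group 1 only at the DMPs, where the
#' Beta mean is shifted by \code{effect} (direction per DMP per
#' \code{direction}; a shift that would leave \[0.02, 0.98\] flips sign
#' when feasible and is clamped otherwise) with the per-CpG precision
#' \eqn{\nu = a + b} preserved.
#'
#' @param params a \linkS4class{CpGParameterSet}
#' @param config a \linkS4class{ScenarioConfig} (or a one-row data.frame
#'   from \code{\link{scenarioGrid}})
#' @param seed integer RNG seed for this replicate
#' @param replicateId replicate number recorded in the result
#' @param direction DMP shift direction: \code{"random"} (default; each
#'   DMP goes up or down with probability 1/2), \code{"up"} or
#'   \code{"down"}
#' @param minCpgs minimum CpGs a target placement must contain
#' @return a \linkS4class{SimulatedDataset}
#' @export
simulateDataset <- function(params, config, seed = 1L, replicateId = 1L,
                            direction = c("random", "up", "down"),
                            minCpgs = 3L) {
    direction <- match.arg(direction)
    stopifnot(is(params, "CpGParameterSet"))
    config <- .asScenarioConfig(config)
    set.seed(as.integer(seed))

    pos <- params@positions
    nC <- length(pos)
    width <- config@regionWidth
    # anchor placements at annotated CpGs; eligible if the window stays on
    # the chromosome and holds at least minCpgs probes
    last <- findInterval(pos + width - 1, pos)
    nIn <- last - seq_len(nC) + 1L
    eligible <- which(pos + width - 1 <= params@chromLength &
                      nIn >= minCpgs)
    if (length(eligible) == 0L)
        stop("no placement of a ", width, " bp region holds ", minCpgs,
             " CpGs")
    a0 <- eligible[sample.int(length(eligible), 1L)]
    region <- GRanges(params@chromosome,
                      IRanges(pos[a0], pos[a0] + width - 1))
    inRegion <- seq.int(a0, last[a0])
    k <- length(inRegion)

    nDmp <- floor(config@dmpFraction * k + 0.5)   # round half up
    dmp <- sort(inRegion[sample.int(k, nDmp)])

    n <- config@nSamples
    n1 <- n %/% 2L
    a <- params@shape1; b <- params@shape2
    betas <- matrix(stats::rbeta(nC * n, a, b), nrow = nC, ncol = n)

    dirs <- integer(0)
    if (nDmp > 0 && config@effect > 0) {
        mu <- a[dmp] / (a[dmp] + b[dmp])
        nu <- a[dmp] + b[dmp]
        dirs <- switch(direction,
                       random = sample(c(-1L, 1L), nDmp, replace = TRUE),
                       up = rep(1L, nDmp),
                       down = rep(-1L, nDmp))
        d <- config@effect
        # flip infeasible directions; clamp what cannot be fixed by a flip
        up <- dirs == 1L
        flipDown <- up & (mu + d > 0.98) & (mu - d >= 0.02)
        flipUp <- !up & (mu - d < 0.02) & (mu + d <= 0.98)
        dirs[flipDown] <- -1L
        dirs[flipUp] <- 1L
        mu2 <- pmin(pmax(mu + dirs * d, 0.02), 0.98)
        nClamped <- sum(abs(mu2 - mu) < d - 1e-12)
        if (nClamped > 0)
            message(nClamped, " DMP mean shift(s) clamped to [0.02, 0.98]")
        g2 <- (n1 + 1L):n
        betas[dmp, g2] <- stats::rbeta(nDmp * length(g2), mu2 * nu,
                                       (1 - mu2) * nu)
    } else if (nDmp > 0) {
        dirs <- rep(0L, nDmp)
    }

    probeIds <- sprintf("cg%07d", seq_len(nC))
    sampleIds <- sprintf("S%03d", seq_len(n))
    dimnames(betas) <- list(probeIds, sampleIds)
    ann <- GRanges(params@chromosome, IRanges(pos, width = 1L))
    names(ann) <- probeIds
    pheno <- data.frame(group = rep(c("g1", "g2"), c(n1, n - n1)),
                        row.names = sampleIds)
    me <- MethylExperiment(betas, ann, pheno)

    new("SimulatedDataset", experiment = me, targetRegion = region,
        dmpIndices = as.integer(dmp), dmpDirections = dirs,
        config = config, replicateId = as.integer(replicateId),
        seed = as.integer(seed))
}

.asScenarioConfig <- function(config) {
    if (is(config, "ScenarioConfig")) return(config)
    if (is.data.frame(config) && nrow(config) == 1L)
        return(scenarioConfig(config$regionWidth, config$nSamples,
                              config$effect, config$dmpFraction,
                              config$nReplicates))
    stop("'config' must be a ScenarioConfig or a one-row scenario ",
         "data.frame")
}

setMethod("show", "SimulatedDataset", function(object) {
    cat("SimulatedDataset: replicate", object@replicateId, "(seed",
        paste0(object@seed, ")"), "\n")
    cat("  target", formatRegion(object@targetRegion), "with",
        length(object@dmpIndices), "DMP(s)\n")
    show(object@config)
})

# deterministic per-(scenario, replicate) seed below 2^31, derived from a
# master seed so cells can be rerun independently
.deriveSeed <- function(master, scenario, replicate, stream = 0L) {
    s <- (as.numeric(master) * 2654435761 + scenario * 40503 +
          replicate * 9973 + stream * 7919) %% 2147483629
    as.integer(s) + 1L
}
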