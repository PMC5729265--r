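#' Run the RDA test over a simulation grid
#'
#' For every scenario and replicate this simulates a dataset, runs the
#' permutation test on the target region, and (when
#' \code{nullRegions = TRUE}) additionally tests a randomly placed
#' signal-free window with the same CpG count, giving the material for
#' power and type-I-error estimation. Seeds follow a fixed hierarchy
#' (master seed, scenario, replicate) so any cell can be reproduced
#' independently.
#'
#' @param params a \linkS4class{CpGParameterSet}
#' @param grid data.frame of scenarios (as from \code{\link{scenarioGrid}})
#'   or list of \linkS4class{ScenarioConfig}
#' @param bPerm permutations per test (default 10000)
#' @param masterSeed master RNG seed
#' @param nullRegions also test one signal-free random window per
#'   replicate
#' @param direction DMP shift direction policy, see
#'   \code{\link{simulateDataset}}
#' @param verbose print one line per scenario
#' @return data.frame with one row per test: scenario index, scenario
#'   parameters, replicate, \code{type} ("target" or "null"), \code{k},
#'   \code{r2}, \code{f}, \code{p}, \code{seed}
#' @export
runGrid <- function(params, grid, bPerm = 10000L, masterSeed = 1L,
                    nullRegions = TRUE, direction = "random",
                    verbose = FALSE) {
    if (is.list(grid) && !is.data.frame(grid))
        grid <- do.call(rbind, lapply(grid, function(s)
            data.frame(regionWidth = s@regionWidth, nSamples = s@nSamples,
                       effect = s@effect, dmpFraction = s@dmpFraction,
                       nReplicates = s@nReplicates)))
    rows <- vector("list", nrow(grid))
    for (s in seq_len(nrow(grid))) {
        cfg <- grid[s, , drop = FALSE]
        if (verbose)
            message(sprintf(
                "scenario %d/%d: width %g, n %d, effect %g, fraction %g",
                s, nrow(grid), cfg$regionWidth, cfg$nSamples, cfg$effect,
                cfg$dmpFraction))
        reps <- lapply(seq_len(cfg$nReplicates), function(r) {
            .benchmarkReplicate(params, cfg, s, r, bPerm, masterSeed,
                                nullRegions, direction)
        })
        rows[[s]] <- do.call(rbind, reps)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

.benchmarkReplicate <- function(params, cfg, s, r, bPerm, masterSeed,
                                nullRegions, direction) {
    simSeed <- .deriveSeed(masterSeed, s, r, 0L)
    sim <- simulateDataset(params, cfg, seed = simSeed, replicateId = r,
                           direction = direction)
    me <- sim@experiment
    design <- encodeDesign(SummarizedExperiment::colData(me), "group")
    sel <- selectRegion(me, sim@targetRegion)

    permSeed <- .deriveSeed(masterSeed, s, r, 1L)
    pt <- rdaPermTest(sel$mvalues, design, nperm = bPerm, seed = permSeed)
    base <- data.frame(scenario = s, regionWidth = cfg$regionWidth,
                       nSamples = cfg$nSamples, effect = cfg$effect,
                       dmpFraction = cfg$dmpFraction, replicate = r)
    out <- cbind(base, data.frame(type = "target", k = sel$k,
                                  r2 = pt@fit@r2, f = pt@fObs,
                                  p = pt@pValue, seed = simSeed))
    if (nullRegions) {
        nullSeed <- .deriveSeed(masterSeed, s, r, 2L)
        w <- sampleRandomWindows(cpgAnnotation(me), k = sel$k, b = 1L,
                                 exclude = sim@targetRegion,
                                 seed = nullSeed)[[1]]
        yNull <- mValues(me)[w, , drop = FALSE]
        ptN <- rdaPermTest(yNull, design, nperm = bPerm,
                           seed = .deriveSeed(masterSeed, s, r, 3L))
        out <- rbind(out,
                     cbind(base, data.frame(type = "null", k = sel$k,
                                            r2 = ptN@fit@r2, f = ptN@fObs,
                                            p = ptN@pValue,
                                            seed = nullSeed)))
    }
    out
}

#' Summarise benchmark results into power and type-I error
#'
#' @param results data.frame from \code{\link{runGrid}}
#' @param alpha significance level (default 0.05)
#' @return data.frame with one row per scenario: \code{power} (target
#'   rejection rate), \code{typeIError} (null-region rejection rate, NA
#'   when no null rows exist), and mean/sd of the R-squared for target and
#'   null regions
#' @export
evaluatePerformance <- function(results, alpha = 0.05) {
    stopifnot(is.data.frame(results),
              all(c("scenario", "type", "r2", "p") %in% colnames(results)))
    if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
    out <- lapply(split(results, results$scenario), function(d) {
        tg <- d[d$type == "target", ]
        nl <- d[d$type == "null", ]
        if (nrow(tg) == 0) {
            warning("scenario ", d$scenario[1],
                    " has no target rows; omitted")
            return(NULL)
        }
        data.frame(scenario = d$scenario[1],
                   regionWidth = d$regionWidth[1],
                   nSamples = d$nSamples[1], effect = d$effect[1],
                   dmpFraction = d$dmpFraction[1],
                   nTarget = nrow(tg), nNull = nrow(nl),
                   power = mean(tg$p < alpha),
                   typeIError = if (nrow(nl)) mean(nl$p < alpha) else NA,
                   meanR2Target = mean(tg$r2), sdR2Target = stats::sd(tg$r2),
                   meanR2Null = if (nrow(nl)) mean(nl$r2) else NA,
                   sdR2Null = if (nrow(nl)) stats::sd(nl$r2) else NA)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
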