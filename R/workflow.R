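#' Test a target region for differential methylation (in memory)
#'
#' The full targeted analysis on a \linkS4class{MethylExperiment}: resolve
#' the region to its CpGs, encode the design, fit the RDA, run the
#' label-permutation pseudo-F test and the random-region R-squared null.
#'
#' @param x a \linkS4class{MethylExperiment}
#' @param region region string (\code{"chr17:37,700,000-38,000,000"}) or
#'   \code{GRanges} of length 1
#' @param outcome outcome column name(s) in \code{colData(x)}
#' @param covariates covariate column name(s) conditioned on
#' @param nperm permutations for the pseudo-F test
#' @param nRegions random windows for the R-squared null
#' @param seed integer RNG seed
#' @param minCpgs,epsilon,scale,r2Denominator analysis options, see
#'   \code{\link{fitRDA}} and \code{\link{selectRegion}}
#' @return list with elements \code{fit} (\linkS4class{RDAFit}),
#'   \code{permutation} (\linkS4class{RDAPermutation}),
#'   \code{regionalNull} (\linkS4class{RegionalNull}), and \code{region}
#' @examples
#' params <- defaultCpGParameters(seed = 7, nCpgs = 400,
#'                                chromLength = 2e6)
#' sim <- simulateDataset(params, scenarioConfig(2e5, 20, 0.3, 0.3),
#'                        seed = 7)
#' res <- rdaRegionTest(sim@experiment, sim@targetRegion, "group",
#'                      nperm = 99, nRegions = 99, seed = 7)
#' pValue(res$permutation)
#' @export
rdaRegionTest <- function(x, region, outcome, covariates = character(),
                          nperm = 10000L, nRegions = 10000L, seed = 1L,
                          minCpgs = 3L, epsilon = 1e-6, scale = FALSE,
                          r2Denominator = c("total", "conditioned")) {
    r2Denominator <- match.arg(r2Denominator)
    stopifnot(is(x, "MethylExperiment"))
    design <- encodeDesign(SummarizedExperiment::colData(x), outcome,
                           covariates)
    sel <- selectRegion(x, region, minCpgs = minCpgs, epsilon = epsilon)
    fit <- fitRDA(sel$mvalues, design, scale = scale,
                  r2Denominator = r2Denominator)
    pt <- rdaPermTest(sel$mvalues, design, nperm = nperm, seed = seed,
                      scale = scale, r2Denominator = r2Denominator)
    rn <- regionR2Null(x, design, sel$region, nRegions = nRegions,
                       seed = seed, minCpgs = minCpgs, scale = scale,
                       r2Denominator = r2Denominator)
    list(fit = fit, permutation = pt, regionalNull = rn,
         region = sel$region)
}

#' File-based targeted RDA analysis
#'
#' Reads the beta matrix, CpG annotation and phenotype table, runs
#' \code{\link{rdaRegionTest}}, and writes a summary JSON
#' (\code{rda_summary.json}: R-squared, sum-of-squares decomposition,
#' pseudo-F, p-values, counts, seeds and the full configuration) plus TSV
#' files with sample scores, CpG loadings and both null distributions.
#'
#' @param betas,annot,pheno input file paths (phenotypes required here,
#'   since the design comes from them)
#' @param region region string
#' @param outcome,covariates column names in the phenotype table
#' @param outDir output directory (created if absent)
#' @param nperm,nRegions,alpha,epsilon,seed,scale,r2Denominator analysis
#'   options
#' @return invisibly, the result list of \code{\link{rdaRegionTest}}
#' @export
runRDARegion <- function(betas, annot, pheno, region, outcome,
                         covariates = character(), outDir = ".",
                         nperm = 10000L, nRegions = 10000L, alpha = 0.05,
                         epsilon = 1e-6, seed = 1L, scale = FALSE,
                         r2Denominator = "total") {
    for (p in c(betas, annot, pheno))
        if (!file.exists(p)) stop("input file not found: ", p)
    if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
    x <- readMethylData(betas, annot, pheno, epsilon = epsilon)
    res <- rdaRegionTest(x, region, outcome, covariates, nperm = nperm,
                         nRegions = nRegions, seed = seed,
                         epsilon = epsilon, scale = scale,
                         r2Denominator = r2Denominator)
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

    fit <- res$fit
    summary <- list(
        region = formatRegion(res$region),
        k = fit@k, n = fit@n, m = fit@m, q = fit@q,
        r2 = fit@r2,
        ss = as.list(ssDecomposition(fit)),
        f_obs = res$permutation@fObs,
        p_permutation = pValue(res$permutation),
        p_regional_null = pValue(res$regionalNull),
        r2_null_mean = mean(nullDraws(res$regionalNull)),
        config = list(betas = betas, annot = annot, pheno = pheno,
                      outcome = outcome, covariates = covariates,
                      nperm = res$permutation@nperm,
                      n_regions = res$regionalNull@nRegions,
                      alpha = alpha, epsilon = epsilon, seed = seed,
                      scale = scale, r2_denominator = r2Denominator))
    jsonlite::write_json(summary, file.path(outDir, "rda_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    .writeTsv(data.frame(sample = rownames(sampleScores(fit)),
                         sampleScores(fit), check.names = FALSE),
              file.path(outDir, "sample_scores.tsv"))
    .writeTsv(data.frame(cpg = rownames(cpgLoadings(fit)),
                         cpgLoadings(fit), check.names = FALSE),
              file.path(outDir, "cpg_loadings.tsv"))
    .writeTsv(data.frame(f_null = nullDraws(res$permutation)),
              file.path(outDir, "permutation_null.tsv"))
    .writeTsv(data.frame(r2_null = nullDraws(res$regionalNull)),
              file.path(outDir, "regional_null.tsv"))
    invisible(res)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' File-based benchmark run
#'
#' Simulates the requested grid, runs the permutation test on every
#' target region and matched signal-free window, and writes the
#' per-replicate results and the per-scenario summary as TSV.
#'
#' @param grid scenario data.frame (default: a single-cell smoke grid) or
#'   path to a TSV with columns \code{regionWidth}, \code{nSamples},
#'   \code{effect}, \code{dmpFraction}, \code{nReplicates}
#' @param outDir output directory
#' @param bPerm permutations per test
#' @param alpha significance level for the summary
#' @param seed master seed
#' @param paramsSeed seed of the per-CpG Beta parameter draw
#' @param direction DMP shift policy
#' @return invisibly, the summary data.frame
#' @export
runBenchmark <- function(grid = scenarioGrid(nReplicates = 10L)[1, ],
                         outDir = ".", bPerm = 10000L, alpha = 0.05,
                         seed = 1L, paramsSeed = 1L,
                         direction = "random") {
    if (is.character(grid))
        grid <- utils::read.table(grid, header = TRUE, sep = "\t")
    params <- defaultCpGParameters(seed = paramsSeed)
    results <- runGrid(params, grid, bPerm = bPerm, masterSeed = seed,
                       direction = direction)
    summary <- evaluatePerformance(results, alpha = alpha)
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    .writeTsv(results, file.path(outDir, "benchmark_results.tsv"))
    .writeTsv(summary, file.path(outDir, "benchmark_summary.tsv"))
    invisible(summary)
}
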