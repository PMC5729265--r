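# fixtures shared across the suite; everything is generated in code

# small MethylExperiment: nCpgs on one chromosome at fixed spacing
makeTinyExperiment <- function(nCpgs = 10, nSamples = 6, seed = 1,
                               chromosome = "chr22", step = 100L) {
    set.seed(seed)
    b <- matrix(runif(nCpgs * nSamples, 0.05, 0.95), nCpgs, nSamples,
                dimnames = list(sprintf("cg%03d", seq_len(nCpgs)),
                                sprintf("S%02d", seq_len(nSamples))))
    ann <- data.frame(probe_id = rownames(b), chromosome = chromosome,
                      position = step * seq_len(nCpgs))
    ph <- data.frame(group = rep(c("A", "B"), length.out = nSamples),
                     age = rnorm(nSamples),
                     row.names = colnames(b))
    MethylExperiment(b, ann, ph)
}

# gaussian region matrix (k CpGs x n samples) plus a balanced two-group
# design, optionally with a numeric conditioning covariate
makeGaussianRegion <- function(k = 8, n = 10, seed = 1,
                               withCovariate = FALSE) {
    set.seed(seed)
    y <- matrix(rnorm(k * n), k, n,
                dimnames = list(sprintf("cg%03d", seq_len(k)),
                                sprintf("S%02d", seq_len(n))))
    ph <- data.frame(group = rep(c("A", "B"), length.out = n),
                     age = rnorm(n), row.names = colnames(y))
    design <- encodeDesign(ph, "group",
                           if (withCovariate) "age" else character())
    list(y = y, ph = ph, design = design)
}

# independent per-CpG least-squares oracle: explained sum of squares of
# each centered CpG regressed on the predictor columns via lm()
olsExplainedSS <- function(y, design) {
    X <- predictorMatrix(design)
    sum(vapply(seq_len(nrow(y)), function(j) {
        yj <- as.numeric(scale(y[j, ], center = TRUE, scale = FALSE))
        fitted <- stats::lm.fit(cbind(1, X), yj)$fitted.values
        sum((fitted - mean(yj))^2)
    }, numeric(1)))
}
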