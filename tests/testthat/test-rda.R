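test_that("single-CpG RDA reduces to the squared Pearson correlation", {
    set.seed(11)
    for (i in 1:5) {
        g <- makeGaussianRegion(k = 1, n = 12, seed = i)
        fit <- fitRDA(g$y, g$design)
        r <- cor(as.numeric(g$y), predictorMatrix(g$design)[, 1])
        expect_equal(explainedR2(fit), r^2, tolerance = 1e-10)
    }
})

test_that("RDA fitted sum of squares equals the per-CpG OLS oracle", {
    set.seed(5)
    for (i in 1:20) {
        k <- sample(2:6, 1); n <- sample(8:12, 1)
        g <- makeGaussianRegion(k = k, n = n, seed = 100 + i,
                                withCovariate = (i %% 2 == 0))
        fit <- fitRDA(g$y, g$design)
        if (nConditioning(g$design) == 0) {
            oracle <- olsExplainedSS(g$y, g$design)
            expect_equal(fit@ssFitted, oracle, tolerance = 1e-10)
        }
        ss <- ssDecomposition(fit)
        expect_equal(unname(ss["total"]),
                     unname(sum(ss[c("conditioned", "fitted",
                                     "residual")])),
                     tolerance = 1e-8)
    }
})

test_that("partial RDA matches residualised least squares", {
    g <- makeGaussianRegion(k = 5, n = 14, seed = 9, withCovariate = TRUE)
    fit <- fitRDA(g$y, g$design)
    # oracle: residualise y and x on the covariate by explicit lm, then
    # accumulate explained SS per CpG
    Z <- conditioningMatrix(g$design)
    X <- predictorMatrix(g$design)
    Xr <- stats::lm.fit(cbind(1, Z), X)$residuals
    ssFit <- sum(vapply(seq_len(nrow(g$y)), function(j) {
        yr <- stats::lm.fit(cbind(1, Z), g$y[j, ])$residuals
        sum(stats::lm.fit(cbind(Xr), yr)$fitted.values^2)
    }, numeric(1)))
    expect_equal(fit@ssFitted, ssFit, tolerance = 1e-8)
    # total-variance denominator: r2 refers to the pre-conditioning total
    expect_equal(explainedR2(fit), fit@ssFitted / fit@ssTotal)
    fit2 <- fitRDA(g$y, g$design, r2Denominator = "conditioned")
    expect_equal(explainedR2(fit2),
                 fit@ssFitted / (fit@ssFitted + fit@ssResidual))
    expect_gt(explainedR2(fit2), explainedR2(fit))
})

test_that("RDA agrees with an independent constrained-ordination oracle", {
    skip_if_not_installed("vegan")
    g <- makeGaussianRegion(k = 8, n = 10, seed = 1)
    fit <- fitRDA(g$y, g$design)
    v <- vegan::rda(t(g$y) ~ group, data = g$ph)
    expect_equal(explainedR2(fit),
                 unname(v$CCA$tot.chi / v$tot.chi), tolerance = 1e-10)
    expect_equal(pseudoF(fit),
                 as.data.frame(vegan::anova.cca(v, permutations = 19))$F[1],
                 tolerance = 1e-8)
    expect_equal(unname(eigenvalues(fit)), unname(v$CCA$eig),
                 tolerance = 1e-8)
    # partial model
    g2 <- makeGaussianRegion(k = 8, n = 12, seed = 2, withCovariate = TRUE)
    fit2 <- fitRDA(g2$y, g2$design)
    v2 <- vegan::rda(t(g2$y) ~ group + Condition(age), data = g2$ph)
    expect_equal(fit2@ssFitted / (fit2@n - 1), unname(v2$CCA$tot.chi),
                 tolerance = 1e-10)
    expect_equal(fit2@ssConditioned / (fit2@n - 1),
                 unname(v2$pCCA$tot.chi), tolerance = 1e-10)
})

test_that("intercept-only designs explain nothing", {
    g <- makeGaussianRegion(k = 4, n = 8, seed = 3)
    d0 <- new("DesignMatrix",
              predictors = matrix(numeric(0), 8, 0),
              conditioning = matrix(numeric(0), 8, 0))
    fit <- fitRDA(g$y, d0)
    expect_equal(explainedR2(fit), 0)
    expect_equal(fit@ssFitted, 0)
    expect_equal(pseudoF(fit), 0)
})

test_that("pseudo-F follows its algebraic form and is monotone in R2", {
    mk <- function(r2, m, q, n) new("RDAFit", r2 = r2, ssTotal = 1,
        ssFitted = r2, ssResidual = 1 - r2, ssConditioned = 0,
        sampleScores = matrix(0, n, 0),
        cpgLoadings = matrix(0, 3, 0), eigenvalues = numeric(0),
        n = as.integer(n), k = 3L, m = as.integer(m), q = as.integer(q),
        r2Denominator = "total")
    expect_equal(pseudoF(mk(0.5, 1, 0, 42)), 40)
    expect_equal(pseudoF(mk(0, 1, 0, 42)), 0)
    expect_lt(pseudoF(mk(0.3, 1, 0, 42)), pseudoF(mk(0.6, 1, 0, 42)))
    expect_warning(f <- pseudoF(mk(1, 1, 0, 42)), "infinite")
    expect_identical(f, Inf)
})

test_that("r2 is invariant to CpG order, constant shifts and column count", {
    g <- makeGaussianRegion(k = 6, n = 10, seed = 21)
    fit <- fitRDA(g$y, g$design)
    perm <- sample(6)
    expect_equal(explainedR2(fitRDA(g$y[perm, ], g$design)),
                 explainedR2(fit))
    shifted <- g$y; shifted[3, ] <- shifted[3, ] + 7
    expect_equal(explainedR2(fitRDA(shifted, g$design)),
                 explainedR2(fit))
})

test_that("null R2 has expectation 1/(n - 1) under an unrelated factor", {
    set.seed(77)
    for (n in c(10, 40)) {
        ph <- data.frame(group = rep(c("A", "B"), each = n / 2),
                         row.names = sprintf("S%03d", 1:n))
        d <- encodeDesign(ph, "group")
        r2 <- replicate(300, {
            y <- matrix(rnorm(5 * n), 5, n)
            explainedR2(fitRDA(y, d, components = FALSE))
        })
        se <- sd(r2) / sqrt(length(r2))
        expect_lt(abs(mean(r2) - 1 / (n - 1)), 3 * se)
    }
})

test_that("fit errors are informative", {
    g <- makeGaussianRegion(k = 3, n = 8, seed = 4)
    ph <- data.frame(a = c("x", "y", "x", "y", "x", "y", "x", "y"),
                     b = c("x", "y", "x", "y", "x", "y", "x", "y"),
                     row.names = colnames(g$y))
    expect_error(encodeDesign(ph, c("a", "b")), "rank deficient")
    tiny <- makeGaussianRegion(k = 3, n = 2, seed = 4)
    expect_error(fitRDA(tiny$y, tiny$design), "insufficient samples")
    bad <- g$y; bad[1, 1] <- NA
    expect_error(fitRDA(bad, g$design), "finite")
})

test_that("biplot coordinates expose scores, centroids and top CpGs", {
    set.seed(8)
    n <- 12; k <- 10
    ph <- data.frame(group = rep(c("A", "B"), each = n / 2),
                     row.names = sprintf("S%02d", 1:n))
    d <- encodeDesign(ph, "group")
    y <- matrix(rnorm(k * n, sd = 0.5), k, n,
                dimnames = list(sprintf("cg%02d", 1:k), rownames(ph)))
    y[4, ph$group == "B"] <- y[4, ph$group == "B"] + 5  # strong CpG
    fit <- fitRDA(y, d)
    bc <- biplotCoordinates(fit, nComponents = 1, nLabeledCpgs = 3,
                            groups = ph$group)
    expect_equal(nrow(bc$samples), n)
    # two balanced groups with a shift: centroids on opposite sides
    expect_lt(prod(bc$centroids$RDA1), 0)
    # the top-loading CpG is the one with maximal per-CpG R2
    perCpG <- apply(y, 1, function(v)
        cor(v, predictorMatrix(d)[, 1])^2)
    expect_equal(bc$cpgs$cpg[1], names(which.max(perCpG)))
    expect_equal(nrow(biplotCoordinates(fit, 1, 0)$cpgs), 0)
    expect_error(biplotCoordinates(fit, nComponents = 5), "component")
})
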