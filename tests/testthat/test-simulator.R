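test_that("default parameters emulate a 450K chromosome 22", {
    params <- defaultCpGParameters(seed = 1)
    expect_length(params@shape1, 8432)
    expect_length(params@positions, 8432)
    expect_true(all(params@shape1 > 0 & params@shape2 > 0))
    mu <- params@shape1 / (params@shape1 + params@shape2)
    expect_true(all(mu > 0 & mu < 1))
    expect_true(all(diff(params@positions) > 0))
    # bimodal marginal: most CpG means sit near 0 or 1
    expect_gt(mean(mu < 0.3 | mu > 0.7), 0.70)
    nu <- params@shape1 + params@shape2
    expect_true(all(nu >= 50 - 1e-9 & nu <= 500 + 1e-9))
})

test_that("method-of-moments fit recovers Beta parameters", {
    # exact arithmetic case: mean 0.2, variance 0.008 => nu 19
    b <- matrix(rep(0.2 + c(-1, 0, 1) * sqrt(0.008), 2), nrow = 2,
                byrow = TRUE)
    p <- fitCpGParameters(b)
    expect_equal(unname(p@shape1), c(3.8, 3.8), tolerance = 1e-9)
    expect_equal(unname(p@shape2), c(15.2, 15.2), tolerance = 1e-9)
    # recovery on data simulated from known shapes, cohort-sized n
    set.seed(10)
    b2 <- matrix(rbeta(50 * 396, 4, 16), 50, 396)
    p2 <- fitCpGParameters(b2)
    mu2 <- p2@shape1 / (p2@shape1 + p2@shape2)
    nu2 <- p2@shape1 + p2@shape2
    expect_lt(median(abs(mu2 - 0.2)), 0.02)
    expect_lt(median(abs(nu2 - 20) / 20), 0.2)
    # constant CpG rows are floored with a warning
    b3 <- rbind(b2[1:2, ], rep(0.4, 396))
    expect_warning(p3 <- fitCpGParameters(b3), "floored")
    expect_equal(unname(p3@shape1[3] + p3@shape2[3]), 2)
})

test_that("DMP count follows the round-half-up rule and stays inside", {
    params <- defaultCpGParameters(seed = 2, nCpgs = 600,
                                   chromLength = 3e6)
    sim <- simulateDataset(params, scenarioConfig(2e6, 10, 0.1, 0.30),
                           seed = 5)
    k <- selectRegion(sim@experiment, sim@targetRegion, minCpgs = 1)$k
    expect_equal(length(sim@dmpIndices), floor(0.30 * k + 0.5))
    expect_s4_class(sim, "SimulatedDataset")  # validity checks containment
    rr <- cpgAnnotation(sim@experiment)
    pos <- GenomicRanges::start(rr)[sim@dmpIndices]
    expect_true(all(pos >= GenomicRanges::start(sim@targetRegion) &
                    pos <= GenomicRanges::end(sim@targetRegion)))
})

test_that("the injected shift reproduces the requested mean difference", {
    params <- defaultCpGParameters(seed = 3, nCpgs = 500,
                                   chromLength = 2.5e6)
    cfg <- scenarioConfig(1e6, 100, 0.3, 0.30)
    sim <- simulateDataset(params, cfg, seed = 11)
    b <- betaValues(sim@experiment)
    grp <- SummarizedExperiment::colData(sim@experiment)$group
    mu <- params@shape1 / (params@shape1 + params@shape2)
    nu <- params@shape1 + params@shape2
    for (i in seq_along(sim@dmpIndices)) {
        j <- sim@dmpIndices[i]
        target <- mu[j] + sim@dmpDirections[i] * 0.3
        if (target < 0.02 || target > 0.98) next  # clamped, skip
        diff <- mean(b[j, grp == "g2"]) - mean(b[j, grp == "g1"])
        se <- sqrt((mu[j] * (1 - mu[j]) + target * (1 - target)) /
                   (nu[j] + 1) / 50)
        expect_lt(abs(diff - sim@dmpDirections[i] * 0.3), 4 * se)
    }
    # directions follow the policy flags
    simUp <- simulateDataset(params, cfg, seed = 12, direction = "up")
    feasible <- mu[simUp@dmpIndices] + 0.3 <= 0.98
    expect_true(all(simUp@dmpDirections[feasible] == 1L))
})

test_that("non-DMP CpGs are identically distributed across groups", {
    params <- defaultCpGParameters(seed = 4, nCpgs = 400,
                                   chromLength = 2e6)
    sim <- simulateDataset(params, scenarioConfig(5e5, 100, 0.3, 0.30),
                           seed = 21)
    b <- betaValues(sim@experiment)
    grp <- SummarizedExperiment::colData(sim@experiment)$group
    others <- setdiff(seq_len(nrow(b)), sim@dmpIndices)
    # pooled KS on non-DMP values, per-CpG standardised, should not reject
    set.seed(1)
    pick <- sample(others, 50)
    p <- vapply(pick, function(j) {
        suppressWarnings(
            ks.test(b[j, grp == "g1"], b[j, grp == "g2"])$p.value)
    }, numeric(1))
    expect_lt(mean(p < 0.01), 0.10)
})

test_that("identical seeds give bit-identical datasets", {
    params <- defaultCpGParameters(seed = 6, nCpgs = 200,
                                   chromLength = 1e6)
    cfg <- scenarioConfig(3e5, 10, 0.1, 0.10)
    a <- simulateDataset(params, cfg, seed = 77)
    b <- simulateDataset(params, cfg, seed = 77)
    expect_identical(betaValues(a@experiment), betaValues(b@experiment))
    expect_identical(a@dmpIndices, b@dmpIndices)
    expect_identical(formatRegion(a@targetRegion),
                     formatRegion(b@targetRegion))
    c <- simulateDataset(params, cfg, seed = 78)
    expect_false(identical(betaValues(a@experiment),
                           betaValues(c@experiment)))
})

test_that("scenario validation catches impossible configurations", {
    expect_error(scenarioConfig(5e5, 7, 0.3, 0.3), "even")
    expect_error(scenarioConfig(5e5, 10, 1.2, 0.3), "effect")
    expect_error(scenarioConfig(5e5, 10, 0.3, 0), "dmpFraction")
    expect_error(scenarioConfig(-1, 10, 0.3, 0.3), "regionWidth")
    g <- scenarioGrid()
    expect_equal(nrow(g), 72)
    expect_setequal(unique(g$regionWidth), c(5e5, 3e5, 1e5, 5e4))
    params <- defaultCpGParameters(seed = 7, nCpgs = 50,
                                   chromLength = 1e5)
    expect_error(simulateDataset(params, scenarioConfig(2e5, 10, .3, .3),
                                 seed = 1), "no placement")
})
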