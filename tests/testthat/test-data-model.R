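test_that("MethylExperiment aligns, clips and sorts its inputs", {
    b <- matrix(c(0.2, 0.8, NA, 0.5, 0.4, 0.6), 3, 2,
                dimnames = list(c("cgB", "cgA", "cgC"), c("S1", "S2")))
    ann <- data.frame(probe_id = c("cgA", "cgB", "cgC"),
                      chromosome = "chr1",
                      position = c(50L, 200L, 100L))
    expect_message(me <- MethylExperiment(b, ann), "dropping 1")
    # cgC (NA row) dropped; rows sorted by position: cgA (50), cgB (200)
    expect_identical(rownames(me), c("cgA", "cgB"))
    expect_equal(unname(betaValues(me)["cgB", ]), c(0.2, 0.5))
    expect_true(all(betaValues(me) > 0 & betaValues(me) < 1))
})

test_that("MethylExperiment rejects bad inputs", {
    b <- matrix(0.5, 2, 2, dimnames = list(c("a", "b"), c("S1", "S2")))
    ann <- data.frame(probe_id = "a", chromosome = "chr1", position = 1L)
    expect_error(MethylExperiment(b, ann), "missing 1 probe")
    expect_error(MethylExperiment(unname(b), ann), "rownames")
})

test_that("region strings parse with separators and fail loudly", {
    r <- parseRegion("chr17:37,700,000-38,000,000")
    expect_equal(as.character(GenomicRanges::seqnames(r)), "chr17")
    expect_equal(GenomicRanges::start(r), 37700000)
    expect_equal(GenomicRanges::end(r), 38000000)
    expect_equal(formatRegion(r), "chr17:37700000-38000000")
    expect_error(parseRegion("chr1:xyz"), "cannot parse")
    expect_error(parseRegion("chr1:200-100"), "start must not exceed")
})

test_that("selectRegion returns exactly the in-interval probes in order", {
    me <- makeTinyExperiment(nCpgs = 10, step = 100L)  # positions 100..1000
    sel <- selectRegion(me, "chr22:250-650")
    expect_equal(sel$k, 4L)
    expect_equal(GenomicRanges::start(cpgAnnotation(me))[sel$index],
                 c(300L, 400L, 500L, 600L))
    expect_equal(dim(sel$mvalues), c(4L, 6L))
    # whole chromosome
    expect_equal(selectRegion(me, "chr22:1-100000")$k, 10L)
    # absent chromosome and too-small regions error
    expect_error(selectRegion(me, "chr1:1-1000"), "empty region")
    expect_error(selectRegion(me, "chr22:101-150"), "empty region")
    expect_error(selectRegion(me, "chr22:100-250"), "region too small")
})

test_that("selectRegion is independent of input row order", {
    set.seed(42)
    b <- matrix(runif(30, 0.1, 0.9), 10, 3,
                dimnames = list(sprintf("cg%02d", 1:10),
                                paste0("S", 1:3)))
    ann <- data.frame(probe_id = rownames(b), chromosome = "chr5",
                      position = 100L * (1:10))
    shuffle <- sample(10)
    me1 <- MethylExperiment(b, ann)
    me2 <- MethylExperiment(b[shuffle, ], ann[shuffle, ])
    s1 <- selectRegion(me1, "chr5:250-650")
    s2 <- selectRegion(me2, "chr5:250-650")
    expect_equal(s1$mvalues, s2$mvalues)
})

test_that("encodeDesign dummy-codes, centers and checks rank", {
    ph <- data.frame(group = c("A", "A", "B", "B"),
                     cond = c("x", "y", "x", "y"),
                     dose = c(1, 2, 3, 4),
                     flat = c(1, 1, 1, 1),
                     row.names = paste0("S", 1:4))
    d <- encodeDesign(ph, "group")
    expect_equal(unname(predictorMatrix(d)[, 1]),
                 c(-0.5, -0.5, 0.5, 0.5))
    expect_equal(nPredictors(d), 1L)
    # 3-level factor gives k - 1 columns
    ph3 <- data.frame(f = c("a", "b", "c", "a", "b", "c"),
                      row.names = paste0("S", 1:6))
    expect_equal(nPredictors(encodeDesign(ph3, "f")), 2L)
    # two binary outcomes give m = 2 (two-variable design)
    d2 <- encodeDesign(ph, c("group", "cond"))
    expect_equal(nPredictors(d2), 2L)
    # covariates land in the conditioning block
    d3 <- encodeDesign(ph, "group", "dose")
    expect_equal(nConditioning(d3), 1L)
    expect_lt(max(abs(colMeans(predictorMatrix(d3)))), 1e-12)
    expect_lt(max(abs(colMeans(conditioningMatrix(d3)))), 1e-12)
    expect_error(encodeDesign(ph, "flat"), "constant")
    expect_error(encodeDesign(ph, "nope"), "unknown")
    ph$na <- c(1, NA, 2, 3)
    expect_error(encodeDesign(ph, "na"), "missing")
})

test_that("file readers round-trip the standard formats", {
    dir <- withr::local_tempdir()
    me <- makeTinyExperiment(nCpgs = 8, nSamples = 4)

    bpath <- file.path(dir, "betas.tsv")
    df <- data.frame(probe_id = rownames(me), betaValues(me),
                     check.names = FALSE)
    write.table(df, bpath, sep = "\t", quote = FALSE, row.names = FALSE)
    b2 <- readBetaMatrix(bpath)
    expect_equal(b2, betaValues(me), tolerance = 1e-7)

    # comma-separated variant is sniffed
    cpath <- file.path(dir, "betas.csv")
    write.table(df, cpath, sep = ",", quote = FALSE, row.names = FALSE)
    expect_equal(readBetaMatrix(cpath), b2, tolerance = 1e-7)

    apath <- file.path(dir, "annot.tsv")
    rr <- cpgAnnotation(me)
    write.table(data.frame(probe_id = names(rr),
                           chromosome = as.character(
                               GenomicRanges::seqnames(rr)),
                           position = GenomicRanges::start(rr)),
                apath, sep = "\t", quote = FALSE, row.names = FALSE)
    a2 <- readCpGAnnotation(apath)
    expect_equal(GenomicRanges::start(a2), GenomicRanges::start(rr))

    # BED is 0-based half-open: start + 1 equals the 1-based position
    bed <- file.path(dir, "annot.bed")
    write.table(data.frame(as.character(GenomicRanges::seqnames(rr)),
                           GenomicRanges::start(rr) - 1L,
                           GenomicRanges::start(rr), names(rr)),
                bed, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    a3 <- readCpGAnnotation(bed)
    expect_equal(GenomicRanges::start(a3), GenomicRanges::start(rr))
    expect_equal(names(a3), names(rr))

    ppath <- file.path(dir, "pheno.tsv")
    cd <- SummarizedExperiment::colData(me)
    write.table(data.frame(sample_id = rownames(cd), as.data.frame(cd)),
                ppath, sep = "\t", quote = FALSE, row.names = FALSE)
    ph2 <- readPhenotypes(ppath)
    expect_equal(ph2$group, as.character(cd$group))

    me2 <- readMethylData(bpath, apath, ppath)
    expect_s4_class(me2, "MethylExperiment")
    expect_equal(mValues(me2), mValues(me), tolerance = 1e-6)
})
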