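test_that("invalid configurations are rejected with the offending field", {
    expect_error(simulationConfig(nGenes = 0), "nGenes")
    expect_error(simulationConfig(nCells = -5), "nCells")
    expect_error(simulationConfig(nGroups = 2,
        groupProportions = c(0.7, 0.2)), "groupProportions")
    expect_error(simulationConfig(nGroups = 2,
        groupProportions = c(1.2, -0.2)), "groupProportions")
    expect_error(simulationConfig(meanShape = 0), "meanShape")
    expect_error(simulationConfig(deLog2fcSd = -1), "deLog2fcSd")
    expect_error(simulationConfig(deProb = 1.5), "deProb")
})

test_that("simulated matrices have the requested shape, labels and dtype", {
    cfg <- fig2Preset(nGroups = 6, nCells = 2000, nGenes = 200, seed = 3)
    sce <- simulateCounts(cfg)
    counts <- assay(sce, "counts")
    expect_identical(dim(counts), c(200L, 2000L))
    expect_true(is.integer(counts))
    expect_true(all(counts >= 0))
    expect_identical(nlevels(colData(sce)$cell_type), 6L)
    expect_setequal(as.character(unique(colData(sce)$cell_type)),
        sprintf("Group%d", 1:6))
    ## per-entry expected values are carried for downstream dropout
    expect_true("mu" %in% assayNames(sce))

    ## identical config + seed => bit-identical output
    sce2 <- simulateCounts(cfg)
    expect_identical(assay(sce, "counts"), assay(sce2, "counts"))
    expect_identical(colData(sce)$cell_type, colData(sce2)$cell_type)
    cfgB <- fig2Preset(nGroups = 6, nCells = 2000, nGenes = 200, seed = 4)
    expect_false(identical(assay(simulateCounts(cfgB), "counts"), counts))
})

test_that("a single group with no DE gives one label and one mean profile", {
    cfg <- simulationConfig(nGenes = 25, nCells = 40, nGroups = 1,
        deProb = 0, libsizeScale = 0, seed = 9)
    sce <- simulateCounts(cfg)
    expect_identical(nlevels(droplevels(colData(sce)$cell_type)), 1L)
    mu <- assay(sce, "mu")
    ## with no DE and constant library size every cell shares the profile
    expect_true(all(abs(mu - mu[, 1]) < 1e-12))
})

test_that("empirical gene means match the Poisson expectation", {
    ## libsize variance zero, no DE: mean count per gene should sit within
    ## 4 * sqrt(lambda / n) of lambda (Poisson moments, n = 10,000 cells)
    cfg <- simulationConfig(nGenes = 5, nCells = 10000, nGroups = 1,
        deProb = 0, libsizeScale = 0, seed = 11)
    sce <- simulateCounts(cfg)
    lambda <- assay(sce, "mu")[, 1]
    emp <- rowMeans(assay(sce, "counts"))
    expect_true(all(abs(emp - lambda) <= 4 * sqrt(lambda / 10000) + 1e-12))
})

test_that("dropout follows the logistic curve and records its mask", {
    sce <- toy_sce(nCells = 50, nGenes = 30, seed = 2)
    ## effectively-zero dropout probability leaves counts untouched
    none <- applyDropout(sce, midpoint = -100, shape = 50, seed = 5)
    expect_identical(assay(none, "counts"), assay(sce, "counts"))
    expect_false(any(assay(none, "dropout_mask")))

    ## an entry at the midpoint is zeroed with probability exactly 1/2:
    ## 10,000 entries at the midpoint stay within 3 * sqrt(0.25 / n) of 0.5
    muVal <- 3
    mu <- matrix(muVal, 100, 100)
    sceMid <- SingleCellExperiment(assays = list(
        counts = matrix(5L, 100, 100), mu = mu))
    dropped <- applyDropout(sceMid, midpoint = log1p(muVal), shape = 2,
        seed = 6)
    frac <- mean(assay(dropped, "dropout_mask"))
    expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))

    ## mask true => count zero; mask false => count unchanged
    drop <- applyDropout(sce, midpoint = 1.5, shape = 1, seed = 7)
    mask <- assay(drop, "dropout_mask")
    expect_true(all(assay(drop, "counts")[mask] == 0))
    expect_identical(assay(drop, "counts")[!mask],
        assay(sce, "counts")[!mask])

    ## without an expected-value channel dropout is undefined
    bare <- SingleCellExperiment(assays = list(
        counts = matrix(1L, 4, 4)))
    expect_error(applyDropout(bare, 1, 1, seed = 1), "mu")
})

test_that("steeper dropout curves only increase zeroing below the midpoint", {
    ## with the midpoint above the typical log-mean, raising `shape` drives
    ## the per-entry zeroing probability (and so the zero fraction) up
    sce <- toy_sce(nCells = 80, nGenes = 50, seed = 3)
    mu <- assay(sce, "mu")
    midpoint <- max(log1p(mu)) + 0.5
    pFrac <- vapply(c(0.5, 1, 2, 4), function(sh) {
        mean(plogis(sh * (midpoint - log1p(mu))))
    }, numeric(1))
    expect_true(all(diff(pFrac) >= 0))
    zeroFrac <- vapply(c(0.5, 1, 2, 4), function(sh) {
        mean(assay(applyDropout(sce, midpoint, sh, seed = 42),
            "counts") == 0)
    }, numeric(1))
    expect_true(all(diff(zeroFrac) >= -0.01))
})

test_that("simulated groups carry detectable silhouette signal", {
    ## true labels should beat permuted labels in nearly every replicate
    wins <- 0L
    for (seed in 1:20) {
        sce <- simulateCounts(simulationConfig(
            nGenes = 60, nCells = 120, nGroups = 3, seed = seed))
        ne <- suppressWarnings(preprocessCounts(sce, nTop = 40))
        labels <- colData(sce)$cell_type
        true <- meanSilhouette(silhouetteScore(zScores(ne), labels))
        set.seed(1000 + seed)
        perm <- meanSilhouette(silhouetteScore(zScores(ne),
            sample(labels)))
        if (true > perm) wins <- wins + 1L
    }
    expect_gte(wins, 19L)
})
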