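test_that("silhouette handles the textbook configurations", {
    ## two clusters of duplicated points: a_i = 0, s_i = 1 for every cell
    x <- rbind(matrix(0, 2, 2), matrix(1, 2, 2))
    res <- silhouetteScore(x, c("a", "a", "b", "b"))
    expect_true(all(res@s == 1))
    expect_identical(meanSilhouette(res), 1)

    ## perfectly symmetric configuration (regular tetrahedron: every
    ## pairwise distance equal): a_i = b_i, mean silhouette 0
    y <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
    resSym <- silhouetteScore(y, c("a", "b", "a", "b"))
    expect_equal(meanSilhouette(resSym), 0, tolerance = 1e-12)

    expect_error(silhouetteScore(x, rep("a", 4)), "2 clusters")
    expect_error(silhouetteScore(x, c("a", "b")), "length")
})

test_that("silhouette equals the brute-force triple loop on random data", {
    set.seed(23)
    for (i in 1:50) {
        n <- sample(6:15, 1)
        k <- sample(2:4, 1)
        x <- matrix(rnorm(n * 2), n, 2)
        labels <- sample(letters[1:k], n, replace = TRUE)
        if (length(unique(labels)) < 2) next
        res <- silhouetteScore(x, labels)
        expect_equal(res@s, silhouette_oracle(x, labels),
            tolerance = 1e-12)
    }
})

test_that("silhouette agrees with the cluster package", {
    set.seed(29)
    x <- matrix(rnorm(60), 30, 2)
    labels <- rep(1:3, each = 10)
    res <- silhouetteScore(x, labels)
    ref <- cluster::silhouette(labels, dist(x))
    expect_equal(mean(ref[, "sil_width"]), meanSilhouette(res),
        tolerance = 1e-9)
})

test_that("silhouette is invariant to label names and rigid rotation", {
    set.seed(37)
    x <- matrix(rnorm(50), 25, 2)
    labels <- sample(c("u", "v", "w"), 25, replace = TRUE)
    base <- silhouetteScore(x, labels)
    renamed <- silhouetteScore(x, factor(labels,
        labels = c("C", "A", "B")))
    expect_equal(base@s, renamed@s, tolerance = 1e-12)
    theta <- 0.83
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    rotated <- silhouetteScore(x %*% rot, labels)
    expect_equal(base@s, rotated@s, tolerance = 1e-9)
})

test_that("singleton clusters are flagged and scored zero", {
    x <- rbind(c(0, 0), c(0.1, 0), c(5, 5))
    res <- silhouetteScore(x, c("a", "a", "lone"))
    expect_true(res@singleton[3])
    expect_identical(res@s[3], 0)
    expect_false(any(res@singleton[1:2]))
})

test_that("pseudo-time fits recover exact orderings", {
    fit <- pseudotimeR2(c(0, 1, 2, 3), factor(c("s0", "s1", "s2", "s3"),
        levels = c("s0", "s1", "s2", "s3")))
    expect_equal(fit@rSquared, 1, tolerance = 1e-12)
    expect_equal(fit@slope, 1, tolerance = 1e-12)
    expect_equal(fit@intercept, 0, tolerance = 1e-12)

    rev <- pseudotimeR2(c(3, 2, 1, 0), c(0, 1, 2, 3))
    expect_equal(rev@rSquared, 1, tolerance = 1e-12)
    expect_lt(rev@slope, 0)
})

test_that("pseudo-time r^2 matches the closed form and lm()", {
    x <- c(1, 2, 3, 4)
    y <- c(2, 4, 5, 9)
    fit <- pseudotimeR2(y, x)
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(fit@r, r, tolerance = 1e-12)
    expect_equal(fit@rSquared, r^2, tolerance = 1e-12)
    lmFit <- lm(y ~ x)
    expect_equal(fit@slope, unname(coef(lmFit)[2]), tolerance = 1e-12)
    expect_equal(fit@intercept, unname(coef(lmFit)[1]), tolerance = 1e-12)
    expect_equal(fit@rSquared, summary(lmFit)$r.squared, tolerance = 1e-12)

    set.seed(43)
    for (i in 1:100) {
        n <- sample(5:20, 1)
        xs <- rnorm(n)
        ys <- rnorm(n)
        expect_equal(pseudotimeR2(ys, xs)@rSquared, cor(xs, ys)^2,
            tolerance = 1e-12)
    }
})

test_that("pseudo-time r^2 ignores affine rescaling of the pseudo-time", {
    set.seed(47)
    stages <- rep(0:3, each = 5)
    pt <- stages + rnorm(20, sd = 0.3)
    base <- pseudotimeR2(pt, stages)@rSquared
    scaled <- pseudotimeR2(5 * pt - 11, stages)@rSquared
    expect_equal(base, scaled, tolerance = 1e-12)
})

test_that("degenerate pseudo-time is flagged, not silently zero", {
    fit <- pseudotimeR2(rep(2, 5), c(0, 0, 1, 1, 2))
    expect_true(fit@degenerate)
    expect_true(is.na(fit@rSquared))
    expect_error(pseudotimeR2(1:5, rep(1, 5)), "distinct")
    expect_error(pseudotimeR2(1:2, 1:2), "3 cells")
})

test_that("the condition harness reports raw and denoised rows per scenario", {
    scenarios <- list(
        clean = simulationConfig(nGenes = 30, nCells = 60, nGroups = 2,
            seed = 1),
        noisy = simulationConfig(nGenes = 30, nCells = 60, nGroups = 2,
            dropoutEnabled = TRUE, seed = 1)
    )
    tab <- suppressWarnings(compareConditions(scenarios, nTop = 20,
        searchConfig = batchSearchConfig(batchStart = 16, batchEnd = 32,
            batchStep = 16, epochsPerCycle = 1, finalEpochs = 2),
        template = toy_template(), seed = 4))
    expect_identical(nrow(tab), 4L)
    expect_identical(tab$condition, rep(c("raw", "denoised"), 2))
    expect_true(all(is.finite(tab$mean_silhouette)))
    expect_setequal(unique(tab$scenario), c("clean", "noisy"))
})
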