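test_that("losses hit their analytic checkpoints", {
    expect_equal(reconstructionLoss(c(1, 0), c(0.5, 0.5)), 0.693147,
        tolerance = 1e-6)
    x <- matrix(c(1, 0, 0, 1), 2)
    expect_lt(reconstructionLoss(x, x), 1e-6)
    expect_equal(generatorLoss(0.5), 0.693147, tolerance = 1e-6)
    expect_lt(generatorLoss(0), 1e-6)
    expect_equal(generatorLoss(0.5, mode = "nonsaturating"), 0.693147,
        tolerance = 1e-6)
    expect_equal(discriminatorLoss(0.5, 0.5), 1.386294, tolerance = 1e-6)
    expect_lt(discriminatorLoss(1, 0), 1e-6)
})

test_that("loss contracts reject malformed inputs", {
    expect_error(reconstructionLoss(matrix(0, 2, 2), matrix(0, 2, 3)),
        "shape")
    expect_error(generatorLoss(c(0.2, 1.4)), "\\[0, 1\\]")
    expect_error(discriminatorLoss(-0.1, 0.5), "\\[0, 1\\]")
    expect_error(discriminatorLoss(c(0.5, 0.5), 0.5), "length")
})

test_that("loss formulas agree with scalar-loop oracles", {
    set.seed(31)
    for (i in 1:100) {
        n <- sample(2:6, 1)
        m <- sample(2:5, 1)
        x <- matrix(runif(n * m), n, m)
        xp <- matrix(runif(n * m), n, m)
        expect_equal(reconstructionLoss(x, xp), bce_oracle(x, xp),
            tolerance = 1e-9)
        dFake <- runif(n)
        dReal <- runif(n)
        pf <- pmin(pmax(dFake, 1e-7), 1 - 1e-7)
        pr <- pmin(pmax(dReal, 1e-7), 1 - 1e-7)
        expect_equal(generatorLoss(dFake),
            -sum(vapply(pf, function(p) log(1 - p), numeric(1))) / n,
            tolerance = 1e-9)
        expect_equal(generatorLoss(dFake, "nonsaturating"),
            -sum(vapply(pf, log, numeric(1))) / n, tolerance = 1e-9)
        expect_equal(discriminatorLoss(dReal, dFake),
            -sum(vapply(seq_len(n), function(j) {
                log(pr[j]) + log(1 - pf[j])
            }, numeric(1))) / n, tolerance = 1e-9)
    }
})

test_that("encode/decode match a scalar-loop oracle and basic identities", {
    m <- toy_model(inputDim = 7, seed = 3)
    set.seed(8)
    x <- matrix(runif(35), 5, 7)
    expect_equal(encodeCells(m, x),
        mlp_oracle(m@encoder, x, 0.2, "relu"), tolerance = 1e-6)
    z <- encodeCells(m, x)
    expect_equal(decodeCells(m, z),
        mlp_oracle(m@decoder, z, 0.2, "sigmoid"), tolerance = 1e-6)

    ## zero weights map anything to zero latent codes
    m0 <- m
    m0@encoder <- lapply(m0@encoder, function(l) {
        l$W[] <- 0
        l
    })
    expect_true(all(encodeCells(m0, x) == 0))
    ## zero latent + zero biases lands on sigmoid(0) = 0.5
    expect_true(all(decodeCells(m, matrix(0, 2, latentDim(m))) == 0.5))
    ## width contracts
    expect_identical(ncol(decodeCells(m, z)), 7L)
    expect_error(encodeCells(m, matrix(0, 2, 6)), "width")
    expect_error(decodeCells(m, matrix(0, 2, 3)), "width")
})

test_that("backpropagated gradients match finite differences", {
    m <- toy_model(inputDim = 6, seed = 12)
    set.seed(5)
    x <- matrix(runif(24), 4, 6)
    lossOf <- function(model) {
        recon <- decodeCells(model, encodeCells(model, x))
        reconstructionLoss(x, recon)
    }
    cacheE <- dbaae:::mlp_forward(m@encoder, x, 0.2, "relu")
    cacheD <- dbaae:::mlp_forward(m@decoder, cacheE$out, 0.2, "sigmoid")
    xp <- dbaae:::clip_prob(cacheD$out)
    dRecon <- (-(x / xp) + (1 - x) / (1 - xp)) / length(x)
    bwdD <- dbaae:::mlp_backward(m@decoder, cacheD, dRecon, 0.2, "sigmoid")
    bwdE <- dbaae:::mlp_backward(m@encoder, cacheE, bwdD$dX, 0.2, "relu")
    eps <- 1e-6
    set.seed(6)
    for (probe in 1:10) {
        l <- sample(length(m@encoder), 1)
        i <- sample(nrow(m@encoder[[l]]$W), 1)
        j <- sample(ncol(m@encoder[[l]]$W), 1)
        mPlus <- m
        mPlus@encoder[[l]]$W[i, j] <- mPlus@encoder[[l]]$W[i, j] + eps
        mMinus <- m
        mMinus@encoder[[l]]$W[i, j] <- mMinus@encoder[[l]]$W[i, j] - eps
        fd <- (lossOf(mPlus) - lossOf(mMinus)) / (2 * eps)
        expect_equal(bwdE$grads[[l]]$W[i, j], fd, tolerance = 1e-4)
    }
    ## a plain gradient-descent step on the reconstruction gradient
    ## strictly decreases the loss
    mStep <- m
    for (l in seq_along(mStep@encoder)) {
        mStep@encoder[[l]]$W <- mStep@encoder[[l]]$W - 0.1 * bwdE$grads[[l]]$W
        mStep@encoder[[l]]$b <- mStep@encoder[[l]]$b - 0.1 * bwdE$grads[[l]]$b
    }
    for (l in seq_along(mStep@decoder)) {
        mStep@decoder[[l]]$W <- mStep@decoder[[l]]$W - 0.1 * bwdD$grads[[l]]$W
        mStep@decoder[[l]]$b <- mStep@decoder[[l]]$b - 0.1 * bwdD$grads[[l]]$b
    }
    expect_lt(lossOf(mStep), lossOf(m))
})

test_that("a zero learning rate reports losses but leaves weights fixed", {
    m <- toy_model(inputDim = 10, seed = 4, learningRate = 0)
    set.seed(10)
    x <- matrix(runif(50), 5, 10)
    step <- adversarialStep(m, x)
    expect_true(all(is.finite(step$losses)))
    expect_identical(step$model@encoder, m@encoder)
    expect_identical(step$model@decoder, m@decoder)
    expect_identical(step$model@discriminator, m@discriminator)
})

test_that("training is deterministic and reduces reconstruction loss", {
    ne <- toy_norm(nCells = 100, nGenes = 25, nTop = 20, seed = 2)
    v <- normValues(ne)
    m <- toy_model(inputDim = ncol(v), seed = 5)
    fitA <- trainAAE(m, v, epochs = 25, batchSize = 16, seed = 3,
        patience = Inf)
    fitB <- trainAAE(m, v, epochs = 25, batchSize = 16, seed = 3,
        patience = Inf)
    expect_identical(fitA$history$L_rec, fitB$history$L_rec)
    expect_identical(fitA$model@encoder, fitB$model@encoder)
    ## 25 epochs x 7 batches = 175 adversarial steps on a separable toy
    expect_lt(tail(fitA$epochLrec, 1), fitA$epochLrec[1])
    expect_true(all(is.finite(as.matrix(fitA$history))))
    ## the input model is untouched by training (no aliasing through the
    ## in-place optimizer)
    expect_identical(m@encoder, toy_model(inputDim = ncol(v),
        seed = 5)@encoder)
})

test_that("full reconstruction is invariant to the batch partition", {
    ne <- toy_norm(nCells = 53, nGenes = 30, nTop = 20, seed = 8)
    v <- normValues(ne)
    m <- toy_model(inputDim = ncol(v), seed = 6)
    full <- reconstructFull(m, ne, batchSize = 53)
    parts <- reconstructFull(m, ne, batchSize = 7)
    expect_lt(max(abs(full - parts)), 1e-6)
    expect_identical(dim(full), dim(v))
    expect_true(all(full >= 0 & full <= 1))
    ## row-wise equivalence with standalone encode/decode
    i <- 17
    row <- v[i, , drop = FALSE]
    expect_equal(parts[i, , drop = FALSE],
        decodeCells(m, encodeCells(m, row)), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("model checkpoints round-trip through a single archive", {
    m <- toy_model(inputDim = 9, seed = 7)
    path <- tempfile(fileext = ".rds")
    saveAAEModel(m, path)
    m2 <- loadAAEModel(path)
    expect_identical(m2@encoder, m@encoder)
    expect_identical(m2@outputActivations, m@outputActivations)
    bad <- tempfile(fileext = ".rds")
    saveRDS(list(a = 1), bad)
    expect_error(loadAAEModel(bad), "checkpoint")
})

test_that("model construction enforces the mirrored architecture", {
    m <- toy_model(inputDim = 12)
    expect_identical(m@decoderDims, rev(m@encoderDims))
    expect_identical(m@discriminatorDims[1], latentDim(m))
    expect_error(aaeModel(inputDim = 5, hiddenDims = c(8, 4),
        discDims = c(3, 1), outputActivations = c(encoder = "relu")),
        "outputActivations")
})
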