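test_that("an empty cycle records the untrained model", {
    ne <- toy_norm(nCells = 60, nGenes = 25, nTop = 20, seed = 4)
    rec <- runCycle(toy_template(), ne, batchSize = 16, epochs = 0, seed = 9)
    expect_identical(rec$epochs_run, 0L)
    expect_true(is.finite(rec$min_loss) && rec$min_loss >= 0)
    expect_true(rec$accuracy >= 0 && rec$accuracy <= 1)
    ## same seed twice => identical records
    rec2 <- runCycle(toy_template(), ne, batchSize = 16, epochs = 0, seed = 9)
    expect_identical(rec, rec2)
})

test_that("longer cycles reach a lower minimum loss on the toy set", {
    ne <- toy_norm(nCells = 100, nGenes = 25, nTop = 20, seed = 2)
    short <- runCycle(toy_template(), ne, batchSize = 16, epochs = 1,
        seed = 5)
    long <- runCycle(toy_template(), ne, batchSize = 16, epochs = 30,
        seed = 5)
    expect_lt(long$min_loss, short$min_loss)
})

test_that("oversized candidate batch sizes are clipped with a warning", {
    ne <- toy_norm(nCells = 40, nGenes = 20, nTop = 15, seed = 3)
    expect_warning(rec <- runCycle(toy_template(), ne, batchSize = 500,
        epochs = 0, seed = 1), "clipped")
    expect_identical(rec$batch_size, 40L)
})

test_that("the selector is a pure lexicographic rule", {
    rec <- data.frame(batch_size = c(32L, 64L, 96L),
        accuracy = c(0.90, 0.95, 0.95),
        min_loss = c(0.5, 0.5, 0.4))
    expect_identical(selectBatchSize(rec), 96L) # lowest loss wins
    rec$min_loss <- c(0.5, 0.5, 0.5)
    expect_identical(selectBatchSize(rec), 64L) # tie: higher accuracy
    rec$accuracy <- c(0.9, 0.9, 0.9)
    expect_identical(selectBatchSize(rec), 32L) # tie: smaller batch
    rec$min_loss <- c(NaN, Inf, NA)
    expect_error(selectBatchSize(rec), "diverged")
})

test_that("the selector agrees with an exhaustive-comparison oracle", {
    set.seed(77)
    for (i in 1:50) {
        k <- sample(2:6, 1)
        rec <- data.frame(
            batch_size = sort(sample(seq(16, 256, by = 16), k)),
            accuracy = round(runif(k), 2),
            min_loss = round(runif(k, 0.1, 0.9), 2) # rounding forces ties
        )
        best <- rec$batch_size[1]
        for (j in seq_len(k)) {
            better <- FALSE
            cur <- rec[rec$batch_size == best, ]
            cand <- rec[j, ]
            if (cand$min_loss < cur$min_loss) {
                better <- TRUE
            } else if (cand$min_loss == cur$min_loss) {
                if (cand$accuracy > cur$accuracy) {
                    better <- TRUE
                } else if (cand$accuracy == cur$accuracy &&
                    cand$batch_size < cur$batch_size) {
                    better <- TRUE
                }
            }
            if (better) best <- cand$batch_size
        }
        expect_identical(selectBatchSize(rec), as.integer(best))
    }
})

test_that("the sweep visits the whole grid and its choice is replayable", {
    ne <- toy_norm(nCells = 60, nGenes = 25, nTop = 20, seed = 6)
    cfg <- batchSearchConfig(batchStart = 10, batchEnd = 30, batchStep = 10,
        epochsPerCycle = 3, finalEpochs = 5, seed = 21)
    res <- searchBatchSize(cfg, ne, toy_template())
    expect_setequal(res$records$batch_size, c(10L, 20L, 30L))
    expect_true(res$batchSize %in% res$records$batch_size)
    ## replaying selection on the stored records reproduces the choice
    expect_identical(selectBatchSize(res$records), res$batchSize)
    ## the search is deterministic
    res2 <- searchBatchSize(cfg, ne, toy_template())
    expect_identical(res$records, res2$records)
})

test_that("successive halving returns a grid member deterministically", {
    ne <- toy_norm(nCells = 60, nGenes = 25, nTop = 20, seed = 6)
    cfg <- batchSearchConfig(batchStart = 10, batchEnd = 40, batchStep = 10,
        epochsPerCycle = 4, finalEpochs = 5, mode = "halving", seed = 3)
    res <- searchBatchSize(cfg, ne, toy_template())
    expect_true(res$batchSize %in% c(10L, 20L, 30L, 40L))
    res2 <- searchBatchSize(cfg, ne, toy_template())
    expect_identical(res$batchSize, res2$batchSize)
})

test_that("final training at epochs = 0 returns the initialised model", {
    ne <- toy_norm(nCells = 50, nGenes = 25, nTop = 20, seed = 8)
    fit <- finalTrain(toy_template(), ne, batchSize = 16, epochs = 0,
        seed = 13)
    ref <- dbaae:::template_model(toy_template(),
        inputDim = ncol(normValues(ne)), seed = 13)
    expect_identical(fit$model@encoder, ref@encoder)
    expect_identical(fit$epochsRun, 0L)
    ## and with epochs > 0 the run is deterministic
    fitA <- finalTrain(toy_template(), ne, batchSize = 16, epochs = 5,
        seed = 13)
    fitB <- finalTrain(toy_template(), ne, batchSize = 16, epochs = 5,
        seed = 13)
    expect_identical(fitA$model@decoder, fitB$model@decoder)
    expect_identical(fitA$epochLrec, fitB$epochLrec)
})

test_that("configuration invariants are enforced", {
    expect_error(batchSearchConfig(batchStart = 64, batchEnd = 32),
        "batchStart")
    expect_error(batchSearchConfig(batchStep = 0), "batchStep")
    expect_error(batchSearchConfig(mode = "random"), "'arg'")
})
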