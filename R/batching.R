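#' Configure the batch-size search
#'
#' @param batchStart,batchEnd,batchStep candidate grid: `batchStart`,
#'   `batchStart + batchStep`, ... up to `batchEnd`, intersected with
#'   `[1, n_cells]` at run time. Defaults 32..256 step 32.
#' @param epochsPerCycle epochs each candidate trains for during the
#'   search.
#' @param finalEpochs epochs of the final training at the selected size.
#' @param mode `"sweep"` (exhaustive, default) or `"halving"`
#'   (successive halving: repeatedly keep the better half of candidates,
#'   doubling the epoch budget each round).
#' @param seed integer seed controlling every cycle.
#' @return A [BatchSearchConfig-class].
#' @examples
#' batchSearchConfig(batchStart = 32, batchEnd = 96, batchStep = 32)
#' @export
batchSearchConfig <- function(batchStart = 32L, batchEnd = 256L,
    batchStep = 32L, epochsPerCycle = 30L, finalEpochs = 300L,
    mode = c("sweep", "halving"), seed = 1L) {
    mode <- match.arg(mode)
    new("BatchSearchConfig",
        batchStart = as.integer(batchStart), batchEnd = as.integer(batchEnd),
        batchStep = as.integer(batchStep),
        epochsPerCycle = as.integer(epochsPerCycle),
        finalEpochs = as.integer(finalEpochs), mode = mode,
        seed = as.integer(seed)
    )
}

#' Model template for the search
#'
#' A plain list of [aaeModel()] arguments (everything except `inputDim`
#' and `seed`, which the search supplies per cycle). Used so every cycle
#' starts from a fresh, identically configured model.
#'
#' @param hiddenDims,discDims,leakySlope,outputActivations,learningRate,genMode
#'   see [aaeModel()].
#' @return a named list.
#' @export
aaeTemplate <- function(hiddenDims = c(1024L, 512L, 512L),
    discDims = c(256L, 1L), leakySlope = 0.2,
    outputActivations = c(encoder = "relu", decoder = "sigmoid",
        discriminator = "sigmoid"),
    learningRate = 2e-5, genMode = "paper") {
    list(hiddenDims = hiddenDims, discDims = discDims,
        leakySlope = leakySlope, outputActivations = outputActivations,
        learningRate = learningRate, genMode = genMode)
}

template_model <- function(template, inputDim, seed) {
    do.call(aaeModel, c(list(inputDim = inputDim, seed = seed), template))
}

## Deterministic held-out split: ~10% of cells (at least 1) for the
## cycle-accuracy statistic.
holdout_split <- function(n, seed) {
    nHold <- max(1L, round(0.1 * n))
    hold <- with_seed(seed, sample.int(n, nHold))
    list(train = setdiff(seq_len(n), hold), holdout = hold)
}

#' Run one batch-size search cycle
#'
#' Initialises a fresh model from the template with a cycle-specific seed,
#' trains for `epochs` epochs at the given batch size on ~90% of cells,
#' and records the minimum reconstruction loss over all steps together
#' with the cycle-end accuracy, defined as `1 -` mean absolute
#' reconstruction error on the held-out ~10% of cells (a denoising-
#' relevant quantity in `[0, 1]`). The mean discriminator accuracy over
#' the cycle is logged alongside.
#'
#' @param template an [aaeTemplate()] list.
#' @param data a [NormalizedExpression-class].
#' @param batchSize candidate batch size; values above the number of cells
#'   are clipped with a warning.
#' @param epochs training epochs for this cycle; `epochs = 0` records the
#'   untrained model.
#' @param seed integer seed (weights, shuffles, holdout split).
#' @return one-row `data.frame`: `batch_size`, `accuracy`, `min_loss`,
#'   `epochs_run`, `disc_accuracy`.
#' @export
runCycle <- function(template, data, batchSize, epochs, seed) {
    stopifnot(is(data, "NormalizedExpression"))
    x <- data@values
    n <- nrow(x)
    if (batchSize > n) {
        warning("batch size ", batchSize, " exceeds the number of cells (",
            n, "); clipped")
        batchSize <- n
    }
    if (batchSize < 1L) stop("batch size must be >= 1")
    split <- holdout_split(n, derive_seed(seed, 101L))
    xTrain <- x[split$train, , drop = FALSE]
    xHold <- x[split$holdout, , drop = FALSE]
    model <- template_model(template, inputDim = ncol(x), seed = seed)
    if (epochs > 0L) {
        fit <- trainAAE(model, xTrain, epochs = epochs,
            batchSize = batchSize, seed = derive_seed(seed, 7L),
            patience = Inf)
        model <- fit$model
        minLoss <- fit$minLrec
        discAcc <- mean(fit$history$disc_accuracy)
    } else {
        minLoss <- reconstructionLoss(xTrain,
            reconstructFull(model, xTrain, batchSize))
        discAcc <- NA_real_
    }
    recon <- reconstructFull(model, xHold, batchSize)
    accuracy <- 1 - mean(abs(xHold - recon))
    data.frame(
        batch_size = as.integer(batchSize), accuracy = accuracy,
        min_loss = minLoss, epochs_run = as.integer(epochs),
        disc_accuracy = discAcc
    )
}

#' Select the winning batch size from search records
#'
#' Pure function of the record table: the candidate with the smallest
#' `min_loss` wins; ties go to the higher `accuracy`, then to the smaller
#' `batch_size`. Candidates with non-finite loss are excluded.
#'
#' @param records `data.frame` with columns `batch_size`, `accuracy`,
#'   `min_loss` (one row per candidate).
#' @return the selected batch size (integer).
#' @examples
#' rec <- data.frame(batch_size = c(32L, 64L),
#'     accuracy = c(0.9, 0.95), min_loss = c(0.5, 0.5))
#' selectBatchSize(rec) # 64: equal loss, higher accuracy
#' @export
selectBatchSize <- function(records) {
    ok <- is.finite(records$min_loss)
    if (!any(ok)) {
        stop("all search cycles diverged (non-finite losses); per-candidate ",
            "records: ", paste(sprintf("bs=%d loss=%g", records$batch_size,
                records$min_loss), collapse = ", "))
    }
    r <- records[ok, , drop = FALSE]
    ord <- order(r$min_loss, -r$accuracy, r$batch_size)
    as.integer(r$batch_size[ord[1L]])
}

#' Sweep candidate batch sizes and pick the best
#'
#' Runs [runCycle()] for every candidate in the grid (each from a fresh
#' model, with a seed derived from the configuration seed and the
#' candidate index, so records are comparable and reproducible), then
#' applies [selectBatchSize()]. In `"halving"` mode poor candidates are
#' eliminated early: each round trains the surviving candidates and keeps
#' the better half, doubling the epoch budget, honouring the
#' resource-allocation idea of Hyperband-style searches.
#'
#' @param config a [BatchSearchConfig-class].
#' @param data a [NormalizedExpression-class].
#' @param template an [aaeTemplate()] list.
#' @return list with `batchSize` (selected) and `records` (the full
#'   table, one row per candidate; in halving mode, the last record of
#'   each candidate).
#' @export
searchBatchSize <- function(config, data, template = aaeTemplate()) {
    stopifnot(is(config, "BatchSearchConfig"))
    validObject(config)
    n <- nrow(data@values)
    cand <- seq(config@batchStart, config@batchEnd, by = config@batchStep)
    cand <- unique(pmin(cand, n))
    cand <- cand[cand >= 1L]
    if (!length(cand)) stop("empty candidate list")
    if (config@mode == "sweep") {
        records <- do.call(rbind, lapply(seq_along(cand), function(i) {
            runCycle(template, data, cand[i], config@epochsPerCycle,
                seed = derive_seed(config@seed, i))
        }))
    } else {
        alive <- cand
        rounds <- max(1L, ceiling(log2(length(cand))))
        epochsRound <- max(1L, config@epochsPerCycle %/% 2^(rounds - 1L))
        recList <- list()
        round <- 1L
        repeat {
            recs <- do.call(rbind, lapply(seq_along(alive), function(i) {
                runCycle(template, data, alive[i], epochsRound,
                    seed = derive_seed(config@seed,
                        1000L * round + match(alive[i], cand)))
            }))
            for (j in seq_len(nrow(recs))) {
                recList[[as.character(recs$batch_size[j])]] <- recs[j, ]
            }
            if (length(alive) == 1L) break
            keep <- order(recs$min_loss, -recs$accuracy,
                recs$batch_size)[seq_len(ceiling(length(alive) / 2))]
            alive <- sort(recs$batch_size[keep])
            epochsRound <- epochsRound * 2L
            round <- round + 1L
        }
        records <- do.call(rbind, recList[as.character(
            intersect(cand, as.integer(names(recList))))])
        rownames(records) <- NULL
    }
    list(batchSize = selectBatchSize(records), records = records)
}

#' Final training at the selected batch size
#'
#' Trains a fresh model from the template on all cells at the chosen
#' batch size, returning the model together with its loss trajectory.
#'
#' @param template an [aaeTemplate()] list.
#' @param data a [NormalizedExpression-class].
#' @param batchSize the selected batch size.
#' @param epochs training epochs; `epochs = 0` returns the initialised
#'   model untrained.
#' @param seed integer seed.
#' @param patience,tol early-stopping parameters (see [trainAAE()]).
#' @return list with `model`, `history`, `epochLrec`, `minLrec`,
#'   `epochsRun`.
#' @export
finalTrain <- function(template, data, batchSize, epochs, seed,
    patience = 20L, tol = 1e-5) {
    stopifnot(is(data, "NormalizedExpression"))
    x <- data@values
    batchSize <- min(batchSize, nrow(x))
    model <- template_model(template, inputDim = ncol(x), seed = seed)
    if (epochs == 0L) {
        return(list(model = model, history = NULL, epochLrec = numeric(0),
            minLrec = NA_real_, epochsRun = 0L))
    }
    fit <- trainAAE(model, x, epochs = epochs, batchSize = batchSize,
        seed = derive_seed(seed, 7L), patience = patience, tol = tol)
    if (!all(is.finite(fit$epochLrec))) {
        stop("final training diverged; per-epoch L_rec trajectory: ",
            paste(signif(fit$epochLrec, 4), collapse = ", "))
    }
    fit
}
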