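#' Denoise a count matrix end to end
#'
#' The full chain: preprocessing (optional `log1p`, highly-variable-gene
#' selection, z-score, unit rescaling), dynamic batch-size search, final
#' adversarial training at the selected size, full-matrix reconstruction,
#' and inverse transform of the reconstruction to the requested output
#' scale. Every stage draws its randomness from seeds derived from the
#' single `seed` argument, so identical inputs and configuration
#' reproduce the output exactly.
#'
#' @param x genes x cells `SummarizedExperiment` with a `counts` assay, or
#'   a cells x genes matrix, or an already-built
#'   [NormalizedExpression-class].
#' @param nTop,log1p,sigmaMode,nBins preprocessing options (see
#'   [preprocessCounts()]); ignored when `x` is already normalised.
#' @param searchConfig a [BatchSearchConfig-class]; its seed is
#'   overridden by `seed`.
#' @param template an [aaeTemplate()] list of model hyperparameters.
#' @param finalEpochs epochs of the final training (defaults to the
#'   search configuration's `finalEpochs`).
#' @param outputScale scale of the denoised layer: `"zscore"` (default;
#'   min-max inverted) or `"expression"` (additionally undoes the
#'   z-score and any `log1p`).
#' @param seed integer master seed.
#' @param labels optional per-cell labels carried into the result.
#' @return A `SingleCellExperiment` over the selected genes with assays
#'   `dbaae_denoised` (genes x cells, on `outputScale`) and, when the
#'   input carried counts, `counts` (the raw subset); `metadata()`
#'   records `selectedBatchSize`, `searchRecords`, `lossTrajectory`
#'   (per-epoch mean reconstruction loss), `normalized` (the
#'   [NormalizedExpression-class]), `runConfig` and `seed`.
#' @examples
#' sce <- simulateDataset(fig2Preset(nGroups = 2, dropout = TRUE,
#'     nCells = 120, nGenes = 40))
#' den <- denoiseCounts(sce, nTop = 20,
#'     searchConfig = batchSearchConfig(batchStart = 32, batchEnd = 64,
#'         batchStep = 32, epochsPerCycle = 2, finalEpochs = 5),
#'     template = aaeTemplate(hiddenDims = c(16, 8, 8), discDims = c(4, 1)),
#'     seed = 1)
#' S4Vectors::metadata(den)$selectedBatchSize
#' @export
denoiseCounts <- function(x, nTop = NULL, log1p = TRUE,
    sigmaMode = "plain", nBins = 20L,
    searchConfig = batchSearchConfig(), template = aaeTemplate(),
    finalEpochs = searchConfig@finalEpochs,
    outputScale = c("zscore", "expression"), seed = 1L, labels = NULL) {
    outputScale <- match.arg(outputScale)
    seed <- as.integer(seed)
    if (is(x, "NormalizedExpression")) {
        ne <- x
        rawCounts <- NULL
    } else {
        if (is.matrix(x) || is(x, "Matrix")) {
            x <- as.matrix(x)
            if (is.null(colnames(x))) {
                colnames(x) <- sprintf("Gene%04d", seq_len(ncol(x)))
            }
            if (is.null(rownames(x))) {
                rownames(x) <- sprintf("Cell%05d", seq_len(nrow(x)))
            }
        }
        ne <- preprocessCounts(x, nTop = nTop, log1p = log1p,
            sigmaMode = sigmaMode, nBins = nBins, labels = labels)
        rawCounts <- if (is(x, "SummarizedExperiment")) {
            assay(x, "counts")[ne@selectedGenes, , drop = FALSE]
        } else {
            t(x)[ne@selectedGenes, , drop = FALSE]
        }
    }
    sc <- searchConfig
    sc@seed <- derive_seed(seed, 11L)
    search <- searchBatchSize(sc, ne, template)
    fit <- finalTrain(template, ne, search$batchSize,
        epochs = as.integer(finalEpochs), seed = derive_seed(seed, 23L))
    recon <- reconstructFull(fit$model, ne, batchSize = search$batchSize)
    denoised <- inverseTransform(ne, values = recon, to = outputScale)
    dimnames(denoised) <- list(ne@cellIds, ne@selectedGenes)
    assays <- list(dbaae_denoised = t(denoised))
    if (!is.null(rawCounts)) assays <- c(list(counts = rawCounts), assays)
    out <- SingleCellExperiment(
        assays = assays,
        colData = S4Vectors::DataFrame(
            cell_type = if (length(ne@cellLabels)) ne@cellLabels else
                factor(rep(NA_character_, length(ne@cellIds))),
            row.names = ne@cellIds
        )
    )
    metadata(out) <- list(
        selectedBatchSize = search$batchSize,
        searchRecords = search$records,
        lossTrajectory = fit$epochLrec,
        finalMinLrec = fit$minLrec,
        epochsRun = fit$epochsRun,
        normalized = ne,
        runConfig = list(
            nTop = nTop, log1p = log1p, sigmaMode = sigmaMode,
            nBins = nBins, searchConfig = sc, template = template,
            finalEpochs = as.integer(finalEpochs),
            outputScale = outputScale, seed = seed
        ),
        seed = seed
    )
    out
}
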