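#' @import methods
NULL

#' Simulation configuration for the gamma-Poisson count generator
#'
#' Holds every parameter of the synthetic scRNA-seq count generator:
#' baseline gene means are gamma distributed, per-cell library-size factors
#' are log-normal, group-specific differential-expression (DE) factors are
#' log-normal around 1, counts are conditionally Poisson, and dropout (when
#' enabled) zeroes entries with a logistic probability in the log expected
#' value. Build instances with [simulationConfig()] or the [fig2Preset()]
#' convenience constructor.
#'
#' @slot nGenes,nCells,nGroups positive integer dimensions of the simulation.
#' @slot groupProportions numeric vector of length `nGroups`, non-negative,
#'   summing to 1; cell labels are drawn from this distribution.
#' @slot meanShape,meanRate positive gamma shape/rate for baseline gene means.
#' @slot libsizeLocation,libsizeScale log-normal meanlog/sdlog of per-cell
#'   library-size factors (`libsizeScale >= 0`).
#' @slot deProb probability a gene is differentially expressed in a group.
#' @slot deLog2fcSd positive spread (sd of the log2 fold change) of DE
#'   multiplicative factors.
#' @slot dropoutEnabled logical; whether dropout is part of this scenario.
#' @slot dropoutMidpoint,dropoutShape logistic dropout curve parameters on
#'   the `log1p(mu)` scale (see [applyDropout()]).
#' @slot seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @seealso [simulateCounts()], [applyDropout()], [simulateDataset()]
#' @export
setClass("SimulationConfig",
    representation(
        nGenes = "integer", nCells = "integer", nGroups = "integer",
        groupProportions = "numeric",
        meanShape = "numeric", meanRate = "numeric",
        libsizeLocation = "numeric", libsizeScale = "numeric",
        deProb = "numeric", deLog2fcSd = "numeric",
        dropoutEnabled = "logical",
        dropoutMidpoint = "numeric", dropoutShape = "numeric",
        seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    pos_int <- function(x, name) {
        if (length(x) != 1L || is.na(x) || x < 1L) {
            sprintf("'%s' must be a positive integer", name)
        } else {
            character()
        }
    }
    msg <- c(msg, pos_int(object@nGenes, "nGenes"),
        pos_int(object@nCells, "nCells"), pos_int(object@nGroups, "nGroups"))
    p <- object@groupProportions
    if (length(p) != object@nGroups) {
        msg <- c(msg, "'groupProportions' length must equal 'nGroups'")
    } else {
        if (any(p < 0)) {
            msg <- c(msg, "'groupProportions' entries must be >= 0")
        }
        if (abs(sum(p) - 1) > 1e-9) {
            msg <- c(msg, "'groupProportions' must sum to 1 (within 1e-9)")
        }
    }
    for (nm in c("meanShape", "meanRate", "deLog2fcSd")) {
        v <- slot(object, nm)
        if (length(v) != 1L || !is.finite(v) || v <= 0) {
            msg <- c(msg, sprintf("'%s' must be strictly positive", nm))
        }
    }
    if (object@libsizeScale < 0) {
        msg <- c(msg, "'libsizeScale' must be >= 0")
    }
    if (object@deProb < 0 || object@deProb > 1) {
        msg <- c(msg, "'deProb' must be a probability in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Normalised network input with exact inverse-transform parameters
#'
#' The model-facing representation of an expression matrix: a cells x genes
#' (note the orientation: cells in rows, as the network consumes it) matrix
#' of highly-variable-gene z-scores rescaled per gene into the unit interval
#' so that the binary-cross-entropy reconstruction loss is well defined.
#' All statistics required to invert the transform exactly (per-gene means,
#' standard deviations, min-max bounds, whether `log1p` was applied) are
#' stored alongside; see [inverseTransform()].
#'
#' @slot values cells x genes matrix in `[0, 1]`: the network input.
#' @slot zScores cells x genes matrix of per-gene z-scores.
#' @slot selectedGenes character, ordered selected gene identifiers.
#' @slot geneMeans,geneSds per-gene mean and (population) sd used by the
#'   z-score; sds are strictly positive for every selected gene.
#' @slot scaleMin,scaleMax per-gene min-max rescaling bounds.
#' @slot cellIds character cell identifiers (row order of `values`).
#' @slot cellLabels factor of per-cell labels; length 0 when unknown.
#' @slot log1pApplied logical; whether `log1p` preceded the z-score.
#' @slot hvgReport `DataFrame` with the per-gene dispersion ranking that
#'   produced `selectedGenes` (see [selectHvg()]).
#' @export
setClass("NormalizedExpression",
    representation(
        values = "matrix", zScores = "matrix",
        selectedGenes = "character",
        geneMeans = "numeric", geneSds = "numeric",
        scaleMin = "numeric", scaleMax = "numeric",
        cellIds = "character", cellLabels = "factor",
        log1pApplied = "logical", hvgReport = "DataFrame"
    )
)

setValidity("NormalizedExpression", function(object) {
    msg <- character()
    v <- object@values
    ng <- length(object@selectedGenes)
    if (ncol(v) != ng) msg <- c(msg, "ncol(values) must match selectedGenes")
    if (!all(dim(v) == dim(object@zScores))) {
        msg <- c(msg, "values and zScores must share dimensions")
    }
    if (any(v < -1e-12 | v > 1 + 1e-12)) {
        msg <- c(msg, "values must lie in [0, 1]")
    }
    for (nm in c("geneMeans", "geneSds", "scaleMin", "scaleMax")) {
        if (length(slot(object, nm)) != ng) {
            msg <- c(msg, sprintf("'%s' must have one entry per gene", nm))
        }
    }
    if (any(object@geneSds <= 0)) {
        msg <- c(msg, "geneSds must be strictly positive for selected genes")
    }
    if (length(object@cellLabels) &&
        length(object@cellLabels) != nrow(v)) {
        msg <- c(msg, "cellLabels length must equal the number of cells")
    }
    if (length(msg)) msg else TRUE
})

#' Adversarial autoencoder model
#'
#' A fully connected adversarial autoencoder: an encoder mapping expression
#' to a latent code, a mirror-image decoder mapping the code back, and a
#' discriminator scoring latent codes. Hidden layers use LeakyReLU; the
#' default output activations are `relu` for the encoder and `sigmoid` for
#' the decoder and discriminator (the probabilistic losses require outputs
#' in (0, 1)). Each of the three parameter groups (autoencoder, generator
#' path, discriminator) carries its own RMSprop optimizer state. Build with
#' [aaeModel()].
#'
#' @slot encoderDims integer, layer widths input..latent (default
#'   input-1024-512-512).
#' @slot decoderDims integer, exact reverse of `encoderDims`.
#' @slot discriminatorDims integer, latent..1 (default 512-256-1).
#' @slot encoder,decoder,discriminator lists of `list(W, b)` dense layers.
#' @slot leakySlope LeakyReLU negative-half slope for hidden layers.
#' @slot outputActivations named character: final activation of each network.
#' @slot learningRate RMSprop learning rate (default 2e-5) shared by all
#'   three optimizers.
#' @slot genMode `"paper"` or `"nonsaturating"` generator-loss form; see
#'   [generatorLoss()].
#' @slot optState RMSprop accumulators for the `ae`, `gen` and `disc`
#'   parameter groups.
#' @slot seed integer seed used for weight initialisation.
#' @export
setClass("AAEModel",
    representation(
        encoderDims = "integer", decoderDims = "integer",
        discriminatorDims = "integer",
        encoder = "list", decoder = "list", discriminator = "list",
        leakySlope = "numeric", outputActivations = "character",
        learningRate = "numeric", genMode = "character",
        optState = "list", seed = "integer"
    )
)

setValidity("AAEModel", function(object) {
    msg <- character()
    if (!identical(object@decoderDims, rev(object@encoderDims))) {
        msg <- c(msg, "decoder dims must be the exact reverse of encoder dims")
    }
    latent <- object@encoderDims[length(object@encoderDims)]
    if (object@discriminatorDims[1L] != latent) {
        msg <- c(msg, "discriminator input width must equal the latent width")
    }
    finite <- function(layers) {
        all(vapply(layers, function(l) all(is.finite(l$W)) &&
            all(is.finite(l$b)), logical(1)))
    }
    if (!finite(object@encoder) || !finite(object@decoder) ||
        !finite(object@discriminator)) {
        msg <- c(msg, "all weight tensors must be finite")
    }
    if (!all(c("encoder", "decoder", "discriminator") %in%
        names(object@outputActivations))) {
        msg <- c(msg, "outputActivations must name encoder/decoder/discriminator")
    }
    if (!object@genMode %in% c("paper", "nonsaturating")) {
        msg <- c(msg, "genMode must be 'paper' or 'nonsaturating'")
    }
    if (length(msg)) msg else TRUE
})

#' Batch-size search configuration
#'
#' Defines the candidate grid of training batch sizes (`batchStart`,
#' `batchStart + batchStep`, ... up to `batchEnd`, clipped to the number of
#' cells), the number of epochs each search cycle trains for, the number of
#' epochs of the final training run at the selected size, and the seed that
#' makes the whole search reproducible. Build with [batchSearchConfig()].
#'
#' @slot batchStart,batchEnd,batchStep positive integers defining the grid.
#' @slot epochsPerCycle,finalEpochs positive integers.
#' @slot mode `"sweep"` (exhaustive grid, default) or `"halving"`
#'   (successive-halving early stopping of poor candidates).
#' @slot seed integer seed.
#' @export
setClass("BatchSearchConfig",
    representation(
        batchStart = "integer", batchEnd = "integer", batchStep = "integer",
        epochsPerCycle = "integer", finalEpochs = "integer",
        mode = "character", seed = "integer"
    )
)

setValidity("BatchSearchConfig", function(object) {
    msg <- character()
    if (object@batchStart < 1L || object@batchEnd < 1L) {
        msg <- c(msg, "batch sizes must be positive")
    }
    if (object@batchStart > object@batchEnd) {
        msg <- c(msg, "batchStart must be <= batchEnd")
    }
    if (object@batchStep < 1L) msg <- c(msg, "batchStep must be >= 1")
    if (object@epochsPerCycle < 0L) {
        msg <- c(msg, "epochsPerCycle must be >= 0")
    }
    if (object@finalEpochs < 0L) msg <- c(msg, "finalEpochs must be >= 0")
    if (!object@mode %in% c("sweep", "halving")) {
        msg <- c(msg, "mode must be 'sweep' or 'halving'")
    }
    if (length(msg)) msg else TRUE
})

#' Per-cell silhouette decomposition
#'
#' Result of [silhouetteScore()]: for each cell the mean intra-cluster
#' distance `a`, the mean distance to the nearest other cluster `b`, the
#' silhouette width `s = (b - a) / max(a, b)`, and the mean silhouette over
#' cells. Cells in singleton clusters have undefined `a` and are assigned
#' `s = 0` with `singleton = TRUE`.
#'
#' @slot s,a,b numeric per-cell statistics (`s` in `[-1, 1]`).
#' @slot singleton logical per-cell flag for singleton-cluster cells.
#' @slot meanSilhouette mean of `s` over all cells.
#' @slot metric distance metric name.
#' @slot labels factor of cluster labels used.
#' @export
setClass("SilhouetteResult",
    representation(
        s = "numeric", a = "numeric", b = "numeric",
        singleton = "logical", meanSilhouette = "numeric",
        metric = "character", labels = "factor"
    )
)

setValidity("SilhouetteResult", function(object) {
    if (any(object@s < -1 - 1e-12 | object@s > 1 + 1e-12)) {
        "every silhouette width must lie in [-1, 1]"
    } else {
        TRUE
    }
})

#' Least-squares fit of pseudo-time against annotated stages
#'
#' Result of [pseudotimeR2()]: the simple linear regression of the
#' pseudo-time vector `y` on numeric stage codes `x`, reported through the
#' closed form `b = r * s_y / s_x`, `a = ybar - b * xbar`, together with
#' Pearson's `r` and `r^2`. When either vector has zero variance the fit is
#' flagged `degenerate` and `r`/`rSquared` are `NA` (never silently 0).
#'
#' @slot slope,intercept,r,rSquared numeric scalars (`rSquared` in `[0, 1]`
#'   or `NA` when degenerate).
#' @slot x numeric stage codes; @slot y numeric pseudo-time values.
#' @slot degenerate logical zero-variance flag.
#' @export
setClass("PseudotimeFit",
    representation(
        slope = "numeric", intercept = "numeric",
        r = "numeric", rSquared = "numeric",
        x = "numeric", y = "numeric", degenerate = "logical"
    )
)

setValidity("PseudotimeFit", function(object) {
    if (!object@degenerate) {
        if (!is.finite(object@rSquared) ||
            object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12) {
            return("rSquared must lie in [0, 1] for a non-degenerate fit")
        }
        if (abs(object@rSquared - object@r^2) > 1e-12) {
            return("rSquared must equal r^2")
        }
    }
    TRUE
})
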