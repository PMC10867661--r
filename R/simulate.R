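#' Create a simulation configuration
#'
#' Constructs a [SimulationConfig-class] for the gamma-Poisson count
#' generator. The generative model is: baseline gene means
#' `lambda_g ~ Gamma(meanShape, meanRate)`; per-cell library-size factors
#' `L_c ~ LogNormal(libsizeLocation, libsizeScale)`; for each (group, gene)
#' pair a differential-expression factor `F_kg` equal to
#' `2^N(0, deLog2fcSd)` with probability `deProb` and 1 otherwise; counts
#' `K_cg ~ Poisson(lambda_g * F_{k(c),g} * L_c)`. Dropout, when enabled,
#' zeroes entries with logistic probability in `log1p` of the expected
#' value (see [applyDropout()]).
#'
#' All default parameter values are package defaults chosen to yield
#' realistic, clusterable benchmark data; they are documented choices of
#' this package, not published simulator settings.
#'
#' @param nGenes,nCells,nGroups simulation dimensions.
#' @param groupProportions group membership probabilities (default uniform).
#' @param meanShape,meanRate gamma shape/rate of baseline gene means.
#' @param libsizeLocation,libsizeScale log-normal meanlog/sdlog of library
#'   size factors.
#' @param deProb probability a gene is differentially expressed in a group.
#' @param deLog2fcSd sd of the log2 fold change of DE factors.
#' @param dropoutEnabled whether [simulateDataset()] applies dropout.
#' @param dropoutMidpoint,dropoutShape logistic dropout parameters.
#' @param seed integer RNG seed.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nGenes = 50, nCells = 100, nGroups = 2, seed = 7)
#' sce <- simulateCounts(cfg)
#' @export
simulationConfig <- function(nGenes = 200L, nCells = 2000L, nGroups = 2L,
    groupProportions = rep(1 / nGroups, nGroups),
    meanShape = 0.6, meanRate = 0.3,
    libsizeLocation = 0, libsizeScale = 0.2,
    deProb = 0.3, deLog2fcSd = 1,
    dropoutEnabled = FALSE, dropoutMidpoint = 1.5, dropoutShape = 1,
    seed = 1L) {
    new("SimulationConfig",
        nGenes = as.integer(nGenes), nCells = as.integer(nCells),
        nGroups = as.integer(nGroups),
        groupProportions = as.numeric(groupProportions),
        meanShape = meanShape, meanRate = meanRate,
        libsizeLocation = libsizeLocation, libsizeScale = libsizeScale,
        deProb = deProb, deLog2fcSd = deLog2fcSd,
        dropoutEnabled = dropoutEnabled,
        dropoutMidpoint = dropoutMidpoint, dropoutShape = dropoutShape,
        seed = as.integer(seed)
    )
}

#' Benchmark preset: 200 genes x 2,000 cells with 2/6/8 groups
#'
#' Convenience constructor for the standard simulated benchmark layout:
#' a 200-gene by 2,000-cell count matrix with two, six or eight equally
#' likely virtual cell types, with or without dropout. The distributional
#' parameter values behind the preset are this package's defaults (see
#' [simulationConfig()]); they are not taken from any published setting.
#'
#' @param nGroups number of virtual cell types (2, 6 or 8 in the standard
#'   layout; any positive integer is accepted).
#' @param dropout logical; simulate the dropout condition?
#' @param nCells,nGenes matrix dimensions, overridable to scale the
#'   benchmark down.
#' @param seed integer RNG seed.
#' @return A [SimulationConfig-class].
#' @examples
#' cfg <- fig2Preset(nGroups = 6, dropout = TRUE, nCells = 300)
#' @export
fig2Preset <- function(nGroups = 6L, dropout = FALSE, nCells = 2000L,
    nGenes = 200L, seed = 1L) {
    simulationConfig(
        nGenes = nGenes, nCells = nCells, nGroups = nGroups,
        dropoutEnabled = dropout, seed = seed
    )
}

#' Simulate a labelled scRNA-seq count matrix
#'
#' Draws a count matrix under the gamma-Poisson model described in
#' [simulationConfig()]. No dropout is applied here regardless of
#' `dropoutEnabled`; use [applyDropout()] or [simulateDataset()] for the
#' dropout condition. The per-entry expected values are kept in the `"mu"`
#' assay so that dropout probabilities can be computed downstream.
#'
#' @param config a [SimulationConfig-class].
#' @return A [SingleCellExperiment::SingleCellExperiment] (genes x cells)
#'   with assays `counts` (integer) and `mu` (expected values), cell labels
#'   in `colData(.)$cell_type`, and the configuration in
#'   `metadata(.)$sim_config`.
#' @examples
#' sce <- simulateCounts(simulationConfig(nGenes = 40, nCells = 80,
#'     nGroups = 3, seed = 2))
#' table(SummarizedExperiment::colData(sce)$cell_type)
#' @export
simulateCounts <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    nG <- config@nGenes
    nC <- config@nCells
    nK <- config@nGroups
    with_seed(config@seed, {
        labels <- sample.int(nK, nC, replace = TRUE,
            prob = config@groupProportions)
        baseMean <- rgamma(nG, shape = config@meanShape,
            rate = config@meanRate)
        isDE <- matrix(rbinom(nK * nG, 1L, config@deProb) == 1L,
            nrow = nK, ncol = nG)
        deFac <- matrix(1, nrow = nK, ncol = nG)
        deFac[isDE] <- 2^rnorm(sum(isDE), mean = 0, sd = config@deLog2fcSd)
        libFac <- rlnorm(nC, meanlog = config@libsizeLocation,
            sdlog = config@libsizeScale)
        ## mu (genes x cells): lambda_g * F_{k(c),g} * L_c
        mu <- t(deFac[labels, , drop = FALSE] * rep(baseMean,
            each = nC)) * rep(libFac, each = nG)
        counts <- matrix(rpois(nG * nC, lambda = mu), nrow = nG, ncol = nC)
    })
    storage.mode(counts) <- "integer"
    geneIds <- sprintf("Gene%04d", seq_len(nG))
    cellIds <- sprintf("Cell%05d", seq_len(nC))
    dimnames(counts) <- dimnames(mu) <- list(geneIds, cellIds)
    sce <- SingleCellExperiment(
        assays = list(counts = counts, mu = mu),
        colData = S4Vectors::DataFrame(
            cell_type = factor(sprintf("Group%d", labels),
                levels = sprintf("Group%d", seq_len(nK))),
            row.names = cellIds
        )
    )
    metadata(sce)$sim_config <- config
    sce
}

#' Apply logistic dropout to a simulated count matrix
#'
#' Each entry is zeroed independently with probability
#' `p = 1 / (1 + exp(-shape * (midpoint - log1p(mu))))`, where `mu` is the
#' entry's pre-sampling expected value (the `"mu"` assay written by
#' [simulateCounts()]). Entries with a larger expected value are on the
#' descending limb of the curve, so strongly expressed genes drop out less.
#' The realised mask is stored in a `dropout_mask` assay; non-zeroed
#' entries are untouched.
#'
#' @param sce a `SingleCellExperiment` with assays `counts` and `mu` (or a
#'   `mu` matrix supplied via `mu=`).
#' @param midpoint,shape logistic curve parameters on the `log1p(mu)` scale.
#' @param seed integer RNG seed for the Bernoulli mask.
#' @param mu optional genes x cells matrix of expected values, required when
#'   `sce` lacks a `"mu"` assay.
#' @return The input object with zeroed counts and a logical
#'   `dropout_mask` assay; `metadata(.)$dropout` records the parameters.
#' @examples
#' sce <- simulateCounts(simulationConfig(nGenes = 30, nCells = 50, seed = 3))
#' drop <- applyDropout(sce, midpoint = 1.5, shape = 1, seed = 4)
#' mean(SummarizedExperiment::assay(drop, "dropout_mask"))
#' @export
applyDropout <- function(sce, midpoint, shape, seed, mu = NULL) {
    stopifnot(is(sce, "SummarizedExperiment"))
    counts <- assay(sce, "counts")
    if (is.null(mu)) {
        if (!"mu" %in% assayNames(sce)) {
            stop("no expected-value channel: the object has no 'mu' assay ",
                "and no 'mu' matrix was supplied; dropout probabilities ",
                "are defined on pre-sampling expected values")
        }
        mu <- assay(sce, "mu")
    }
    if (!all(dim(mu) == dim(counts))) {
        stop("'mu' must have the same dimensions as counts")
    }
    if (any(counts < 0)) stop("counts must be non-negative")
    p <- plogis(shape * (midpoint - log1p(mu)))
    mask <- with_seed(seed,
        matrix(runif(length(p)) < p, nrow = nrow(p), ncol = ncol(p)))
    dimnames(mask) <- dimnames(counts)
    counts[mask] <- 0L
    assay(sce, "counts") <- counts
    assay(sce, "dropout_mask") <- mask
    metadata(sce)$dropout <- list(midpoint = midpoint, shape = shape,
        seed = as.integer(seed))
    sce
}

#' Simulate a full scenario (counts, then dropout if configured)
#'
#' Runs [simulateCounts()] and, when `config` has `dropoutEnabled = TRUE`,
#' applies [applyDropout()] with the configured midpoint/shape and a seed
#' derived deterministically from the configuration seed.
#'
#' @param config a [SimulationConfig-class].
#' @return A `SingleCellExperiment`; see [simulateCounts()].
#' @examples
#' sce <- simulateDataset(fig2Preset(nGroups = 2, dropout = TRUE,
#'     nCells = 100, nGenes = 40))
#' @export
simulateDataset <- function(config) {
    sce <- simulateCounts(config)
    if (config@dropoutEnabled) {
        sce <- applyDropout(sce, midpoint = config@dropoutMidpoint,
            shape = config@dropoutShape,
            seed = derive_seed(config@seed, 1L))
    }
    sce
}

#' @describeIn SimulationConfig-class compact description of a configuration
#' @param object a `SimulationConfig`
#' @export
setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nGenes, "genes x", object@nCells,
        "cells,", object@nGroups, "groups\n")
    cat("  gene means ~ Gamma(", object@meanShape, ",", object@meanRate,
        "); libsize ~ LogNormal(", object@libsizeLocation, ",",
        object@libsizeScale, ")\n")
    cat("  DE: prob", object@deProb, ", log2FC sd", object@deLog2fcSd, "\n")
    cat("  dropout:", if (object@dropoutEnabled) {
        sprintf("enabled (midpoint %g, shape %g)", object@dropoutMidpoint,
            object@dropoutShape)
    } else {
        "disabled"
    }, "| seed", object@seed, "\n")
})
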