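suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(SingleCellExperiment)
})

## Small model template: keeps training-path tests fast while exercising
## the same code as the full-width architecture.
toy_template <- function(genMode = "paper") {
    aaeTemplate(hiddenDims = c(16L, 8L, 8L), discDims = c(4L, 1L),
        genMode = genMode)
}

toy_model <- function(inputDim = 20L, seed = 1L, ...) {
    aaeModel(inputDim = inputDim, hiddenDims = c(16L, 8L, 8L),
        discDims = c(4L, 1L), seed = seed, ...)
}

## A small labelled simulation with clear group structure.
toy_sce <- function(nCells = 100L, nGenes = 30L, nGroups = 3L, seed = 1L,
    dropout = FALSE) {
    simulateDataset(simulationConfig(
        nGenes = nGenes, nCells = nCells, nGroups = nGroups,
        dropoutEnabled = dropout, seed = seed
    ))
}

toy_norm <- function(nCells = 100L, nGenes = 30L, nGroups = 3L, seed = 1L,
    nTop = 20L, dropout = FALSE) {
    sce <- toy_sce(nCells, nGenes, nGroups, seed, dropout)
    suppressWarnings(preprocessCounts(sce, nTop = nTop))
}

## Brute-force triple-loop silhouette (independent oracle).
silhouette_oracle <- function(x, labels) {
    labels <- as.character(labels)
    n <- nrow(x)
    d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
    s <- numeric(n)
    for (i in seq_len(n)) {
        own <- labels == labels[i]
        if (sum(own) == 1L) {
            s[i] <- 0
            next
        }
        ai <- 0
        for (j in which(own)) if (j != i) ai <- ai + d(i, j)
        ai <- ai / (sum(own) - 1L)
        bi <- Inf
        for (k in setdiff(unique(labels), labels[i])) {
            tot <- 0
            members <- which(labels == k)
            for (j in members) tot <- tot + d(i, j)
            bi <- min(bi, tot / length(members))
        }
        s[i] <- (bi - ai) / max(ai, bi)
    }
    s
}

## Element-loop BCE (independent oracle).
bce_oracle <- function(x, xp) {
    x <- as.numeric(x)
    xp <- pmin(pmax(as.numeric(xp), 1e-7), 1 - 1e-7)
    tot <- 0
    for (i in seq_along(x)) {
        tot <- tot + x[i] * log(xp[i]) + (1 - x[i]) * log(1 - xp[i])
    }
    -tot / length(x)
}

## Scalar-loop dense-stack forward (independent oracle for encode/decode).
mlp_oracle <- function(layers, X, slope, finalAct) {
    act <- function(u, name) {
        if (name == "leaky") {
            if (u > 0) u else slope * u
        } else if (name == "relu") {
            max(u, 0)
        } else if (name == "sigmoid") {
            1 / (1 + exp(-u))
        } else {
            u
        }
    }
    H <- X
    for (l in seq_along(layers)) {
        W <- layers[[l]]$W
        b <- layers[[l]]$b
        name <- if (l == length(layers)) finalAct else "leaky"
        out <- matrix(0, nrow(H), ncol(W))
        for (i in seq_len(nrow(H))) {
            for (j in seq_len(ncol(W))) {
                u <- b[j]
                for (k in seq_len(ncol(H))) u <- u + H[i, k] * W[k, j]
                out[i, j] <- act(u, name)
            }
        }
        H <- out
    }
    H
}
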