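#' Per-gene z-score transform
#'
#' Standardises each gene column: `z_mn = (G_mn - Gbar_m) / sigma_m`, where
#' `Gbar_m` is the per-gene mean over cells. By default `sigma_m` is the
#' plain per-gene population standard deviation (`ddof = 0`); with
#' `sigmaMode = "trend"` it is the expected standard deviation for the
#' gene's mean, read off a smoothed global mean-variance trend. Genes with
#' zero variance cannot be standardised; their z-scores are set to 0 and
#' flagged.
#'
#' @param x cells x genes numeric matrix (cells in rows).
#' @param sigmaMode `"plain"` (per-gene sd) or `"trend"` (mean-variance
#'   trend expected sd).
#' @return list with `z` (cells x genes), `means`, `sds` (the sigma used),
#'   and `zeroVariance` (logical per gene).
#' @examples
#' zscoreGenes(cbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5)))$z
#' @export
zscoreGenes <- function(x, sigmaMode = c("plain", "trend")) {
    sigmaMode <- match.arg(sigmaMode)
    x <- as.matrix(x)
    if (nrow(x) < 2L) {
        stop("at least 2 cells are required: variance is undefined for a ",
            "single cell")
    }
    if (!all(is.finite(x))) stop("input matrix must be finite")
    means <- colMeans(x)
    ## population (ddof = 0) variance
    vars <- colMeans(x^2) - means^2
    vars[vars < 0] <- 0
    sds <- sqrt(vars)
    zeroVar <- sds == 0
    if (sigmaMode == "trend") {
        sds <- trend_expected_sd(means, vars)
        sds[zeroVar] <- 0
    }
    safe <- ifelse(zeroVar, 1, sds)
    z <- sweep(sweep(x, 2L, means, "-"), 2L, safe, "/")
    z[, zeroVar] <- 0
    list(z = z, means = means, sds = sds, zeroVariance = zeroVar)
}

## Expected sd at each gene's mean from a lowess fit of variance on mean.
## Falls back to the plain sd where the fitted variance is non-positive.
trend_expected_sd <- function(means, vars) {
    ok <- vars > 0
    if (sum(ok) < 3L) return(sqrt(vars))
    fit <- lowess(means[ok], vars[ok], f = 0.5)
    fitted <- approx(fit$x, fit$y, xout = means, rule = 2, ties = mean)$y
    out <- sqrt(ifelse(fitted > 0, fitted, vars))
    out
}

#' Rank genes by normalised dispersion and select the top set
#'
#' Computes per-gene mean and dispersion (variance / mean), standardises
#' the dispersion within mean-bins (equal-frequency bins; a bin whose
#' dispersion spread is zero contributes 0), and ranks genes by the
#' binned, standardised ("normalised") dispersion, largest first. Ties are
#' broken by gene index, and zero-variance genes always rank after every
#' gene with positive dispersion. Cell order cannot influence the result.
#'
#' @param x cells x genes matrix, or a `SummarizedExperiment` whose
#'   `counts` assay is used (transposed internally).
#' @param nTop number of genes to select (`1 <= nTop <= n_genes`).
#' @param nBins number of mean-bins for dispersion standardisation.
#' @param log1p apply `log1p` before computing the statistics (recommended
#'   for raw counts).
#' @return A `DataFrame` with one row per gene (`gene_id`, `mean`,
#'   `variance`, `dispersion`, `norm_dispersion`, `rank`, `selected`);
#'   `metadata(.)$nSelected` and `metadata(.)$selectedGenes` record the
#'   selection (in rank order).
#' @examples
#' sce <- simulateCounts(simulationConfig(nGenes = 30, nCells = 60, seed = 5))
#' rep <- selectHvg(sce, nTop = 10)
#' S4Vectors::metadata(rep)$selectedGenes
#' @export
selectHvg <- function(x, nTop, nBins = 20L, log1p = FALSE) {
    m <- as_cells_by_genes(x)
    if (log1p) m <- log1p(m)
    nGenes <- ncol(m)
    if (length(nTop) != 1L || is.na(nTop) || nTop <= 0) {
        stop("'nTop' must be a positive integer")
    }
    if (nTop > nGenes) stop("'nTop' cannot exceed the number of genes")
    if (any(m < 0)) stop("expression values must be non-negative")
    means <- colMeans(m)
    vars <- apply(m, 2L, var)
    disp <- ifelse(means > 0, vars / means, 0)
    posVar <- vars > 0
    normDisp <- rep(0, nGenes)
    if (any(posVar)) {
        breaks <- unique(quantile(means[posVar],
            probs = seq(0, 1, length.out = nBins + 1L)))
        if (length(breaks) < 2L) {
            bins <- factor(rep(1L, sum(posVar)))
        } else {
            bins <- cut(means[posVar], breaks = breaks, include.lowest = TRUE)
        }
        d <- disp[posVar]
        for (b in levels(bins)) {
            idx <- bins == b
            if (sum(idx) >= 2L && sd(d[idx]) > 0) {
                normDisp[posVar][idx] <- (d[idx] - mean(d[idx])) / sd(d[idx])
            } else {
                normDisp[posVar][idx] <- 0
            }
        }
    }
    ## zero-variance genes sort after every positive-dispersion gene
    sortKey <- ifelse(posVar, normDisp, -Inf)
    ord <- order(-sortKey, seq_len(nGenes))
    rank <- integer(nGenes)
    rank[ord] <- seq_len(nGenes)
    geneIds <- colnames(m) %||% sprintf("Gene%04d", seq_len(nGenes))
    selected <- rank <= nTop
    rep <- DataFrame(
        gene_id = geneIds, mean = means, variance = vars,
        dispersion = disp, norm_dispersion = normDisp,
        rank = rank, selected = selected, row.names = geneIds
    )
    metadata(rep)$nSelected <- as.integer(nTop)
    metadata(rep)$selectedGenes <- geneIds[ord][seq_len(nTop)]
    rep
}

#' Rescale a z-score matrix into the unit interval
#'
#' Per-gene affine min-max mapping into `[0, 1]`, as required by the
#' binary-cross-entropy reconstruction loss. Constant columns map to 0.5 by
#' convention and invert back to the constant. The bounds are returned so
#' the map is exactly invertible via [inverseRescale()].
#'
#' @param z cells x genes numeric matrix.
#' @return list with `values` (in `[0, 1]`), `scaleMin`, `scaleMax`.
#' @examples
#' rescaleUnit(cbind(c(-1, 0, 1)))$values
#' @export
rescaleUnit <- function(z) {
    z <- as.matrix(z)
    if (!all(is.finite(z))) stop("z-score matrix must be finite")
    lo <- apply(z, 2L, min)
    hi <- apply(z, 2L, max)
    rng <- hi - lo
    safe <- ifelse(rng == 0, 1, rng)
    v <- sweep(sweep(z, 2L, lo, "-"), 2L, safe, "/")
    v[, rng == 0] <- 0.5
    list(values = v, scaleMin = lo, scaleMax = hi)
}

#' Invert the unit-interval rescaling
#'
#' @param values cells x genes matrix in `[0, 1]`.
#' @param scaleMin,scaleMax per-gene bounds stored by [rescaleUnit()].
#' @return The z-score-scale matrix.
#' @export
inverseRescale <- function(values, scaleMin, scaleMax) {
    values <- as.matrix(values)
    sweep(sweep(values, 2L, scaleMax - scaleMin, "*"), 2L, scaleMin, "+")
}

#' Preprocess a count matrix into network input
#'
#' The full deterministic preprocessing chain: optional `log1p`,
#' dispersion-based selection of the top `nTop` highly variable genes,
#' per-gene z-scoring ([zscoreGenes()]), and per-gene min-max rescaling
#' into `[0, 1]` ([rescaleUnit()]). Genes whose variance is zero are
#' excluded from the selection (they carry no signal and cannot be
#' standardised). Every statistic needed to invert the transform is stored
#' in the returned [NormalizedExpression-class].
#'
#' @param x genes x cells `SummarizedExperiment` (assay `counts`) or a
#'   cells x genes numeric matrix.
#' @param nTop number of highly variable genes (default
#'   `min(2000, n_genes)`).
#' @param log1p apply `log1p` to raw counts before z-scoring.
#' @param sigmaMode passed to [zscoreGenes()].
#' @param nBins passed to [selectHvg()].
#' @param labels optional per-cell labels; taken from
#'   `colData(x)$cell_type` when `x` is a `SummarizedExperiment`.
#' @return A [NormalizedExpression-class].
#' @examples
#' sce <- simulateCounts(simulationConfig(nGenes = 40, nCells = 80, seed = 6))
#' ne <- preprocessCounts(sce, nTop = 20)
#' dim(normValues(ne))
#' @export
preprocessCounts <- function(x, nTop = NULL, log1p = TRUE,
    sigmaMode = c("plain", "trend"), nBins = 20L, labels = NULL) {
    sigmaMode <- match.arg(sigmaMode)
    if (is(x, "SummarizedExperiment") && is.null(labels) &&
        "cell_type" %in% colnames(colData(x))) {
        labels <- colData(x)$cell_type
    }
    m <- as_cells_by_genes(x)
    if (is.null(colnames(m))) colnames(m) <- sprintf("Gene%04d", seq_len(ncol(m)))
    if (is.null(rownames(m))) rownames(m) <- sprintf("Cell%05d", seq_len(nrow(m)))
    expr <- if (log1p) log1p(m) else m
    if (is.null(nTop)) nTop <- min(2000L, ncol(expr))
    hvg <- selectHvg(expr, nTop = nTop, nBins = nBins, log1p = FALSE)
    sel <- metadata(hvg)$selectedGenes
    ## drop zero-variance genes from the selection: they cannot be z-scored
    zeroVarGenes <- hvg$gene_id[hvg$variance == 0]
    if (any(sel %in% zeroVarGenes)) {
        warning(sum(sel %in% zeroVarGenes), " selected gene(s) have zero ",
            "variance and were dropped from the network input")
        sel <- setdiff(sel, zeroVarGenes)
    }
    if (length(sel) < 2L) {
        stop("fewer than 2 genes with positive variance; nothing to model")
    }
    sub <- expr[, sel, drop = FALSE]
    zs <- zscoreGenes(sub, sigmaMode = sigmaMode)
    rs <- rescaleUnit(zs$z)
    new("NormalizedExpression",
        values = rs$values, zScores = zs$z,
        selectedGenes = sel,
        geneMeans = unname(zs$means), geneSds = unname(zs$sds),
        scaleMin = unname(rs$scaleMin), scaleMax = unname(rs$scaleMax),
        cellIds = rownames(m),
        cellLabels = if (is.null(labels)) factor() else as.factor(labels),
        log1pApplied = log1p, hvgReport = hvg
    )
}

#' Invert the preprocessing transform
#'
#' Maps network-scale values back towards the original expression scale:
#' `"zscore"` undoes only the min-max rescaling; `"expression"`
#' additionally undoes the z-score (`z * sigma_m + Gbar_m`); `"counts"`
#' further applies `expm1` when `log1p` was part of the forward transform.
#'
#' @param ne a [NormalizedExpression-class].
#' @param values optional cells x genes matrix on the `[0, 1]` scale
#'   (defaults to `normValues(ne)`); a denoised reconstruction, typically.
#' @param to target scale.
#' @return cells x genes matrix on the requested scale.
#' @examples
#' sce <- simulateCounts(simulationConfig(nGenes = 40, nCells = 80, seed = 6))
#' ne <- preprocessCounts(sce, nTop = 20)
#' back <- inverseTransform(ne, to = "counts")
#' @export
inverseTransform <- function(ne, values = NULL,
    to = c("zscore", "expression", "counts")) {
    stopifnot(is(ne, "NormalizedExpression"))
    to <- match.arg(to)
    v <- values %||% ne@values
    z <- inverseRescale(v, ne@scaleMin, ne@scaleMax)
    if (to == "zscore") return(z)
    expr <- sweep(sweep(z, 2L, ne@geneSds, "*"), 2L, ne@geneMeans, "+")
    if (to == "expression") return(expr)
    if (ne@log1pApplied) expm1(expr) else expr
}

#' @rdname NormalizedExpression-class
#' @param ne a `NormalizedExpression`
#' @return `normValues`: the `[0, 1]` network input matrix (cells x genes).
#' @export
normValues <- function(ne) ne@values

#' @rdname NormalizedExpression-class
#' @return `zScores`: the z-score matrix (cells x genes).
#' @export
zScores <- function(ne) ne@zScores

#' @rdname NormalizedExpression-class
#' @return `selectedGenes`: ordered selected gene identifiers.
#' @export
selectedGenes <- function(ne) ne@selectedGenes

#' @rdname NormalizedExpression-class
#' @return `cellLabels`: per-cell label factor (length 0 when absent).
#' @export
cellLabels <- function(ne) ne@cellLabels

#' @describeIn NormalizedExpression-class compact summary
#' @param object a `NormalizedExpression`
#' @export
setMethod("show", "NormalizedExpression", function(object) {
    cat("NormalizedExpression:", nrow(object@values), "cells x",
        ncol(object@values), "genes (unit-scaled z-scores)\n")
    cat("  log1p:", object@log1pApplied, "| labels:",
        if (length(object@cellLabels)) {
            paste(nlevels(object@cellLabels), "levels")
        } else {
            "absent"
        }, "\n")
})
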