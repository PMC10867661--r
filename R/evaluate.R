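#' Silhouette score over known labels
#'
#' For each cell `i` with cluster `c_i`:
#' `a_i = mean_{j in c_i, j != i} d(i, j)` (mean intra-cluster distance),
#' `b_i = min_{k != c_i} mean_{j in C_k} d(i, j)` (mean distance to the
#' nearest other cluster), and `s_i = (b_i - a_i) / max(a_i, b_i)`.
#' The mean of `s_i` over cells summarises how well the labels separate
#' in the supplied representation. Cells in singleton clusters have no
#' intra-cluster distance; they are flagged and assigned `s_i = 0`.
#'
#' The statistic is computed directly on the supplied matrix (expression,
#' z-scores, a denoised layer, or any precomputed embedding) — pass a 2-D
#' embedding explicitly if silhouettes in an embedding space are wanted.
#'
#' @param x cells x features numeric matrix, or a `dist` object.
#' @param labels per-cell cluster labels (>= 2 distinct values).
#' @param metric `"euclidean"` or `"manhattan"` (ignored for `dist`
#'   input).
#' @return A [SilhouetteResult-class].
#' @examples
#' x <- rbind(matrix(0, 2, 2), matrix(1, 2, 2))
#' silhouetteScore(x, c("a", "a", "b", "b"))@meanSilhouette # 1
#' @export
silhouetteScore <- function(x, labels, metric = c("euclidean", "manhattan")) {
    metric <- match.arg(metric)
    if (inherits(x, "dist")) {
        D <- as.matrix(x)
    } else {
        x <- as.matrix(x)
        if (!all(is.finite(x))) stop("matrix must be finite")
        D <- as.matrix(stats::dist(x, method = metric))
    }
    labels <- as.factor(labels)
    labels <- droplevels(labels)
    n <- nrow(D)
    if (length(labels) != n) {
        stop("labels length must equal the number of cells")
    }
    if (nlevels(labels) < 2L) {
        stop("at least 2 clusters are required: the nearest-other-cluster ",
            "distance is undefined for a single cluster")
    }
    ind <- stats::model.matrix(~ labels - 1) # n x k indicator
    sizes <- colSums(ind)
    sums <- D %*% ind # n x k: total distance from cell i to cluster k
    k <- ncol(ind)
    own <- ind == 1
    a <- numeric(n)
    b <- numeric(n)
    singleton <- logical(n)
    for (i in seq_len(n)) {
        ki <- which(own[i, ])
        if (sizes[ki] == 1L) {
            singleton[i] <- TRUE
            a[i] <- NA_real_
        } else {
            a[i] <- sums[i, ki] / (sizes[ki] - 1)
        }
        b[i] <- min(sums[i, -ki] / sizes[-ki])
    }
    s <- ifelse(singleton, 0, (b - a) / pmax(a, b))
    s[!singleton & a == 0 & b == 0] <- 0
    res <- new("SilhouetteResult",
        s = as.numeric(s), a = as.numeric(a), b = as.numeric(b),
        singleton = singleton, meanSilhouette = mean(s),
        metric = metric, labels = labels
    )
    validObject(res)
    res
}

#' @rdname SilhouetteResult-class
#' @param x a `SilhouetteResult`
#' @return `meanSilhouette`: the mean silhouette width.
#' @export
meanSilhouette <- function(x) x@meanSilhouette

#' @describeIn SilhouetteResult-class compact summary
#' @param object a `SilhouetteResult`
#' @export
setMethod("show", "SilhouetteResult", function(object) {
    cat("SilhouetteResult:", length(object@s), "cells,",
        nlevels(object@labels), "clusters (", object@metric, ")\n")
    cat("  mean silhouette:", format(object@meanSilhouette, digits = 4),
        if (any(object@singleton)) {
            sprintf("| %d singleton cell(s) scored 0",
                sum(object@singleton))
        } else {
            ""
        }, "\n")
})

#' Squared correlation between pseudo-time and annotated stages
#'
#' Fits the simple regression of the pseudo-time vector `y` on numeric
#' stage codes `x` through the closed form `b = r * s_y / s_x`,
#' `a = ybar - b * xbar`, and reports Pearson's `r` and `r^2`. A high
#' `r^2` indicates the inferred ordering tracks the annotated stages.
#' Ordered/factor stages are mapped to codes 0, 1, 2, ... in level order
#' (characters: order of first appearance); numeric stages are used as
#' given. If either vector has zero variance the fit is flagged
#' `degenerate` and `r`/`r^2` are `NA` rather than silently 0.
#'
#' @param pseudotime per-cell numeric pseudo-time values (from any
#'   trajectory method; this package evaluates, it does not infer).
#' @param stages per-cell annotated stages (ordered factor, factor,
#'   character or numeric) with at least 2 distinct values.
#' @return A [PseudotimeFit-class].
#' @examples
#' pseudotimeR2(c(0.1, 0.9, 2.1, 2.9), c("E1", "E1", "E2", "E2"))@rSquared
#' @export
pseudotimeR2 <- function(pseudotime, stages) {
    y <- as.numeric(pseudotime)
    if (length(y) < 3L) stop("at least 3 cells are required")
    if (length(stages) != length(y)) {
        stop("stages and pseudotime must have equal length")
    }
    if (is.numeric(stages)) {
        x <- as.numeric(stages)
    } else if (is.factor(stages)) {
        x <- as.numeric(stages) - 1
    } else {
        x <- as.numeric(factor(stages, levels = unique(stages))) - 1
    }
    if (length(unique(x)) < 2L) {
        stop("stages must contain at least 2 distinct values")
    }
    sx <- sd(x)
    sy <- sd(y)
    if (sx == 0 || sy == 0) {
        return(new("PseudotimeFit",
            slope = NA_real_, intercept = NA_real_,
            r = NA_real_, rSquared = NA_real_,
            x = x, y = y, degenerate = TRUE
        ))
    }
    r <- cor(x, y)
    b <- r * sy / sx
    a <- mean(y) - b * mean(x)
    new("PseudotimeFit",
        slope = b, intercept = a, r = r, rSquared = r^2,
        x = x, y = y, degenerate = FALSE
    )
}

#' @describeIn PseudotimeFit-class compact summary
#' @param object a `PseudotimeFit`
#' @export
setMethod("show", "PseudotimeFit", function(object) {
    if (object@degenerate) {
        cat("PseudotimeFit: degenerate (zero variance); r^2 undefined\n")
    } else {
        cat(sprintf(
            "PseudotimeFit: y = %.4g + %.4g x | r = %.4f, r^2 = %.4f\n",
            object@intercept, object@slope, object@r, object@rSquared))
    }
})

#' Raw-versus-denoised benchmark over simulated scenarios
#'
#' For each scenario, simulates the dataset ([simulateDataset()]),
#' preprocesses it, scores the mean silhouette over the true labels on
#' the raw z-scores, runs the full denoising pipeline
#' ([denoiseCounts()]), and scores the denoised matrix the same way.
#' Numbers only — one `raw` and one `denoised` row per scenario.
#'
#' @param scenarios list of [SimulationConfig-class] objects (give each a
#'   name for readable output).
#' @param nTop,searchConfig,template,finalEpochs,outputScale passed to
#'   [denoiseCounts()].
#' @param seed pipeline seed (simulation seeds live in the scenarios).
#' @return `data.frame` with columns `scenario`, `n_groups`, `dropout`,
#'   `sim_seed`, `condition` (`raw`/`denoised`), `mean_silhouette`,
#'   `selected_batch_size`.
#' @export
compareConditions <- function(scenarios, nTop = NULL,
    searchConfig = batchSearchConfig(), template = aaeTemplate(),
    finalEpochs = searchConfig@finalEpochs, outputScale = "zscore",
    seed = 1L) {
    if (is(scenarios, "SimulationConfig")) scenarios <- list(scenarios)
    names(scenarios) <- names(scenarios) %||%
        sprintf("scenario%d", seq_along(scenarios))
    rows <- lapply(names(scenarios), function(nm) {
        cfg <- scenarios[[nm]]
        sce <- simulateDataset(cfg)
        den <- denoiseCounts(sce, nTop = nTop, searchConfig = searchConfig,
            template = template, finalEpochs = finalEpochs,
            outputScale = outputScale, seed = seed)
        labels <- colData(sce)$cell_type
        ne <- metadata(den)$normalized
        rawSil <- meanSilhouette(silhouetteScore(zScores(ne), labels))
        denSil <- meanSilhouette(silhouetteScore(
            t(assay(den, "dbaae_denoised")), labels))
        data.frame(
            scenario = nm, n_groups = cfg@nGroups,
            dropout = cfg@dropoutEnabled, sim_seed = cfg@seed,
            condition = c("raw", "denoised"),
            mean_silhouette = c(rawSil, denSil),
            selected_batch_size = metadata(den)$selectedBatchSize
        )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
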