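## Internal helpers shared across modules.

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream. Mersenne-Twister is forced so results are platform-stable.
with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        get(".Random.seed", envir = globalenv())
    } else {
        NULL
    }
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
                rm(".Random.seed", envir = globalenv())
            }
        } else {
            assign(".Random.seed", old, envir = globalenv())
        }
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
    force(expr)
}

## Derive a child seed from a base seed; keeps results < 2^31 - 1.
derive_seed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 12347) %%
        2147483587)
}

## Probability clipping ahead of log() terms in the losses.
PROB_EPS <- 1e-7

clip_prob <- function(p, eps = PROB_EPS) {
    pmin(pmax(p, eps), 1 - eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Coerce assorted inputs to a dense cells x genes matrix.
as_cells_by_genes <- function(x) {
    if (methods::is(x, "SummarizedExperiment")) {
        m <- SummarizedExperiment::assay(x, "counts")
        m <- t(as.matrix(m))
    } else {
        m <- as.matrix(x)
    }
    storage.mode(m) <- "double"
    m
}
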