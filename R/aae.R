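## ---- dense-stack primitives -------------------------------------------
## A network is a list of layers, each list(W = in x out matrix, b = out).
## Hidden layers use LeakyReLU; the final layer uses a named activation.

act_forward <- function(name, u, slope) {
    switch(name,
        leaky = pmax(u, 0) + slope * pmin(u, 0),
        relu = pmax(u, 0),
        sigmoid = plogis(u),
        linear = u,
        stop("unknown activation: ", name)
    )
}

## derivative of the activation, expressed via pre-activation u and output h
act_deriv <- function(name, u, h, slope) {
    switch(name,
        leaky = slope + (1 - slope) * (u > 0),
        relu = (u > 0) * 1,
        sigmoid = h * (1 - h),
        linear = 1,
        stop("unknown activation: ", name)
    )
}

glorot_init <- function(dims) {
    lapply(seq_len(length(dims) - 1L), function(i) {
        fanIn <- dims[i]
        fanOut <- dims[i + 1L]
        lim <- sqrt(6 / (fanIn + fanOut))
        list(
            W = matrix(runif(fanIn * fanOut, -lim, lim),
                nrow = fanIn, ncol = fanOut),
            b = numeric(fanOut)
        )
    })
}

## forward pass keeping the per-layer cache needed by backprop
mlp_forward <- function(layers, X, slope, finalAct) {
    nL <- length(layers)
    h <- vector("list", nL + 1L)
    u <- vector("list", nL)
    h[[1L]] <- X
    for (l in seq_len(nL)) {
        u[[l]] <- h[[l]] %*% layers[[l]]$W +
            rep(layers[[l]]$b, each = nrow(X))
        act <- if (l == nL) finalAct else "leaky"
        h[[l + 1L]] <- act_forward(act, u[[l]], slope)
    }
    list(out = h[[nL + 1L]], h = h, u = u)
}

## backward pass; dOut = dL/d(output activation). Returns per-layer grads
## and dL/dX for chaining through upstream networks.
mlp_backward <- function(layers, cache, dOut, slope, finalAct) {
    nL <- length(layers)
    grads <- vector("list", nL)
    d <- dOut
    for (l in rev(seq_len(nL))) {
        act <- if (l == nL) finalAct else "leaky"
        dPre <- d * act_deriv(act, cache$u[[l]], cache$h[[l + 1L]], slope)
        grads[[l]] <- list(
            W = crossprod(cache$h[[l]], dPre),
            b = colSums(dPre)
        )
        d <- tcrossprod(dPre, layers[[l]]$W)
    }
    list(grads = grads, dX = d)
}

## RMSprop: v <- rho v + (1 - rho) g^2 ; w <- w - lr g / (sqrt(v) + eps)
rmsprop_init <- function(layers) {
    lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
}

rmsprop_update <- function(layers, grads, state, lr, rho = 0.9, eps = 1e-7) {
    for (l in seq_along(layers)) {
        for (p in c("W", "b")) {
            g <- grads[[l]][[p]]
            state[[l]][[p]] <- rho * state[[l]][[p]] + (1 - rho) * g^2
            layers[[l]][[p]] <- layers[[l]][[p]] -
                lr * g / (sqrt(state[[l]][[p]]) + eps)
        }
    }
    list(layers = layers, state = state)
}

## Deep-copy the trainable state so that in-place C-level updates cannot
## be observed through any other binding.
copy_layers <- function(layers) {
    lapply(layers, function(l) list(W = l$W + 0, b = l$b + 0))
}

copy_model_state <- function(model) {
    model@encoder <- copy_layers(model@encoder)
    model@decoder <- copy_layers(model@decoder)
    model@discriminator <- copy_layers(model@discriminator)
    model@optState <- list(
        ae = list(encoder = copy_layers(model@optState$ae$encoder),
            decoder = copy_layers(model@optState$ae$decoder)),
        gen = copy_layers(model@optState$gen),
        disc = copy_layers(model@optState$disc)
    )
    model
}

## ---- model construction ------------------------------------------------

#' Construct an adversarial autoencoder model
#'
#' Builds the three networks with seeded Glorot-uniform weights and zero
#' biases. Default dimensions follow the reference architecture: encoder
#' `input-1024-512-512` (latent width 512), decoder mirrored, discriminator
#' `512-256-1`. Hidden layers are LeakyReLU throughout; the decoder and
#' discriminator end in a sigmoid so the binary-cross-entropy and
#' adversarial losses are defined, while the encoder output is ReLU (all
#' final activations are overridable).
#'
#' @param inputDim width of the input (number of selected genes).
#' @param hiddenDims encoder widths after the input layer; the last entry
#'   is the latent width.
#' @param discDims discriminator widths after its (latent-wide) input; the
#'   last entry must be 1.
#' @param leakySlope LeakyReLU negative-half slope.
#' @param outputActivations named character overriding the final
#'   activations (`encoder`, `decoder`, `discriminator`).
#' @param learningRate RMSprop learning rate for all three optimizers.
#' @param genMode generator-loss form, `"paper"` or `"nonsaturating"`; see
#'   [generatorLoss()].
#' @param seed integer seed for weight initialisation.
#' @return An [AAEModel-class].
#' @examples
#' m <- aaeModel(inputDim = 20, hiddenDims = c(16, 8, 8),
#'     discDims = c(4, 1), seed = 1)
#' dim(encodeCells(m, matrix(runif(100), 5, 20)))
#' @export
aaeModel <- function(inputDim, hiddenDims = c(1024L, 512L, 512L),
    discDims = c(256L, 1L), leakySlope = 0.2,
    outputActivations = c(encoder = "relu", decoder = "sigmoid",
        discriminator = "sigmoid"),
    learningRate = 2e-5, genMode = c("paper", "nonsaturating"), seed = 1L) {
    genMode <- match.arg(genMode)
    encoderDims <- as.integer(c(inputDim, hiddenDims))
    decoderDims <- rev(encoderDims)
    latent <- encoderDims[length(encoderDims)]
    discriminatorDims <- as.integer(c(latent, discDims))
    nets <- with_seed(seed, list(
        encoder = glorot_init(encoderDims),
        decoder = glorot_init(decoderDims),
        discriminator = glorot_init(discriminatorDims)
    ))
    model <- new("AAEModel",
        encoderDims = encoderDims, decoderDims = decoderDims,
        discriminatorDims = discriminatorDims,
        encoder = nets$encoder, decoder = nets$decoder,
        discriminator = nets$discriminator,
        leakySlope = leakySlope,
        outputActivations = outputActivations,
        learningRate = learningRate, genMode = genMode,
        optState = list(
            ae = list(encoder = rmsprop_init(nets$encoder),
                decoder = rmsprop_init(nets$decoder)),
            gen = rmsprop_init(nets$encoder),
            disc = rmsprop_init(nets$discriminator)
        ),
        seed = as.integer(seed)
    )
    validObject(model)
    model
}

#' @rdname AAEModel-class
#' @param model an `AAEModel`
#' @return `latentDim`: the latent-code width.
#' @export
latentDim <- function(model) {
    model@encoderDims[length(model@encoderDims)]
}

check_width <- function(x, expected, what) {
    if (ncol(x) != expected) {
        stop(sprintf("%s has width %d but the model expects %d",
            what, ncol(x), expected))
    }
}

#' Encode a batch into latent codes
#'
#' Applies the stacked encoder layers (`LeakyReLU(X W_e)` per layer, final
#' activation per the model) to a cells x genes batch.
#'
#' @param model an [AAEModel-class].
#' @param x batch matrix (rows = cells) of width `encoderDims[1]`.
#' @return batch x latent matrix.
#' @export
encodeCells <- function(model, x) {
    x <- as.matrix(x)
    check_width(x, model@encoderDims[1L], "encoder input")
    mlp_forward(model@encoder, x, model@leakySlope,
        model@outputActivations[["encoder"]])$out
}

#' Decode latent codes into reconstructions
#'
#' Applies the mirrored decoder stack; the default sigmoid output maps
#' reconstructions into `[0, 1]`, matching the network-input scale.
#'
#' @param model an [AAEModel-class].
#' @param z latent matrix (rows = cells) of width `latentDim(model)`.
#' @return batch x input-width reconstruction.
#' @export
decodeCells <- function(model, z) {
    z <- as.matrix(z)
    check_width(z, latentDim(model), "decoder input")
    out <- mlp_forward(model@decoder, z, model@leakySlope,
        model@outputActivations[["decoder"]])$out
    if (model@outputActivations[["decoder"]] == "relu") {
        out <- pmin(out, 1) # keep the BCE target range under a relu head
    }
    out
}

## ---- losses ------------------------------------------------------------

#' Binary-cross-entropy reconstruction loss
#'
#' `L_rec = -mean(x log x' + (1 - x) log(1 - x'))`, averaged over all
#' elements, with `x'` clipped to `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param x,xPrime matrices of identical shape with entries in `[0, 1]`.
#' @return non-negative scalar.
#' @examples
#' reconstructionLoss(c(1, 0), c(0.5, 0.5)) # log 2
#' @export
reconstructionLoss <- function(x, xPrime) {
    x <- as.matrix(x)
    xPrime <- as.matrix(xPrime)
    if (!all(dim(x) == dim(xPrime))) {
        stop("input and reconstruction must have identical shapes")
    }
    xp <- clip_prob(xPrime)
    -mean(x * log(xp) + (1 - x) * log(1 - xp))
}

check_probs <- function(p, what) {
    if (any(p < 0 | p > 1)) {
        stop(what, " must lie in [0, 1]: the discriminator output ",
            "contract is broken")
    }
    clip_prob(p)
}

#' Generator loss
#'
#' In the default `"paper"` mode the loss is
#' `L_gen = -mean(log(1 - D(l_e(x'))))`, the literal published form. Note
#' this form rewards making reconstructed-batch latent codes easy for the
#' discriminator to reject; the conventional adversarial objective is the
#' `"nonsaturating"` mode, `-mean(log(D(l_e(x'))))`. Both are provided;
#' see the package vignette for discussion.
#'
#' @param dFake discriminator outputs on latent codes of reconstructions,
#'   in `[0, 1]`.
#' @param mode `"paper"` (default) or `"nonsaturating"`.
#' @return scalar loss.
#' @examples
#' generatorLoss(0.5) # log 2 in paper mode
#' @export
generatorLoss <- function(dFake, mode = c("paper", "nonsaturating")) {
    mode <- match.arg(mode)
    p <- check_probs(dFake, "dFake")
    if (mode == "paper") -mean(log(1 - p)) else -mean(log(p))
}

#' Discriminator loss
#'
#' `L_disc = -mean(log D(l_e(x)) + log(1 - D(l_e(x'))))`: the standard
#' binary classification loss on real (current-batch latent) versus fake
#' (reconstruction latent) codes.
#'
#' @param dReal,dFake discriminator outputs in `[0, 1]`, equal length.
#' @return non-negative scalar.
#' @examples
#' discriminatorLoss(0.5, 0.5) # 2 log 2
#' @export
discriminatorLoss <- function(dReal, dFake) {
    if (length(dReal) != length(dFake)) {
        stop("dReal and dFake must have equal length")
    }
    pr <- check_probs(dReal, "dReal")
    pf <- check_probs(dFake, "dFake")
    -mean(log(pr) + log(1 - pf))
}

## ---- adversarial training step ----------------------------------------

#' One adversarial training step
#'
#' Implements the per-batch protocol: (1) the autoencoder (encoder +
#' decoder) is updated on the reconstruction loss for the current batch
#' `x_b`; (2) the discriminator is updated to separate the "authentic"
#' latent code `z_b = l_e(x_b)` from the "simulated" code
#' `n_r = l_e(x'_prev)`, the encoding of the previous batch's
#' reconstruction; (3) the generator path (the encoder acting on
#' `x'_prev`, through the frozen discriminator) is updated on the
#' generator loss. On the very first step, where no prior reconstruction
#' exists, the current batch's own reconstruction is used with gradients
#' blocked. Each parameter group has an independent RMSprop state.
#'
#' @param model an [AAEModel-class].
#' @param xB current batch (rows = cells) in `[0, 1]`.
#' @param priorRecon reconstruction of the previous batch, or `NULL` on
#'   the first step.
#' @param inPlace internal fast path used by [trainAAE()]: update the
#'   weight and optimizer tensors in place instead of copying them. Only
#'   safe when the caller owns the model exclusively (e.g. after
#'   deep-copying it once per training run); results are identical either
#'   way.
#' @return list with `model` (updated), `losses` (named: `L_rec`, `L_gen`,
#'   `L_disc`, `a_loss` = `L_gen + L_disc`, and `disc_accuracy`, the
#'   0.5-threshold classification accuracy), and `recon` (`x'_b`, to pass
#'   as the next step's `priorRecon`).
#' @export
adversarialStep <- function(model, xB, priorRecon = NULL, inPlace = FALSE) {
    xB <- as.matrix(xB)
    if (nrow(xB) == 0L) stop("batch must be non-empty")
    check_width(xB, model@encoderDims[1L], "batch")
    slope <- model@leakySlope
    actE <- model@outputActivations[["encoder"]]
    actD <- model@outputActivations[["decoder"]]
    actDisc <- model@outputActivations[["discriminator"]]
    lr <- model@learningRate
    n <- nrow(xB)

    ## All forward passes are taken on the current weights; the three
    ## parameter-group updates are computed from that single snapshot and
    ## applied together (simultaneous update).

    ## (1) autoencoder gradients on L_rec
    cacheE <- mlp_forward(model@encoder, xB, slope, actE)
    zB <- cacheE$out
    cacheD <- mlp_forward(model@decoder, zB, slope, actD)
    recon <- cacheD$out
    lRec <- reconstructionLoss(xB, recon)
    if (!is.finite(lRec)) {
        stop("non-finite reconstruction loss (L_rec); training aborted")
    }
    xp <- clip_prob(recon)
    dRecon <- (-(xB / xp) + (1 - xB) / (1 - xp)) / length(xB)
    bwdD <- mlp_backward(model@decoder, cacheD, dRecon, slope, actD)
    bwdE <- mlp_backward(model@encoder, cacheE, bwdD$dX, slope, actE)

    if (is.null(priorRecon)) priorRecon <- recon # detached by construction
    priorRecon <- as.matrix(priorRecon)
    check_width(priorRecon, model@encoderDims[1L], "prior reconstruction")

    ## (2) discriminator gradients: real = l_e(x_b), fake = l_e(x'_prev)
    cacheG <- mlp_forward(model@encoder, priorRecon, slope, actE)
    cacheR <- mlp_forward(model@discriminator, zB, slope, actDisc)
    cacheF <- mlp_forward(model@discriminator, cacheG$out, slope, actDisc)
    pR <- clip_prob(cacheR$out)
    pF <- clip_prob(cacheF$out)
    ## real and fake batches can differ in size (last incomplete batch
    ## versus the prior batch), so average the two terms separately
    lDisc <- -(mean(log(pR)) + mean(log(1 - pF)))
    if (!is.finite(lDisc)) {
        stop("non-finite discriminator loss (L_disc); training aborted")
    }
    nR <- length(pR)
    nF <- length(pF)
    gR <- mlp_backward(model@discriminator, cacheR,
        -1 / (pR * nR), slope, actDisc)$grads
    gF <- mlp_backward(model@discriminator, cacheF,
        1 / ((1 - pF) * nF), slope, actDisc)$grads
    gSum <- mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
        gR, gF, SIMPLIFY = FALSE)
    discAcc <- (sum(pR > 0.5) + sum(pF <= 0.5)) / (nR + nF)

    ## (3) generator gradients: encoder at x'_prev through the frozen
    ## discriminator (same forward pass as the fake branch above)
    if (model@genMode == "paper") {
        lGen <- -mean(log(1 - pF))
        dP <- 1 / ((1 - pF) * nF)
    } else {
        lGen <- -mean(log(pF))
        dP <- -1 / (pF * nF)
    }
    if (!is.finite(lGen)) {
        stop("non-finite generator loss (L_gen); training aborted")
    }
    dZ <- mlp_backward(model@discriminator, cacheF, dP, slope, actDisc)$dX
    gGen <- mlp_backward(model@encoder, cacheG, dZ, slope, actE)$grads

    ## apply the three updates
    if (inPlace) {
        .rmsprop_step_inplace(model@encoder, bwdE$grads,
            model@optState$ae$encoder, lr, 0.9, 1e-7)
        .rmsprop_step_inplace(model@decoder, bwdD$grads,
            model@optState$ae$decoder, lr, 0.9, 1e-7)
        .rmsprop_step_inplace(model@discriminator, gSum,
            model@optState$disc, lr, 0.9, 1e-7)
        .rmsprop_step_inplace(model@encoder, gGen, model@optState$gen,
            lr, 0.9, 1e-7)
    } else {
        updE <- rmsprop_update(model@encoder, bwdE$grads,
            model@optState$ae$encoder, lr)
        updD <- rmsprop_update(model@decoder, bwdD$grads,
            model@optState$ae$decoder, lr)
        model@encoder <- updE$layers
        model@decoder <- updD$layers
        model@optState$ae$encoder <- updE$state
        model@optState$ae$decoder <- updD$state
        updDisc <- rmsprop_update(model@discriminator, gSum,
            model@optState$disc, lr)
        model@discriminator <- updDisc$layers
        model@optState$disc <- updDisc$state
        updGen <- rmsprop_update(model@encoder, gGen, model@optState$gen, lr)
        model@encoder <- updGen$layers
        model@optState$gen <- updGen$state
    }

    list(
        model = model,
        losses = c(L_rec = lRec, L_gen = lGen, L_disc = lDisc,
            a_loss = lGen + lDisc, disc_accuracy = discAcc),
        recon = recon
    )
}

#' Train an adversarial autoencoder
#'
#' Runs [adversarialStep()] over shuffled mini-batches for up to `epochs`
#' epochs (the last, incomplete batch of each epoch is kept, so every cell
#' participates). The previous batch's reconstruction is carried across
#' batches and epochs as the "simulated" latent source. Training stops
#' early when the per-epoch mean reconstruction loss has not improved by
#' more than `tol` for `patience` consecutive epochs.
#'
#' @param model an [AAEModel-class].
#' @param x cells x genes matrix in `[0, 1]` (e.g. [normValues()]).
#' @param epochs maximum number of epochs (default 300).
#' @param batchSize mini-batch size.
#' @param seed integer seed for the per-epoch shuffles.
#' @param patience,tol early-stopping plateau parameters; set
#'   `patience = Inf` to disable.
#' @param shuffle shuffle cells each epoch (deterministic given `seed`).
#' @return list with `model`, `history` (per-step losses, `data.frame`),
#'   `epochLrec` (per-epoch mean L_rec), `minLrec` and `epochsRun`.
#' @export
trainAAE <- function(model, x, epochs = 300L, batchSize = 64L, seed = 1L,
    patience = 20L, tol = 1e-5, shuffle = TRUE) {
    x <- as.matrix(x)
    n <- nrow(x)
    batchSize <- min(batchSize, n)
    model <- copy_model_state(model) # own the tensors: in-place steps below
    hist <- list()
    epochLrec <- numeric(0)
    prior <- NULL
    best <- Inf
    wait <- 0L
    epochsRun <- 0L
    perm_all <- if (epochs > 0L && shuffle) {
        with_seed(seed, replicate(epochs, sample.int(n), simplify = FALSE))
    } else {
        replicate(max(epochs, 0L), seq_len(n), simplify = FALSE)
    }
    for (ep in seq_len(epochs)) {
        perm <- perm_all[[ep]]
        starts <- seq(1L, n, by = batchSize)
        epLosses <- numeric(0)
        for (s in starts) {
            idx <- perm[s:min(s + batchSize - 1L, n)]
            step <- adversarialStep(model, x[idx, , drop = FALSE], prior,
                inPlace = TRUE)
            model <- step$model
            prior <- step$recon
            hist[[length(hist) + 1L]] <- step$losses
            epLosses <- c(epLosses, step$losses[["L_rec"]])
        }
        epochsRun <- ep
        epochLrec <- c(epochLrec, mean(epLosses))
        cur <- epochLrec[ep]
        if (cur < best - tol) {
            best <- cur
            wait <- 0L
        } else {
            wait <- wait + 1L
            if (is.finite(patience) && wait >= patience) break
        }
    }
    history <- if (length(hist)) {
        as.data.frame(do.call(rbind, hist))
    } else {
        data.frame(L_rec = numeric(0), L_gen = numeric(0),
            L_disc = numeric(0), a_loss = numeric(0),
            disc_accuracy = numeric(0))
    }
    list(
        model = model, history = history, epochLrec = epochLrec,
        minLrec = if (nrow(history)) min(history$L_rec) else NA_real_,
        epochsRun = epochsRun
    )
}

#' Reconstruct a full matrix batch by batch
#'
#' Splits the cells into consecutive batches, passes each through
#' encoder + decoder, and reassembles the union of reconstructions in the
#' original cell order. The result is invariant to the batch partition.
#'
#' @param model a trained [AAEModel-class].
#' @param data a [NormalizedExpression-class] or a cells x genes matrix in
#'   `[0, 1]`.
#' @param batchSize batch size (`>= 1`).
#' @return cells x genes matrix in `[0, 1]`, same shape and row order as
#'   the input.
#' @export
reconstructFull <- function(model, data, batchSize = 128L) {
    x <- if (is(data, "NormalizedExpression")) data@values else as.matrix(data)
    stopifnot(batchSize >= 1L)
    n <- nrow(x)
    out <- matrix(0, nrow = n, ncol = ncol(x), dimnames = dimnames(x))
    for (s in seq(1L, n, by = batchSize)) {
        idx <- s:min(s + batchSize - 1L, n)
        z <- encodeCells(model, x[idx, , drop = FALSE])
        out[idx, ] <- decodeCells(model, z)
    }
    out
}

#' Save / load an AAE model checkpoint
#'
#' Checkpoints are a single RDS archive (format version 1) holding the
#' dimensions, activations, seed, weight tensors and optimizer state.
#'
#' @param model an [AAEModel-class].
#' @param path file path.
#' @return `loadAAEModel` returns the restored [AAEModel-class].
#' @export
saveAAEModel <- function(model, path) {
    stopifnot(is(model, "AAEModel"))
    saveRDS(list(format = "dbaae-checkpoint", version = 1L, model = model),
        path)
    invisible(path)
}

#' @rdname saveAAEModel
#' @export
loadAAEModel <- function(path) {
    obj <- readRDS(path)
    if (!identical(obj$format, "dbaae-checkpoint")) {
        stop("not a dbaae model checkpoint: ", path)
    }
    validObject(obj$model)
    obj$model
}

#' @describeIn AAEModel-class compact architecture summary
#' @param object an `AAEModel`
#' @export
setMethod("show", "AAEModel", function(object) {
    cat("AAEModel\n")
    cat("  encoder:", paste(object@encoderDims, collapse = "-"),
        sprintf("(final: %s)\n", object@outputActivations[["encoder"]]))
    cat("  decoder:", paste(object@decoderDims, collapse = "-"),
        sprintf("(final: %s)\n", object@outputActivations[["decoder"]]))
    cat("  discriminator:",
        paste(object@discriminatorDims, collapse = "-"),
        sprintf("(final: %s)\n",
            object@outputActivations[["discriminator"]]))
    cat("  LeakyReLU slope", object@leakySlope, "| RMSprop lr",
        object@learningRate, "| generator loss:", object@genMode,
        "| seed", object@seed, "\n")
})
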