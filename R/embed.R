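#' Fuzzy neighborhood graph
#'
#' The first stage of the manifold embedding: a sparse symmetric graph of
#' local relationships. For each point i, directed weights to its k nearest
#' neighbors are `exp(-max(0, d_ij - rho_i) / sigma_i)` where `rho_i` is the
#' distance to the nearest neighbor and `sigma_i` is calibrated by binary
#' search so the directed weights sum to `log2(k)` (residual < 1e-5). The
#' symmetrized weight is the fuzzy union `w_ij + w_ji - w_ij * w_ji`.
#'
#' @slot nPoints number of points.
#' @slot kNeighbors neighborhood size.
#' @slot rho,sigma per-point nearest-neighbor distance and bandwidth.
#' @slot weights sparse symmetric weight matrix (entries in (0, 1]).
#' @slot metric distance metric name.
#' @export
setClass("FuzzyGraph",
    slots = c(nPoints = "integer", kNeighbors = "integer", rho = "numeric",
              sigma = "numeric", weights = "ANY", metric = "character"))

setMethod("show", "FuzzyGraph", function(object) {
    cat(sprintf("FuzzyGraph: %d points, k = %d, %d nonzero symmetric weights\n",
                object@nPoints, object@kNeighbors,
                Matrix::nnzero(object@weights)))
})

#' Trained parametric embedding model
#'
#' A deterministic neural-network encoder from K-dimensional peak space to a
#' d-dimensional embedding. Because the mapping is an explicit function (not
#' a per-point layout), it can be applied to rows never seen in training --
#' the backfit contract that lets a model trained on a binned cube embed the
#' full-resolution unbinned cube.
#'
#' @slot inputDim,outputDim encoder dimensions (K and d).
#' @slot weights list of layer parameter lists (`W`, `b`).
#' @slot hyper hyperparameter list (kNeighbors, minDist, aCurve, bCurve,
#'   epochs, learningRate, negativeSamples, batchSize, hidden, seed, metric).
#' @slot provenance md5 fingerprint of the training matrix.
#' @export
setClass("EmbeddingModel",
    slots = c(inputDim = "integer", outputDim = "integer", weights = "list",
              hyper = "list", provenance = "character"))

setMethod("show", "EmbeddingModel", function(object) {
    cat(sprintf("EmbeddingModel: %d -> %s -> %d, k = %s, epochs = %s, seed = %s\n",
                object@inputDim,
                paste(object@hyper$hidden, collapse = "-"),
                object@outputDim, object@hyper$kNeighbors,
                object@hyper$epochs, object@hyper$seed))
})

## ---- k nearest neighbors (exact, blockwise) ---------------------------

.exactKnn <- function(X, k, blockRows = 2048L) {
    n <- nrow(X)
    idx <- matrix(0L, n, k)
    dst <- matrix(0, n, k)
    sq <- rowSums(X^2)
    for (start in seq(1L, n, by = blockRows)) {
        end <- min(start + blockRows - 1L, n)
        d2 <- outer(sq[start:end], sq, "+") - 2 * tcrossprod(
            X[start:end, , drop = FALSE], X)
        d2[d2 < 0] <- 0
        for (ii in seq_len(end - start + 1L)) {
            i <- start + ii - 1L
            v <- d2[ii, ]
            v[i] <- Inf  # exclude self
            o <- order(v)[seq_len(k)]
            idx[i, ] <- o
            dst[i, ] <- sqrt(v[o])
        }
    }
    list(idx = idx, dist = dst)
}

## Calibrate sigma_i: sum_j exp(-max(0, d_ij - rho_i)/sigma_i) = log2(k).
.smoothKnnSigma <- function(dists, rho, target, tol = 1e-6, maxIter = 100L) {
    adj <- pmax(0, dists - rho)
    lo <- 0; hi <- Inf; sigma <- 1
    for (it in seq_len(maxIter)) {
        s <- sum(exp(-adj / sigma))
        if (abs(s - target) < tol) break
        if (s > target) { hi <- sigma; sigma <- (lo + hi) / 2 }
        else {
            lo <- sigma
            sigma <- if (is.finite(hi)) (lo + hi) / 2 else sigma * 2
        }
    }
    max(sigma, 1e-12)
}

#' Build the fuzzy neighborhood graph
#'
#' Exact k-nearest-neighbor search (blockwise full distances). For very
#' large point sets this is quadratic; a message notes the cost above 10^4
#' points. Only the binned (training) matrix ever needs a graph, so exact
#' search is the default and only mode.
#'
#' @param X numeric matrix of points (rows).
#' @param kNeighbors neighborhood size, `2 <= k < n`.
#' @param metric distance metric; only `"euclidean"` is implemented.
#' @return A [FuzzyGraph-class].
#' @export
buildFuzzyGraph <- function(X, kNeighbors = 15L, metric = "euclidean") {
    X <- as.matrix(X)
    n <- nrow(X)
    kNeighbors <- as.integer(kNeighbors)
    if (kNeighbors < 2L) stop("kNeighbors must be >= 2")
    if (n <= kNeighbors)
        stop("need more points (", n, ") than kNeighbors (", kNeighbors, ")")
    if (!identical(metric, "euclidean"))
        stop("only the euclidean metric is implemented")
    if (n > 1e4)
        message("exact kNN on ", n, " points: O(n^2) distances")
    nn <- .exactKnn(X, kNeighbors)
    rho <- nn$dist[, 1]
    target <- log2(kNeighbors)
    sigma <- vapply(seq_len(n), function(i)
        .smoothKnnSigma(nn$dist[i, ], rho[i], target), numeric(1))
    w <- exp(-pmax(0, nn$dist - rho) / sigma)
    W <- Matrix::sparseMatrix(i = rep(seq_len(n), kNeighbors),
                              j = as.vector(nn$idx), x = as.vector(w),
                              dims = c(n, n))
    S <- W + Matrix::t(W) - W * Matrix::t(W)
    new("FuzzyGraph", nPoints = n, kNeighbors = kNeighbors, rho = rho,
        sigma = sigma, weights = S, metric = metric)
}

#' Low-dimensional similarity curve parameters
#'
#' Least-squares fit of the embedding similarity `1 / (1 + a * d^(2b))`
#' against the target curve that is 1 up to `minDist` and decays as
#' `exp(-(d - minDist) / spread)` beyond it.
#'
#' @param minDist minimum separation of embedded neighbors.
#' @param spread scale of the decay.
#' @return Named vector `c(a = , b = )`.
#' @export
findCurveParams <- function(minDist = 0.1, spread = 1.0) {
    d <- seq(0, 3 * spread, length.out = 300)
    target <- ifelse(d < minDist, 1, exp(-(d - minDist) / spread))
    obj <- function(p) {
        a <- exp(p[1]); b <- exp(p[2])
        sum((1 / (1 + a * d^(2 * b)) - target)^2)
    }
    fit <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    c(a = exp(fit$par[1]), b = exp(fit$par[2]))
}

## ---- multilayer perceptron encoder ------------------------------------

.mlpInit <- function(dims) {
    lapply(seq_len(length(dims) - 1L), function(l) {
        fanIn <- dims[l]
        list(W = matrix(rnorm(fanIn * dims[l + 1L], sd = sqrt(2 / fanIn)),
                        fanIn, dims[l + 1L]),
             b = numeric(dims[l + 1L]))
    })
}

## forward pass; returns activations (list, a[[1]] = input) for backprop
.mlpForward <- function(layers, X, keepActivations = FALSE) {
    L <- length(layers)
    acts <- if (keepActivations) vector("list", L + 1L) else NULL
    a <- X
    if (keepActivations) acts[[1L]] <- a
    for (l in seq_len(L)) {
        z <- a %*% layers[[l]]$W
        z <- z + rep(layers[[l]]$b, each = nrow(z))
        a <- if (l < L) z * (z > 0) else z  # ReLU hidden, linear output
        if (keepActivations) acts[[l + 1L]] <- a
    }
    if (keepActivations) acts else a
}

.mlpBackward <- function(layers, acts, dOut) {
    L <- length(layers)
    grads <- vector("list", L)
    delta <- dOut
    for (l in rev(seq_len(L))) {
        grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                           b = colSums(delta))
        if (l > 1L)
            delta <- tcrossprod(delta, layers[[l]]$W) * (acts[[l]] > 0)
    }
    grads
}

#' Train a parametric embedding on a (binned) count matrix
#'
#' Fits a multilayer-perceptron encoder whose d-dimensional outputs minimize
#' the fuzzy cross-entropy between the high-dimensional graph weights and
#' the embedding similarity `1 / (1 + a * ||yi - yj||^(2b))`, optimized by
#' Adam over edge minibatches with uniform negative sampling -- the
#' parametric counterpart of the usual per-point layout optimization. The
#' encoder being an explicit function is what makes the bin-train-backfit
#' strategy possible.
#'
#' Training is deterministic given `seed` (single-threaded; identical seeds
#' reproduce the same weights up to floating-point evaluation order of the
#' BLAS in use).
#'
#' @param X M x K training matrix (typically the densified binned cube,
#'   scaled to per-original-pixel units by the pipeline).
#' @param d embedding dimension, 2 (mass domain) or 3 (pixel domain).
#' @param kNeighbors,minDist fuzzy graph size and embedding compactness.
#' @param epochs passes over the edge set (default 50).
#' @param learningRate Adam step size.
#' @param negativeSamples negative (repulsive) samples per edge.
#' @param repulsionStrength weight of the repulsive (negative-sample) term
#'   relative to the attractive term.
#' @param batchSize edges per minibatch.
#' @param hidden hidden layer widths of the encoder.
#' @param seed RNG seed controlling init, edge and negative sampling.
#' @param init `"pca"` pretrains the encoder to reproduce the first d
#'   principal components of the training rows (rescaled) before the
#'   cross-entropy optimization, anchoring the global layout the way
#'   spectral/PCA initialization does for non-parametric layouts; crucially
#'   it keeps high-density input clusters compact instead of letting the
#'   repulsive term inflate them. `"random"` starts from the random
#'   He-initialized network.
#' @param pretrainBatches minibatches of the PCA pretraining stage.
#' @param inputNoise counting-noise augmentation of encoder inputs:
#'   `"none"` feeds the training rows as-is; `"poisson"` / `"bernoulli"`
#'   replace each input row by a random count vector drawn with the row as
#'   its rate, every time it enters a batch. When the training rows are
#'   per-pixel rate estimates from a binned cube, the augmented encoder is
#'   trained on the very distribution of single-pixel spectra it will
#'   backfit, instead of extrapolating from the smooth binned manifold to
#'   sparse count vectors. The fuzzy graph is always built on the clean
#'   rows.
#' @param verbose print loss every few hundred batches.
#' @return An [EmbeddingModel-class].
#' @export
trainEmbedding <- function(X, d = 3L, kNeighbors = 15L, minDist = 0.1,
                           epochs = 50L, learningRate = 1e-3,
                           negativeSamples = 5L, repulsionStrength = 1.0,
                           batchSize = 512L,
                           hidden = c(128L, 128L), seed = 42L,
                           init = c("pca", "random"),
                           pretrainBatches = 1000L,
                           inputNoise = c("none", "poisson", "bernoulli"),
                           verbose = FALSE) {
    inputNoise <- match.arg(inputNoise)
    init <- match.arg(init)
    X <- as.matrix(X)
    M <- nrow(X); K <- ncol(X)
    if (M < 50L) stop("need at least 50 training rows, got ", M)
    d <- as.integer(d)
    if (!d %in% c(2L, 3L)) stop("d must be 2 or 3")
    graph <- buildFuzzyGraph(X, kNeighbors)
    tri <- Matrix::triu(graph@weights, k = 1)
    ed <- Matrix::summary(tri)
    heads <- ed$i; tails <- ed$j; ew <- ed$x
    ab <- findCurveParams(minDist)
    a <- ab[["a"]]; b <- ab[["b"]]
    nEdges <- length(heads)
    nBatches <- ceiling(nEdges * epochs / batchSize)

    layers <- NULL
    .withSeed(seed, {
        layers <- .mlpInit(c(K, hidden, d))
        L <- length(layers)
        beta1 <- 0.9; beta2 <- 0.999; epsAdam <- 1e-7
        mW <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
        vW <- mW
        t <- 0
        adamStep <- function(grads) {
            t <<- t + 1
            for (l in seq_len(L)) {
                for (p in c("W", "b")) {
                    g <- grads[[l]][[p]]
                    mW[[l]][[p]] <<- beta1 * mW[[l]][[p]] + (1 - beta1) * g
                    vW[[l]][[p]] <<- beta2 * vW[[l]][[p]] + (1 - beta2) * g^2
                    layers[[l]][[p]] <<- layers[[l]][[p]] - learningRate *
                        (mW[[l]][[p]] / (1 - beta1^t)) /
                        (sqrt(vW[[l]][[p]] / (1 - beta2^t)) + epsAdam)
                }
            }
        }
        corrupt <- function(Xb) {
            if (inputNoise == "poisson")
                matrix(rpois(length(Xb), Xb), nrow(Xb), ncol(Xb))
            else if (inputNoise == "bernoulli")
                matrix(as.numeric(runif(length(Xb)) < pmin(Xb, 1)),
                       nrow(Xb), ncol(Xb))
            else Xb
        }

        if (init == "pca") {
            ## pretrain the encoder to a rescaled PCA layout of the clean
            ## rows (targets), fed the same noise-corrupted inputs
            pc <- prcomp(X, rank. = d, center = TRUE)
            target <- pc$x[, seq_len(d), drop = FALSE]
            rms <- sqrt(mean(rowSums(target^2)))
            if (rms > 0) target <- target * (5 / rms)
            for (batch in seq_len(pretrainBatches)) {
                ridx <- sample.int(M, batchSize, replace = TRUE)
                acts <- .mlpForward(layers, corrupt(X[ridx, , drop = FALSE]),
                                    keepActivations = TRUE)
                dY <- (acts[[length(acts)]] -
                       target[ridx, , drop = FALSE]) * (2 / batchSize)
                if (!all(is.finite(dY)))
                    stop("non-finite gradient in PCA pretraining at batch ",
                         batch)
                adamStep(.mlpBackward(layers, acts, dY))
            }
            ## fresh optimizer state for the cross-entropy stage
            mW <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
            vW <- mW
            t <- 0
        }

        for (batch in seq_len(nBatches)) {
            eIdx <- sample.int(nEdges, batchSize, replace = TRUE, prob = ew)
            h <- heads[eIdx]; tl <- tails[eIdx]
            ng <- sample.int(M, batchSize * negativeSamples, replace = TRUE)
            nb <- batchSize
            rowsIdx <- c(h, tl, ng)
            acts <- .mlpForward(layers, corrupt(X[rowsIdx, , drop = FALSE]),
                                keepActivations = TRUE)
            Y <- acts[[length(acts)]]
            yh <- Y[seq_len(nb), , drop = FALSE]
            yt <- Y[nb + seq_len(nb), , drop = FALSE]
            yn <- Y[2 * nb + seq_len(nb * negativeSamples), , drop = FALSE]

            ## attraction: -log q(h, t)
            diffA <- yh - yt
            rA <- pmax(rowSums(diffA^2), 1e-12)
            gA <- (2 * a * b * rA^(b - 1)) / (1 + a * rA^b)
            gA <- pmin(gA, 4)
            dYh <- diffA * gA
            dYt <- -dYh

            ## repulsion: -log(1 - q(h, n)) for uniform negatives
            yhRep <- yh[rep(seq_len(nb), negativeSamples), , drop = FALSE]
            diffR <- yhRep - yn
            rR <- rowSums(diffR^2)
            gR <- (-2 * b * repulsionStrength) /
                  ((0.001 + rR) * (1 + a * rR^b))
            gR <- pmax(gR, -4)
            dYn <- -diffR * gR
            dYhRep <- diffR * gR
            for (s in seq_len(negativeSamples))
                dYh <- dYh + dYhRep[(s - 1) * nb + seq_len(nb), , drop = FALSE]

            if (verbose && batch %% 500 == 0) {
                loss <- mean(log1p(a * rA^b)) +
                    negativeSamples * mean(log1p(1 / (a * pmax(rR, 1e-12)^b)))
                message(sprintf("batch %d/%d  loss %.4f", batch, nBatches, loss))
            }
            dY <- rbind(dYh, dYt, dYn) / nb
            if (!all(is.finite(dY)))
                stop("non-finite gradient at batch ", batch,
                     "; inputs may contain non-finite values or the learning rate is too high")
            adamStep(.mlpBackward(layers, acts, dY))
        }
    })
    new("EmbeddingModel", inputDim = as.integer(K), outputDim = d,
        weights = layers,
        hyper = list(kNeighbors = as.integer(kNeighbors), minDist = minDist,
                     aCurve = a, bCurve = b, epochs = as.integer(epochs),
                     learningRate = learningRate,
                     negativeSamples = as.integer(negativeSamples),
                     repulsionStrength = repulsionStrength,
                     batchSize = as.integer(batchSize),
                     hidden = as.integer(hidden), seed = as.integer(seed),
                     init = init,
                     pretrainBatches = as.integer(pretrainBatches),
                     inputNoise = inputNoise, metric = "euclidean"),
        provenance = .matrixFingerprint(X))
}

#' Backfit: apply a trained encoder to new rows
#'
#' Applies the encoder row-wise, streaming in row blocks. No re-training
#' happens and rows are independent, so permuting input rows permutes the
#' output identically. This is how an embedding learned from the binned cube
#' transfers to the full-resolution unbinned cube.
#'
#' @param model an [EmbeddingModel-class].
#' @param X N x K matrix; K must equal `model@inputDim`.
#' @param blockRows rows per forward block.
#' @return N x d coordinate matrix.
#' @export
backfit <- function(model, X, blockRows = 65536L) {
    stopifnot(is(model, "EmbeddingModel"))
    X <- as.matrix(X)
    if (ncol(X) != model@inputDim)
        stop("X has ", ncol(X), " columns but the model expects ",
             model@inputDim)
    n <- nrow(X)
    Y <- matrix(0, n, model@outputDim)
    for (start in seq(1L, max(n, 1L), by = blockRows)) {
        end <- min(start + blockRows - 1L, n)
        if (start > end) break
        Y[start:end, ] <- .mlpForward(model@weights,
                                      X[start:end, , drop = FALSE])
    }
    Y
}

#' Serialize / restore an embedding model
#'
#' Single-file JSON container: a version-tagged header with the
#' hyperparameters and provenance, plus the layer weights at full printed
#' precision. `loadEmbeddingModel(saveEmbeddingModel(m, f))` reproduces the
#' encoder outputs to stored precision.
#'
#' @param model an [EmbeddingModel-class].
#' @param path file path.
#' @return `saveEmbeddingModel`: `path` invisibly; `loadEmbeddingModel`:
#'   the restored [EmbeddingModel-class].
#' @export
saveEmbeddingModel <- function(model, path) {
    stopifnot(is(model, "EmbeddingModel"))
    payload <- list(
        format = "MSIbackfit-embedding-model", version = 1L,
        inputDim = model@inputDim, outputDim = model@outputDim,
        hyper = model@hyper, provenance = model@provenance,
        layers = lapply(model@weights, function(l)
            list(dim = dim(l$W), W = as.vector(l$W), b = l$b)))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname saveEmbeddingModel
#' @export
loadEmbeddingModel <- function(path) {
    p <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(p$format, "MSIbackfit-embedding-model"))
        stop("not an embedding model container: ", path)
    layers <- lapply(seq_len(nrow(p$layers)), function(i)
        list(W = matrix(p$layers$W[[i]], p$layers$dim[[i]][1],
                        p$layers$dim[[i]][2]),
             b = p$layers$b[[i]]))
    new("EmbeddingModel", inputDim = as.integer(p$inputDim),
        outputDim = as.integer(p$outputDim), weights = layers,
        hyper = as.list(p$hyper), provenance = as.character(p$provenance))
}

#' RGB similarity map from 3-D embedding coordinates
#'
#' Each embedding axis is rescaled to `[0, 1]` by clipping at its 1st and
#' 99th percentiles and assigned, in axis order, to the red, green and blue
#' channels; a degenerate (constant) axis maps to mid-gray 0.5. Rows are in
#' row-major pixel order.
#'
#' @param coords N x 3 matrix with `N = height * width`.
#' @param height,width raster geometry.
#' @return An `height x width x 3` array in `[0, 1]`.
#' @export
rgbMap <- function(coords, height, width) {
    coords <- as.matrix(coords)
    if (ncol(coords) != 3L) stop("rgbMap needs 3 embedding axes, got ",
                                 ncol(coords))
    if (nrow(coords) != height * width)
        stop("coords rows (", nrow(coords), ") != height * width")
    out <- array(0, c(height, width, 3L))
    for (ch in 1:3) {
        v <- coords[, ch]
        q <- quantile(v, c(0.01, 0.99), names = FALSE)
        if (q[2] - q[1] <= 0) {
            vv <- rep(0.5, length(v))
        } else {
            vv <- (pmin(pmax(v, q[1]), q[2]) - q[1]) / (q[2] - q[1])
        }
        out[, , ch] <- t(matrix(vv, nrow = width))
    }
    out
}

#' Trustworthiness of an embedding
#'
#' Fraction-based penalty for points that enter the embedding's
#' k-neighborhood without being high-dimensional neighbors (1 = perfectly
#' trustworthy local structure).
#'
#' @param X high-dimensional points.
#' @param Y embedded points (same row order).
#' @param k neighborhood size.
#' @return Scalar in `[0, 1]`.
#' @export
embeddingTrustworthiness <- function(X, Y, k = 10L) {
    n <- nrow(X)
    stopifnot(nrow(Y) == n, k < (n - 1) / 2)
    dX <- as.matrix(dist(X)); diag(dX) <- Inf
    dY <- as.matrix(dist(Y)); diag(dY) <- Inf
    penalty <- 0
    for (i in seq_len(n)) {
        rankX <- rank(dX[i, ], ties.method = "first")
        nnY <- order(dY[i, ])[seq_len(k)]
        r <- rankX[nnY]
        penalty <- penalty + sum(pmax(0, r - k))
    }
    1 - 2 * penalty / (n * k * (2 * n - 3 * k - 1))
}
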