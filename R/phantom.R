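#' Synthetic overlapping-fingermark phantom
#'
#' `phantomConfig()` describes a synthetic scene that reproduces the counting
#' regime of a macroraster ToF-SIMS image of two partially overlapping
#' fingermarks on a substrate: four spatial classes (substrate = 0,
#' print A = 1, print B = 2, chemically shared overlap = 3), sinusoidal
#' ridges inside elliptical print footprints, sparse per-class Bernoulli
#' event rates so that per-peak counts are 0 or 1 and the per-pixel total
#' ion count stays far below `ticCap`, and a deposition-order occlusion
#' effect: in the overlap the surface-sensitive signal is a convex
#' combination of the two prints, weighted `occlusionAlpha` toward the print
#' deposited last (on top), plus an optional shared chemical component.
#'
#' Default signatures are built from four sparse seeded templates
#' (`templateSeed`, independent of the sampling `seed`): 10 substrate peaks
#' at rate 0.20, 18 peaks per print at 0.35 plus 25% substrate
#' bleed-through, a 9-peak shared overlap component at 0.30, and a 0.0075
#' background on every peak. With the default 504 x 504 raster and K = 64
#' peaks this gives mean pixel TICs of about 2.5 (substrate), 7 (prints)
#' and 10 (overlap) counts.
#'
#' @slot height,width raster size in pixels.
#' @slot nPeaks number of peaks K.
#' @slot ridgeFrequency ridge frequency in cycles per pixel.
#' @slot duty fraction of the ridge period that is "on".
#' @slot prints list of two print descriptors (center, semi-axes in pixels,
#'   ridge angle and phase in radians).
#' @slot signatures 4 x K matrix of per-peak Bernoulli/Poisson rates for
#'   classes (substrate, printA, printB, overlap).
#' @slot occlusionAlpha weight of the top print in the overlap signature.
#' @slot order `"A"` or `"B"`: which print is deposited last (on top).
#' @slot samplingMode `"bernoulli"` or `"poisson"`.
#' @slot ticCap cap on the per-class expected TIC.
#' @slot seed sampling seed.
#' @export
setClass("PhantomConfig",
    slots = c(height = "integer", width = "integer", nPeaks = "integer",
              ridgeFrequency = "numeric", duty = "numeric", prints = "list",
              signatures = "matrix", occlusionAlpha = "numeric",
              order = "character", samplingMode = "character",
              ticCap = "numeric", seed = "integer"))

setValidity("PhantomConfig", function(object) {
    if (!object@samplingMode %in% c("bernoulli", "poisson"))
        return("samplingMode must be 'bernoulli' or 'poisson'")
    sig <- object@signatures
    if (!is.matrix(sig) || nrow(sig) != 4L || ncol(sig) != object@nPeaks)
        return("signatures must be a 4 x nPeaks matrix")
    if (any(sig < 0)) return("signature rates must be nonnegative")
    if (object@samplingMode == "bernoulli" && any(sig > 1))
        return("signature rates must be in [0, 1] in bernoulli mode")
    if (any(rowSums(sig) > object@ticCap))
        return("per-class expected TIC (row sum of signatures) exceeds ticCap")
    if (object@occlusionAlpha < 0 || object@occlusionAlpha > 1)
        return("occlusionAlpha must be in [0, 1]")
    if (!object@order %in% c("A", "B")) return("order must be 'A' or 'B'")
    if (length(object@prints) != 2L ||
        !all(c("A", "B") %in% names(object@prints)))
        return("prints must be a named list with elements A and B")
    if (object@duty < 0 || object@duty > 1) return("duty must be in [0, 1]")
    TRUE
})

setMethod("$", "PhantomConfig", function(x, name) slot(x, name))

setMethod("show", "PhantomConfig", function(object) {
    cat(sprintf(
        "PhantomConfig: %d x %d pixels, %d peaks, %s sampling, seed %d\n",
        object@height, object@width, object@nPeaks, object@samplingMode,
        object@seed))
    cat(sprintf("  occlusionAlpha %.2f, print %s on top, expected class TICs: %s\n",
                object@occlusionAlpha, object@order,
                paste(sprintf("%.1f", rowSums(object@signatures)),
                      collapse = ", ")))
})

#' Ground truth of a phantom scene
#'
#' @slot classMap H x W integer matrix with labels 0 (substrate),
#'   1 (print A), 2 (print B), 3 (overlap).
#' @slot signatures realized 4 x K rate matrix.
#' @slot order which print is on top.
#' @export
setClass("PhantomTruth",
    slots = c(classMap = "matrix", signatures = "matrix", order = "character"))

setMethod("show", "PhantomTruth", function(object) {
    tab <- tabulate(as.integer(object@classMap) + 1L, 4L)
    cat(sprintf(
        "PhantomTruth: %d x %d pixels; substrate/printA/printB/overlap = %s; %s on top\n",
        nrow(object@classMap), ncol(object@classMap),
        paste(tab, collapse = "/"), object@order))
})

#' @describeIn PhantomTruth the H x W class map (0-3).
#' @param x a PhantomTruth.
#' @export
classMap <- function(x) x@classMap

.defaultSignatures <- function(nPeaks, occlusionAlpha, order,
                               templateSeed = 99L, background = 0.0075,
                               substrateRate = 0.20, printRate = 0.35,
                               sharedRate = 0.30, bleed = 0.25) {
    sig <- matrix(background, 4L, nPeaks)
    shared <- numeric(nPeaks)
    .withSeed(templateSeed, {
        sub <- sample.int(nPeaks, min(10L, nPeaks))
        A <- sample.int(nPeaks, min(18L, nPeaks))
        B <- sample.int(nPeaks, min(18L, nPeaks))
        ex <- sample.int(nPeaks, min(9L, nPeaks))
    })
    sig[1L, sub] <- sig[1L, sub] + substrateRate
    for (i in c(2L, 3L)) sig[i, sub] <- sig[i, sub] + bleed * substrateRate
    sig[2L, A] <- sig[2L, A] + printRate
    sig[3L, B] <- sig[3L, B] + printRate
    shared[ex] <- sharedRate
    top <- if (order == "A") 2L else 3L
    bottom <- if (order == "A") 3L else 2L
    sig[4L, ] <- pmin(1, occlusionAlpha * sig[top, ] +
                         (1 - occlusionAlpha) * sig[bottom, ] + shared)
    rownames(sig) <- c("substrate", "printA", "printB", "overlap")
    sig
}

#' Construct a phantom configuration
#'
#' All arguments default to the reference low-count regime (see
#' [PhantomConfig-class]); pass `signatures` to override the seeded default
#' templates entirely (the overlap row is then taken as given).
#'
#' @param height,width raster size in pixels.
#' @param nPeaks number of peaks K.
#' @param ridgeFrequency ridge frequency, cycles per pixel (default period
#'   42 px).
#' @param duty "on" fraction of the ridge period.
#' @param prints named list (`A`, `B`) of print descriptors, each a list
#'   with `center = c(row, col)`, `axes = c(rowSemiAxis, colSemiAxis)`,
#'   `angle`, `phase`.
#' @param signatures optional 4 x K rate matrix; built from seeded sparse
#'   templates when NULL.
#' @param occlusionAlpha weight of the top print in the overlap signature.
#' @param order `"A"` or `"B"`; which print was deposited last (on top).
#' @param samplingMode `"bernoulli"` (counts in \{0,1\}) or `"poisson"`.
#' @param ticCap cap on per-class expected TIC (validity-checked).
#' @param seed sampling seed for [sampleCube()].
#' @param templateSeed seed for the default signature templates.
#' @param substrateRate,printRate,sharedRate,background,bleed rates of the
#'   default signature templates: substrate peaks, print-characteristic
#'   peaks, the shared overlap component (0 disables it), the background on
#'   every peak, and the substrate bleed-through fraction under the prints.
#' @return A [PhantomConfig-class].
#' @examples
#' cfg <- phantomConfig(height = 60, width = 60, seed = 7)
#' truth <- composeScene(cfg)
#' table(classMap(truth))
#' @export
phantomConfig <- function(height = 504L, width = 504L, nPeaks = 64L,
                          ridgeFrequency = 1 / 42, duty = 0.5,
                          prints = NULL, signatures = NULL,
                          occlusionAlpha = 0.8, order = c("A", "B"),
                          samplingMode = c("bernoulli", "poisson"),
                          ticCap = 100, seed = 1L, templateSeed = 99L,
                          substrateRate = 0.20, printRate = 0.35,
                          sharedRate = 0.30, background = 0.0075,
                          bleed = 0.25) {
    order <- match.arg(order)
    samplingMode <- match.arg(samplingMode)
    if (is.null(prints)) {
        ## default geometry scales with the raster so small test phantoms
        ## keep the same scene layout and ridge count
        sc <- min(height, width) / 504
        prints <- list(
            A = list(center = c(230, 180) * sc, axes = c(152, 150) * sc,
                     angle = 0.35, phase = 0.0),
            B = list(center = c(280, 330) * sc, axes = c(152, 150) * sc,
                     angle = 1.90, phase = 1.0))
        if (missing(ridgeFrequency)) ridgeFrequency <- ridgeFrequency / sc
    }
    if (is.null(signatures))
        signatures <- .defaultSignatures(nPeaks, occlusionAlpha, order,
                                         templateSeed, background,
                                         substrateRate, printRate,
                                         sharedRate, bleed)
    new("PhantomConfig", height = as.integer(height),
        width = as.integer(width), nPeaks = as.integer(nPeaks),
        ridgeFrequency = ridgeFrequency, duty = duty, prints = prints,
        signatures = signatures, occlusionAlpha = occlusionAlpha,
        order = order, samplingMode = samplingMode, ticCap = ticCap,
        seed = as.integer(seed))
}

#' Ridge mask of one print
#'
#' A pixel belongs to the print iff it lies inside the print's ellipse and
#' the ridge sinusoid `sin(2 pi f (x cos(angle) + y sin(angle)) + phase)`
#' exceeds the duty-cycle threshold `cos(pi * duty)`, so the "on" fraction
#' of the period equals `duty`. Deterministic in the configuration; x is the
#' 0-based column, y the 0-based row.
#'
#' @param config a [PhantomConfig-class].
#' @param which `"A"` or `"B"`.
#' @return An H x W logical matrix.
#' @export
ridgeMask <- function(config, which = c("A", "B")) {
    which <- match.arg(which)
    p <- config@prints[[which]]
    H <- config@height; W <- config@width
    y <- matrix(seq_len(H) - 1, H, W)          # row index
    x <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)  # col index
    if (any(p$axes <= 0)) return(matrix(FALSE, H, W))
    ell <- ((y - p$center[1]) / p$axes[1])^2 +
           ((x - p$center[2]) / p$axes[2])^2 <= 1
    if (config@duty >= 1) return(ell)
    if (config@duty <= 0) return(matrix(FALSE, H, W))
    s <- sin(2 * pi * config@ridgeFrequency *
             (x * cos(p$angle) + y * sin(p$angle)) + p$phase)
    ell & (s > cos(pi * config@duty))
}

#' Compose the ground-truth scene
#'
#' Label 3 (overlap) exactly where both ridge masks are true, 1/2 where
#' exactly one is, 0 elsewhere. An empty overlap (disjoint prints) is legal.
#'
#' @param config a [PhantomConfig-class].
#' @return A [PhantomTruth-class].
#' @export
composeScene <- function(config) {
    validObject(config)
    mA <- ridgeMask(config, "A")
    mB <- ridgeMask(config, "B")
    cls <- matrix(0L, config@height, config@width)
    cls[mA & !mB] <- 1L
    cls[mB & !mA] <- 2L
    cls[mA & mB] <- 3L
    new("PhantomTruth", classMap = cls, signatures = config@signatures,
        order = config@order)
}

#' Sample a sparse cube from a phantom scene
#'
#' For every pixel of class c and every peak k the count is drawn
#' independently as Bernoulli(signatures[c, k]) (counts 0/1) or
#' Poisson(signatures[c, k]); only nonzero counts are stored. Fully
#' reproducible from `config@seed`.
#'
#' @param truth a [PhantomTruth-class] from [composeScene()].
#' @param config the [PhantomConfig-class] that produced `truth`.
#' @return A [SparseCube-class].
#' @export
sampleCube <- function(truth, config) {
    validObject(config)
    H <- config@height; W <- config@width; K <- config@nPeaks
    clsRM <- as.integer(t(truth@classMap))  # row-major pixel order
    sig <- config@signatures
    bern <- config@samplingMode == "bernoulli"
    rows <- cols <- pks <- cnts <- vector("list", K)
    .withSeed(config@seed, {
        for (k in seq_len(K)) {
            rate <- sig[clsRM + 1L, k]
            if (bern) {
                hit <- which(runif(H * W) < rate)
                cn <- rep.int(1L, length(hit))
            } else {
                cn <- rpois(H * W, rate)
                hit <- which(cn > 0L)
                cn <- cn[hit]
            }
            if (!length(hit)) next
            p0 <- hit - 1L
            rows[[k]] <- p0 %/% W
            cols[[k]] <- p0 %% W
            pks[[k]] <- rep.int(k - 1L, length(hit))
            cnts[[k]] <- as.integer(cn)
        }
    })
    ev <- data.frame(row = as.integer(unlist(rows)),
                     col = as.integer(unlist(cols)),
                     peak = as.integer(unlist(pks)),
                     count = as.integer(unlist(cnts)))
    SparseCube(H, W, K, ev,
               meta = list(provenance = "phantom", seed = config@seed,
                           sampling_mode = config@samplingMode,
                           order = config@order,
                           occlusion_alpha = config@occlusionAlpha))
}
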