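#' Pick peaks from a total mass spectrum
#'
#' Accepts local maxima of the intensity trace whose topographic prominence
#' is at least `minProminence`, greedily from the most intense down,
#' enforcing a pairwise centroid separation of at least `minSeparation`.
#' Integration windows extend to the midpoints toward the neighboring
#' accepted peaks and are clipped to +/- `maxHalfWidth` m/z around the
#' centroid; windows are half-open `[lo, hi)`.
#'
#' The picker is deliberately plain: macroraster total spectra are dense in
#' counts, and the peak list is a user-auditable artifact, not a fitted
#' model.
#'
#' @param mz numeric vector of m/z values, ascending.
#' @param intensity nonnegative intensities, same length.
#' @param minProminence minimum prominence in counts (default 5).
#' @param minSeparation minimum centroid separation in m/z (default 0.5).
#' @param maxHalfWidth window half-width clip in m/z (default 0.5).
#' @return A [PeakList-class].
#' @export
peakPick <- function(mz, intensity, minProminence = 5, minSeparation = 0.5,
                     maxHalfWidth = 0.5) {
    if (length(mz) == 0L) stop("empty spectrum")
    stopifnot(length(mz) == length(intensity))
    if (is.unsorted(mz, strictly = TRUE))
        stop("mz must be strictly ascending")
    n <- length(mz)
    if (n < 3L) cand <- integer() else {
        y <- intensity
        cand <- which(y[2:(n - 1)] > y[1:(n - 2)] &
                      y[2:(n - 1)] >= y[3:n]) + 1L
    }
    ## topographic prominence: drop to the highest saddle separating the
    ## peak from higher terrain on either side
    prom <- vapply(cand, function(i) {
        h <- intensity[i]
        leftMin <- h
        j <- i - 1L
        while (j >= 1L && intensity[j] <= h) {
            leftMin <- min(leftMin, intensity[j]); j <- j - 1L
        }
        leftBase <- if (j >= 1L) leftMin else min(intensity[1:i])
        rightMin <- h
        j <- i + 1L
        while (j <= n && intensity[j] <= h) {
            rightMin <- min(rightMin, intensity[j]); j <- j + 1L
        }
        rightBase <- if (j <= n) rightMin else min(intensity[i:n])
        h - max(leftBase, rightBase)
    }, numeric(1))
    cand <- cand[prom >= minProminence]
    ## greedy separation filter, most intense first
    cand <- cand[order(-intensity[cand], mz[cand])]
    kept <- integer()
    for (i in cand)
        if (!length(kept) || all(abs(mz[i] - mz[kept]) >= minSeparation))
            kept <- c(kept, i)
    kept <- sort(kept)
    if (!length(kept))
        return(PeakList(character(), numeric(), numeric(), numeric()))
    cen <- mz[kept]
    mid <- if (length(cen) > 1) (cen[-length(cen)] + cen[-1]) / 2 else numeric()
    lo <- pmax(c(-Inf, mid), cen - maxHalfWidth)
    hi <- pmin(c(mid, Inf), cen + maxHalfWidth)
    PeakList(sprintf("mz%.4f", cen), cen, lo, hi)
}

#' Bin a cube over B x B neighboring pixels
#'
#' Sums the raw counts of each B x B block of neighboring pixels into one
#' output pixel, the standard remedy for low signal-to-noise ion images;
#' output dimensions are `floor(H/B) x floor(W/B)`. Summing (not averaging)
#' preserves the counting statistics. With `edgePolicy = "crop"` trailing
#' rows/columns not filling a block are discarded with a warning reporting
#' the discarded counts; with `"error"` the factor must divide both
#' dimensions. Cumulative binning provenance is recorded in the cube meta,
#' and `binCube(c, 1)` is the identity on the event multiset.
#'
#' @param cube a [SparseCube-class].
#' @param factor block edge B >= 1; must not exceed either dimension.
#' @param edgePolicy `"crop"` (default) or `"error"`.
#' @return A binned [SparseCube-class].
#' @examples
#' ev <- data.frame(row = 0:3, col = 0:3, peak = 0L, count = 1L)
#' b <- binCube(SparseCube(4, 4, 1, ev), 2)
#' dim(b)
#' @export
binCube <- function(cube, factor, edgePolicy = c("crop", "error")) {
    stopifnot(is(cube, "SparseCube"))
    edgePolicy <- match.arg(edgePolicy)
    B <- as.integer(factor)
    if (is.na(B) || B < 1L) stop("factor must be a positive integer")
    H <- cube@height; W <- cube@width
    if (B > min(H, W))
        stop("factor ", B, " exceeds the smallest cube dimension ", min(H, W))
    if (edgePolicy == "error" && (H %% B != 0L || W %% B != 0L))
        stop("factor ", B, " does not divide dims ", H, " x ", W,
             " (edgePolicy = 'error')")
    Hb <- H %/% B; Wb <- W %/% B
    ev <- cube@events
    keep <- ev$row < Hb * B & ev$col < Wb * B
    if (!all(keep)) {
        warning(sprintf("cropped %d trailing pixels' events (%.0f counts) not filling a %dx%d block",
                        sum(!keep), sum(as.numeric(ev$count[!keep])), B, B),
                call. = FALSE)
        ev <- ev[keep, , drop = FALSE]
    }
    if (B > 1L && nrow(ev)) {
        key <- (ev$row %/% B) * (Wb * as.double(cube@nPeaks)) +
               (ev$col %/% B) * as.double(cube@nPeaks) + ev$peak
        agg <- rowsum(as.numeric(ev$count), key, reorder = FALSE)
        k <- as.numeric(rownames(agg))
        pk <- as.integer(k %% cube@nPeaks)
        rest <- (k - pk) / cube@nPeaks
        ev <- data.frame(row = as.integer(rest %/% Wb),
                         col = as.integer(rest %% Wb),
                         peak = pk, count = as.integer(agg[, 1]))
    } else if (B > 1L) {
        ev <- ev[0, , drop = FALSE]
    }
    meta <- cube@meta
    prev <- if (is.null(meta$bin_factor)) 1L else as.integer(meta$bin_factor)
    meta$bin_factor <- prev * B
    meta$binning <- c(meta$binning,
                      list(list(factor = B, edge_policy = edgePolicy,
                                input_dims = c(H, W))))
    SparseCube(Hb, Wb, cube@nPeaks, ev, peaks = cube@peaks, meta = meta)
}

#' Densify a cube into a pixel-by-peak count matrix
#'
#' Rows follow row-major pixel order (pixel `p` is `(row, col)` with
#' `p = row * W + col`, 0-based), so pixel index and raster position stay
#' interconvertible; columns are peak indices. This is the matrix fed to the
#' embedding.
#'
#' @param cube a [SparseCube-class].
#' @param maxCells memory budget in matrix cells (default 3e8, ~2.4 GB).
#' @return An N x K numeric matrix, N = H * W.
#' @export
densify <- function(cube, maxCells = 3e8) {
    stopifnot(is(cube, "SparseCube"))
    N <- as.double(cube@height) * cube@width
    if (N * cube@nPeaks > maxCells)
        stop("densified size ", N, " x ", cube@nPeaks,
             " exceeds the cell budget (", maxCells,
             "); stream the cube in row blocks instead")
    X <- matrix(0, N, cube@nPeaks)
    ev <- cube@events
    if (nrow(ev))
        X[cbind(ev$row * as.double(cube@width) + ev$col + 1, ev$peak + 1)] <-
            as.numeric(ev$count)
    X
}
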