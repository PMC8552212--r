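#' Cluster pixels in embedding space
#'
#' Ward agglomerative clustering (stats::hclust, `ward.D2`) on a seeded
#' uniform subsample of the embedded pixels, followed by nearest-centroid
#' assignment of every pixel, so the method scales to rasters far beyond
#' what full-pairwise linkage allows. With `k = "auto"` the cluster number
#' is chosen in `kRange` by maximum mean silhouette width on the subsample.
#' Every pixel receives a label (no noise class in the pixel domain);
#' clusters are relabeled 0, 1, ... by decreasing size so the substrate
#' typically becomes cluster 0.
#'
#' @param coords N x d embedding coordinates.
#' @param k number of clusters, or `"auto"`.
#' @param seed subsampling seed (logged in the result's meta).
#' @param geometry `c(height, width)` with `height * width = N`; defaults
#'   to an N x 1 strip.
#' @param subsampleSize Ward subsample cap (must be <= 20000).
#' @param kRange candidate k values for auto selection.
#' @return A pixel-domain [LabelImage-class]. The selected k, the seed and
#'   the cluster centroids are attached as attributes `"k"`, `"seed"`,
#'   `"centroids"`.
#' @export
clusterPixels <- function(coords, k = "auto", seed = 1L, geometry = NULL,
                          subsampleSize = 4000L, kRange = 2:8) {
    coords <- as.matrix(coords)
    if (!all(is.finite(coords))) stop("coords must be finite")
    N <- nrow(coords)
    if (is.null(geometry)) geometry <- c(N, 1L)
    if (geometry[1] * geometry[2] != N)
        stop("geometry does not match the number of coordinate rows")
    if (subsampleSize > 20000L) stop("subsampleSize must be <= 20000")
    if (is.numeric(k) && k > N) stop("k_clusters exceeds the number of points")
    if (is.numeric(k) && k == 1L) {
        lab <- rep(0L, N)
        cen <- matrix(colMeans(coords), 1)
    } else {
        idx <- seq_len(N)
        if (N > subsampleSize)
            idx <- .withSeed(seed, sort(sample.int(N, subsampleSize)))
        sub <- coords[idx, , drop = FALSE]
        dd <- dist(sub)
        hc <- hclust(dd, method = "ward.D2")
        if (identical(k, "auto")) {
            kRange <- kRange[kRange < length(idx)]
            sil <- vapply(kRange, function(kk) {
                cl <- cutree(hc, kk)
                if (length(unique(cl)) < 2L) return(-1)
                mean(cluster::silhouette(cl, dd)[, "sil_width"])
            }, numeric(1))
            k <- kRange[which.max(sil)]
        }
        subLab <- cutree(hc, k)
        cen <- rowsum(sub, subLab) / as.vector(table(subLab))
        lab <- .nearestCentroid(coords, cen) - 1L
        ## re-estimate centroids from the full assignment for reporting
        cen <- rowsum(coords, lab) / as.vector(table(lab))
    }
    ## canonical labels: decreasing cluster size, ties by first centroid axis
    sizes <- tabulate(lab + 1L, nbins = nrow(cen))
    ord <- order(-sizes, cen[, 1])
    remap <- integer(nrow(cen)); remap[ord] <- seq_len(nrow(cen)) - 1L
    lab <- remap[lab + 1L]
    cen <- cen[ord, , drop = FALSE]
    labMat <- matrix(lab, nrow = geometry[1], byrow = TRUE)
    out <- LabelImage(labMat, domain = "pixel", nClusters = nrow(cen))
    attr(out, "k") <- nrow(cen)
    attr(out, "seed") <- seed
    attr(out, "centroids") <- cen
    out
}

.nearestCentroid <- function(coords, centroids, blockRows = 65536L) {
    n <- nrow(coords)
    lab <- integer(n)
    for (start in seq(1L, n, by = blockRows)) {
        end <- min(start + blockRows - 1L, n)
        d2 <- .crossDist2(coords[start:end, , drop = FALSE], centroids)
        lab[start:end] <- max.col(-d2, ties.method = "first")
    }
    lab
}

#' Transpose a pixel-by-peak matrix for mass-domain analysis
#'
#' The mass-domain (ToF) reduction embeds the K peaks as points described
#' by their N pixel intensities: the exact transpose of the spatial-domain
#' matrix, peak order preserved as rows.
#'
#' @param X N x K matrix.
#' @return The K x N transpose.
#' @export
transposeMatrix <- function(X) t(X)

#' Density-based hierarchical clustering of peaks with a noise label
#'
#' Clusters the 2-D mass-domain embedding with a compact HDBSCAN-style
#' procedure: mutual-reachability distances (core distance = distance to the
#' `minClusterSize`-th neighbor), single-linkage hierarchy, condensation of
#' the dendrogram at `minClusterSize`, and stability-based cluster
#' selection. Points in no selected dense region get label -1 (noise) --
#' the gray points of the mass-domain plot. Deterministic given its inputs.
#'
#' @param coords K x d coordinates (d = 2 in the mass domain).
#' @param minClusterSize smallest cluster size considered real.
#' @return A peak-domain [LabelImage-class] (label -1 = noise).
#' @export
clusterPeaks <- function(coords, minClusterSize = 5L) {
    coords <- as.matrix(coords)
    n <- nrow(coords)
    minClusterSize <- as.integer(minClusterSize)
    if (minClusterSize < 2L) stop("minClusterSize must be >= 2")
    if (n < minClusterSize || n < 2L) {
        warning("fewer points than minClusterSize: all points are noise",
                call. = FALSE)
        return(LabelImage(rep(-1L, n), domain = "peak", nClusters = 0L))
    }
    lab <- .densityCluster(coords, minClusterSize)
    nCl <- max(0L, max(lab) + 1L)
    if (nCl == 0L)
        warning("no dense region of size >= ", minClusterSize,
                ": all points are noise", call. = FALSE)
    LabelImage(lab, domain = "peak", nClusters = nCl)
}

## density clustering core shared by clusterPeaks and the pipeline's
## binned-coordinate cluster model; returns 0-based labels, -1 = noise
.densityCluster <- function(coords, minClusterSize) {
    n <- nrow(coords)
    if (n < minClusterSize || n < 2L) return(rep(-1L, n))
    d <- as.matrix(dist(coords))
    kCore <- min(minClusterSize, n - 1L)
    core <- vapply(seq_len(n), function(i)
        sort(d[i, -i], partial = kCore)[kCore], numeric(1))
    mr <- pmax(d, outer(core, core, pmax))
    diag(mr) <- 0
    hc <- hclust(as.dist(mr), method = "single")
    .condensedTreeLabels(hc, n, minClusterSize)
}

#' Assign points to the nearest cluster centroid
#'
#' Nearest-centroid (minimum Euclidean distance) assignment, streaming in
#' row blocks; the transfer step that carries a cluster model learned on
#' binned coordinates onto every full-resolution pixel.
#'
#' @param coords N x d coordinates to label.
#' @param centroids C x d cluster centroids.
#' @param geometry optional `c(height, width)` to shape a pixel-domain
#'   [LabelImage-class]; defaults to an N x 1 strip.
#' @return A pixel-domain [LabelImage-class] with attribute `"centroids"`.
#' @export
assignPixels <- function(coords, centroids, geometry = NULL) {
    coords <- as.matrix(coords)
    centroids <- as.matrix(centroids)
    N <- nrow(coords)
    if (is.null(geometry)) geometry <- c(N, 1L)
    if (geometry[1] * geometry[2] != N)
        stop("geometry does not match the number of coordinate rows")
    lab <- .nearestCentroid(coords, centroids) - 1L
    out <- LabelImage(matrix(lab, nrow = geometry[1], byrow = TRUE),
                      domain = "pixel", nClusters = nrow(centroids))
    attr(out, "centroids") <- centroids
    out
}

## Condensed-tree extraction and stability selection on an hclust single-
## linkage dendrogram. Returns 0-based labels with -1 = noise.
.condensedTreeLabels <- function(hc, n, mcs) {
    nm <- nrow(hc$merge)
    if (max(hc$height) <= 0)      # all points coincide: one cluster
        return(rep(0L, n))
    hFloor <- min(hc$height[hc$height > 0]) * 1e-6
    lam <- 1 / pmax(hc$height, hFloor)

    ## leaves under each merge node
    leaves <- vector("list", nm)
    sizes <- integer(nm)
    for (m in seq_len(nm)) {
        ch <- hc$merge[m, ]
        l <- c(if (ch[1] < 0) -ch[1] else NULL,
               if (ch[1] > 0) leaves[[ch[1]]] else NULL,
               if (ch[2] < 0) -ch[2] else NULL,
               if (ch[2] > 0) leaves[[ch[2]]] else NULL)
        leaves[[m]] <- l
        sizes[m] <- length(l)
    }
    nodeSize <- function(ch) if (ch < 0) 1L else sizes[ch]

    ## condensed clusters
    clParent <- integer(0); clBirth <- numeric(0); clStab <- numeric(0)
    clPoints <- list()
    newCluster <- function(parent, birth, pts) {
        clParent[length(clParent) + 1L] <<- parent
        clBirth[length(clBirth) + 1L] <<- birth
        clStab[length(clStab) + 1L] <<- 0
        clPoints[[length(clPoints) + 1L]] <<- pts
        length(clParent)
    }
    root <- newCluster(0L, lam[nm], leaves[[nm]])
    ## walk top-down: stack of (node, cluster)
    stack <- list(list(node = nm, cl = root))
    while (length(stack)) {
        fr <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        m <- fr$node; cl <- fr$cl
        ch <- hc$merge[m, ]
        sA <- nodeSize(ch[1]); sB <- nodeSize(ch[2])
        if (sA >= mcs && sB >= mcs) {
            ## true split: cluster cl's points all leave at lam[m]
            clStab[cl] <- clStab[cl] + (sA + sB) * (lam[m] - clBirth[cl])
            for (c2 in 1:2) {
                pts <- if (ch[c2] < 0) -ch[c2] else leaves[[ch[c2]]]
                child <- newCluster(cl, lam[m], pts)
                if (ch[c2] > 0)
                    stack[[length(stack) + 1L]] <- list(node = ch[c2],
                                                        cl = child)
                ## a leaf can't be >= mcs >= 2, so ch[c2] > 0 always here
            }
        } else {
            ## smaller side(s) fall out of cl at lam[m]
            for (c2 in 1:2) {
                sz <- nodeSize(ch[c2])
                if (sz >= mcs) {
                    stack[[length(stack) + 1L]] <- list(node = ch[c2],
                                                        cl = cl)
                } else {
                    clStab[cl] <- clStab[cl] + sz * (lam[m] - clBirth[cl])
                }
            }
        }
    }

    children <- split(seq_along(clParent), clParent)
    ## bottom-up selected stability
    selStab <- clStab
    selected <- rep(TRUE, length(clParent))
    for (cl in rev(seq_along(clParent))) {
        kids <- children[[as.character(cl)]]
        if (!is.null(kids)) {
            kidSum <- sum(selStab[kids])
            if (clStab[cl] < kidSum) {
                selStab[cl] <- kidSum
                selected[cl] <- FALSE
            }
        }
    }
    ## top-down harvest, excluding the root unless it never split
    rootKids <- children[["1"]]
    lab <- rep(-1L, n)
    if (is.null(rootKids)) {
        lab[clPoints[[root]]] <- 0L
        return(lab)
    }
    take <- integer(0)
    stack <- rootKids
    while (length(stack)) {
        cl <- stack[[1]]; stack <- stack[-1]
        kids <- children[[as.character(cl)]]
        if (selected[cl] || is.null(kids)) take <- c(take, cl)
        else stack <- c(stack, kids)
    }
    ## stable ordering: by smallest member index
    take <- take[order(vapply(take, function(cl) min(clPoints[[cl]]), 1))]
    for (i in seq_along(take)) lab[clPoints[[take[i]]]] <- i - 1L
    lab
}

#' Render cluster labels as a false-color image
#'
#' Deterministic palette (a pure function of the number of clusters); the
#' noise label -1 is rendered gray (128, 128, 128). Pixel-domain labels give
#' an H x W x 3 array; peak-domain labels a 1 x K x 3 strip.
#'
#' @param labels a [LabelImage-class].
#' @return Numeric array with values in `[0, 1]`.
#' @export
renderLabels <- function(labels) {
    stopifnot(is(labels, "LabelImage"))
    pal <- .clusterPalette(labels@nClusters)
    lab <- if (labels@domain == "pixel") labels@labels
           else matrix(labels@labels, nrow = 1)
    H <- nrow(lab); W <- ncol(lab)
    out <- array(0, c(H, W, 3))
    gray <- 128 / 255
    for (ch in 1:3) {
        chan <- matrix(gray, H, W)
        pos <- lab >= 0L
        chan[pos] <- pal[lab[pos] + 1L, ch]
        out[, , ch] <- chan
    }
    out
}

## Fixed palette; first four echo the usual substrate-green / print-pink /
## print-blue / shared-red reading of segmented fingermark maps.
.clusterPalette <- function(n) {
    base <- c("#4DAF4A", "#F781BF", "#377EB8", "#E41A1C", "#FF7F00",
              "#984EA3", "#A65628", "#66C2A5", "#FFD92F", "#8DA0CB",
              "#E78AC3", "#A6D854")
    if (n == 0) return(matrix(numeric(), 0, 3))
    cols <- rep_len(base, n)
    t(grDevices::col2rgb(cols)) / 255
}
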