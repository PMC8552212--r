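make4Blobs <- function(nPer = 150, seed = 12) {
    set.seed(seed)
    centers <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
    list(coords = do.call(rbind, lapply(1:4, function(c)
             sweep(matrix(rnorm(3 * nPer, sd = 0.3), ncol = 3), 2,
                   centers[c, ], "+"))),
         labels = rep(1:4, each = nPer))
}

test_that("pixel clustering selects k and recovers separated blobs exactly", {
    b <- make4Blobs()
    li <- clusterPixels(b$coords, k = "auto", seed = 1)
    expect_equal(numClusters(li), 4L)
    expect_equal(mclust::adjustedRandIndex(as.integer(clusterLabels(li)),
                                           b$labels), 1)
    # every pixel labeled, no noise label in the pixel domain
    expect_true(all(clusterLabels(li) >= 0L))

    li1 <- clusterPixels(b$coords, k = 1)
    expect_equal(numClusters(li1), 1L)
    expect_true(all(clusterLabels(li1) == 0L))
    expect_error(clusterPixels(b$coords[1:3, ], k = 10), "exceeds")
})

test_that("pixel clustering is permutation invariant and deterministic", {
    b <- make4Blobs(nPer = 80)
    li <- clusterPixels(b$coords, k = 4, seed = 5)
    perm <- sample(nrow(b$coords))
    liP <- clusterPixels(b$coords[perm, ], k = 4, seed = 5)
    expect_equal(mclust::adjustedRandIndex(
        as.integer(clusterLabels(li))[perm],
        as.integer(clusterLabels(liP))), 1)
    # duplicates always share a label
    co <- rbind(b$coords, b$coords[1:5, ])
    liD <- clusterPixels(co, k = 4, seed = 5)
    lab <- as.integer(clusterLabels(liD))
    expect_equal(lab[nrow(b$coords) + 1:5], lab[1:5])
    # repeated identical calls give identical labels
    expect_identical(clusterLabels(clusterPixels(b$coords, seed = 2)),
                     clusterLabels(clusterPixels(b$coords, seed = 2)))
})

test_that("pixel clustering reshapes to raster geometry", {
    b <- make4Blobs(nPer = 100)
    li <- clusterPixels(b$coords, k = 4, seed = 1, geometry = c(20, 20))
    expect_equal(dim(clusterLabels(li)), c(20L, 20L))
    expect_error(clusterPixels(b$coords, geometry = c(7, 7)), "geometry")
})

test_that("matrix transposition is exact and involutive", {
    X <- matrix(rnorm(6), 2, 3)
    expect_identical(transposeMatrix(transposeMatrix(X)), X)
    expect_equal(rowSums(transposeMatrix(X)), colSums(X))
    for (i in 1:2) for (j in 1:3)
        expect_equal(transposeMatrix(X)[j, i], X[i, j])
})

test_that("peak clustering finds dense regions and flags noise", {
    set.seed(13)
    co <- rbind(matrix(rnorm(60, sd = 0.2), 30, 2),
                sweep(matrix(rnorm(60, sd = 0.2), 30, 2), 2, c(8, 8), "+"),
                matrix(runif(10, 30, 60), 5, 2))
    li <- clusterPeaks(co, minClusterSize = 10)
    expect_equal(numClusters(li), 2L)
    expect_gte(sum(clusterLabels(li) == -1L), 1L)
    # the two blobs are recovered exactly on non-noise points
    lab <- clusterLabels(li)
    blob <- rep(1:2, each = 30)
    nn <- lab[1:60] != -1L
    expect_equal(mclust::adjustedRandIndex(lab[1:60][nn], blob[nn]), 1)
    # deterministic
    expect_identical(clusterLabels(clusterPeaks(co, 10)), lab)
})

test_that("peak clustering degenerate cases", {
    same <- matrix(1, 20, 2)
    li <- clusterPeaks(same, minClusterSize = 5)
    expect_equal(numClusters(li), 1L)
    expect_true(all(clusterLabels(li) == 0L))

    co <- matrix(rnorm(20), 10, 2)
    expect_warning(liN <- clusterPeaks(co, minClusterSize = 11), "noise")
    expect_equal(numClusters(liN), 0L)
    expect_true(all(clusterLabels(liN) == -1L))
})

test_that("label rendering is deterministic with gray noise", {
    lab <- LabelImage(matrix(0L, 3, 4), domain = "pixel")
    img <- renderLabels(lab)
    expect_equal(dim(img), c(3, 4, 3))
    expect_equal(length(unique(as.vector(img))), 3L)  # one color

    li <- LabelImage(c(0L, 1L, -1L, 1L), domain = "peak")
    strip <- renderLabels(li)
    expect_equal(dim(strip), c(1, 4, 3))
    expect_equal(strip[1, 3, ], rep(128 / 255, 3))  # noise is gray
    expect_identical(renderLabels(li), strip)

    allNoise <- LabelImage(rep(-1L, 5), domain = "peak", nClusters = 0L)
    expect_true(all(renderLabels(allNoise) == 128 / 255))
})

test_that("centroid assignment labels every point by proximity", {
    cen <- rbind(c(0, 0), c(10, 0))
    co <- rbind(c(1, 0), c(9, 1), c(-2, 0), c(11, 0))
    li <- assignPixels(co, cen, geometry = c(2, 2))
    expect_equal(as.vector(t(clusterLabels(li))), c(0L, 1L, 0L, 1L))
})

test_that("mass-domain workflow: transposed embedding groups peaks by chemical template", {
    cfg <- phantomConfig(height = 168, width = 168, seed = 7)
    truth <- composeScene(cfg)
    cube <- sampleCube(truth, cfg)
    Xb <- densify(binCube(cube, 4)) / 16   # binned, per-pixel units
    Xt <- transposeMatrix(Xb)              # peaks described by pixel profiles
    m <- trainEmbedding(Xt, d = 2, kNeighbors = 8, epochs = 30, seed = 1)
    Y <- backfit(m, Xt)
    expect_identical(dim(Y), c(64L, 2L))
    expect_true(all(is.finite(Y)))

    sig <- cfg@signatures
    onlyA <- sig[2, ] > 0.3 & sig[1, ] < 0.1 & sig[3, ] < 0.3
    onlyB <- sig[3, ] > 0.3 & sig[1, ] < 0.1 & sig[2, ] < 0.3
    sub <- sig[1, ] > 0.1
    med <- function(i, j) median(as.vector(
        MSIbackfit:::.crossDist2(Y[i, , drop = FALSE], Y[j, , drop = FALSE])))
    # peaks of one print's template sit far closer to each other than to the
    # other print's or the substrate's peaks
    expect_lt(med(onlyA, onlyA) * 5, med(onlyA, onlyB))
    expect_lt(med(onlyA, onlyA) * 5, med(onlyA, sub))
    expect_lt(med(onlyB, onlyB) * 5, med(onlyB, sub))

    li <- clusterPeaks(Y, minClusterSize = 5)
    expect_gte(numClusters(li), 2L)
})
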