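test_that("ridge mask is the ellipse gated by the duty-cycle threshold", {
    zero <- phantomConfig(height = 60, width = 60,
                          prints = list(A = list(center = c(30, 30),
                                                 axes = c(0, 0), angle = 0,
                                                 phase = 0),
                                        B = list(center = c(30, 30),
                                                 axes = c(10, 10), angle = 0,
                                                 phase = 0)))
    expect_false(any(ridgeMask(zero, "A")))

    full <- phantomConfig(height = 80, width = 80, duty = 1)
    mA <- ridgeMask(full, "A")
    p <- full@prints$A
    y <- matrix(0:79, 80, 80); x <- t(y)
    ell <- ((y - p$center[1]) / p$axes[1])^2 +
           ((x - p$center[2]) / p$axes[2])^2 <= 1
    expect_equal(mA, ell)

    # duty = 0.5: the on-fraction inside a large ellipse is 0.5 +/- 0.02
    big <- phantomConfig(height = 420, width = 420, duty = 0.5,
                         ridgeFrequency = 1 / 42,
                         prints = list(A = list(center = c(210, 210),
                                                axes = c(200, 200),
                                                angle = 0.35, phase = 0),
                                       B = list(center = c(210, 210),
                                                axes = c(200, 200),
                                                angle = 0.35, phase = 0)))
    inside <- ridgeMask(phantomConfig(height = 420, width = 420, duty = 1,
                                      prints = big@prints), "A")
    frac <- sum(ridgeMask(big, "A")) / sum(inside)
    expect_lt(abs(frac - 0.5), 0.02)
})

test_that("scene composition labels overlap, single prints and substrate", {
    disjoint <- phantomConfig(height = 100, width = 100,
        prints = list(A = list(center = c(25, 25), axes = c(15, 15),
                               angle = 0, phase = 0),
                      B = list(center = c(75, 75), axes = c(15, 15),
                               angle = 1, phase = 0)))
    expect_false(any(classMap(composeScene(disjoint)) == 3L))

    same <- list(center = c(50, 50), axes = c(30, 30), angle = 0.3, phase = 1)
    identical_prints <- phantomConfig(height = 100, width = 100,
                                      prints = list(A = same, B = same))
    cm <- classMap(composeScene(identical_prints))
    expect_true(all(cm %in% c(0L, 3L)))
    expect_equal(sum(cm == 3L), sum(ridgeMask(identical_prints, "A")))

    ph <- smallPhantom()
    expect_equal(sort(unique(as.vector(classMap(ph$truth)))), 0:3)
    expect_equal(length(classMap(ph$truth)), 120 * 120)
})

test_that("occlusion formula: alpha = 1 without shared component copies the top print", {
    cfg <- phantomConfig(occlusionAlpha = 1, sharedRate = 0, order = "A")
    expect_equal(cfg@signatures[4, ], cfg@signatures[2, ])
    cfgB <- phantomConfig(occlusionAlpha = 1, sharedRate = 0, order = "B")
    expect_equal(cfgB@signatures[4, ], cfgB@signatures[3, ])
    # general alpha: convex combination plus the shared component, in [0, 1]
    cfgM <- phantomConfig(occlusionAlpha = 0.8)
    expect_true(all(cfgM@signatures >= 0 & cfgM@signatures <= 1))
})

test_that("sampling follows the per-class Bernoulli rates", {
    # all-zero signatures give an empty cube
    cfg0 <- substrateOnlyConfig(20, 20, rates = numeric(0))
    cube0 <- sampleCube(composeScene(cfg0), cfg0)
    expect_equal(nrow(cubeEvents(cube0)), 0L)

    # bernoulli counts are all 1
    ph <- smallPhantom()
    expect_true(all(cubeEvents(ph$cube)$count == 1L))

    # rate 0.3 over 1e5+ substrate pixels: empirical frequency 0.3 +/- 0.005
    cfg <- substrateOnlyConfig(320, 320, rates = 0.3, seed = 5)
    cube <- sampleCube(composeScene(cfg), cfg)
    freq <- totalCounts(cube) / (320 * 320)
    expect_lt(abs(freq - 0.3), 0.005)
})

test_that("poisson mode stores only positive counts and matches its mean", {
    sig <- matrix(0, 4, 2); sig[1, ] <- c(1.5, 0.2)
    cfg <- phantomConfig(height = 150, width = 150, nPeaks = 2,
                         signatures = sig, samplingMode = "poisson",
                         seed = 3,
                         prints = list(A = list(center = c(1, 1),
                                                axes = c(0, 0), angle = 0,
                                                phase = 0),
                                       B = list(center = c(1, 1),
                                                axes = c(0, 0), angle = 0,
                                                phase = 0)))
    cube <- sampleCube(composeScene(cfg), cfg)
    ev <- cubeEvents(cube)
    expect_true(all(ev$count >= 1L))
    expect_gt(max(ev$count), 1L)  # a Poisson(1.5) field has multi-counts
    m <- sum(ev$count[ev$peak == 0]) / (150 * 150)
    expect_lt(abs(m - 1.5) / sqrt(1.5 / 150^2), 4)  # within 4 sigma
})

test_that("identical config and seed give byte-identical cube files", {
    dir <- withr::local_tempdir()
    ph1 <- smallPhantom(seed = 9)
    ph2 <- smallPhantom(seed = 9)
    writeCube(ph1$cube, file.path(dir, "a"))
    writeCube(ph2$cube, file.path(dir, "b"))
    expect_identical(readBin(file.path(dir, "a.events.tsv"), "raw", 1e7),
                     readBin(file.path(dir, "b.events.tsv"), "raw", 1e7))
    ph3 <- smallPhantom(seed = 10)
    expect_false(identical(cubeEvents(ph3$cube), cubeEvents(ph1$cube)))
})

test_that("class-conditional mean spectra converge to the signature rows", {
    ph <- smallPhantom(seed = 11, height = 160, width = 160)
    X <- densify(ph$cube)
    cls <- as.integer(t(classMap(ph$truth)))
    sig <- ph$config@signatures
    for (c in 0:3) {
        n <- sum(cls == c)
        emp <- colMeans(X[cls == c, , drop = FALSE])
        se <- sqrt(pmax(sig[c + 1, ] * (1 - sig[c + 1, ]), 1e-6) / n)
        expect_true(all(abs(emp - sig[c + 1, ]) < 4 * se),
                    label = sprintf("class %d within 4 sigma", c))
    }
})

test_that("barcode counting statistics hold on a desk-scale phantom", {
    ph <- smallPhantom(seed = 2)
    expect_lte(max(totalIonMap(ph$cube)), 100)
    expect_true(all(cubeEvents(ph$cube)$count == 1L))
    expect_true(all(rowSums(ph$config@signatures) <= ph$config@ticCap))
})
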