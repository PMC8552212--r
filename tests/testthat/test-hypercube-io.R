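test_that("empty cube round-trips with declared dims and zero counts", {
    cube <- makeCube(4, 4, 3)
    expect_equal(totalCounts(cube), 0)
    prefix <- file.path(withr::local_tempdir(), "empty")
    writeCube(cube, prefix)
    back <- loadCube(prefix)
    expect_equal(dim(back), c(4L, 4L))
    expect_equal(nPeaks(back), 3L)
    expect_equal(totalCounts(back), 0)
    expect_true(all(totalIonMap(back) == 0))
})

test_that("write/load round-trip preserves dims, peaks and event multiset", {
    set.seed(42)
    ev <- unique(data.frame(row = sample(0:5, 40, TRUE),
                            col = sample(0:7, 40, TRUE),
                            peak = sample(0:2, 40, TRUE)))
    ev$count <- sample(1:9, nrow(ev), TRUE)
    cube <- SparseCube(6, 8, 3, ev, peaks = makePeaks(3),
                       meta = list(pixel_size_um = 2))
    prefix <- file.path(withr::local_tempdir(), "cube")
    writeCube(cube, prefix)
    back <- loadCube(prefix)
    expect_equal(dim(back), dim(cube))
    canon <- function(x) {
        e <- cubeEvents(x)
        e <- e[order(e$row, e$col, e$peak), ]
        rownames(e) <- NULL
        e
    }
    expect_equal(canon(back), canon(cube))
    expect_equal(peakList(back)@centroidMz, makePeaks(3)@centroidMz)
    expect_equal(cubeMeta(back)$pixel_size_um, 2)
    # second round trip is bit-exact
    prefix2 <- file.path(withr::local_tempdir(), "cube2")
    writeCube(back, prefix2)
    expect_identical(readLines(paste0(prefix, ".events.tsv")),
                     readLines(paste0(prefix2, ".events.tsv")))
})

test_that("equal event multisets in different order give byte-identical files", {
    ev <- data.frame(row = c(2L, 0L, 1L), col = c(1L, 2L, 0L),
                     peak = c(0L, 1L, 2L), count = c(3L, 1L, 2L))
    dir <- withr::local_tempdir()
    writeCube(SparseCube(3, 3, 3, ev), file.path(dir, "a"))
    writeCube(SparseCube(3, 3, 3, ev[c(3, 1, 2), ]), file.path(dir, "b"))
    expect_identical(readBin(file.path(dir, "a.events.tsv"), "raw", 10000),
                     readBin(file.path(dir, "b.events.tsv"), "raw", 10000))
})

test_that("loading merges duplicate triplets by summing, with a warning", {
    dir <- withr::local_tempdir()
    writeLines(c("row\tcol\tpeak\tcount", "0\t0\t0\t1", "0\t0\t0\t2"),
               file.path(dir, "d.events.tsv"))
    jsonlite::write_json(list(height = 4, width = 4, n_peaks = 3),
                         file.path(dir, "d.meta.json"), auto_unbox = TRUE)
    expect_warning(cube <- loadCube(file.path(dir, "d")), "merged 1 duplicate")
    expect_equal(nrow(cubeEvents(cube)), 1L)
    expect_equal(cubeEvents(cube)$count, 3L)
})

test_that("malformed containers fail loudly, naming the offending record", {
    dir <- withr::local_tempdir()
    meta <- file.path(dir, "x.meta.json")
    jsonlite::write_json(list(height = 2, width = 2, n_peaks = 1), meta,
                         auto_unbox = TRUE)
    writeLines(c("a\tb\tc\td", "0\t0\t0\t1"), file.path(dir, "x.events.tsv"))
    expect_error(loadCube(file.path(dir, "x")), "malformed event header")
    writeLines(c("row\tcol\tpeak\tcount", "0\t0\t0\t1", "5\t0\t0\t1"),
               file.path(dir, "x.events.tsv"))
    expect_error(loadCube(file.path(dir, "x")), "record 2.*outside declared bounds")
    writeLines(c("row\tcol\tpeak\tcount", "0\t0\t0\t-2"),
               file.path(dir, "x.events.tsv"))
    expect_error(loadCube(file.path(dir, "x")), "non-positive count")
})

test_that("total ion map sums events per pixel and partitions over peaks", {
    expect_true(all(totalIonMap(makeCube()) == 0))
    one <- makeCube(4, 5, 3, data.frame(row = 2, col = 3, peak = 1, count = 5))
    tim <- totalIonMap(one)
    expect_equal(tim[3, 4], 5L)
    expect_equal(sum(tim), 5)

    ev <- data.frame(row = c(0, 0, 1), col = c(0, 0, 1),
                     peak = c(0, 1, 2), count = c(1, 1, 1))
    cube <- makeCube(2, 2, 3, ev)
    expect_equal(totalIonMap(cube), matrix(c(2L, 0L, 0L, 1L), 2, byrow = TRUE))

    ph <- smallPhantom()
    maps <- lapply(seq_len(nPeaks(ph$cube)) - 1L, ionMap, cube = ph$cube)
    expect_equal(Reduce(`+`, maps), totalIonMap(ph$cube))
})

test_that("single-peak ion maps respect the single-count regime", {
    cube <- smallPhantom()$cube  # bernoulli counts
    m <- ionMap(cube, 0L)
    expect_true(all(m %in% c(0L, 1L)))
    expect_true(all(ionMap(makeCube(), 2L) == 0))
    expect_error(ionMap(makeCube(), 3L), "peakIndex")
    expect_error(ionMap(makeCube(), -1L), "peakIndex")
})

test_that("PNG export writes images readable at the same size", {
    dir <- withr::local_tempdir()
    img <- matrix(0:11, 3, 4)
    p <- writeImagePNG(img, file.path(dir, "g.png"))
    expect_equal(dim(png::readPNG(p)), c(3, 4))
    rgb <- array(runif(24), c(2, 4, 3))
    p2 <- writeImagePNG(rgb, file.path(dir, "c.png"))
    expect_equal(dim(png::readPNG(p2)), c(2, 4, 3))
})

test_that("imzML import integrates spectra into peak windows on the grid", {
    dir <- withr::local_tempdir()
    peaks <- makePeaks(3)  # windows [9.5,10.5), [19.5,20.5), [29.5,30.5)
    spectra <- list(
        list(x = 1, y = 1, mz = c(9.9, 10.1, 20.0, 35.0),
             intensity = c(1, 1, 2, 7)),
        list(x = 2, y = 1, mz = c(29.9), intensity = c(1)),
        list(x = 1, y = 2, mz = c(10.49, 10.51), intensity = c(1, 1)))
    path <- writeTinyImzML(dir, spectra)
    cube <- readImzML(path, peaks)
    expect_equal(dim(cube), c(2L, 2L))
    expect_equal(nPeaks(cube), 3L)
    # pixel (0,0): peak0 = 1+1, peak1 = 2; the 35.0 signal is outside all windows
    expect_equal(ionMap(cube, 0L)[1, 1], 2L)
    expect_equal(ionMap(cube, 1L)[1, 1], 2L)
    expect_equal(ionMap(cube, 2L)[1, 2], 1L)
    # half-open window: 10.49 in, 10.51 out
    expect_equal(ionMap(cube, 0L)[2, 1], 1L)
    expect_equal(totalCounts(cube), 6)
})
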