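# Shared fixture builders; everything is generated in code.

makeCube <- function(height = 4, width = 4, nPeaks = 3, events = NULL,
                     peaks = NULL) {
    SparseCube(height, width, nPeaks, events, peaks = peaks)
}

makePeaks <- function(n = 3) {
    PeakList(paste0("p", seq_len(n)), centroidMz = 10 * seq_len(n),
             windowLo = 10 * seq_len(n) - 0.5,
             windowHi = 10 * seq_len(n) + 0.5)
}

# three Gaussian blobs with 2-D intrinsic structure lifted into 5-D
makeBlobs <- function(nPer = 200, sep = 25, seed = 2, noiseSd = 0.05) {
    set.seed(seed)
    B <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
    centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
    Z <- do.call(rbind, lapply(1:3, function(c)
        sweep(matrix(rnorm(2 * nPer), ncol = 2), 2, centers[c, ], "+")))
    list(X = Z %*% t(B) + matrix(rnorm(5 * 3 * nPer, sd = noiseSd), ncol = 5),
         labels = rep(1:3, each = nPer))
}

# small phantom used by several module tests (not the acceptance phantom)
smallPhantom <- function(seed = 7, height = 120, width = 120) {
    cfg <- phantomConfig(height = height, width = width, seed = seed)
    truth <- composeScene(cfg)
    list(config = cfg, truth = truth, cube = sampleCube(truth, cfg))
}

# a phantom whose scene is 100% substrate (prints of zero area)
substrateOnlyConfig <- function(height, width, nPeaks = 4, rates, seed = 1) {
    sig <- matrix(0, 4, nPeaks)
    sig[1, seq_along(rates)] <- rates
    phantomConfig(height = height, width = width, nPeaks = nPeaks,
                  signatures = sig, seed = seed,
                  prints = list(A = list(center = c(1, 1), axes = c(0, 0),
                                         angle = 0, phase = 0),
                                B = list(center = c(1, 1), axes = c(0, 0),
                                         angle = 0, phase = 0)))
}

# minimal imzML + ibd pair (continuous-style external binary arrays)
writeTinyImzML <- function(dir, spectra, dtype = "MS:1000523") {
    # spectra: list of list(x=, y=, mz=, intensity=)
    ibd <- file.path(dir, "tiny.ibd")
    con <- file(ibd, "wb")
    offsets <- list()
    pos <- 0
    for (i in seq_along(spectra)) {
        sp <- spectra[[i]]
        writeBin(as.numeric(sp$mz), con, size = 8)
        offsets[[i]] <- list(mz = pos, mzLen = length(sp$mz))
        pos <- pos + 8 * length(sp$mz)
        writeBin(as.numeric(sp$intensity), con, size = 8)
        offsets[[i]]$int <- pos
        offsets[[i]]$intLen <- length(sp$intensity)
        pos <- pos + 8 * length(sp$intensity)
    }
    close(con)
    arr <- function(ref, acc, off) sprintf(
        '<binaryDataArray encodedLength="0">
           <referenceableParamGroupRef ref="%s"/>
           <cvParam accession="IMS:1000102" name="external offset" value="%d"/>
           <cvParam accession="IMS:1000103" name="external array length" value="%d"/>
           <binary/>
         </binaryDataArray>', ref, off$off, off$len)
    spx <- vapply(seq_along(spectra), function(i) {
        sp <- spectra[[i]]; off <- offsets[[i]]
        sprintf('<spectrum index="%d" id="spectrum=%d">
          <scanList count="1"><scan>
            <cvParam accession="IMS:1000050" name="position x" value="%d"/>
            <cvParam accession="IMS:1000051" name="position y" value="%d"/>
          </scan></scanList>
          <binaryDataArrayList count="2">%s%s</binaryDataArrayList>
        </spectrum>',
            i - 1L, i, sp$x, sp$y,
            arr("mzArray", "MS:1000514", list(off = off$mz, len = off$mzLen)),
            arr("intensityArray", "MS:1000515",
                list(off = off$int, len = off$intLen)))
    }, character(1))
    xml <- sprintf('<?xml version="1.0" encoding="UTF-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">
  <referenceableParamGroupList count="2">
    <referenceableParamGroup id="mzArray">
      <cvParam accession="MS:1000514" name="m/z array" value=""/>
      <cvParam accession="%s" name="float" value=""/>
    </referenceableParamGroup>
    <referenceableParamGroup id="intensityArray">
      <cvParam accession="MS:1000515" name="intensity array" value=""/>
      <cvParam accession="%s" name="float" value=""/>
    </referenceableParamGroup>
  </referenceableParamGroupList>
  <run id="r1">
    <spectrumList count="%d">%s</spectrumList>
  </run>
</mzML>', dtype, dtype, length(spectra), paste(spx, collapse = "\n"))
    path <- file.path(dir, "tiny.imzML")
    writeLines(xml, path)
    path
}

# Independent oracle: smooth-kNN bandwidth by bisection over the full
# distance matrix, written against the definition only.
oracleSigma <- function(X, k) {
    d <- as.matrix(dist(X))
    n <- nrow(X)
    sapply(seq_len(n), function(i) {
        di <- sort(d[i, -i])[seq_len(k)]
        rho <- di[1]
        f <- function(s) sum(exp(-pmax(0, di - rho) / s)) - log2(k)
        lo <- 1e-8; hi <- 100
        for (it in 1:200) {
            mid <- (lo + hi) / 2
            if (f(mid) > 0) hi <- mid else lo <- mid
        }
        (lo + hi) / 2
    })
}
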