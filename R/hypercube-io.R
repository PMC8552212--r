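#' Write a SparseCube to the native sparse container
#'
#' Writes three files sharing a prefix: `<prefix>.events.tsv` (columns
#' `row`, `col`, `peak`, `count`, tab-separated, events in (row, col, peak)
#' lexicographic order so equal cubes produce byte-identical files),
#' `<prefix>.meta.json` (raster geometry and provenance) and, when the cube
#' carries a [PeakList-class], `<prefix>.peaks.tsv`.
#'
#' @param cube a [SparseCube-class].
#' @param prefix output path prefix (directories must exist).
#' @return The prefix, invisibly.
#' @seealso [loadCube()]
#' @export
writeCube <- function(cube, prefix) {
    stopifnot(is(cube, "SparseCube"))
    validObject(cube)
    ev <- .canonicalEventOrder(cube@events)
    data.table::fwrite(ev, paste0(prefix, ".events.tsv"), sep = "\t",
                       eol = "\n")
    meta <- cube@meta
    meta$height <- cube@height
    meta$width <- cube@width
    meta$n_peaks <- cube@nPeaks
    if (is.null(meta$bin_factor)) meta$bin_factor <- 1L
    jsonlite::write_json(meta, paste0(prefix, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(cube@peaks)) {
        pk <- data.frame(peak_id = cube@peaks@peakId,
                         centroid_mz = cube@peaks@centroidMz,
                         window_lo = cube@peaks@windowLo,
                         window_hi = cube@peaks@windowHi)
        data.table::fwrite(pk, paste0(prefix, ".peaks.tsv"), sep = "\t",
                           eol = "\n")
    }
    invisible(prefix)
}

#' Load a SparseCube from the native sparse container
#'
#' Reads the three-file container written by [writeCube()]. Duplicate
#' (row, col, peak) triplets are merged by summing their counts, with a
#' warning. Malformed headers, indices outside the declared bounds and
#' non-positive counts are hard errors naming the offending record.
#'
#' @param prefix path prefix of the container.
#' @return A [SparseCube-class].
#' @export
loadCube <- function(prefix) {
    metaPath <- paste0(prefix, ".meta.json")
    evPath <- paste0(prefix, ".events.tsv")
    if (!file.exists(metaPath)) stop("missing sidecar: ", metaPath)
    if (!file.exists(evPath)) stop("missing event table: ", evPath)
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    for (f in c("height", "width", "n_peaks"))
        if (is.null(meta[[f]])) stop("meta.json lacks required field '", f, "'")
    height <- as.integer(meta$height)
    width <- as.integer(meta$width)
    nPeaks <- as.integer(meta$n_peaks)
    ev <- as.data.frame(data.table::fread(evPath, sep = "\t"))
    if (!identical(names(ev), c("row", "col", "peak", "count")))
        stop("malformed event header in ", evPath,
             ": expected 'row col peak count', got '",
             paste(names(ev), collapse = " "), "'")
    if (nrow(ev)) {
        bad <- which(ev$row < 0 | ev$row >= height | ev$col < 0 |
                     ev$col >= width | ev$peak < 0 | ev$peak >= nPeaks)
        if (length(bad))
            stop(sprintf("event record %d (row=%s col=%s peak=%s) outside declared bounds %dx%dx%d",
                         bad[1], ev$row[bad[1]], ev$col[bad[1]], ev$peak[bad[1]],
                         height, width, nPeaks))
        bad <- which(ev$count < 1)
        if (length(bad))
            stop(sprintf("event record %d has non-positive count %s",
                         bad[1], ev$count[bad[1]]))
    }
    peaks <- NULL
    pkPath <- paste0(prefix, ".peaks.tsv")
    if (file.exists(pkPath)) {
        pk <- as.data.frame(data.table::fread(pkPath, sep = "\t"))
        peaks <- PeakList(pk$peak_id, pk$centroid_mz, pk$window_lo,
                          pk$window_hi)
    }
    keep <- setdiff(names(meta), c("height", "width", "n_peaks"))
    SparseCube(height, width, nPeaks, ev, peaks = peaks,
               meta = as.list(meta)[keep], mergeDuplicates = TRUE)
}

#' Total ion count (TIC) map
#'
#' The TIC map is the per-pixel sum of the counts of all integrated peaks:
#' the image the detector "saw" across the whole peak list. Its grand sum
#' equals `totalCounts(cube)`.
#'
#' @param cube a [SparseCube-class].
#' @return An H x W integer matrix.
#' @export
totalIonMap <- function(cube) {
    stopifnot(is(cube, "SparseCube"))
    .accumulatePixelCounts(cube, cube@events)
}

#' Single-peak ion map
#'
#' Per-pixel counts of one integrated peak, e.g. the m/z 12 carbon channel.
#' In the single-count regime the result is a black-and-white image with
#' values in \{0, 1\}.
#'
#' @param cube a [SparseCube-class].
#' @param peakIndex 0-based peak index in `[0, nPeaks)`.
#' @return An H x W integer matrix.
#' @export
ionMap <- function(cube, peakIndex) {
    stopifnot(is(cube, "SparseCube"))
    peakIndex <- as.integer(peakIndex)
    if (length(peakIndex) != 1L || is.na(peakIndex) || peakIndex < 0L ||
        peakIndex >= cube@nPeaks)
        stop("peakIndex must be a single integer in [0, ", cube@nPeaks, ")")
    .accumulatePixelCounts(cube, cube@events[cube@events$peak == peakIndex, ])
}

.accumulatePixelCounts <- function(cube, ev) {
    H <- cube@height; W <- cube@width
    img <- matrix(0L, H, W)
    if (nrow(ev)) {
        lin <- ev$row * as.double(W) + ev$col
        agg <- rowsum(as.numeric(ev$count), lin, reorder = FALSE)
        p <- as.numeric(rownames(agg))
        img[cbind(p %/% W + 1, p %% W + 1)] <- as.integer(agg[, 1])
    }
    img
}

#' Export an image matrix or RGB array as PNG
#'
#' Grayscale matrices are rescaled to `[0, 1]` by their maximum (an all-zero
#' image stays black); RGB arrays (H x W x 3, values in `[0, 1]`) are written
#' as-is. 8-bit output.
#'
#' @param img numeric matrix or H x W x 3 array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(img, path) {
    if (is.matrix(img)) {
        mx <- max(img)
        img <- if (mx > 0) img / mx else img * 0
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    png::writePNG(img, path)
    invisible(path)
}

## ---- imzML import -----------------------------------------------------

#' Import an imzML/ibd pair as a SparseCube
#'
#' Minimal reader for the imzML interchange format (continuous or processed
#' mode): spectra are located on the pixel grid via the standard position
#' cvParams (IMS:1000050/51, 1-based), their m/z and intensity arrays are
#' read from the external `.ibd` binary at the declared offsets, and
#' intensities are integrated into the half-open windows of `peaks` to give
#' the K channels of the cube.
#'
#' @param path path to the `.imzML` XML file; the `.ibd` file is expected
#'   alongside it (same stem).
#' @param peaks a [PeakList-class] defining the integration windows.
#' @return A [SparseCube-class] with `nPeaks = length(peaks)`.
#' @export
readImzML <- function(path, peaks) {
    stopifnot(is(peaks, "PeakList"))
    ibd <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
    if (!file.exists(ibd)) stop("missing binary companion file: ", ibd)
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)

    paramTable <- function(nodes) data.frame(
        accession = xml2::xml_attr(nodes, "accession"),
        value = xml2::xml_attr(nodes, "value"),
        stringsAsFactors = FALSE)
    ## referenceable param groups (commonly hold array dtype / array kind)
    groups <- list()
    for (g in xml2::xml_find_all(doc, ".//referenceableParamGroup")) {
        id <- xml2::xml_attr(g, "id")
        groups[[id]] <- paramTable(xml2::xml_find_all(g, "./cvParam"))
    }
    valOf <- function(tab, acc) {
        hit <- which(tab$accession == acc)
        if (length(hit)) tab$value[hit[1]] else NA_character_
    }
    spectra <- xml2::xml_find_all(doc, ".//spectrum")
    if (!length(spectra)) stop("no spectrum elements found in ", path)

    con <- file(ibd, "rb")
    on.exit(close(con))
    rows <- cols <- pk <- cnt <- vector("list", length(spectra))
    maxX <- 0L; maxY <- 0L
    for (si in seq_along(spectra)) {
        sp <- spectra[[si]]
        scanParams <- paramTable(xml2::xml_find_all(sp, ".//scan/cvParam"))
        x <- as.integer(valOf(scanParams, "IMS:1000050"))
        y <- as.integer(valOf(scanParams, "IMS:1000051"))
        if (is.na(x) || is.na(y))
            stop("spectrum ", si, " lacks pixel position cvParams")
        maxX <- max(maxX, x); maxY <- max(maxY, y)
        mzv <- intv <- NULL
        for (arr in xml2::xml_find_all(sp, ".//binaryDataArray")) {
            params <- paramTable(xml2::xml_find_all(arr, "./cvParam"))
            ref <- xml2::xml_attr(xml2::xml_find_first(arr,
                        "./referenceableParamGroupRef"), "ref")
            if (!is.na(ref) && !is.null(groups[[ref]]))
                params <- rbind(params, groups[[ref]])
            acc <- params$accession
            offset <- as.numeric(valOf(params, "IMS:1000102"))
            alen <- as.integer(valOf(params, "IMS:1000103"))
            if (is.na(offset) || is.na(alen))
                stop("binary array in spectrum ", si,
                     " lacks external offset/length cvParams")
            size <- if ("MS:1000523" %in% acc) 8L else 4L
            seek(con, where = offset, origin = "start")
            vals <- readBin(con, "double", n = alen, size = size)
            if ("MS:1000514" %in% acc) mzv <- vals
            else if ("MS:1000515" %in% acc) intv <- vals
        }
        if (is.null(mzv) || is.null(intv))
            stop("spectrum ", si, " lacks m/z or intensity array")
        ## integrate into half-open windows [lo, hi)
        k <- findInterval(mzv, peaks@windowLo)
        inWin <- k >= 1 & mzv < peaks@windowHi[pmax(k, 1L)]
        if (!any(inWin)) next
        agg <- rowsum(intv[inWin], k[inWin])
        kk <- as.integer(rownames(agg))
        c0 <- as.integer(round(agg[, 1]))
        keep <- c0 > 0L
        rows[[si]] <- rep.int(y - 1L, sum(keep))
        cols[[si]] <- rep.int(x - 1L, sum(keep))
        pk[[si]] <- kk[keep] - 1L
        cnt[[si]] <- c0[keep]
    }
    ev <- data.frame(row = unlist(rows), col = unlist(cols),
                     peak = unlist(pk), count = unlist(cnt))
    if (is.null(ev$row)) ev <- data.frame(row = integer(), col = integer(),
                                          peak = integer(), count = integer())
    SparseCube(maxY, maxX, length(peaks), ev, peaks = peaks,
               meta = list(provenance = paste("imzML import:", basename(path))),
               mergeDuplicates = TRUE)
}
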