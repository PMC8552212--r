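#' @import methods
#' @importFrom stats dist hclust cutree as.dist prcomp rpois runif rnorm
#'   quantile sd
NULL

#' Peak list: m/z integration windows defining the hyperspectral channels
#'
#' An ordered set of K mass peaks. Each peak has an identifier, a centroid
#' m/z and a half-open integration window `[windowLo, windowHi)`. The peak
#' index used throughout the package (0-based) is the position in this list,
#' which is sorted by centroid m/z.
#'
#' @slot peakId character vector of unique peak identifiers.
#' @slot centroidMz numeric vector of centroid m/z values, ascending.
#' @slot windowLo,windowHi numeric vectors of window bounds, half-open.
#' @export
setClass("PeakList",
    slots = c(
        peakId = "character",
        centroidMz = "numeric",
        windowLo = "numeric",
        windowHi = "numeric"
    )
)

setValidity("PeakList", function(object) {
    n <- length(object@peakId)
    if (length(object@centroidMz) != n || length(object@windowLo) != n ||
        length(object@windowHi) != n)
        return("peakId, centroidMz, windowLo, windowHi must have equal length")
    if (n == 0L) return(TRUE)
    if (anyDuplicated(object@peakId)) return("peakId values must be unique")
    if (any(!is.finite(object@centroidMz)) || any(object@centroidMz <= 0))
        return("centroidMz must be finite and positive")
    if (any(object@windowLo >= object@windowHi))
        return("every window must satisfy windowLo < windowHi")
    if (any(object@centroidMz < object@windowLo |
            object@centroidMz >= object@windowHi))
        return("centroidMz must lie inside its half-open window [lo, hi)")
    if (is.unsorted(object@centroidMz))
        return("entries must be sorted by centroidMz ascending")
    TRUE
})

#' Construct a PeakList
#'
#' Entries are sorted by centroid m/z; the 0-based position in the sorted
#' list is the peak index used by [SparseCube] events.
#'
#' @param peakId character identifiers (unique).
#' @param centroidMz positive centroid m/z values.
#' @param windowLo,windowHi half-open integration window bounds, with
#'   `windowLo <= centroidMz < windowHi`.
#' @return A [PeakList-class] object.
#' @examples
#' pl <- PeakList(c("C", "CH"), c(12.0, 13.008),
#'                windowLo = c(11.8, 12.8), windowHi = c(12.4, 13.4))
#' length(pl)
#' @export
PeakList <- function(peakId, centroidMz, windowLo, windowHi) {
    ord <- order(centroidMz)
    new("PeakList",
        peakId = as.character(peakId)[ord],
        centroidMz = as.numeric(centroidMz)[ord],
        windowLo = as.numeric(windowLo)[ord],
        windowHi = as.numeric(windowHi)[ord])
}

#' @describeIn PeakList number of peaks.
#' @param x a PeakList.
#' @export
setMethod("length", "PeakList", function(x) length(x@peakId))

setMethod("show", "PeakList", function(object) {
    cat(sprintf("PeakList with %d peaks", length(object)))
    if (length(object) > 0)
        cat(sprintf(", m/z %.4g-%.4g", min(object@centroidMz),
                    max(object@centroidMz)))
    cat("\n")
})

setIsValidEvents <- function(events, height, width, nPeaks) {
    required <- c("row", "col", "peak", "count")
    if (!is.data.frame(events) || !all(required %in% names(events)))
        return("events must be a data.frame with columns row, col, peak, count")
    ev <- events[required]
    if (nrow(ev) == 0L) return(TRUE)
    bad <- which(ev$row < 0L | ev$row >= height | ev$col < 0L |
                 ev$col >= width | ev$peak < 0L | ev$peak >= nPeaks)
    if (length(bad))
        return(sprintf("event %d has indices out of bounds (row=%d col=%d peak=%d)",
                       bad[1], ev$row[bad[1]], ev$col[bad[1]], ev$peak[bad[1]]))
    bad <- which(ev$count < 1L)
    if (length(bad))
        return(sprintf("event %d has non-positive count %d (zeros must be absent)",
                       bad[1], ev$count[bad[1]]))
    if (anyDuplicated(ev$row * (width * as.double(nPeaks)) +
                      ev$col * as.double(nPeaks) + ev$peak))
        return("duplicate (row, col, peak) triplets; merge before construction")
    TRUE
}

setClassUnion("PeakListOrNULL", members = c("PeakList", "NULL"))

#' Sparse hyperspectral image cube
#'
#' An H x W pixel raster with K integrated mass peaks, stored as an event
#' list: one record per nonzero (row, col, peak) triplet with its integer
#' count. Zeros are absent, not stored, which is the natural representation
#' for the "barcode" counting regime of macroraster ToF-SIMS images where
#' almost all cells are empty. Coordinates and peak indices are 0-based,
#' row-major, origin at the top-left pixel.
#'
#' @slot height,width raster dimensions in pixels.
#' @slot nPeaks number of integrated peaks K.
#' @slot events data.frame with integer columns `row`, `col`, `peak`,
#'   `count`; at most one record per triplet, counts >= 1.
#' @slot peaks optional [PeakList-class] describing the K channels.
#' @slot meta free-form provenance list (bin factor, pixel size, source).
#' @export
setClass("SparseCube",
    slots = c(
        height = "integer",
        width = "integer",
        nPeaks = "integer",
        events = "data.frame",
        peaks = "PeakListOrNULL",
        meta = "list"
    )
)

setValidity("SparseCube", function(object) {
    if (length(object@height) != 1L || object@height < 1L)
        return("height must be a single positive integer")
    if (length(object@width) != 1L || object@width < 1L)
        return("width must be a single positive integer")
    if (length(object@nPeaks) != 1L || object@nPeaks < 1L)
        return("nPeaks must be a single positive integer")
    if (!is.null(object@peaks) && length(object@peaks) != object@nPeaks)
        return("peaks list length must equal nPeaks")
    setIsValidEvents(object@events, object@height, object@width, object@nPeaks)
})

.mergeEvents <- function(events, warn = TRUE) {
    if (nrow(events) == 0L) return(events)
    key <- paste(events$row, events$col, events$peak)
    if (anyDuplicated(key)) {
        if (warn)
            warning(sprintf("merged %d duplicate (row, col, peak) triplets by summing counts",
                            sum(duplicated(key))), call. = FALSE)
        agg <- rowsum(as.numeric(events$count), key, reorder = FALSE)
        first <- !duplicated(key)
        events <- events[first, , drop = FALSE]
        events$count <- as.integer(agg[match(key[first], rownames(agg)), 1])
    }
    events
}

.canonicalEventOrder <- function(events) {
    events[order(events$row, events$col, events$peak), , drop = FALSE]
}

#' Construct a SparseCube
#'
#' @param height,width raster dimensions in pixels.
#' @param nPeaks number of peaks K.
#' @param events data.frame with 0-based integer columns `row`, `col`,
#'   `peak` and positive integer `count`. Omitted triplets are zeros.
#' @param peaks optional [PeakList-class] of length `nPeaks`.
#' @param meta provenance list.
#' @param mergeDuplicates if TRUE, duplicate triplets are summed (with a
#'   warning) instead of being rejected by the validity check.
#' @return A [SparseCube-class].
#' @examples
#' ev <- data.frame(row = 0L, col = 1L, peak = 0L, count = 2L)
#' cube <- SparseCube(2, 2, 3, ev)
#' totalCounts(cube)
#' @export
SparseCube <- function(height, width, nPeaks, events = NULL, peaks = NULL,
                       meta = list(), mergeDuplicates = FALSE) {
    if (is.null(events))
        events <- data.frame(row = integer(), col = integer(),
                             peak = integer(), count = integer())
    events <- data.frame(row = as.integer(events$row),
                         col = as.integer(events$col),
                         peak = as.integer(events$peak),
                         count = as.integer(events$count))
    if (mergeDuplicates) events <- .mergeEvents(events)
    rownames(events) <- NULL
    new("SparseCube", height = as.integer(height), width = as.integer(width),
        nPeaks = as.integer(nPeaks), events = events, peaks = peaks,
        meta = meta)
}

setMethod("show", "SparseCube", function(object) {
    cat(sprintf("SparseCube: %d x %d pixels, %d peaks, %d events, %.0f total counts\n",
                object@height, object@width, object@nPeaks,
                nrow(object@events), totalCounts(object)))
    if (!is.null(object@meta$bin_factor))
        cat(sprintf("  bin factor: %s\n", object@meta$bin_factor))
})

#' @describeIn SparseCube raster dimensions `c(height, width)`.
#' @param x a SparseCube.
#' @export
setMethod("dim", "SparseCube", function(x) c(x@height, x@width))

#' Accessors for SparseCube
#'
#' @param x a [SparseCube-class].
#' @return `cubeEvents` the event data.frame; `nPeaks` the number of peaks;
#'   `peakList` the [PeakList-class] or NULL; `cubeMeta` the provenance
#'   list; `totalCounts` the sum of all event counts.
#' @name cube-accessors
NULL

#' @rdname cube-accessors
#' @export
cubeEvents <- function(x) x@events

#' @rdname cube-accessors
#' @export
nPeaks <- function(x) x@nPeaks

#' @rdname cube-accessors
#' @export
peakList <- function(x) x@peaks

#' @rdname cube-accessors
#' @export
cubeMeta <- function(x) x@meta

#' @rdname cube-accessors
#' @export
totalCounts <- function(x) sum(as.numeric(x@events$count))

#' Per-pixel or per-peak cluster labels
#'
#' In the pixel domain, `labels` is an H x W integer matrix with values in
#' `[0, nClusters)`; every pixel is labeled (no noise label). In the peak
#' (mass) domain, `labels` is a length-K integer vector where -1 marks noise
#' points left unclustered by the density-based algorithm, mirroring the
#' gray points of a mass-domain embedding plot.
#'
#' @slot labels integer matrix (pixel domain) or vector (peak domain).
#' @slot nClusters number of clusters (noise excluded).
#' @slot domain `"pixel"` or `"peak"`.
#' @export
setClass("LabelImage",
    slots = c(labels = "ANY", nClusters = "integer", domain = "character"))

setValidity("LabelImage", function(object) {
    if (!object@domain %in% c("pixel", "peak"))
        return("domain must be 'pixel' or 'peak'")
    lab <- as.integer(object@labels)
    if (any(is.na(lab))) return("labels must not contain NA")
    if (object@domain == "pixel") {
        if (!is.matrix(object@labels)) return("pixel-domain labels must be a matrix")
        if (any(lab < 0L)) return("noise label -1 is forbidden in the pixel domain")
    } else {
        if (any(lab < -1L)) return("peak-domain labels must be >= -1")
    }
    if (any(lab >= object@nClusters))
        return("labels must be < nClusters")
    TRUE
})

#' @describeIn LabelImage constructor.
#' @param labels integer matrix (pixel) or vector (peak); -1 is noise
#'   (peak domain only).
#' @param domain `"pixel"` or `"peak"`.
#' @param nClusters number of clusters; defaults to `max(labels) + 1`.
#' @export
LabelImage <- function(labels, domain = c("pixel", "peak"),
                       nClusters = NULL) {
    domain <- match.arg(domain)
    if (is.null(nClusters))
        nClusters <- max(0L, max(as.integer(labels)) + 1L)
    if (domain == "pixel") storage.mode(labels) <- "integer"
    else labels <- as.integer(labels)
    new("LabelImage", labels = labels, nClusters = as.integer(nClusters),
        domain = domain)
}

setMethod("show", "LabelImage", function(object) {
    if (object@domain == "pixel") {
        cat(sprintf("LabelImage (pixel domain): %d x %d pixels, %d clusters\n",
                    nrow(object@labels), ncol(object@labels), object@nClusters))
    } else {
        cat(sprintf("LabelImage (peak domain): %d peaks, %d clusters, %d noise\n",
                    length(object@labels), object@nClusters,
                    sum(object@labels == -1L)))
    }
})

#' @describeIn LabelImage the label matrix or vector.
#' @param x a LabelImage.
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn LabelImage number of clusters (noise label excluded).
#' @export
numClusters <- function(x) x@nClusters
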