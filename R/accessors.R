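#' @name accessors
#' @title Accessors for spheroidquant classes
#' @description Small accessor generics: slot access stays behind functions.
#' @param object,x an object of the documented classes.
#' @param i slice index (1-based).
NULL

#' @rdname accessors
#' @export
setGeneric("calibration", function(object) standardGeneric("calibration"))
#' @rdname accessors
#' @export
setMethod("calibration", "ImageStack", function(object) object@calibration)

#' @rdname accessors
#' @export
setGeneric("xySize", function(object) standardGeneric("xySize"))
#' @rdname accessors
#' @export
setMethod("xySize", "PixelCalibration", function(object) object@xySize)
#' @rdname accessors
#' @export
setMethod("xySize", "ImageStack", function(object) object@calibration@xySize)

#' @rdname accessors
#' @export
setGeneric("zStep", function(object) standardGeneric("zStep"))
#' @rdname accessors
#' @export
setMethod("zStep", "PixelCalibration", function(object) object@zStep)
#' @rdname accessors
#' @export
setMethod("zStep", "ImageStack", function(object) object@calibration@zStep)

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setMethod("voxels", "ImageStack", function(object) object@voxels)

#' @rdname accessors
#' @export
setGeneric("nSlices", function(object) standardGeneric("nSlices"))
#' @rdname accessors
#' @export
setMethod("nSlices", "ImageStack", function(object) dim(object@voxels)[1])

#' @rdname accessors
#' @export
setGeneric("depthOffset", function(object) standardGeneric("depthOffset"))
#' @rdname accessors
#' @export
setMethod("depthOffset", "ImageStack", function(object) object@depthOffset)

#' Extract one slice as a (row, col) matrix
#' @rdname accessors
#' @export
sliceImage <- function(x, i) {
  stopifnot(is(x, "ImageStack"), i >= 1, i <= nSlices(x))
  d <- dim(x@voxels)
  matrix(x@voxels[i, , ], nrow = d[2], ncol = d[3])
}

#' Depth (micrometers) of each slice below the specimen border
#' @rdname accessors
#' @export
sliceDepths <- function(x) {
  stopifnot(is(x, "ImageStack"))
  x@depthOffset + (seq_len(nSlices(x)) - 1) * zStep(x)
}

#' @rdname accessors
#' @export
setGeneric("zoneLabels", function(object) standardGeneric("zoneLabels"))
#' @rdname accessors
#' @export
setMethod("zoneLabels", "ZoneMap", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("spheroidCentroid", function(object) standardGeneric("spheroidCentroid"))
#' @rdname accessors
#' @export
setMethod("spheroidCentroid", "ZoneMap", function(object) object@centroid)

#' @rdname accessors
#' @export
setGeneric("boundaryEllipses", function(object) standardGeneric("boundaryEllipses"))
#' @rdname accessors
#' @export
setMethod("boundaryEllipses", "ZoneMap", function(object) object@ellipses)

#' @rdname accessors
#' @export
setGeneric("truthCells", function(object) standardGeneric("truthCells"))
#' @rdname accessors
#' @export
setMethod("truthCells", "GroundTruth", function(object) object@cells)

#' @rdname accessors
#' @export
setGeneric("truthFragments", function(object) standardGeneric("truthFragments"))
#' @rdname accessors
#' @export
setMethod("truthFragments", "GroundTruth", function(object) object@fragments)

#' @rdname accessors
#' @export
setGeneric("nucleiTable", function(object) standardGeneric("nucleiTable"))
#' @rdname accessors
#' @export
setMethod("nucleiTable", "QuantResult", function(object) object@nuclei)

#' @rdname accessors
#' @export
setGeneric("eventsTable", function(object) standardGeneric("eventsTable"))
#' @rdname accessors
#' @export
setMethod("eventsTable", "QuantResult", function(object) object@events)

#' @rdname accessors
#' @export
setGeneric("zoneSummary", function(object) standardGeneric("zoneSummary"))
#' @rdname accessors
#' @export
setMethod("zoneSummary", "QuantResult", function(object) object@zoneSummary)

#' @rdname accessors
#' @export
setGeneric("invasionSummary", function(object) standardGeneric("invasionSummary"))
#' @rdname accessors
#' @export
setMethod("invasionSummary", "QuantResult", function(object) object@invasionSummary)

#' @rdname accessors
#' @export
setGeneric("snrTable", function(object) standardGeneric("snrTable"))
#' @rdname accessors
#' @export
setMethod("snrTable", "SNRProfile", function(object) object@profile)

#' @rdname accessors
#' @export
setGeneric("segmentableDepth", function(object) standardGeneric("segmentableDepth"))
#' @rdname accessors
#' @export
setMethod("segmentableDepth", "SNRProfile", function(object) object@segmentableDepth)

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setMethod("pValue", "ComparisonResult", function(object) object@pValue)

#' @rdname accessors
#' @export
setGeneric("uStatistic", function(object) standardGeneric("uStatistic"))
#' @rdname accessors
#' @export
setMethod("uStatistic", "ComparisonResult", function(object) object@U)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack: %d slice(s) of %d x %d px (%.3g um/px, z-step %.3g um)\n",
              d[1], d[2], d[3], xySize(object), zStep(object)))
  cat(sprintf("  depth range %.1f - %.1f um; intensity range [%.3g, %.3g]\n",
              min(sliceDepths(object)), max(sliceDepths(object)),
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "ZoneMap", function(object) {
  tab <- tabulate(object@labels + 1L, nbins = 4L)
  cat(sprintf("ZoneMap %d x %d px; centroid (%.1f, %.1f)\n",
              nrow(object@labels), ncol(object@labels),
              object@centroid[1], object@centroid[2]))
  cat(sprintf("  pixels: outside %d, core %d, rim %d, invasion %d\n",
              tab[1], tab[2], tab[3], tab[4]))
})

setMethod("show", "GroundTruth", function(object) {
  z <- table(factor(object@cells$zone, levels = c("core", "rim", "invasion")))
  s <- table(factor(object@cells$state, levels = c("normal", "apoptotic", "mitotic")))
  cat(sprintf("GroundTruth: %d cells (core %d, rim %d, invasion %d)\n",
              nrow(object@cells), z[1], z[2], z[3]))
  cat(sprintf("  states: normal %d, apoptotic %d, mitotic %d; %d fragments; seed %g\n",
              s[1], s[2], s[3], nrow(object@fragments), object@seed))
})

setMethod("show", "SNRProfile", function(object) {
  cat(sprintf("SNRProfile: %d slices, depth %.0f - %.0f um\n",
              nrow(object@profile), min(object@profile$depth_um),
              max(object@profile$depth_um)))
  cat(sprintf("  SNR range [%.2f, %.2f]; segmentable depth %.0f um (threshold %.1f)\n",
              min(object@profile$snr), max(object@profile$snr),
              object@segmentableDepth, object@threshold))
})

setMethod("show", "QuantResult", function(object) {
  cat(sprintf("QuantResult ('%s'): %d nuclei, %d apoptosis events, %d mitoses\n",
              object@timeLabel, nrow(object@nuclei), nrow(object@events),
              nrow(object@mitoses)))
  if (nrow(object@zoneSummary)) {
    print(object@zoneSummary, row.names = FALSE)
  }
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("Mann-Whitney comparison %s (n=%d) vs %s (n=%d)\n",
              object@labels[1], length(object@values[[1]]),
              object@labels[2], length(object@values[[2]])))
  cat(sprintf("  U = %g, two-sided p = %.4g (%s)\n",
              object@U, object@pValue, object@method))
})
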