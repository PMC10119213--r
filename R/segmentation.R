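#' Gaussian preprocessing of a slice
#'
#' Isotropic Gaussian smoothing with sigma given in physical units
#' (micrometers) and converted to pixels via the calibration
#' (\code{sigma / xySize}), mirroring scaled-units blurring in interactive
#' tools. Reflective boundary handling; output has the input shape.
#'
#' @param slice 2D intensity matrix (row, col).
#' @param sigma blur sigma, micrometers.
#' @param calibration a \linkS4class{PixelCalibration}.
#' @return Smoothed matrix.
#' @export
gaussianPreprocess <- function(slice, sigma, calibration) {
  if (sigma <= 0) sqStop("sqParamError", "sigma must be > 0")
  cpp_gaussian_blur(slice, sigma / calibration@xySize)
}

#' Phansalkar local adaptive threshold
#'
#' The slice is first rescaled to [0, 1] by its global minimum and maximum.
#' For each pixel, with m and s the mean and (population) standard deviation
#' of the rescaled values in the circular window of radius
#' \code{windowRadius} (reflective padding), the threshold is
#' \deqn{t = m (1 + p e^{-q m} + k ((s/r) - 1))}
#' and the pixel is foreground iff its rescaled value exceeds t. Designed for
#' low-contrast nuclei whose brightness varies with z-position.
#'
#' @param slice 2D intensity matrix.
#' @param params a \linkS4class{SegmentationParams}.
#' @return Binary integer matrix (1 = foreground).
#' @export
phansalkarThreshold <- function(slice, params = SegmentationParams()) {
  mn <- min(slice); mx <- max(slice)
  if (mx == mn) {
    warning("constant image: rescaling undefined, returning all-background mask")
    return(matrix(0L, nrow(slice), ncol(slice)))
  }
  x <- (slice - mn) / (mx - mn)
  ms <- cpp_local_mean_sd(x, params@windowRadius)
  t <- ms$mean * (1 + params@p * exp(-params@q * ms$mean) +
                    params@k * ((ms$sd / params@r) - 1))
  mask <- matrix(0L, nrow(slice), ncol(slice))
  mask[x > t] <- 1L
  mask
}

#' Binary median postprocessing
#'
#' Majority vote over the disc of the given pixel radius (reflective
#' padding): removes speckle and smooths mask boundaries.
#'
#' @param mask binary integer matrix.
#' @param medianRadius disc radius, pixels.
#' @return Binary integer matrix.
#' @export
postprocessMask <- function(mask, medianRadius = 3L) {
  if (medianRadius < 1) sqStop("sqParamError", "medianRadius must be >= 1")
  cpp_median_disc(mask, as.integer(medianRadius))
}

#' Watershed separation of touching nuclei
#'
#' Binary watershed in the style of interactive EDM watershed: Euclidean
#' distance transform of the mask, seeds at its regional maxima (adjacent
#' maxima merge, and saddles shallower than half a pixel do not split),
#' watershed of the negated distance map restricted to the mask. Output
#' labels partition the foreground; separating watershed lines are assigned
#' to background. Labels are consecutive positive integers, each
#' 8-connected.
#'
#' @param mask binary integer matrix.
#' @return Integer label matrix (0 = background).
#' @export
watershedSplit <- function(mask) {
  if (!all(mask %in% c(0L, 1L))) sqStop("sqParamError", "mask must be binary")
  if (!any(mask > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(mask)
  w <- EBImage::watershed(d, tolerance = 0.5, ext = 1)
  labels <- matrix(as.integer(w), nrow(mask), ncol(mask))
  labels <- cpp_watershed_lines(labels)
  relabelConsecutive(labels)
}

relabelConsecutive <- function(labels) {
  # renumber to consecutive positive integers and split any label broken in
  # two by line assignment back into 8-connected components
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[labels > 0] <- 1L
  comp <- cpp_label8(out)
  comp
}

#' Particle (area) filter
#'
#' Converts each label's pixel count to square micrometers via
#' \code{xySize^2} and keeps labels inside the nucleus area band as nucleus
#' records (intensity-weighted centroid, mean intensity). Labels below the
#' band are retained separately as fragment candidates for apoptosis
#' detection; labels above it are discarded as debris.
#'
#' @param labels integer label matrix.
#' @param sliceImage 2D intensity matrix (same shape).
#' @param calibration a \linkS4class{PixelCalibration}.
#' @param params a \linkS4class{SegmentationParams}.
#' @param slice slice index recorded on the output rows (1-based).
#' @return List with data.frames \code{nuclei} and \code{fragments}.
#' @export
filterParticles <- function(labels, sliceImage, calibration,
                            params = SegmentationParams(), slice = 1L) {
  if (is.null(calibration) || !is(calibration, "PixelCalibration"))
    sqStop("sqParamError", "calibration is required")
  if (!all(dim(labels) == dim(sliceImage)))
    sqStop("sqParamError", "labels and slice image must have the same shape")
  k <- max(labels)
  if (k == 0) return(list(nuclei = emptyNucleusTable(), fragments = emptyFragmentTable()))
  lv <- as.vector(labels)
  sel <- lv > 0
  lv <- lv[sel]
  iv <- as.vector(sliceImage)[sel]
  # 0-based pixel-center coordinates of the retained pixels
  nr <- nrow(labels)
  idx <- which(sel)
  rows0 <- (idx - 1) %% nr
  cols0 <- (idx - 1) %/% nr
  npix <- tabulate(lv, nbins = k)
  isum <- as.vector(rowsum(iv, lv))
  wr <- as.vector(rowsum(iv * rows0, lv)) / isum
  wc <- as.vector(rowsum(iv * cols0, lv)) / isum
  # zero-intensity labels fall back to the geometric centroid
  flat <- !is.finite(wr) | !is.finite(wc)
  if (any(flat)) {
    wr[flat] <- (as.vector(rowsum(rows0, lv)) / npix)[flat]
    wc[flat] <- (as.vector(rowsum(cols0, lv)) / npix)[flat]
  }
  area <- npix * calibration@xySize^2
  df <- data.frame(id = seq_len(k), slice = as.integer(slice), row = wr, col = wc,
                   area_um2 = area, mean_intensity = isum / npix,
                   stringsAsFactors = FALSE)
  inBand <- area >= params@minArea & area <= params@maxArea
  nuclei <- df[inBand, , drop = FALSE]
  if (nrow(nuclei)) {
    nuclei$zone <- "unassigned"; nuclei$radial_um <- NA_real_; nuclei$state <- "normal"
  } else nuclei <- emptyNucleusTable()
  fragments <- df[area < params@minArea, , drop = FALSE]
  if (!nrow(fragments)) fragments <- emptyFragmentTable()
  rownames(nuclei) <- NULL; rownames(fragments) <- NULL
  list(nuclei = nuclei, fragments = fragments)
}

#' Segment a full stack
#'
#' Applies the complete per-slice chain (Gaussian blur, Phansalkar local
#' threshold, binary median, watershed separation, particle filter) to every
#' slice; deterministic. Records carry their slice index (1-based); zones are
#' assigned downstream.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param params a \linkS4class{SegmentationParams}.
#' @return List with data.frames \code{nuclei} and \code{fragments} pooled
#'   over slices (ids unique within the stack).
#' @export
segmentStack <- function(stack, params = SegmentationParams()) {
  nucAll <- list(); frAll <- list()
  nextId <- 1L
  for (s in seq_len(nSlices(stack))) {
    img <- sliceImage(stack, s)
    g <- gaussianPreprocess(img, params@gaussianSigma, calibration(stack))
    m <- suppressWarnings(phansalkarThreshold(g, params))
    m <- postprocessMask(m, params@medianRadius)
    lab <- watershedSplit(m)
    res <- filterParticles(lab, img, calibration(stack), params, slice = s)
    if (nrow(res$nuclei)) {
      res$nuclei$id <- seq.int(nextId, length.out = nrow(res$nuclei))
      nextId <- nextId + nrow(res$nuclei)
    }
    if (nrow(res$fragments)) {
      res$fragments$id <- seq.int(nextId, length.out = nrow(res$fragments))
      nextId <- nextId + nrow(res$fragments)
    }
    nucAll[[s]] <- res$nuclei; frAll[[s]] <- res$fragments
  }
  list(nuclei = do.call(rbind, nucAll), fragments = do.call(rbind, frAll))
}
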