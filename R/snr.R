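#' Signal-to-noise ratio of one slice
#'
#' \eqn{SNR = (I_{mean} - B_{mean}) / SD_{mean}} where \eqn{I_{mean}} is the
#' mean of the brightest 5 percent of pixel values of the whole slice
#' (ceiling of 0.05 N pixels) and \eqn{B_{mean}}, \eqn{SD_{mean}} are the
#' mean and population standard deviation (divisor N) inside the
#' user-supplied dark background region.
#'
#' @param slice 2D intensity matrix.
#' @param backgroundRegion list with \code{rows = c(r0, r1)} and
#'   \code{cols = c(c0, c1)}, 0-based inclusive pixel bounds of a dark
#'   rectangle; default is the top-left corner window of 10 percent by 10
#'   percent of the image.
#' @return List with \code{snr}, \code{iMean}, \code{bMean}, \code{sdMean}.
#' @export
sliceSNR <- function(slice, backgroundRegion = NULL) {
  if (is.null(backgroundRegion))
    backgroundRegion <- list(rows = c(0, max(0, ceiling(nrow(slice) * 0.1) - 1)),
                             cols = c(0, max(0, ceiling(ncol(slice) * 0.1) - 1)))
  r <- backgroundRegion$rows; cc <- backgroundRegion$cols
  if (r[1] < 0 || r[2] >= nrow(slice) || cc[1] < 0 || cc[2] >= ncol(slice) ||
      r[1] > r[2] || cc[1] > cc[2])
    sqStop("sqParamError", "background region empty or outside the slice")
  bg <- slice[(r[1]:r[2]) + 1, (cc[1]:cc[2]) + 1]
  bMean <- mean(bg)
  sdMean <- sqrt(mean((bg - bMean)^2))  # population SD, divisor N
  if (sdMean == 0)
    sqStop("sqSNRError", "constant background: SNR undefined")
  v <- sort(as.vector(slice), decreasing = TRUE)
  k <- ceiling(0.05 * length(v))
  iMean <- mean(v[seq_len(k)])
  list(snr = (iMean - bMean) / sdMean, iMean = iMean, bMean = bMean, sdMean = sdMean)
}

#' SNR-versus-depth profile
#'
#' Computes \code{\link{sliceSNR}} for every slice at depth
#' \code{depthOffset + index * zStep} and the segmentable depth: the greatest
#' depth whose SNR is at or above the threshold (0 if none). Quantifies the
#' imaging-depth gain of optical clearing.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param backgroundRegion see \code{\link{sliceSNR}}.
#' @param threshold segmentability threshold on SNR (default 5).
#' @return An \linkS4class{SNRProfile}.
#' @export
depthProfile <- function(stack, backgroundRegion = NULL, threshold = 5) {
  depths <- sliceDepths(stack)
  res <- lapply(seq_len(nSlices(stack)), function(s)
    sliceSNR(sliceImage(stack, s), backgroundRegion))
  snr <- vapply(res, `[[`, numeric(1), "snr")
  prof <- data.frame(depth_um = depths, snr = snr)
  segDepth <- if (any(snr >= threshold)) max(depths[snr >= threshold]) else 0
  new("SNRProfile", profile = prof,
      bMean = res[[length(res)]]$bMean, sdMean = res[[length(res)]]$sdMean,
      threshold = threshold, segmentableDepth = segDepth)
}
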