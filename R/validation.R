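#' Match segmented nuclei against simulator ground truth
#'
#' Per-slice nearest-neighbor matching of detected nuclei to simulated cells.
#' A truth cell is counted as expected on a slice when its rendered amplitude
#' there is at least half its peak (the cell's equator lies within the
#' slice); a detection is a true positive when any truth cell whose rendered
#' amplitude on the slice is non-negligible lies within the match radius.
#' Recall is computed over the expected cells, precision over all
#' detections; apoptotic cells are excluded (they have no intact nucleus).
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param nuclei segmented nucleus records (slice, row, col).
#' @param stack the segmented \linkS4class{ImageStack} (for depths and
#'   calibration).
#' @param matchRadiusUm in-plane match radius, micrometers.
#' @return List with \code{precision}, \code{recall}, \code{nExpected},
#'   \code{nDetected}.
#' @export
matchToGroundTruth <- function(truth, nuclei, stack, matchRadiusUm = 10) {
  cells <- truthCells(truth)
  cells <- cells[cells$state != "apoptotic", , drop = FALSE]
  depths <- sliceDepths(stack)
  xy <- xySize(stack)
  radPx <- matchRadiusUm / xy
  nExp <- 0L; nExpHit <- 0L; nDet <- 0L; nDetHit <- 0L
  for (s in seq_len(nSlices(stack))) {
    sigz <- cells$diameter_um / 4
    f <- exp(-(cells$z_um - depths[s])^2 / (2 * sigz^2))
    expected <- cells[f >= 0.5, , drop = FALSE]
    plausible <- cells[f >= 0.05, , drop = FALSE]
    det <- nuclei[nuclei$slice == s, , drop = FALSE]
    nExp <- nExp + nrow(expected); nDet <- nDet + nrow(det)
    if (nrow(det) && nrow(expected)) {
      dmat <- outer(expected$row_px, det$row, "-")^2 +
        outer(expected$col_px, det$col, "-")^2
      nExpHit <- nExpHit + sum(apply(dmat, 1, min) <= radPx^2)
    }
    if (nrow(det) && nrow(plausible)) {
      dmat <- outer(det$row, plausible$row_px, "-")^2 +
        outer(det$col, plausible$col_px, "-")^2
      nDetHit <- nDetHit + sum(apply(dmat, 1, min) <= radPx^2)
    }
  }
  list(precision = if (nDet) nDetHit / nDet else NA_real_,
       recall = if (nExp) nExpHit / nExp else NA_real_,
       nExpected = nExp, nDetected = nDet)
}
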