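# Polygon area / centroid / second central moments via Green's theorem.
# Vertices are (row, col); internally x = col, y = row.
polygonMoments <- function(v) {
  y <- v[, 1]; x <- v[, 2]
  n <- nrow(v)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-9) sqStop("sqGeometryError", "degenerate (zero-area) polygon")
  cx <- sum((x + x[j]) * cr) / (6 * A)
  cy <- sum((y + y[j]) * cr) / (6 * A)
  Ixx <- sum((x^2 + x * x[j] + x[j]^2) * cr) / 12
  Iyy <- sum((y^2 + y * y[j] + y[j]^2) * cr) / 12
  Ixy <- sum((x * y[j] + 2 * x * y + 2 * x[j] * y[j] + x[j] * y) * cr) / 24
  # central moments normalized by area (sign-corrected for orientation)
  s <- sign(A)
  list(area = abs(A), centroid = c(row = cy, col = cx),
       covXX = s * Ixx / abs(A) - cx^2, covYY = s * Iyy / abs(A) - cy^2,
       covXY = s * Ixy / abs(A) - cx * cy)
}

#' Fit an ellipse to a boundary polygon
#'
#' Returns the ellipse with the polygon's area, centroid and second-order
#' central moment structure: semi-axes derived from the eigenvalues of the
#' normalized moment matrix and rescaled so the ellipse area equals the
#' polygon area exactly (the moment-based "fit ellipse" of interactive image
#' analysis).
#'
#' @param polygon a \linkS4class{BoundaryPolygon}.
#' @return List with \code{center} (row, col), \code{semiMajor},
#'   \code{semiMinor} (pixels) and \code{theta} (radians, major-axis angle
#'   from the +col axis toward +row).
#' @export
fitBoundaryEllipse <- function(polygon) {
  m <- polygonMoments(polygon@vertices)
  C <- matrix(c(m$covXX, m$covXY, m$covXY, m$covYY), 2, 2)
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 1e-12)
  a0 <- 2 * sqrt(lam[1]); b0 <- 2 * sqrt(lam[2])
  sc <- sqrt(m$area / (pi * a0 * b0))
  vec <- e$vectors[, 1]  # (x, y) direction of the major axis
  list(center = m$centroid, semiMajor = sc * a0, semiMinor = sc * b0,
       theta = atan2(vec[2], vec[1]), label = polygon@label)
}

ellipseContains <- function(ell, rows, cols, tol = 0) {
  dy <- rows - ell$center[1]; dx <- cols - ell$center[2]
  u <- (dx * cos(ell$theta) + dy * sin(ell$theta)) / ell$semiMajor
  v <- (-dx * sin(ell$theta) + dy * cos(ell$theta)) / ell$semiMinor
  u^2 + v^2 <= 1 + tol
}

circleEllipse <- function(center, radiusPx, label = NULL) {
  list(center = c(row = center[1], col = center[2]), semiMajor = radiusPx,
       semiMinor = radiusPx, theta = 0, label = label)
}

#' Build the per-slice zone map
#'
#' Pixels inside the core/rim ellipse are core; between the two ellipses,
#' rim; outside the rim/invasion ellipse, invasion zone. The spheroid
#' centroid is the center of the core/rim ellipse. The core ellipse must lie
#' inside the rim/invasion ellipse; coincident boundaries give an empty rim
#' with a warning.
#'
#' @param coreRim,rimInvasion ellipse parameter lists (see
#'   \code{\link{fitBoundaryEllipse}}).
#' @param imageShape c(rows, cols).
#' @return A \linkS4class{ZoneMap}.
#' @export
buildZoneMap <- function(coreRim, rimInvasion, imageShape) {
  thetaSeq <- seq(0, 2 * pi, length.out = 181)[-181]
  br <- coreRim$center[1] + coreRim$semiMajor * cos(thetaSeq) * sin(coreRim$theta) +
    coreRim$semiMinor * sin(thetaSeq) * cos(coreRim$theta)
  bc <- coreRim$center[2] + coreRim$semiMajor * cos(thetaSeq) * cos(coreRim$theta) -
    coreRim$semiMinor * sin(thetaSeq) * sin(coreRim$theta)
  inside <- ellipseContains(rimInvasion, br, bc, tol = 1e-6)
  if (!all(inside))
    sqStop("sqGeometryError", sprintf(
      "core_rim boundary crosses rim_invasion boundary (%.1f%% of the core boundary outside)",
      100 * mean(!inside)))
  nr <- imageShape[1]; nc <- imageShape[2]
  rows <- matrix(rep(0:(nr - 1), nc), nr, nc)
  cols <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  lab <- matrix(3L, nr, nc)  # default invasion
  inOuter <- ellipseContains(rimInvasion, rows, cols)
  inInner <- ellipseContains(coreRim, rows, cols)
  lab[inOuter] <- 2L
  lab[inInner] <- 1L
  if (!any(lab == 2L)) warning("rim region is empty (coincident boundaries)")
  new("ZoneMap", labels = lab,
      centroid = as.numeric(coreRim$center),
      ellipses = list(core_rim = coreRim, rim_invasion = rimInvasion))
}

#' Zone map from circular radii
#'
#' Convenience for simulated specimens whose boundaries are known circles.
#'
#' @param centroid (row, col) pixel centroid.
#' @param coreRadiusUm,rimOuterRadiusUm circle radii, micrometers.
#' @param imageShape c(rows, cols).
#' @param calibration a \linkS4class{PixelCalibration}.
#' @return A \linkS4class{ZoneMap}.
#' @export
zoneMapFromRadii <- function(centroid, coreRadiusUm, rimOuterRadiusUm,
                             imageShape, calibration) {
  xy <- calibration@xySize
  buildZoneMap(circleEllipse(centroid, coreRadiusUm / xy, "core_rim"),
               circleEllipse(centroid, rimOuterRadiusUm / xy, "rim_invasion"),
               imageShape)
}

#' Estimate zone boundaries from the image (auto mode)
#'
#' Automation of the manual boundary step: smooths the central slice,
#' computes the radial mean-intensity profile about the intensity centroid,
#' places the rim/invasion radius at the steepest intensity drop beyond the
#' densest ring and the core/rim radius at the inner edge of that ring.
#' Returns circles as 72-gon \linkS4class{BoundaryPolygon}s; user-supplied
#' ROIs always take precedence over this estimate.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param centralSlice slice index (1-based) to analyze.
#' @return List of two \linkS4class{BoundaryPolygon} (core_rim, rim_invasion).
#' @export
estimateBoundaries <- function(stack, centralSlice = ceiling(nSlices(stack) / 2)) {
  img <- sliceImage(stack, centralSlice)
  sm <- cpp_gaussian_blur(img, 2)
  bg <- median(sm[c(1:10), c(1:10)])
  w <- pmax(0, sm - bg)
  tot <- sum(w)
  if (tot <= 0) sqStop("sqEstimationError",
                       "no radial structure detected; supply manual ROIs")
  nr <- nrow(img); nc <- ncol(img)
  rows <- matrix(rep(0:(nr - 1), nc), nr, nc)
  cols <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  cr <- sum(w * rows) / tot; cc <- sum(w * cols) / tot
  rad <- sqrt((rows - cr)^2 + (cols - cc)^2)
  binW <- 2
  bin <- floor(rad / binW)
  prof <- as.vector(rowsum(as.vector(w), as.vector(bin)))
  cnt <- tabulate(as.vector(bin) + 1L)
  nb <- min(length(prof), length(cnt))
  prof <- prof[seq_len(nb)] / pmax(1, cnt[seq_len(nb)])
  # restrict to bins with enough pixels for a stable mean
  valid <- which(cnt[seq_len(nb)] >= 100)
  if (length(valid) < 10)
    sqStop("sqEstimationError", "no radial structure detected; supply manual ROIs")
  ks <- c(1, 2, 3, 2, 1) / 9
  profS <- as.vector(stats::filter(prof, ks, sides = 2))
  profS[is.na(profS)] <- prof[is.na(profS)]
  pk <- valid[which.max(profS[valid])]
  mx <- profS[pk]
  noiseScale <- stats::mad(sm[c(1:10), c(1:10)], constant = 1.4826)
  if (!is.finite(mx) || mx <= 0 || mx < 3 * noiseScale + 1e-9)
    sqStop("sqEstimationError", "no radial structure detected; supply manual ROIs")
  # far-field floor from the outermost valid bins
  farIdx <- valid[valid > stats::quantile(valid, 0.9)]
  floorLev <- if (length(farIdx)) median(profS[farIdx]) else 0
  # half level between ring peak and far field: the half-maximum crossing of
  # the blurred edge sits at the outermost cell centers
  level <- floorLev + 0.5 * (mx - floorLev)
  above <- valid[profS[valid] >= level]
  if (!length(above) || max(above) >= nb - 1)
    sqStop("sqEstimationError", "no radial structure detected; supply manual ROIs")
  ob <- max(above)
  tOut <- (profS[ob] - level) / max(profS[ob] - profS[ob + 1], 1e-9)
  rOuterPx <- (ob - 0.5 + min(1, tOut)) * binW
  # inner edge of the densest ring: scan inward from the profile peak to the
  # midpoint between the interior level and the ring peak
  coreBins <- valid[valid <= max(1, floor(0.6 * pk))]
  coreLevel <- if (length(coreBins)) median(profS[coreBins]) else profS[valid[1]]
  if (mx > 1.15 * coreLevel && pk > 3) {
    thr <- (coreLevel + mx) / 2
    innerIdx <- pk
    while (innerIdx > 1 && profS[innerIdx - 1] > thr) innerIdx <- innerIdx - 1
    tIn <- if (innerIdx > 1)
      (thr - profS[innerIdx - 1]) / max(profS[innerIdx] - profS[innerIdx - 1], 1e-9)
    else 0
    rInnerPx <- (innerIdx - 1.5 + max(0, min(1, tIn))) * binW
  } else {
    # no detectable ring contrast: fall back to a thin-rim prior
    warning("weak core/rim ring contrast; core_rim boundary set to 0.8 of the outer radius")
    rInnerPx <- 0.8 * rOuterPx
  }
  if (rInnerPx >= rOuterPx) rInnerPx <- 0.8 * rOuterPx
  mkCircle <- function(rpx, label) {
    th <- seq(0, 2 * pi, length.out = 73)[-73]
    BoundaryPolygon(cbind(cr + rpx * sin(th), cc + rpx * cos(th)), label)
  }
  list(mkCircle(rInnerPx, "core_rim"), mkCircle(rOuterPx, "rim_invasion"))
}

#' Select the random analysis quadrant
#'
#' Uniformly draws one of the four axis-aligned quadrants anchored at the
#' spheroid centroid, using the given seed (deterministic and reproducible).
#'
#' @param zoneMap a \linkS4class{ZoneMap}.
#' @param seed RNG seed for the draw.
#' @return A \linkS4class{QuadrantSelection}.
#' @export
selectQuadrant <- function(zoneMap, seed) {
  q <- withSeed(seed, floor(runif(1) * 4))
  new("QuadrantSelection", quadrant = as.integer(min(q, 3)), seed = seed,
      centroid = zoneMap@centroid)
}

#' Mask of one quadrant
#'
#' Logical matrix: TRUE where the pixel's (row - centroid, col - centroid)
#' signs match the selected quadrant. Pixels exactly on the centroid axes are
#' in no quadrant.
#'
#' @param selection a \linkS4class{QuadrantSelection}.
#' @param imageShape c(rows, cols).
#' @return Logical matrix.
#' @export
quadrantMask <- function(selection, imageShape) {
  nr <- imageShape[1]; nc <- imageShape[2]
  dr <- matrix(rep(0:(nr - 1) - selection@centroid[1], nc), nr, nc)
  dc <- matrix(rep(0:(nc - 1) - selection@centroid[2], each = nr), nr, nc)
  quadrantOf(dr, dc) == selection@quadrant
}

# quadrant index from sign pattern; -1 on the axes
quadrantOf <- function(dr, dc) {
  q <- matrix(-1L, nrow(as.matrix(dr)), ncol(as.matrix(dr)))
  q[dr < 0 & dc > 0] <- 0L
  q[dr < 0 & dc < 0] <- 1L
  q[dr > 0 & dc < 0] <- 2L
  q[dr > 0 & dc > 0] <- 3L
  q
}

#' Radial distance of records from the spheroid centroid
#'
#' In-plane Euclidean distance times the pixel size; stored on the records as
#' \code{radial_um}. Estimates the distance migrated by each cell.
#'
#' @param records data.frame with \code{row}, \code{col} (0-based pixels).
#' @param centroid (row, col) centroid, 0-based pixels.
#' @param calibration a \linkS4class{PixelCalibration}.
#' @return \code{records} with \code{radial_um} filled.
#' @export
radialDistance <- function(records, centroid, calibration) {
  records$radial_um <- sqrt((records$row - centroid[1])^2 +
                            (records$col - centroid[2])^2) * calibration@xySize
  records
}

#' Assign zones to records
#'
#' Each record's zone is the zone-map label at its centroid pixel (nearest
#' pixel). With \code{restrictInvasionToQuadrant}, invasion-zone records
#' outside the selected quadrant are marked \code{unassigned} (excluded from
#' counts); core and rim records always use the full regions. Records whose
#' centroid falls outside the image are marked \code{unassigned} with a
#' warning.
#'
#' @param records data.frame with \code{row}, \code{col}.
#' @param zoneMap a \linkS4class{ZoneMap}.
#' @param quadrant a \linkS4class{QuadrantSelection} or NULL.
#' @param restrictInvasionToQuadrant apply the quadrant restriction.
#' @return \code{records} with \code{zone} filled.
#' @export
assignZones <- function(records, zoneMap, quadrant = NULL,
                        restrictInvasionToQuadrant = FALSE) {
  if (!nrow(records)) { records$zone <- character(0); return(records) }
  nr <- nrow(zoneMap@labels); nc <- ncol(zoneMap@labels)
  ri <- round(records$row) + 1; ci <- round(records$col) + 1
  outside <- ri < 1 | ri > nr | ci < 1 | ci > nc
  if (any(outside))
    warning(sum(outside), " record(s) outside the image marked unassigned")
  zone <- rep("unassigned", nrow(records))
  ok <- !outside
  code <- zoneMap@labels[cbind(ri[ok], ci[ok])]
  zone[ok] <- c("unassigned", "core", "rim", "invasion")[code + 1L]
  if (restrictInvasionToQuadrant) {
    if (is.null(quadrant)) sqStop("sqParamError", "quadrant selection required")
    dr <- records$row - quadrant@centroid[1]
    dc <- records$col - quadrant@centroid[2]
    inQ <- quadrantOf(dr, dc) == quadrant@quadrant
    zone[zone == "invasion" & !inQ] <- "unassigned"
  }
  records$zone <- zone
  records
}
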