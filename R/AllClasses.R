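#' Pixel calibration
#'
#' Physical calibration of an image stack: in-plane pixel size and axial step,
#' both in micrometers. Calibration is mandatory user input throughout the
#' package; areas are converted with \code{xySize^2} everywhere.
#'
#' @slot xySize micrometers per pixel in-plane (isotropic).
#' @slot zStep micrometers between consecutive z-slices.
#' @export
setClass("PixelCalibration",
  representation(xySize = "numeric", zStep = "numeric"),
  validity = function(object) {
    if (length(object@xySize) != 1 || !is.finite(object@xySize) || object@xySize <= 0)
      return("xySize must be a single positive number")
    if (length(object@zStep) != 1 || !is.finite(object@zStep) || object@zStep <= 0)
      return("zStep must be a single positive number")
    TRUE
  })

#' @param xySize micrometers per pixel in-plane.
#' @param zStep micrometers between slices.
#' @return A \code{PixelCalibration} object.
#' @examples
#' PixelCalibration(xySize = 2, zStep = 10)
#' @rdname PixelCalibration-class
#' @export
PixelCalibration <- function(xySize, zStep = 10) {
  new("PixelCalibration", xySize = as.numeric(xySize), zStep = as.numeric(zStep))
}

#' Calibrated fluorescence image stack
#'
#' A 3D single-channel intensity volume indexed (slice, row, col). The
#' coordinate convention is uniform across the package: (row, col), 0-based,
#' pixel centers at integer coordinates; slice 0 is the shallowest plane
#' (closest to the objective). \code{depthOffset} is the depth in micrometers
#' of slice 0 below the upper specimen border, used for attenuation and for
#' SNR depth profiles.
#'
#' @slot voxels numeric array with dim (n_slices, n_rows, n_cols), finite and
#'   non-negative.
#' @slot calibration a \linkS4class{PixelCalibration}.
#' @slot depthOffset micrometers of slice 0 below the upper specimen border.
#' @export
setClass("ImageStack",
  representation(voxels = "array", calibration = "PixelCalibration",
                 depthOffset = "numeric"),
  validity = function(object) {
    d <- dim(object@voxels)
    if (length(d) != 3) return("voxels must be a 3D array (slice, row, col)")
    if (d[1] < 1) return("stack must contain at least one slice")
    if (!all(is.finite(object@voxels))) return("intensities must be finite")
    if (any(object@voxels < 0)) return("intensities must be non-negative")
    if (length(object@depthOffset) != 1 || object@depthOffset < 0)
      return("depthOffset must be a single non-negative number")
    TRUE
  })

#' @param voxels 3D array (slice, row, col) or a matrix (treated as one slice).
#' @param calibration a \linkS4class{PixelCalibration}.
#' @param depthOffset depth of slice 0 below the specimen border, micrometers.
#' @rdname ImageStack-class
#' @export
ImageStack <- function(voxels, calibration, depthOffset = 0) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(1, nrow(voxels), ncol(voxels)))
  new("ImageStack", voxels = voxels, calibration = calibration,
      depthOffset = as.numeric(depthOffset))
}

#' Zone boundary polygon
#'
#' A closed polygon in pixel coordinates delimiting either the core/rim
#' transition or the rim/invasion-zone transition of a spheroid slice.
#'
#' @slot vertices numeric matrix, one vertex per row as (row, col), 0-based
#'   pixel coordinates; the polygon is closed implicitly.
#' @slot label one of \code{"core_rim"} or \code{"rim_invasion"}.
#' @export
setClass("BoundaryPolygon",
  representation(vertices = "matrix", label = "character"),
  validity = function(object) {
    if (nrow(object@vertices) < 3) return("polygon needs at least 3 vertices")
    if (ncol(object@vertices) != 2) return("vertices must be an n x 2 matrix (row, col)")
    if (!object@label %in% c("core_rim", "rim_invasion"))
      return("label must be 'core_rim' or 'rim_invasion'")
    if (!polygonIsSimple(object@vertices))
      return("polygon is self-intersecting")
    TRUE
  })

#' @param vertices n x 2 matrix of (row, col) vertices.
#' @param label boundary label.
#' @rdname BoundaryPolygon-class
#' @export
BoundaryPolygon <- function(vertices, label) {
  new("BoundaryPolygon", vertices = as.matrix(vertices), label = label)
}

#' Per-pixel zone partition of a slice
#'
#' Integer zone labels per pixel (0 outside, 1 core, 2 rim, 3 invasion), the
#' spheroid centroid (center of the core/rim ellipse), and the two fitted
#' boundary ellipses. Every pixel carries exactly one zone label.
#'
#' @slot labels integer matrix of zone codes.
#' @slot centroid numeric (row, col), 0-based pixel coordinates.
#' @slot ellipses named list with elements \code{core_rim} and
#'   \code{rim_invasion}, each an ellipse parameter list (center, semiMajor,
#'   semiMinor, theta).
#' @export
setClass("ZoneMap",
  representation(labels = "matrix", centroid = "numeric", ellipses = "list"),
  validity = function(object) {
    if (!all(object@labels %in% 0:3)) return("zone labels must be in 0:3")
    if (length(object@centroid) != 2) return("centroid must be (row, col)")
    TRUE
  })

#' Random analysis quadrant
#'
#' The axis-aligned quadrant (anchored at the spheroid centroid) selected for
#' invasion-zone quantification, together with the seed that produced it.
#' Quadrant indices: 0 = (-row, +col), 1 = (-row, -col), 2 = (+row, -col),
#' 3 = (+row, +col), where signs are the signs of (row - centroid_row,
#' col - centroid_col); pixels exactly on the centroid axes belong to no
#' quadrant.
#'
#' @slot quadrant integer in 0..3.
#' @slot seed the seed used for the draw.
#' @slot centroid numeric (row, col) anchor.
#' @export
setClass("QuadrantSelection",
  representation(quadrant = "integer", seed = "numeric", centroid = "numeric"),
  validity = function(object) {
    if (!object@quadrant %in% 0:3) return("quadrant must be in 0:3")
    TRUE
  })

#' Nucleus segmentation parameters
#'
#' Parameters of the per-slice segmentation chain: Gaussian blur (sigma in
#' micrometers, converted to pixels via the calibration), Phansalkar local
#' adaptive threshold (circular window, Fiji default constants), binary median
#' filter, and calibrated area band of the particle filter.
#'
#' @slot gaussianSigma blur sigma, micrometers (default 1.5).
#' @slot windowRadius Phansalkar window radius, pixels (default 15).
#' @slot k,r,p,q Phansalkar constants (defaults 0.25, 0.5, 2, 10).
#' @slot medianRadius binary median filter radius, pixels (default 3).
#' @slot minArea,maxArea nucleus area band, square micrometers (defaults
#'   45 and 700).
#' @export
setClass("SegmentationParams",
  representation(gaussianSigma = "numeric", windowRadius = "integer",
                 k = "numeric", r = "numeric", p = "numeric", q = "numeric",
                 medianRadius = "integer", minArea = "numeric", maxArea = "numeric"),
  validity = function(object) {
    if (object@gaussianSigma <= 0) return("gaussianSigma must be > 0")
    if (object@windowRadius < 1) return("windowRadius must be >= 1")
    if (object@medianRadius < 1) return("medianRadius must be >= 1")
    if (!(object@minArea > 0 && object@minArea < object@maxArea))
      return("need 0 < minArea < maxArea")
    TRUE
  })

#' @param gaussianSigma,windowRadius,k,r,p,q,medianRadius,minArea,maxArea see slots.
#' @rdname SegmentationParams-class
#' @export
SegmentationParams <- function(gaussianSigma = 1.5, windowRadius = 15L,
                               k = 0.25, r = 0.5, p = 2, q = 10,
                               medianRadius = 3L, minArea = 45, maxArea = 700) {
  new("SegmentationParams", gaussianSigma = gaussianSigma,
      windowRadius = as.integer(windowRadius), k = k, r = r, p = p, q = q,
      medianRadius = as.integer(medianRadius), minArea = minArea, maxArea = maxArea)
}

#' Synthetic spheroid simulation parameters
#'
#' All knobs of the synthetic spheroid-invasion specimen and its optics. The
#' specimen is a dense core ball, a compact concentric rim shell, and
#' radially invading single cells whose density decays exponentially with
#' distance beyond the rim; states are normal, apoptotic (rendered as a
#' cluster of nuclear fragments) or mitotic (compact, brighter). Optics are a
#' single-exponential depth attenuation (small attenuation length = uncleared,
#' large = cleared), in-plane point-spread blur, background, Gaussian read
#' noise and Poisson shot noise.
#'
#' @slot coreRadius,rimThickness,maxInvasionDistance geometry, micrometers.
#' @slot nCore,nRim,nInvading cell counts per zone.
#' @slot nucleusDiameterMean,nucleusDiameterSD nucleus diameter, micrometers.
#' @slot invasionDensityDecay decay length of invading-cell density beyond the
#'   rim, micrometers (density proportional to exp(-d/decay)).
#' @slot invasionSlabHalfDepth half-thickness of the equatorial slab in which
#'   invading cells are placed, micrometers.
#' @slot apoptoticFraction named numeric (core, rim, invasion) in [0,1].
#' @slot fragmentsPerEventMin,fragmentsPerEventMax fragments per apoptotic event.
#' @slot fragmentDiameterRange fragment diameter range, micrometers.
#' @slot fragmentScatterRadius scatter disc radius for fragments, micrometers
#'   (at most 20).
#' @slot fragmentIntensityFactor fragment peak intensity relative to a nucleus.
#' @slot mitoticFraction fraction of (non-apoptotic) cells in mitosis.
#' @slot mitoticIntensityGain fold intensity gain of mitotic figures.
#' @slot invasionElongation in-plane aspect ratio of invading nuclei along the
#'   radial direction (radial polarization).
#' @slot nucleusIntensity peak intensity of a normal nucleus, a.u.
#' @slot attenuationLength optical mean free path, micrometers (Inf = none).
#' @slot backgroundLevel,gaussianNoiseSD background offset and read noise, a.u.
#' @slot psfSigma in-plane PSF sigma, micrometers.
#' @slot imageShape (rows, cols) of each slice.
#' @slot nSlices number of z-slices.
#' @slot calibration a \linkS4class{PixelCalibration}.
#' @slot depthOffset depth of slice 0 below the specimen border, micrometers.
#' @slot centerDepth depth of the spheroid center, micrometers (NA = middle
#'   of the stack).
#' @slot seed RNG seed (mandatory).
#' @export
setClass("SimParams",
  representation(coreRadius = "numeric", rimThickness = "numeric",
                 maxInvasionDistance = "numeric",
                 nCore = "integer", nRim = "integer", nInvading = "integer",
                 nucleusDiameterMean = "numeric", nucleusDiameterSD = "numeric",
                 invasionDensityDecay = "numeric", invasionSlabHalfDepth = "numeric",
                 apoptoticFraction = "numeric",
                 fragmentsPerEventMin = "integer", fragmentsPerEventMax = "integer",
                 fragmentDiameterRange = "numeric", fragmentScatterRadius = "numeric",
                 fragmentIntensityFactor = "numeric",
                 mitoticFraction = "numeric", mitoticIntensityGain = "numeric",
                 invasionElongation = "numeric",
                 nucleusIntensity = "numeric",
                 attenuationLength = "numeric", backgroundLevel = "numeric",
                 gaussianNoiseSD = "numeric", psfSigma = "numeric",
                 imageShape = "integer", nSlices = "integer",
                 calibration = "PixelCalibration", depthOffset = "numeric",
                 centerDepth = "numeric", seed = "numeric"),
  validity = function(object) {
    lens <- c(object@coreRadius, object@rimThickness, object@maxInvasionDistance,
              object@nucleusDiameterMean, object@invasionDensityDecay,
              object@invasionSlabHalfDepth, object@fragmentScatterRadius,
              object@psfSigma)
    if (any(!is.finite(lens)) || any(lens <= 0))
      return("all length parameters must be positive and finite")
    fr <- c(object@apoptoticFraction, object@mitoticFraction)
    if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
    if (length(object@apoptoticFraction) != 3)
      return("apoptoticFraction must have 3 elements (core, rim, invasion)")
    if (any(c(object@nCore, object@nRim, object@nInvading) < 0))
      return("cell counts must be >= 0")
    if (object@fragmentsPerEventMin < 2)
      return("fragmentsPerEventMin must be >= 2 (an event is a fragment cluster)")
    if (object@fragmentsPerEventMax < object@fragmentsPerEventMin)
      return("fragmentsPerEventMax must be >= fragmentsPerEventMin")
    if (object@fragmentScatterRadius > 20)
      return("fragmentScatterRadius must be <= 20 (the event linking radius)")
    if (object@coreRadius + object@rimThickness >= object@maxInvasionDistance)
      return("need coreRadius + rimThickness < maxInvasionDistance")
    halfExtent <- min(object@imageShape) / 2 * object@calibration@xySize
    if (object@maxInvasionDistance > halfExtent)
      return(sprintf("maxInvasionDistance (%.0f um) exceeds image half-extent (%.0f um)",
                     object@maxInvasionDistance, halfExtent))
    if (object@attenuationLength <= 0) return("attenuationLength must be > 0 (Inf allowed)")
    if (length(object@seed) != 1 || !is.finite(object@seed))
      return("seed is mandatory")
    TRUE
  })

#' Simulator ground truth
#'
#' Per-cell truth exported by the simulator: 3D position (micrometers; x/y
#' relative to the spheroid centroid, z absolute depth), zone, 3D radial
#' distance from the spheroid center, state, nucleus diameter and pixel
#' coordinates; plus one row per apoptotic fragment. Enables
#' parameter-recovery tests of every downstream stage.
#'
#' @slot cells data.frame, one row per cell.
#' @slot fragments data.frame, one row per apoptotic fragment.
#' @slot attenuationLength attenuation length actually applied, micrometers.
#' @slot seed the simulation seed.
#' @export
setClass("GroundTruth",
  representation(cells = "data.frame", fragments = "data.frame",
                 attenuationLength = "numeric", seed = "numeric"))

#' SNR-versus-depth profile
#'
#' Per-slice signal-to-noise ratio (mean of the brightest 5 percent of slice
#' pixels minus background mean, over background standard deviation) as a
#' function of imaging depth, with the greatest depth at which nuclei remain
#' segmentable (SNR at or above the threshold).
#'
#' @slot profile data.frame with columns depth_um and snr, depths increasing.
#' @slot bMean,sdMean background statistics of the deepest evaluated slice set
#'   (per-slice values are in \code{profile}).
#' @slot threshold segmentability threshold on SNR.
#' @slot segmentableDepth greatest depth with SNR >= threshold, micrometers
#'   (0 if none).
#' @export
setClass("SNRProfile",
  representation(profile = "data.frame", bMean = "numeric", sdMean = "numeric",
                 threshold = "numeric", segmentableDepth = "numeric"),
  validity = function(object) {
    d <- object@profile$depth_um
    if (length(d) > 1 && any(diff(d) <= 0)) return("depths must be strictly increasing")
    if (!all(is.finite(object@profile$snr))) return("SNR values must be finite")
    TRUE
  })

#' Quantification result for one specimen and time point
#'
#' Per-nucleus records, apoptosis events, mitosis annotations, per-slice and
#' per-zone count tables, death and mitosis frequencies, and the invasion
#' distance summary.
#'
#' @slot nuclei per-nucleus data.frame (id, slice, row, col, area_um2,
#'   mean_intensity, zone, radial_um, state).
#' @slot fragments sub-threshold fragment candidates (with event membership).
#' @slot events apoptosis events data.frame.
#' @slot mitoses ingested mitosis annotations data.frame.
#' @slot sliceZoneCounts nucleus counts per (slice, zone).
#' @slot zoneSummary per-zone totals, means per slice, death and mitosis
#'   frequencies.
#' @slot invasionSummary list with max_um, q95_um, median_um, n.
#' @slot snr an \linkS4class{SNRProfile} or NULL.
#' @slot timeLabel free-text time point label.
#' @slot params list of all effective parameters (for the run metadata).
#' @export
setClass("QuantResult",
  representation(nuclei = "data.frame", fragments = "data.frame",
                 events = "data.frame", mitoses = "data.frame",
                 sliceZoneCounts = "data.frame", zoneSummary = "data.frame",
                 invasionSummary = "list", snr = "ANY",
                 timeLabel = "character", params = "list"))

#' Two-group comparison result
#'
#' Mann-Whitney U comparison of two groups of per-spheroid values: U statistic
#' for the first group, two-sided p-value, and whether the exact enumeration
#' or the normal approximation (with tie correction) was used.
#'
#' @slot labels group labels.
#' @slot values list of the two numeric value vectors.
#' @slot U U statistic of the first group.
#' @slot pValue two-sided p-value.
#' @slot method "exact" or "normal approximation".
#' @export
setClass("ComparisonResult",
  representation(labels = "character", values = "list", U = "numeric",
                 pValue = "numeric", method = "character"),
  validity = function(object) {
    if (object@pValue < 0 || object@pValue > 1) return("p-value out of [0,1]")
    n1 <- length(object@values[[1]]); n2 <- length(object@values[[2]])
    if (object@U > n1 * n2 + 1e-9) return("U exceeds n1*n2")
    TRUE
  })
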