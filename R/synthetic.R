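#' Construct simulation parameters
#'
#' Builds a validated \linkS4class{SimParams}. Defaults describe a day-7
#' invasion culture imaged after optical clearing: a 150 um residual core, a
#' compact 30 um rim, invading cells out to 850 um with density decaying
#' exponentially (decay length 300 um) beyond the rim, 12 um nuclei, a low
#' (0.5 percent) spontaneous apoptotic fraction, 2 percent mitoses, and
#' cleared optics (attenuation length 500 um). The three central analysis
#' slices sit at the spheroid center (z-step 10 um), 160-180 um below the
#' specimen border.
#'
#' @param coreRadius,rimThickness,maxInvasionDistance geometry, micrometers.
#' @param nCore,nRim,nInvading cell counts.
#' @param nucleusDiameterMean,nucleusDiameterSD nucleus diameter, micrometers.
#' @param invasionDensityDecay density decay length beyond the rim, micrometers.
#' @param invasionSlabHalfDepth half-depth of the equatorial invasion slab, um.
#' @param apoptoticFraction length-3 numeric (core, rim, invasion) or scalar.
#' @param fragmentsPerEventMin,fragmentsPerEventMax fragments per apoptotic event.
#' @param fragmentDiameterRange fragment diameters, micrometers.
#' @param fragmentScatterRadius fragment scatter disc radius, micrometers.
#' @param fragmentIntensityFactor fragment peak intensity relative to a nucleus.
#' @param mitoticFraction,mitoticIntensityGain mitosis fraction and brightness gain.
#' @param invasionElongation radial aspect ratio of invading nuclei.
#' @param nucleusIntensity peak nucleus intensity, a.u.
#' @param attenuationLength optical mean free path, micrometers (Inf = none).
#' @param backgroundLevel,gaussianNoiseSD background offset and read noise, a.u.
#' @param psfSigma in-plane PSF sigma, micrometers.
#' @param imageShape c(rows, cols) per slice.
#' @param nSlices number of slices.
#' @param calibration a \linkS4class{PixelCalibration}.
#' @param depthOffset depth of slice 0, micrometers.
#' @param centerDepth spheroid center depth, micrometers (NA = stack middle).
#' @param seed RNG seed (mandatory).
#' @return A \linkS4class{SimParams}.
#' @export
SimParams <- function(seed,
                      coreRadius = 150, rimThickness = 30, maxInvasionDistance = 850,
                      nCore = 1500L, nRim = 1700L, nInvading = 400L,
                      nucleusDiameterMean = 12, nucleusDiameterSD = 1.5,
                      invasionDensityDecay = 300, invasionSlabHalfDepth = 15,
                      apoptoticFraction = c(core = 0.005, rim = 0.005, invasion = 0.005),
                      fragmentsPerEventMin = 4L, fragmentsPerEventMax = 6L,
                      fragmentDiameterRange = c(2.2, 3.2), fragmentScatterRadius = 18,
                      fragmentIntensityFactor = 3,
                      mitoticFraction = 0.02, mitoticIntensityGain = 2,
                      invasionElongation = 1.8,
                      nucleusIntensity = 100,
                      attenuationLength = 500, backgroundLevel = 10,
                      gaussianNoiseSD = 2, psfSigma = 1,
                      imageShape = c(896L, 896L), nSlices = 3L,
                      calibration = PixelCalibration(xySize = 2, zStep = 10),
                      depthOffset = 160, centerDepth = NA_real_) {
  if (length(apoptoticFraction) == 1)
    apoptoticFraction <- rep(apoptoticFraction, 3)
  names(apoptoticFraction) <- c("core", "rim", "invasion")
  new("SimParams",
      coreRadius = coreRadius, rimThickness = rimThickness,
      maxInvasionDistance = maxInvasionDistance,
      nCore = as.integer(nCore), nRim = as.integer(nRim),
      nInvading = as.integer(nInvading),
      nucleusDiameterMean = nucleusDiameterMean, nucleusDiameterSD = nucleusDiameterSD,
      invasionDensityDecay = invasionDensityDecay,
      invasionSlabHalfDepth = invasionSlabHalfDepth,
      apoptoticFraction = apoptoticFraction,
      fragmentsPerEventMin = as.integer(fragmentsPerEventMin),
      fragmentsPerEventMax = as.integer(fragmentsPerEventMax),
      fragmentDiameterRange = fragmentDiameterRange,
      fragmentScatterRadius = fragmentScatterRadius,
      fragmentIntensityFactor = fragmentIntensityFactor,
      mitoticFraction = mitoticFraction, mitoticIntensityGain = mitoticIntensityGain,
      invasionElongation = invasionElongation,
      nucleusIntensity = nucleusIntensity,
      attenuationLength = attenuationLength, backgroundLevel = backgroundLevel,
      gaussianNoiseSD = gaussianNoiseSD, psfSigma = psfSigma,
      imageShape = as.integer(imageShape), nSlices = as.integer(nSlices),
      calibration = calibration, depthOffset = depthOffset,
      centerDepth = as.numeric(centerDepth), seed = seed)
}

simCenterDepth <- function(params) {
  if (is.finite(params@centerDepth)) return(params@centerDepth)
  params@depthOffset + (params@nSlices - 1) / 2 * params@calibration@zStep
}

simCentroidPx <- function(params) {
  (params@imageShape - 1) / 2  # (row, col), 0-based
}

# Average in-plane packing fraction of the central slab of each zone; the
# simulator refuses scenes so crowded that 2D segmentation is meaningless.
checkPacking <- function(params) {
  h <- params@nucleusDiameterMean / 2
  meanArea <- pi * (params@nucleusDiameterMean / 2)^2
  R1 <- params@coreRadius; R2 <- R1 + params@rimThickness
  ballSlabFrac <- function(R) min(1, 1.5 * h / R - 0.5 * (h / R)^3)
  packing <- c(
    core = if (params@nCore > 0)
      params@nCore * ballSlabFrac(R1) * meanArea / (pi * R1^2) else 0,
    rim = if (params@nRim > 0)
      params@nRim * (2 * h * pi * (R2^2 - R1^2)) /
        ((4 / 3) * pi * (R2^3 - R1^3)) * meanArea / (pi * (R2^2 - R1^2)) else 0,
    invasion = if (params@nInvading > 0)
      params@nInvading * min(1, h / params@invasionSlabHalfDepth) * meanArea /
        (pi * (params@maxInvasionDistance^2 - R2^2)) else 0)
  over <- names(packing)[packing > 0.9]
  if (length(over))
    sqStop("sqParamError", "overlap saturation: packing fraction > 0.9 in zone(s) ",
           paste(over, collapse = ", "))
  invisible(packing)
}

# Sample the ground-truth specimen. All randomness is drawn from one stream
# seeded with params@seed, in this documented order:
#  1. nucleus diameters:   rnorm(nCells)
#  2. apoptosis draws:     runif(nCells), apoptotic iff u < apoptoticFraction[zone]
#  3. mitosis draws:       runif(nCells), mitotic iff non-apoptotic and u < mitoticFraction
#  4. intensity jitter:    runif(nCells, 0.85, 1.15)
#  5. positions, core then rim then invading; core and rim use rejection
#     sampling with a hard-core minimum separation (nuclei in compact tissue
#     have excluded volume), so the number of uniforms consumed is
#     realization-dependent, which is why all per-cell state draws come
#     first; invading cells are sparse migrating singles and are placed
#     independently, preserving the exponential radial law exactly
#  6. per apoptotic cell, in cell order: fragment count (1 uniform), fragment
#     diameters, scatter radii, scatter azimuths
sampleTruth <- function(params) {
  checkPacking(params)
  R1 <- params@coreRadius; R2 <- R1 + params@rimThickness
  zc <- simCenterDepth(params)
  dmin <- 0.75 * params@nucleusDiameterMean
  withSeed(params@seed, {
    n <- params@nCore + params@nRim + params@nInvading
    zone <- rep(c("core", "rim", "invasion"),
                c(params@nCore, params@nRim, params@nInvading))
    diam <- pmax(4, rnorm(n, params@nucleusDiameterMean, params@nucleusDiameterSD))
    uA <- runif(n)
    apop <- uA < params@apoptoticFraction[zone]
    uM <- runif(n)
    mito <- !apop & uM < params@mitoticFraction
    jitter <- runif(n, 0.85, 1.15)
    state <- ifelse(apop, "apoptotic", ifelse(mito, "mitotic", "normal"))

    # rejection sampler with hard-core separation against all accepted cells
    accX <- accY <- accZ <- numeric(0)
    placeZone <- function(nWant, propose) {
      out <- matrix(numeric(0), 0, 4)
      tries <- 0L
      while (nrow(out) < nWant && tries < 60L) {
        tries <- tries + 1L
        prop <- propose(nWant - nrow(out))
        for (i in seq_len(nrow(prop))) {
          if (length(accX)) {
            d2 <- (accX - prop[i, 1])^2 + (accY - prop[i, 2])^2 +
              (accZ - prop[i, 3])^2
            if (min(d2) < dmin^2 && tries < 60L) next
          }
          accX <<- c(accX, prop[i, 1]); accY <<- c(accY, prop[i, 2])
          accZ <<- c(accZ, prop[i, 3])
          out <- rbind(out, prop[i, ])
        }
      }
      data.frame(x = out[, 1], y = out[, 2], z = out[, 3], r3 = out[, 4])
    }
    sphereProp <- function(rFun) function(k) {
      r <- rFun(k)
      cz <- runif(k, -1, 1); th <- runif(k, 0, 2 * pi)
      rho <- r * sqrt(pmax(0, 1 - cz^2))
      cbind(rho * cos(th), rho * sin(th), zc + r * cz, r)
    }
    core <- placeZone(params@nCore, sphereProp(function(k) R1 * runif(k)^(1 / 3)))
    rim <- placeZone(params@nRim,
                     sphereProp(function(k) (R1^3 + (R2^3 - R1^3) * runif(k))^(1 / 3)))
    span <- params@maxInvasionDistance - R2
    nI <- params@nInvading
    u <- runif(nI)
    rI <- R2 - params@invasionDensityDecay *
      log(1 - u * (1 - exp(-span / params@invasionDensityDecay)))
    thI <- runif(nI, 0, 2 * pi)
    zI <- runif(nI, -params@invasionSlabHalfDepth, params@invasionSlabHalfDepth)
    rhoI <- sqrt(pmax(0, rI^2 - zI^2))
    inv <- data.frame(x = rhoI * cos(thI), y = rhoI * sin(thI), z = zc + zI, r3 = rI)
    cells <- rbind(core, rim, inv)
    ctr <- simCentroidPx(params)
    xy <- params@calibration@xySize
    cellDf <- data.frame(
      id = seq_len(n), x_um = cells$x, y_um = cells$y, z_um = cells$z,
      zone = zone, radial_um = cells$r3, state = state,
      diameter_um = diam, intensity_jitter = jitter,
      row_px = ctr[1] + cells$y / xy, col_px = ctr[2] + cells$x / xy,
      stringsAsFactors = FALSE)
    frags <- sampleFragments(params, cellDf)
    new("GroundTruth", cells = cellDf, fragments = frags,
        attenuationLength = params@attenuationLength, seed = params@seed)
  })
}

# Fragment sampling for the apoptotic cells of `cells`, consuming the current
# RNG stream (called inside sampleTruth / treatment conversion, in cell order).
sampleFragments <- function(params, cells) {
  apopIdx <- which(cells$state == "apoptotic")
  out <- vector("list", length(apopIdx))
  xy <- params@calibration@xySize
  lo <- params@fragmentsPerEventMin; hi <- params@fragmentsPerEventMax
  dlo <- params@fragmentDiameterRange[1]; dhi <- params@fragmentDiameterRange[2]
  for (k in seq_along(apopIdx)) {
    i <- apopIdx[k]
    nf <- lo + floor(runif(1) * (hi - lo + 1))
    nf <- min(nf, hi)
    fd <- runif(nf, dlo, dhi)
    # membrane-bound apoptotic bodies are distinct objects: fragments sit at
    # evenly spaced (jittered) angles in an annulus of the scatter disc, which
    # keeps them separated beyond the optical merging scale
    rho <- params@fragmentScatterRadius * sqrt(runif(nf, 0.16, 1))
    phi <- 2 * pi * (seq_len(nf) - 1) / nf + runif(1, 0, 2 * pi) +
      runif(nf, -0.35, 0.35) * 2 * pi / nf
    out[[k]] <- data.frame(
      cell_id = cells$id[i],
      row_px = cells$row_px[i] + rho * sin(phi) / xy,
      col_px = cells$col_px[i] + rho * cos(phi) / xy,
      z_um = cells$z_um[i], diameter_um = fd, area_um2 = pi * (fd / 2)^2,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(cell_id = integer(0), row_px = numeric(0), col_px = numeric(0),
                      z_um = numeric(0), diameter_um = numeric(0),
                      area_um2 = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Deterministic rendering of a noise-free stack from ground truth. Nuclei are
# Gaussian blobs whose half-maximum contour matches the nominal diameter;
# axial extent sigma_z = diameter/4. Mitotic figures are 0.7x diameter with
# the configured intensity gain; invading normal nuclei are elongated along
# the radial direction at constant area; apoptotic cells are rendered as
# their fragment cluster (axial extent of the former nucleus).
renderTruth <- function(params, truth) {
  xy <- params@calibration@xySize
  nr <- params@imageShape[1]; nc <- params@imageShape[2]
  arr <- array(0, dim = c(params@nSlices, nr, nc))
  cells <- truth@cells
  ctr <- simCentroidPx(params)
  objs <- list()
  if (nrow(cells)) {
    live <- cells[cells$state != "apoptotic", , drop = FALSE]
    if (nrow(live)) {
      d <- ifelse(live$state == "mitotic", 0.7 * live$diameter_um, live$diameter_um)
      # sigma = diameter/4: the adaptive threshold segments a Gaussian blob
      # well below its half maximum, so this compact profile makes the
      # detected footprint of an isolated nucleus match its nominal
      # cross-section after PSF blur
      sig <- d / 4 / xy
      amp <- params@nucleusIntensity * live$intensity_jitter *
        ifelse(live$state == "mitotic", params@mitoticIntensityGain, 1)
      elong <- ifelse(live$zone == "invasion" & live$state == "normal",
                      params@invasionElongation, 1)
      dr <- live$row_px - ctr[1]; dc <- live$col_px - ctr[2]
      rho <- sqrt(dr^2 + dc^2)
      er <- ifelse(rho > 0, dr / rho, 1); ec <- ifelse(rho > 0, dc / rho, 0)
      objs[[1]] <- data.frame(row = live$row_px, col = live$col_px, z = live$z_um,
                              siga = sig * sqrt(elong), sigb = sig / sqrt(elong),
                              er = er, ec = ec, amp = amp,
                              sigz = live$diameter_um / 4)
    }
  }
  frags <- truth@fragments
  if (nrow(frags)) {
    pj <- cells$intensity_jitter[match(frags$cell_id, cells$id)]
    pd <- cells$diameter_um[match(frags$cell_id, cells$id)]
    sig <- frags$diameter_um / 4 / xy
    # the fragment cluster disperses through (and slightly beyond) the former
    # cell volume, so its axial extent is wider than an intact nucleus
    objs[[length(objs) + 1]] <- data.frame(
      row = frags$row_px, col = frags$col_px, z = frags$z_um,
      siga = sig, sigb = sig, er = 1, ec = 0,
      amp = params@nucleusIntensity * pj * params@fragmentIntensityFactor,
      sigz = pd / 3)
  }
  if (length(objs) == 0)
    return(ImageStack(arr, params@calibration, params@depthOffset))
  ob <- do.call(rbind, objs)
  depths <- params@depthOffset + (seq_len(params@nSlices) - 1) * params@calibration@zStep
  for (s in seq_len(params@nSlices)) {
    fz <- exp(-(ob$z - depths[s])^2 / (2 * ob$sigz^2))
    keep <- which(fz >= 0.005)
    if (!length(keep)) next
    sl <- matrix(arr[s, , ], nr, nc)
    for (i in keep) {
      rad <- ceiling(3.5 * max(ob$siga[i], ob$sigb[i]))
      r0 <- max(1, round(ob$row[i]) + 1 - rad); r1 <- min(nr, round(ob$row[i]) + 1 + rad)
      c0 <- max(1, round(ob$col[i]) + 1 - rad); c1 <- min(nc, round(ob$col[i]) + 1 + rad)
      if (r0 > r1 || c0 > c1) next
      rr <- (r0:r1) - 1 - ob$row[i]
      cc <- (c0:c1) - 1 - ob$col[i]
      A <- outer(rr, cc, function(a, b) {
        u <- a * ob$er[i] + b * ob$ec[i]
        v <- -a * ob$ec[i] + b * ob$er[i]
        exp(-0.5 * (u / ob$siga[i])^2 - 0.5 * (v / ob$sigb[i])^2)
      })
      sl[r0:r1, c0:c1] <- sl[r0:r1, c0:c1] + ob$amp[i] * fz[i] * A
    }
    arr[s, , ] <- sl
  }
  ImageStack(arr, params@calibration, params@depthOffset)
}

#' Apply imaging optics to a noise-free stack
#'
#' Pure function of its inputs and seed: per-slice in-plane PSF blur, depth
#' attenuation \eqn{I(z) = I_0 e^{-z/\lambda}} with depth
#' \code{depthOffset + index * zStep} (Beer-Lambert; \code{Inf} disables),
#' optional Poisson shot noise on the attenuated signal, then background
#' offset and additive Gaussian read noise.
#'
#' @param cleanStack noise-free \linkS4class{ImageStack}.
#' @param attenuationLength optical mean free path, micrometers.
#' @param backgroundLevel background offset, a.u.
#' @param gaussianNoiseSD read-noise standard deviation, a.u.
#' @param psfSigma in-plane PSF sigma, micrometers.
#' @param seed RNG seed for the noise realization.
#' @param poissonShot apply Poisson shot noise to the signal.
#' @return An \linkS4class{ImageStack}.
#' @export
applyOptics <- function(cleanStack, attenuationLength, backgroundLevel = 0,
                        gaussianNoiseSD = 0, psfSigma = 0, seed = 0,
                        poissonShot = TRUE) {
  if (!is.finite(attenuationLength) && !is.infinite(attenuationLength))
    sqStop("sqParamError", "attenuationLength must be positive (Inf allowed)")
  if (attenuationLength <= 0)
    sqStop("sqParamError", "attenuationLength must be positive (Inf allowed)")
  d <- dim(cleanStack@voxels)
  out <- array(0, dim = d)
  depths <- sliceDepths(cleanStack)
  psfPx <- psfSigma / xySize(cleanStack)
  withSeed(seed, {
    for (s in seq_len(d[1])) {
      img <- sliceImage(cleanStack, s)
      if (psfPx > 0) img <- cpp_gaussian_blur(img, psfPx)
      att <- if (is.infinite(attenuationLength)) 1 else exp(-depths[s] / attenuationLength)
      sig <- img * att
      if (poissonShot) sig <- matrix(rpois(length(sig), sig), d[2], d[3])
      sl <- sig + backgroundLevel
      if (gaussianNoiseSD > 0)
        sl <- sl + matrix(rnorm(length(sl), 0, gaussianNoiseSD), d[2], d[3])
      out[s, , ] <- pmax(0, sl)
    }
  })
  ImageStack(out, cleanStack@calibration, cleanStack@depthOffset)
}

#' Simulate a spheroid invasion specimen
#'
#' Places \code{nCore} cells uniformly in the core ball, \code{nRim} in the
#' rim shell and \code{nInvading} at radii following the exponential density
#' decay out to \code{maxInvasionDistance} (within an equatorial slab, with
#' radially polarized elongation), assigns apoptotic/mitotic states, renders
#' the noise-free specimen and applies the configured optics. Identical seeds
#' give voxel-identical output.
#'
#' @param params a \linkS4class{SimParams}.
#' @return List with elements \code{stack} (\linkS4class{ImageStack}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' p <- SimParams(seed = 1, nCore = 50L, nRim = 50L, nInvading = 20L,
#'                coreRadius = 60, rimThickness = 20, maxInvasionDistance = 150,
#'                imageShape = c(192L, 192L), depthOffset = 60)
#' sim <- simulateSpheroid(p)
#' sim$truth
#' @export
simulateSpheroid <- function(params) {
  truth <- sampleTruth(params)
  clean <- renderTruth(params, truth)
  stack <- applyOptics(clean, params@attenuationLength, params@backgroundLevel,
                       params@gaussianNoiseSD, params@psfSigma,
                       seed = params@seed + 1)
  list(stack = stack, truth = truth)
}

#' Simulate a control/treated specimen pair
#'
#' The control arm uses \code{params} unchanged. The treated arm starts from
#' the identical base specimen (same seed), then, under seed
#' \code{params@seed + 2}: each invading cell is removed independently with
#' probability \code{invasionKillFraction} (one uniform per invading cell, in
#' cell order: killed iff u < fraction); invading cells beyond
#' \code{maxInvasionDistance - invasionDistanceReduction} are removed; and
#' each surviving non-apoptotic invasion-zone cell converts to apoptosis with
#' probability \code{extraApoptoticFraction} (fresh fragment clusters drawn
#' from the same stream). Core and rim populations are untouched.
#'
#' @param params a \linkS4class{SimParams}.
#' @param invasionKillFraction probability in [0,1] of removing each invading cell.
#' @param invasionDistanceReduction truncation of the invasion front, micrometers.
#' @param extraApoptoticFraction additional apoptotic conversion probability in [0,1].
#' @return List with elements \code{control} and \code{treated}, each a list
#'   with \code{stack} and \code{truth}.
#' @export
simulateTreatmentPair <- function(params, invasionKillFraction = 0,
                                  invasionDistanceReduction = 0,
                                  extraApoptoticFraction = 0) {
  if (invasionKillFraction < 0 || invasionKillFraction > 1 ||
      extraApoptoticFraction < 0 || extraApoptoticFraction > 1)
    sqStop("sqParamError", "fractions must lie in [0, 1]")
  newMax <- params@maxInvasionDistance - invasionDistanceReduction
  if (invasionDistanceReduction < 0 ||
      newMax <= params@coreRadius + params@rimThickness)
    sqStop("sqParamError", "invasionDistanceReduction outside geometric bounds")
  control <- simulateSpheroid(params)
  base <- sampleTruth(params)
  cells <- base@cells
  frags <- base@fragments
  withSeed(params@seed + 2, {
    inv <- which(cells$zone == "invasion")
    uKill <- runif(length(inv))
    drop <- inv[uKill < invasionKillFraction]
    drop <- union(drop, inv[cells$radial_um[inv] > newMax])
    if (length(drop)) {
      frags <- frags[!frags$cell_id %in% cells$id[drop], , drop = FALSE]
      cells <- cells[-drop, , drop = FALSE]
    }
    surv <- which(cells$zone == "invasion" & cells$state != "apoptotic")
    uConv <- runif(length(surv))
    conv <- surv[uConv < extraApoptoticFraction]
    if (length(conv)) {
      cells$state[conv] <- "apoptotic"
      newFr <- sampleFragments(params, cells[conv, , drop = FALSE])
      frags <- rbind(frags, newFr)
    }
  })
  treatedTruth <- new("GroundTruth", cells = cells, fragments = frags,
                      attenuationLength = params@attenuationLength,
                      seed = params@seed)
  clean <- renderTruth(params, treatedTruth)
  stack <- applyOptics(clean, params@attenuationLength, params@backgroundLevel,
                       params@gaussianNoiseSD, params@psfSigma,
                       seed = params@seed + 3)
  list(control = control, treated = list(stack = stack, truth = treatedTruth))
}

#' Preset simulation parameter sets
#'
#' \code{"control"} and \code{"cleared"} use cleared optics (attenuation
#' length 500 um); \code{"uncleared"} uses 25 um, reproducing the shallow
#' usable depth of native specimens; \code{"irradiated"} marks the specimen
#' for the treated arm of \code{\link{simulateTreatmentPair}} (50 percent
#' invasion-zone kill, 100 um invasion-front reduction, apoptotic conversion
#' to a total of about 8 percent).
#'
#' @param preset one of "control", "irradiated", "uncleared", "cleared".
#' @param seed RNG seed.
#' @param ... overrides passed to \code{\link{SimParams}}.
#' @return A \linkS4class{SimParams}; for "irradiated" the treatment effect
#'   sizes are attached as the \code{"treatment"} attribute.
#' @export
simPreset <- function(preset = c("control", "irradiated", "uncleared", "cleared"),
                      seed, ...) {
  preset <- match.arg(preset)
  args <- list(seed = seed, ...)
  if (preset == "uncleared" && is.null(args$attenuationLength))
    args$attenuationLength <- 25
  p <- do.call(SimParams, args)
  if (preset == "irradiated")
    attr(p, "treatment") <- list(invasionKillFraction = 0.5,
                                 invasionDistanceReduction = 100,
                                 extraApoptoticFraction = 0.075)
  p
}
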