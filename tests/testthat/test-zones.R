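cal <- PixelCalibration(2, 10)

test_that("ellipse fitting recovers disc and rectangle moments", {
  # 64-gon approximating a disc of radius 50
  poly <- BoundaryPolygon(regularPolygon(c(100, 100), 50, 64), "core_rim")
  e <- fitBoundaryEllipse(poly)
  expect_equal(e$semiMajor, 50, tolerance = 1 / 50)
  expect_equal(e$semiMinor, 50, tolerance = 1 / 50)
  expect_equal(pi * e$semiMajor * e$semiMinor, pi * 50^2, tolerance = 0.01)
  expect_equal(unname(e$center), c(100, 100), tolerance = 1e-6)

  # axis-aligned rectangle 80 x 40 (cols x rows): orientation 0, ratio 2
  rect <- BoundaryPolygon(cbind(c(10, 10, 50, 50), c(20, 100, 100, 20)), "core_rim")
  er <- fitBoundaryEllipse(rect)
  expect_equal(abs(er$theta) %% pi, 0, tolerance = 0.01)
  expect_equal(er$semiMajor / er$semiMinor, 2, tolerance = 0.02 * 2)

  # rotating the polygon rotates the fitted orientation equivariantly
  rot <- 30 * pi / 180
  v <- rect@vertices
  ctr <- colMeans(v)
  vr <- t(t(cbind(
    (v[, 1] - ctr[1]) * cos(rot) + (v[, 2] - ctr[2]) * sin(rot),
    -(v[, 1] - ctr[1]) * sin(rot) + (v[, 2] - ctr[2]) * cos(rot))) + ctr)
  err <- fitBoundaryEllipse(BoundaryPolygon(vr, "core_rim"))
  dTheta <- abs(err$theta - er$theta) %% pi
  expect_equal(min(dTheta, pi - dTheta), rot, tolerance = 1 * pi / 180)

  degen <- BoundaryPolygon(cbind(c(0, 1, 2), c(0, 1, 2)), "core_rim")
  expect_error(fitBoundaryEllipse(degen), class = "sqGeometryError")
})

test_that("zone maps partition the slice with analytic ring areas", {
  zm <- zoneMapFromRadii(c(127.5, 127.5), 60, 120, c(256L, 256L), cal)
  lab <- zoneLabels(zm)
  expect_equal(sort(unique(as.vector(lab))), c(1L, 2L, 3L))   # full partition
  # pixel radii: 60 um = 30 px, 120 um = 60 px
  expect_equal(sum(lab == 1), pi * 30^2, tolerance = 0.02)
  expect_equal(sum(lab == 2), pi * (60^2 - 30^2), tolerance = 0.02)
  expect_equal(sum(lab == 3), 256^2 - pi * 60^2, tolerance = 0.02)

  # coincident boundaries: empty rim accepted with a warning
  expect_warning(zm0 <- zoneMapFromRadii(c(127.5, 127.5), 60, 60, c(256L, 256L), cal),
                 "rim")
  expect_equal(sum(zoneLabels(zm0) == 2), 0)

  # crossing boundaries are a geometry error
  inner <- spheroidquant:::circleEllipse(c(127.5, 127.5), 30)
  outer <- spheroidquant:::circleEllipse(c(180, 127.5), 35)
  expect_error(buildZoneMap(inner, outer, c(256L, 256L)), class = "sqGeometryError")
})

test_that("image-based boundary estimation recovers known radii and rejects noise", {
  p <- SimParams(seed = 7, coreRadius = 100, rimThickness = 30,
                 maxInvasionDistance = 300, nCore = 450L, nRim = 1250L,
                 nInvading = 150L, imageShape = c(384L, 384L),
                 depthOffset = 110, nSlices = 3L)
  sim <- simulateSpheroid(p)
  b <- estimateBoundaries(sim$stack, 2)
  labs <- vapply(b, function(x) x@label, character(1))
  expect_setequal(labs, c("core_rim", "rim_invasion"))
  rr <- vapply(b, function(x) {
    e <- fitBoundaryEllipse(x)
    mean(c(e$semiMajor, e$semiMinor)) * 2   # px -> um at 2 um/px
  }, numeric(1))
  expect_equal(rr[labs == "core_rim"], 100, tolerance = 0.10, ignore_attr = TRUE)
  expect_equal(rr[labs == "rim_invasion"], 130, tolerance = 0.10, ignore_attr = TRUE)

  blank <- applyOptics(ImageStack(array(0, c(3, 128, 128)), cal), Inf,
                       backgroundLevel = 10, gaussianNoiseSD = 2, seed = 2)
  expect_error(estimateBoundaries(blank, 2), class = "sqEstimationError")
})

test_that("quadrant selection is seeded, uniform and partitions the slice", {
  zm <- zoneMapFromRadii(c(64, 64), 40, 60, c(129L, 129L), cal)
  q1 <- selectQuadrant(zm, 99); q2 <- selectQuadrant(zm, 99)
  expect_equal(q1@quadrant, q2@quadrant)

  draws <- vapply(1:4000, function(s) selectQuadrant(zm, s)@quadrant, integer(1))
  expect_true(all(abs(tabulate(draws + 1L, 4) / 4000 - 0.25) <= 0.02))

  masks <- lapply(0:3, function(k) {
    sel <- new("QuadrantSelection", quadrant = as.integer(k), seed = 0,
               centroid = c(64, 64))
    quadrantMask(sel, c(129L, 129L))
  })
  tot <- Reduce(`+`, lapply(masks, function(m) m + 0))
  expect_true(all(tot <= 1))                       # disjoint
  onAxes <- row(tot) - 1 == 64 | col(tot) - 1 == 64
  expect_true(all(tot[!onAxes] == 1))              # cover everything off-axis
  expect_true(all(tot[onAxes] == 0))
})

test_that("radial distances use the calibration and rotation-invariant geometry", {
  rec <- data.frame(row = c(10, 13), col = c(20, 24))
  out <- radialDistance(rec, c(10, 20), cal)
  expect_equal(out$radial_um, c(0, 10))   # 3-4-5 triangle at 2 um/px

  # rotating the scene about the centroid leaves distances unchanged
  set.seed(1)
  pts <- data.frame(row = runif(20, 0, 100), col = runif(20, 0, 100))
  d0 <- radialDistance(pts, c(50, 50), cal)$radial_um
  rot <- data.frame(row = 50 + (pts$col - 50), col = 50 - (pts$row - 50))
  expect_equal(radialDistance(rot, c(50, 50), cal)$radial_um, d0)
})

test_that("zone assignment honors the quadrant restriction contract", {
  zm <- zoneMapFromRadii(c(64, 64), 40, 60, c(128L, 128L), cal)
  sel <- new("QuadrantSelection", quadrant = 3L, seed = 0, centroid = c(64, 64))
  rec <- data.frame(row = c(64, 100, 20, 200), col = c(64, 100, 20, 20))
  expect_warning(out <- assignZones(rec, zm, sel, restrictInvasionToQuadrant = FALSE),
                 "outside")
  expect_warning(outR <- assignZones(rec, zm, sel, restrictInvasionToQuadrant = TRUE),
                 "outside")
  expect_equal(out$zone, c("core", "invasion", "invasion", "unassigned"))
  # quadrant 3 is (+row, +col): the (20, 20) invasion record drops out
  expect_equal(outR$zone[2:3], c("invasion", "unassigned"))
})

test_that("assigned zones agree with simulator ground truth for matched nuclei", {
  p <- recoveryParams(17)
  sim <- simulateSpheroid(p)
  seg <- segmentStack(sim$stack)
  zm <- zoneMapFromRadii(spheroidquant:::simCentroidPx(p), 100, 125,
                         c(384L, 384L), calibration(sim$stack))
  nuc <- assignZones(radialDistance(seg$nuclei, spheroidCentroid(zm),
                                    calibration(sim$stack)), zm)
  tc <- truthCells(sim$truth); tc <- tc[tc$state != "apoptotic", ]
  depths <- sliceDepths(sim$stack)
  agree <- 0L; total <- 0L
  for (s in 1:3) {
    det <- nuc[nuc$slice == s, ]
    if (!nrow(det)) next
    d2 <- outer(det$row, tc$row_px, "-")^2 + outer(det$col, tc$col_px, "-")^2
    nn <- apply(d2, 1, which.min)
    ok <- sqrt(d2[cbind(seq_len(nrow(det)), nn)]) * 2 <= 10 &
      abs(tc$z_um[nn] - depths[s]) <= 8
    agree <- agree + sum(det$zone[ok] == tc$zone[nn[ok]])
    total <- total + sum(ok)
  }
  expect_gt(total, 100)
  expect_gte(agree / total, 0.95)
})
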