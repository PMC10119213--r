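test_that("empty scenes and determinism behave as contracted", {
  p0 <- SimParams(seed = 3, nCore = 0L, nRim = 0L, nInvading = 0L,
                  coreRadius = 60, rimThickness = 20, maxInvasionDistance = 150,
                  imageShape = c(160L, 160L), depthOffset = 60)
  sim <- simulateSpheroid(p0)
  expect_equal(nrow(truthCells(sim$truth)), 0)
  # pure background noise: mean close to backgroundLevel
  expect_lt(abs(mean(voxels(sim$stack)) - p0@backgroundLevel), 1)

  p <- SimParams(seed = 7, nCore = 60L, nRim = 60L, nInvading = 30L,
                 coreRadius = 60, rimThickness = 20, maxInvasionDistance = 150,
                 imageShape = c(160L, 160L), depthOffset = 60)
  s1 <- simulateSpheroid(p); s2 <- simulateSpheroid(p)
  expect_identical(voxels(s1$stack), voxels(s2$stack))
  expect_identical(truthCells(s1$truth), truthCells(s2$truth))
})

test_that("ground-truth zone counts equal the requested cell numbers", {
  p <- SimParams(seed = 11, nCore = 123L, nRim = 77L, nInvading = 55L,
                 coreRadius = 60, rimThickness = 20, maxInvasionDistance = 150,
                 imageShape = c(160L, 160L), depthOffset = 60)
  tc <- truthCells(simulateSpheroid(p)$truth)
  expect_equal(sum(tc$zone == "core"), 123)
  expect_equal(sum(tc$zone == "rim"), 77)
  expect_equal(sum(tc$zone == "invasion"), 55)
  # zone labels consistent with radial distance and the configured radii
  expect_true(all(tc$radial_um[tc$zone == "core"] <= 60))
  expect_true(all(tc$radial_um[tc$zone == "rim"] > 60 &
                    tc$radial_um[tc$zone == "rim"] <= 80))
  expect_true(all(tc$radial_um[tc$zone == "invasion"] > 80 &
                    tc$radial_um[tc$zone == "invasion"] <= 150))
})

test_that("optics follow the closed-form attenuation law", {
  cal <- PixelCalibration(2, 10)
  clean <- ImageStack(array(1, c(4, 16, 16)), cal, depthOffset = 5)
  out <- applyOptics(clean, attenuationLength = 50, backgroundLevel = 2,
                     gaussianNoiseSD = 0, psfSigma = 0, seed = 1,
                     poissonShot = FALSE)
  depths <- 5 + (0:3) * 10
  for (s in 1:4)
    expect_equal(unique(as.vector(sliceImage(out, s))),
                 exp(-depths[s] / 50) + 2, tolerance = 1e-12)
  # infinite attenuation length: identity plus background
  id <- applyOptics(clean, Inf, backgroundLevel = 2, gaussianNoiseSD = 0,
                    psfSigma = 0, seed = 1, poissonShot = FALSE)
  expect_equal(voxels(id), voxels(clean) + 2)
  # identical seed, identical noise realization
  n1 <- applyOptics(clean, 50, 2, gaussianNoiseSD = 1, seed = 9)
  n2 <- applyOptics(clean, 50, 2, gaussianNoiseSD = 1, seed = 9)
  expect_identical(voxels(n1), voxels(n2))
  expect_error(applyOptics(clean, -1, seed = 1), class = "sqParamError")
})

test_that("mean slice intensity is non-increasing with depth under finite attenuation", {
  p <- SimParams(seed = 5, coreRadius = 60, rimThickness = 15,
                 maxInvasionDistance = 120, nCore = 400L, nRim = 100L,
                 nInvading = 20L, imageShape = c(128L, 128L),
                 calibration = PixelCalibration(2, 6), nSlices = 20L,
                 depthOffset = 0, centerDepth = 60, attenuationLength = 40,
                 gaussianNoiseSD = 0, backgroundLevel = 0)
  clean <- spheroidquant:::renderTruth(p, spheroidquant:::sampleTruth(p))
  out <- applyOptics(clean, 40, 0, 0, psfSigma = 1, seed = 1, poissonShot = FALSE)
  means <- vapply(1:20, function(s) mean(sliceImage(out, s)), numeric(1))
  cleanMeans <- vapply(1:20, function(s) mean(sliceImage(clean, s)), numeric(1))
  # attenuation can only reduce each slice relative to its noise-free render,
  # increasingly with depth
  ratio <- means / pmax(cleanMeans, 1e-12)
  expect_true(all(diff(ratio) < 1e-9))
})

test_that("invading-cell radii follow the truncated exponential density", {
  p <- SimParams(seed = 13, coreRadius = 100, rimThickness = 30,
                 maxInvasionDistance = 850, nCore = 0L, nRim = 0L,
                 nInvading = 10000L, invasionDensityDecay = 300,
                 imageShape = c(896L, 896L), depthOffset = 160)
  tc <- truthCells(spheroidquant:::sampleTruth(p))
  r <- tc$radial_um - 130
  span <- 850 - 130
  # compare empirical quantiles with the truncated-exponential quantile function
  u <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  qTheory <- -300 * log(1 - u * (1 - exp(-span / 300)))
  qEmp <- unname(quantile(r, u))
  expect_lt(max(abs(qEmp - qTheory)), 15)  # ~2% of the span at n = 1e4
})

test_that("state assignment reproduces the documented RNG procedure", {
  p <- SimParams(seed = 21, coreRadius = 100, rimThickness = 30,
                 maxInvasionDistance = 400, nCore = 0L, nRim = 0L,
                 nInvading = 200L, imageShape = c(448L, 448L), depthOffset = 160,
                 apoptoticFraction = 0.08)
  tc <- truthCells(spheroidquant:::sampleTruth(p))
  # independent oracle: consume the stream exactly as documented
  expected <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
    set.seed(21L, kind = "Mersenne-Twister", normal.kind = "Inversion")
    rnorm(200)                     # diameters are drawn first
    sum(runif(200) < 0.08)         # then the apoptosis draws
  })
  expect_equal(sum(tc$state == "apoptotic"), expected)
})

test_that("fragment clusters respect their geometric contract", {
  p <- SimParams(seed = 8, coreRadius = 100, rimThickness = 30,
                 maxInvasionDistance = 400, nCore = 100L, nRim = 100L,
                 nInvading = 300L, imageShape = c(448L, 448L), depthOffset = 160,
                 apoptoticFraction = 0.2)
  tr <- spheroidquant:::sampleTruth(p)
  tf <- truthFragments(tr); tc <- truthCells(tr)
  expect_gt(nrow(tf), 0)
  counts <- table(tf$cell_id)
  expect_true(all(counts >= p@fragmentsPerEventMin))
  expect_true(all(counts <= p@fragmentsPerEventMax))
  expect_true(all(tf$area_um2 >= 3 & tf$area_um2 <= 25))
  # each fragment within the scatter radius of its event center
  m <- match(tf$cell_id, tc$id)
  d <- sqrt((tf$row_px - tc$row_px[m])^2 + (tf$col_px - tc$col_px[m])^2) * 2
  expect_true(all(d <= p@fragmentScatterRadius + 1e-9))
})

test_that("parameter validation rejects impossible scenes", {
  expect_error(SimParams(seed = 1, coreRadius = 200, rimThickness = 100,
                         maxInvasionDistance = 250), "maxInvasionDistance")
  expect_error(SimParams(seed = 1, maxInvasionDistance = 5000), "half-extent")
  expect_error(SimParams(seed = 1, apoptoticFraction = 1.5), "fractions")
  # overlap saturation names the zone
  p <- SimParams(seed = 1, coreRadius = 60, rimThickness = 20,
                 maxInvasionDistance = 150, nCore = 60000L, nRim = 0L,
                 nInvading = 0L, imageShape = c(160L, 160L), depthOffset = 60)
  expect_error(simulateSpheroid(p), "core", class = "sqParamError")
})

test_that("treatment pairs apply kill, truncation and conversions to invasion only", {
  p <- SimParams(seed = 31, coreRadius = 80, rimThickness = 20,
                 maxInvasionDistance = 300, nCore = 80L, nRim = 80L,
                 nInvading = 400L, imageShape = c(384L, 384L), depthOffset = 100)
  # no-op treatment keeps every cell
  pair0 <- simulateTreatmentPair(p, 0, 0, 0)
  expect_equal(nrow(truthCells(pair0$treated$truth)),
               nrow(truthCells(pair0$control$truth)))
  # full kill empties the invasion zone, core and rim untouched
  pair1 <- simulateTreatmentPair(p, 1, 0, 0)
  tt <- truthCells(pair1$treated$truth)
  expect_equal(sum(tt$zone == "invasion"), 0)
  expect_equal(sum(tt$zone == "core"), 80)
  expect_equal(sum(tt$zone == "rim"), 80)
  # survival draws reproduce the documented seed + 2 stream
  pair <- simulateTreatmentPair(p, 0.5, 0, 0)
  surv <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
    set.seed(31L + 2L, kind = "Mersenne-Twister")
    sum(runif(400) >= 0.5)
  })
  expect_equal(sum(truthCells(pair$treated$truth)$zone == "invasion"), surv)
  expect_error(simulateTreatmentPair(p, 1.2, 0, 0), class = "sqParamError")
  expect_error(simulateTreatmentPair(p, 0, 250, 0), class = "sqParamError")
})
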