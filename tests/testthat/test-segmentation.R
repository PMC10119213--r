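cal1 <- PixelCalibration(1, 10)

test_that("Gaussian preprocessing is smoothing-invariant, symmetric and conservative", {
  const <- matrix(7, 32, 32)
  expect_equal(gaussianPreprocess(const, 1.5, cal1), const, tolerance = 1e-12)

  imp <- matrix(0, 41, 41); imp[21, 21] <- 100
  out <- gaussianPreprocess(imp, 2, cal1)
  expect_equal(which(out == max(out)), 21 + 20 * 41)   # maximum stays put
  expect_equal(sum(out), 100, tolerance = 1e-6)        # mass conserved
  expect_equal(out, t(out), tolerance = 1e-12)         # symmetric kernel

  # 1D step edge: value at the edge midway between the plateaus within 1%
  step <- matrix(rep(c(0, 10), each = 30), 1, 60, byrow = TRUE)
  step <- matrix(rep(ifelse(seq_len(60) <= 30, 0, 10), each = 20), 20, 60)
  sm <- gaussianPreprocess(step, 3, cal1)
  edgeVal <- mean(sm[, 30:31])
  expect_equal(edgeVal, 5, tolerance = 0.05)
})

test_that("Phansalkar threshold matches its formula on canonical cases", {
  expect_warning(m0 <- phansalkarThreshold(matrix(0, 16, 16)), "constant")
  expect_true(all(m0 == 0))

  # bright disc on black: interior foreground (t = 0.75 < 1 at m ~ 1, s ~ 0),
  # far background not foreground (t = 0 and value 0 is not > 0)
  img <- matrix(0, 64, 64)
  rows <- row(img); cols <- col(img)
  disc <- (rows - 32)^2 + (cols - 32)^2 <= 20^2
  img[disc] <- 100
  mask <- phansalkarThreshold(img, SegmentationParams(windowRadius = 5L))
  inner <- (rows - 32)^2 + (cols - 32)^2 <= 12^2
  far <- (rows - 32)^2 + (cols - 32)^2 >= 30^2
  expect_true(all(mask[inner] == 1))
  expect_true(all(mask[far] == 0))
})

test_that("Phansalkar and median filters match brute-force oracles", {
  set.seed(77)
  for (i in 1:4) {
    img <- matrix(runif(24 * 24) + (i %% 2) * 3 *
                    dnorm(as.vector(row(matrix(0, 24, 24))) - 12, sd = 4), 24, 24)
    rad <- c(3L, 5L, 7L, 4L)[i]
    got <- phansalkarThreshold(img, SegmentationParams(windowRadius = rad))
    expect_identical(got, oraclePhansalkar(img, rad))
    mask <- matrix(as.integer(runif(24 * 24) < 0.4), 24, 24)
    expect_identical(postprocessMask(mask, rad), oracleMedianDisc(mask, rad))
  }
})

test_that("binary median keeps solid regions and removes speckle", {
  solid <- matrix(1L, 20, 20)
  expect_identical(postprocessMask(solid, 3L), solid)
  speck <- matrix(0L, 20, 20); speck[10, 10] <- 1L
  expect_true(all(postprocessMask(speck, 3L) == 0))
})

test_that("watershed separates touching discs without splitting solitary ones", {
  mk <- function(centers, r, shape = c(60, 80)) {
    m <- matrix(0L, shape[1], shape[2])
    for (i in seq_len(nrow(centers)))
      m[(row(m) - centers[i, 1])^2 + (col(m) - centers[i, 2])^2 <= r^2] <- 1L
    m
  }
  one <- mk(cbind(30, 40), 10)
  expect_equal(max(watershedSplit(one)), 1)

  two <- mk(cbind(c(20, 20), c(20, 60)), 10)
  expect_equal(max(watershedSplit(two)), 2)

  # dumbbell: equal discs, centers 16 px apart; split line within 1 px of the
  # symmetry axis (column 40 between centers at 32 and 48)
  db <- mk(cbind(c(30, 30), c(32, 48)), 10)
  lab <- watershedSplit(db)
  expect_equal(max(lab), 2)
  lineCols <- col(db)[db == 1 & lab == 0]
  expect_true(all(abs(lineCols - 40) <= 1))

  # conservation: no foreground created; line pixels border a label
  expect_true(all(lab[db == 0] == 0))
})

test_that("particle filter applies the calibrated area band and keeps fragments", {
  lab <- matrix(0L, 40, 40)
  lab[2:5, 2:11] <- 1L     # 40 px
  lab[20:29, 20:29] <- 2L  # 100 px
  img <- matrix(10, 40, 40)
  res1 <- filterParticles(lab, img, PixelCalibration(1, 10))
  expect_equal(nrow(res1$nuclei), 1)          # 100 um2 inside 45-700
  expect_equal(res1$nuclei$area_um2, 100)
  expect_equal(nrow(res1$fragments), 1)       # 40 um2 kept as fragment candidate
  expect_equal(res1$fragments$area_um2, 40)

  # calibration governs: the same 40 px label at 2 um/px is 160 um2, a nucleus
  res2 <- filterParticles(lab, img, PixelCalibration(2, 10))
  expect_equal(sort(res2$nuclei$area_um2), c(160, 400))
  expect_equal(nrow(res2$fragments), 0)

  # intensity-weighted centroid in 0-based pixel coordinates: 99 unit pixels
  # plus one of weight 100 at (28, 28) pull the centroid to 5122/199
  img2 <- matrix(0, 40, 40); img2[20:29, 20:29] <- 1; img2[29, 29] <- 100
  res3 <- filterParticles(lab, img2, PixelCalibration(1, 10))
  big <- res3$nuclei[res3$nuclei$area_um2 == 100, ]
  expect_equal(big$row, 5122 / 199, tolerance = 1e-9)
  expect_equal(big$col, 5122 / 199, tolerance = 1e-9)
  expect_error(filterParticles(lab, img, NULL), class = "sqParamError")
})

test_that("full-stack segmentation is deterministic and recovers isolated nuclei", {
  # empty specimen (uniform background): nothing segmented
  empty <- ImageStack(array(10, c(2, 96, 96)), cal1)
  seg0 <- segmentStack(empty)
  expect_equal(nrow(seg0$nuclei), 0)

  # six well-separated synthetic nuclei on one slice
  centers <- as.matrix(expand.grid(c(25, 64, 103), c(35, 90)))
  clean <- blobStack(centers, shape = c(128L, 128L), sigmaPx = 3,
                     calibration = cal1)
  st <- applyOptics(clean, Inf, backgroundLevel = 10, gaussianNoiseSD = 2, seed = 5)
  seg <- segmentStack(st)
  expect_equal(nrow(seg$nuclei), 6)
  # detections sit on the planted centers
  d <- sqrt(outer(seg$nuclei$row, centers[, 1], "-")^2 +
              outer(seg$nuclei$col, centers[, 2], "-")^2)
  expect_lt(max(apply(d, 1, min)), 2)

  seg2 <- segmentStack(st)
  expect_identical(seg$nuclei, seg2$nuclei)
})
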