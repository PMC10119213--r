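cal <- PixelCalibration(1, 10)

fragRow <- function(id, row, col, area, slice = 1L) {
  data.frame(id = id, slice = slice, row = row, col = col, area_um2 = area,
             mean_intensity = 20)
}

test_that("apoptosis detection applies the size band and linking radius", {
  # single 2 um2 fragment: below the 3 um2 floor, no event
  r <- detectApoptosis(fragRow(1, 10, 10, 2), cal)
  expect_equal(nrow(r$events), 0)

  # two 10 um2 fragments 25 um apart: beyond the 20 um rule, no event
  r <- detectApoptosis(rbind(fragRow(1, 10, 10, 10), fragRow(2, 10, 35, 10)), cal)
  expect_equal(nrow(r$events), 0)

  # four 5 um2 fragments pairwise within 10 um: exactly one event of 4
  fr <- rbind(fragRow(1, 10, 10, 5), fragRow(2, 14, 12, 5),
              fragRow(3, 12, 18, 5), fragRow(4, 17, 16, 5))
  r <- detectApoptosis(fr, cal)
  expect_equal(nrow(r$events), 1)
  expect_equal(r$events$n_fragments, 4)
  expect_equal(r$events$row, mean(fr$row))
  # no fragment is in more than one event
  expect_true(all(table(r$fragments$event_id) >= 2))
  expect_false(anyNA(r$fragments$event_id[!is.na(r$fragments$event_id)]))

  # chains link by single linkage: 3 fragments at 15 um steps form one event
  ch <- rbind(fragRow(1, 10, 10, 8), fragRow(2, 10, 25, 8), fragRow(3, 10, 40, 8))
  r <- detectApoptosis(ch, cal)
  expect_equal(nrow(r$events), 1)
  expect_equal(r$events$n_fragments, 3)

  # fragments on different slices never cluster together
  tw <- rbind(fragRow(1, 10, 10, 8, 1L), fragRow(2, 10, 12, 8, 2L))
  expect_equal(nrow(detectApoptosis(tw, cal)$events), 0)
})

test_that("death frequency is events over events plus intact nuclei", {
  ev <- data.frame(event_id = 1:8, zone = "invasion")
  nuc <- data.frame(id = 1:92, zone = "invasion")
  expect_equal(deathFrequency(ev, nuc, "invasion"), 0.08)
  expect_equal(deathFrequency(ev[0, ], nuc, "invasion"), 0)
  expect_warning(z <- deathFrequency(ev[0, ], nuc[0, ], "invasion"), "death frequency")
  expect_equal(z, 0)
})

test_that("mitosis ingestion validates, deduplicates and assigns zones", {
  zm <- zoneMapFromRadii(c(64, 64), 40, 60, c(128L, 128L), cal)
  nuc <- data.frame(id = 1:98, zone = rep(c("core", "invasion"), c(49, 49)))

  r0 <- ingestMitoses(NULL, zm, nuc, cal)
  expect_true(all(r0$frequency == 0))

  ann <- data.frame(slice = 1L, row = c(64, 57), col = c(64, 64), label = "mitosis")
  r <- ingestMitoses(ann, zm, nuc, cal)
  expect_equal(unname(r$counts["core"]), 2L)
  expect_equal(unname(r$frequency["core"]), 2 / (2 + 49))

  # duplicates within 5 um on one slice collapse with a warning
  dup <- data.frame(slice = 1L, row = c(30, 31), col = c(64, 65), label = "mitosis")
  expect_warning(rd <- ingestMitoses(dup, zm, nuc, cal), "duplicate")
  expect_equal(sum(rd$counts), 1L)

  # out-of-bounds annotations are rejected with a warning
  oob <- data.frame(slice = 1L, row = c(64, 500), col = c(64, 64), label = "mitosis")
  expect_warning(ro <- ingestMitoses(oob, zm, nuc, cal), "outside")
  expect_equal(sum(ro$counts), 1L)
})

test_that("summaries cover per-slice counts, frequencies and invasion distances", {
  zm <- zoneMapFromRadii(c(64, 64), 40, 60, c(128L, 128L), cal)
  empty <- summarizeQuantification(NULL, NULL, NULL, zm, NULL, cal)
  expect_true(all(zoneSummary(empty)$total_nuclei == 0))
  expect_equal(invasionSummary(empty)$max_um, 0)

  nuc <- data.frame(id = 1:6, slice = c(1, 1, 1, 2, 2, 2), row = 1, col = 1,
                    area_um2 = 100, mean_intensity = 10,
                    zone = c("core", "invasion", "invasion", "core", "rim", "invasion"),
                    radial_um = c(5, 80, 120, 6, 50, 95), state = "normal")
  ev <- data.frame(event_id = 1L, slice = 1L, row = 1, col = 1,
                   n_fragments = 3L, zone = "invasion")
  res <- summarizeQuantification(nuc, ev, NULL, zm, NULL, cal, timeLabel = "d7")
  zs <- zoneSummary(res)
  expect_equal(zs$total_nuclei[zs$zone == "invasion"], 3)
  expect_equal(zs$mean_per_slice[zs$zone == "invasion"], 1.5)
  expect_equal(zs$death_frequency[zs$zone == "invasion"], 1 / 4)
  expect_equal(invasionSummary(res)$max_um, 120)
  szc <- res@sliceZoneCounts
  expect_equal(szc$n_nuclei[szc$slice == 1 & szc$zone == "invasion"], 2)
})

test_that("Mann-Whitney matches exact enumeration and handles ties", {
  r <- mannWhitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pValue(r), 1)

  r <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(uStatistic(r), 0)
  expect_equal(pValue(r), 0.1)   # 2 of the 20 assignments are as extreme
  expect_equal(r@method, "exact")

  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    vals <- sample(1:6, n1 + n2, replace = TRUE)   # ties likely
    a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
    got <- mannWhitney(a, b)
    ora <- oracleMannWhitney(a, b)
    expect_equal(uStatistic(got), ora$U)
    expect_equal(pValue(got), ora$p)
    expect_lte(uStatistic(got), n1 * n2)
  }

  # large samples: normal approximation agrees with the reference implementation
  set.seed(5)
  a <- rnorm(20); b <- rnorm(25, 0.7)
  got <- mannWhitney(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, correct = TRUE, exact = FALSE))
  expect_equal(got@method, "normal approximation")
  expect_equal(pValue(got), ref$p.value, tolerance = 1e-9)
  expect_error(mannWhitney(numeric(0), 1:3), class = "sqParamError")
})
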