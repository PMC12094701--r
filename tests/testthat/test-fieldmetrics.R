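test_that("field detection finds exactly the seven fixture fields", {
  m <- diskFixture(ringOnly = TRUE)
  l <- detectFields(m)
  expect_equal(nFields(l), 7L)
  # threshold 1 keeps only the peak bins (disk profile: all in-field bins)
  g <- idealRateMap(matrix(c(50, 50), 1), "gaussian", 8, 10)
  lab1 <- detectFields(g, thresholdFrac = 1, minBins = 1L)
  expect_identical(which(fieldLabels(lab1) > 0),
                   which(rateValues(g) == max(rateValues(g))))
  expect_error(detectFields(m, thresholdFrac = 0), "thresholdFrac")
  expect_error(detectFields(RateMap(matrix(0, 34, 34), 3, 100)), "peak")
})

test_that("too-low thresholds merge neighbouring fields", {
  two <- idealRateMap(matrix(c(40, 50, 60, 50), 2, byrow = TRUE),
                      "gaussian", 5, 10)
  expect_equal(nFields(detectFields(two, 0.5)), 2L)
  expect_equal(nFields(detectFields(two, 0.05)), 1L)  # merged
})

test_that("field statistics implement centroid, area and circle diameter", {
  v <- matrix(0, 34, 34); v[10, 12] <- 10
  l <- detectFields(RateMap(v, 3, 100), 0.5, minBins = 1L)
  st <- fieldStats(l)
  expect_equal(st$areaCm2, 9)
  expect_equal(st$diameterCm, 2 * sqrt(9 / pi), tolerance = 1e-12)
  expect_equal(st$cx, 11.5 * 3); expect_equal(st$cy, 9.5 * 3)
  # fine-binned disk: diameter estimate converges to the true diameter
  disk <- idealRateMap(matrix(c(50, 50), 1), "disk", 10, 5,
                       binCm = 1, arenaCm = 100)
  st2 <- fieldStats(detectFields(disk, 0.5))
  expect_equal(st2$diameterCm, 20, tolerance = 0.02 * 20)
  expect_equal(c(st2$cx, st2$cy), c(50, 50), tolerance = 0.5)
})

test_that("central-plus-ring selection returns the six lattice neighbours", {
  a <- arr7()
  m <- diskFixture(a)
  st <- fieldStats(detectFields(m))
  sel <- selectCentralRing(st, c(50, 50))
  expect_equal(nrow(sel$ring), 6L)
  truth <- ringFieldCenters(a, 1L, spacing = 12, center = c(50, 50))
  expect_equal(c(sel$central$cx, sel$central$cy), truth[1, ],
               tolerance = 1.5, ignore_attr = TRUE)
  ringTruth <- truth[-1, ]
  for (i in seq_len(6)) {
    d <- sqrt((ringTruth[, 1] - sel$ring$cx[i])^2 +
              (ringTruth[, 2] - sel$ring$cy[i])^2)
    expect_lt(min(d), 1.5)  # within half a bin of a true centre
  }
  expect_identical(sel, selectCentralRing(st, c(50, 50)))  # deterministic
  expect_error(selectCentralRing(st[1:6, ], c(50, 50)), "insufficient")
})

test_that("the touching-disk fixture yields the sqrt(7) spacing-to-size ratio", {
  res <- spacingAndRatio(diskFixture())
  expect_equal(spacingSizeRatio(res), sqrt(7), tolerance = 0.02)
  expect_equal(meanSpacing(res), sqrt(7) * 12, tolerance = 0.02 * sqrt(7) * 12)
  expect_equal(res@nFieldsUsed, 7L)
  # scale invariance: double every length, identical ratio
  big <- diskFixture(fieldDiameter = 24, arenaCm = 200, binCm = 6)
  expect_equal(spacingSizeRatio(spacingAndRatio(big)),
               spacingSizeRatio(res), tolerance = 1e-9)
})

test_that("raising the threshold never grows a field", {
  m <- diskFixture(profile = "gaussian")
  areas <- vapply(seq(0.15, 0.75, by = 0.1), function(f) {
    l <- detectFields(m, f)
    c(sum(fieldLabels(l) > 0), max(fieldStats(l)$nBins))
  }, numeric(2))
  expect_true(all(diff(areas[1, ]) <= 0))  # total supra-threshold bins
  expect_true(all(diff(areas[2, ]) <= 0))  # largest field
})

test_that("centroids and spacing are recovered on noiseless arrangement maps", {
  for (a in list(arr7(), enumerateArrangements(8)[[1]], arr9())) {
    n <- nElements(a)
    sp <- if (n == 9) 13 else 12
    cc <- fieldCenters(a, 1L, extent = 100, spacing = sp)
    i0 <- which.min((cc[, 1] - 50)^2 + (cc[, 2] - 50)^2)
    cc <- sweep(cc, 2, cc[i0, ] - c(50, 50), "-")
    m <- idealRateMap(cc, "gaussian", sp / 3.2, 15)
    st <- fieldStats(detectFields(m))
    inner <- st[!st$touchesBorder, ]
    for (i in seq_len(nrow(inner))) {
      d <- sqrt((cc[, 1] - inner$cx[i])^2 + (cc[, 2] - inner$cy[i])^2)
      expect_lt(min(d), 1.5)
    }
    sel <- selectCentralRing(st, c(50, 50))
    spMeas <- mean(sqrt((sel$ring$cx - sel$central$cx)^2 +
                        (sel$ring$cy - sel$central$cy)^2))
    ring <- ringFieldCenters(a, 1L, spacing = sp, center = c(50, 50))
    spTrue <- mean(sqrt(rowSums(sweep(ring[-1, ], 2, ring[1, ], "-")^2)))
    expect_equal(spMeas, spTrue, tolerance = 0.02)
  }
})

test_that("detection success peaks at intermediate thresholds", {
  wide <- idealRateMap(ringFieldCenters(arr7(), spacing = 12,
                                        center = c(50, 50)),
                       "gaussian", 6, 15)
  maps <- list(diskFixture(ringOnly = TRUE), wide)
  sw <- thresholdSweep(maps, c(0.02, 0.31, 0.5, 0.99))
  expect_equal(sw$success[sw$thresholdFrac == 0.31], 1)
  expect_lt(sw$success[sw$thresholdFrac == 0.02], 1)   # fields merge
  expect_lt(sw$success[sw$thresholdFrac == 0.99], 1)   # fields vanish
})
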