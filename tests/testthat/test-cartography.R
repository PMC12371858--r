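# small synthetic image helpers used across cartography tests
.testMeseImage <- function(t2 = c(30, 80), nr = 2, nc = 2,
                           protocol = protocolPreset("short_te",
                                                     refocusingFlipDeg = 180)) {
  te <- echoTimes(protocol)
  arr <- array(0, c(nr, nc, length(te)))
  t2map <- matrix(rep_len(t2, nr * nc), nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    arr[i, j, ] <- exp(-te / t2map[i, j])
  list(image = multiEchoImage(arr, protocol), t2 = t2map)
}

test_that("multiEchoImage validates shapes against the protocol", {
  p <- protocolPreset("short_te")
  expect_error(multiEchoImage(array(0, c(2, 2, 12)), p), "nEchoes")
  expect_error(multiEchoImage(matrix(0, 2, 2), p), "array")
  img <- multiEchoImage(array(0, c(2, 2, 13)), p)
  expect_true(all(img@mask))
  expect_equal(echoTimes(img), echoTimes(p))
})

test_that("mapVoxelwise mono_t2 recovers per-voxel T2 and respects the mask", {
  tm <- .testMeseImage(c(25, 40, 60, 90))
  maps <- mapVoxelwise(tm$image, "mono_t2")
  expect_equal(mapValues(maps$map), tm$t2, tolerance = 1e-4)
  expect_true(all(mapValid(maps$map)))
  expect_equal(mapValues(maps$s0), matrix(1, 2, 2), tolerance = 1e-4)

  # masked voxels are not fitted and come back invalid
  mask <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  img2 <- multiEchoImage(tm$image@data, tm$image@protocol, mask = mask)
  maps2 <- mapVoxelwise(img2, "mono_t2")
  expect_identical(mapValid(maps2$map), mask)
  expect_true(is.na(mapValues(maps2$map)[2, 1]))
})

test_that("mapVoxelwise biexp_tvf maps a two-compartment image", {
  p <- protocolPreset("short_te", refocusingFlipDeg = 180)
  te <- echoTimes(p)
  tvfTrue <- matrix(c(20, 40, 60, 80), 2, 2)
  arr <- array(0, c(2, 2, 13))
  for (k in 1:4) {
    f <- tvfTrue[k] / 100
    arr[(k - 1) %% 2 + 1, (k - 1) %/% 2 + 1, ] <-
      f * exp(-te / 150) + (1 - f) * exp(-te / 30)
  }
  maps <- mapVoxelwise(multiEchoImage(arr, p), "biexp_tvf")
  expect_equal(mapValues(maps$map), tvfTrue, tolerance = 1e-3)
  expect_equal(mapValues(maps$t2short), matrix(30, 2, 2), tolerance = 1e-2)
})

test_that("mapVoxelwise rejects model/protocol mismatches by name", {
  tm <- .testMeseImage()
  expect_error(mapVoxelwise(tm$image, "mono_t2star"),
               "MGEProtocol.*MESEProtocol")
  g <- protocolPreset("mge")
  teg <- echoTimes(g)
  arrg <- array(rep(exp(-teg / 12), each = 4), c(2, 2, 10))
  img <- multiEchoImage(arrg, g)
  expect_error(mapVoxelwise(img, "mono_t2"), "MESEProtocol")
  expect_error(mapVoxelwise(img, "biexp_tvf"), "MESEProtocol")
  maps <- mapVoxelwise(img, "mono_t2star")
  expect_equal(mapValues(maps$map), matrix(12, 2, 2), tolerance = 1e-4)
})

test_that("t2primeMap combines maps and excludes non-physical voxels", {
  t2 <- new("ParametricMap", values = matrix(c(50, 40, 30, 20), 2, 2),
            valid = matrix(TRUE, 2, 2), units = "ms")
  t2s <- new("ParametricMap", values = matrix(c(10, 40, 15, 25), 2, 2),
             valid = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2), units = "ms")
  out <- t2primeMap(t2, t2s)
  expect_equal(mapValues(out)[1, 1], 12.5)
  expect_equal(mapValues(out)[1, 2], 30)
  expect_true(is.na(mapValues(out)[2, 1]))  # T2* == T2 -> excluded
  expect_true(is.na(mapValues(out)[2, 2]))  # invalid input
  expect_identical(attr(out, "nExcluded"), 1L)
  # roundtrip: T2* reconstructed from T2 and T2' to 1e-9
  t2p <- mapValues(out)[1, 1]
  expect_equal(1 / (1 / t2p + 1 / 50), 10, tolerance = 1e-9)
})

test_that("roiMedian summarizes layers and returns NA for empty layers", {
  vals <- matrix(c(10, 20, 30, 40), 2, 2)
  map <- new("ParametricMap", values = vals, valid = matrix(TRUE, 2, 2),
             units = "ms")
  lab <- roiLabels(matrix(c(1L, 1L, 2L, 0L), 2, 2))
  med <- roiMedian(map, lab)
  expect_equal(med[["cortex"]], 15)
  expect_equal(med[["outer_medulla"]], 30)
  expect_true(is.na(med[["inner_medulla"]]))
  expect_error(roiMedian(map, roiLabels(matrix(0L, 3, 3))), "shapes differ")
  expect_error(roiLabels(matrix(5L, 2, 2)), "labels")
})

test_that("layerTimeCourse and intervalSummary implement the baseline logic", {
  v <- rbind(cortex = c(10, 10, 12, 14), outer_medulla = c(20, 20, 22, 18))
  tc <- layerTimeCourse(v, baselineIdx = 1:2, interval1Idx = 3L,
                        interval2Idx = 4L)
  s <- intervalSummary(tc)
  expect_equal(s$baseline_mean, c(10, 20))
  expect_equal(s$interval1_change_percent, c(20, 10))
  expect_equal(s$interval2_change_percent, c(40, -10))
  expect_error(layerTimeCourse(v, 1:2, 2:3, 4L), "disjoint")
  expect_error(layerTimeCourse(v, 1:2, 3L, 5L), "within the series")
  zero <- layerTimeCourse(rbind(a = c(0, 0, 1, 1)), 1:2, 3L, 4L)
  expect_error(intervalSummary(zero), "positive")
})
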