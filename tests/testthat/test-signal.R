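test_that("temporal derivative handles linear, constant and ends", {
  tr <- 1.05
  lin <- 3 * (0:19)
  expect_equal(temporal_derivative(lin, tr), rep(3 / tr, 20))
  expect_equal(temporal_derivative(rep(7, 10), tr), rep(0, 10))
  expect_error(temporal_derivative(1, tr), "at least 2")
})

test_that("temporal derivative tracks the analytic derivative of a sine", {
  tr <- 0.5
  f <- 0.05                      # Hz, well below Nyquist
  t <- (0:999) * tr
  x <- sin(2 * pi * f * t)
  d <- temporal_derivative(x, tr)
  analytic <- 2 * pi * f * cos(2 * pi * f * t)
  interior <- 2:999
  expect_lt(max(abs(d[interior] - analytic[interior])), 2 * pi * f * 0.01)
  expect_equal(max(abs(d)), 2 * pi * f, tolerance = 0.01)
})

test_that("trace resampling interpolates linearly and holds edges", {
  tr <- 1.05
  tt <- (0:9) * tr
  trace <- physio_trace(tt, 40 + tt, "CO2")
  expect_equal(resample_trace(trace, tr, 10L), 40 + tt)
  two <- physio_trace(c(0, 10.5), c(40, 50), "CO2")
  expect_equal(resample_trace(two, 1.05, 11L)[6], 45)  # volume 5, midpoint
  expect_equal(resample_trace(two, 1.05, 20L)[12:20], rep(50, 9))
  expect_error(physio_trace(numeric(0), numeric(0)), "empty")
  expect_error(resample_trace(list(times = numeric(0)), 1, 5), "empty")
})

test_that("physio trace invariants are enforced", {
  expect_error(physio_trace(c(0, 1, 1), c(40, 41, 42)), "increasing")
  expect_error(physio_trace(c(0, 1), c(40, -1)), "positive")
  expect_error(physio_trace(c(0, 1), c(40, Inf)), "positive")
})

test_that("bulk alignment recovers constructed shifts", {
  set.seed(5)
  x <- as.numeric(arima.sim(list(ar = 0.9), 300)) + 100
  expect_equal(bulk_align(x, x, 20L)$lag, 0L)
  # co2 is a delayed copy of the bold signal by 7 volumes
  co2 <- c(rep(x[1], 7), x[1:293])
  out <- bulk_align(x, co2, 20L)
  expect_equal(out$lag, 7L)
  expect_equal(out$co2[1:293], x[1:293])  # aligned back onto bold
  expect_error(bulk_align(rep(1, 50), rnorm(50), 10L), "constant")
  expect_error(bulk_align(rnorm(50), rnorm(50), 30L), "max_lag")
})

test_that("bulk alignment maximises correlation, not |correlation|", {
  set.seed(8)
  x <- as.numeric(arima.sim(list(ar = 0.8), 200))
  y <- -c(rep(x[1], 4), x[1:196])          # anti-correlated, delayed
  got <- bulk_align(x, y, 15L)$lag
  o <- brute_xcorr(x, y, 15L)
  expect_equal(got, o$lag)                  # sign respected: argmax of r
})

test_that("regional mean averages the requested voxels only", {
  dims <- c(4L, 4L, 3L)
  gm <- array(FALSE, dims); gm[1, 1, 1] <- gm[2, 1, 1] <- TRUE
  brain <- array(TRUE, dims)
  wm <- csf <- array(FALSE, dims)
  m <- mask_volume(brain, gm, wm, csf)
  arr <- array(0, c(dims, 2L))
  arr[1, 1, 1, ] <- c(1, 3)
  arr[2, 1, 1, ] <- c(3, 5)
  b <- bold_series(arr, 1.05)
  expect_equal(extract_regional_mean(b, m, "gm"), c(2, 4))
  # uniform signal -> constant trace
  arr2 <- array(7, c(dims, 3L))
  expect_equal(extract_regional_mean(bold_series(arr2, 1), m, "gm"),
               rep(7, 3))
  # excluding everything is an error
  m$edema <- gm
  expect_error(extract_regional_mean(b, m, "gm", exclude = "edema"),
               "empty region")
  expect_error(extract_regional_mean(b, m, "lesion"), "unknown label")
})

test_that("mask dilation uses the face-adjacent structuring element", {
  dims <- c(5L, 5L, 5L)
  e <- array(FALSE, dims); e[3, 3, 3] <- TRUE
  m <- mask_volume(array(TRUE, dims), array(FALSE, dims),
                   array(FALSE, dims), array(FALSE, dims), e)
  d1 <- dilate_mask(m, "edema", 1L)
  expect_equal(sum(d1$edema), 7L)           # centre + 6 faces
  expect_true(all(d1$edema[cbind(c(3, 2, 4, 3, 3, 3, 3),
                                 c(3, 3, 3, 2, 4, 3, 3),
                                 c(3, 3, 3, 3, 3, 2, 4))]))
  expect_identical(dilate_mask(m, "edema", 0L)$edema, m$edema)
  empty <- m; empty$edema <- array(FALSE, dims)
  expect_equal(sum(dilate_mask(empty, "edema", 2L)$edema), 0L)
  expect_error(dilate_mask(m, "tumour", 1L), "unknown label")
  # dilation at the boundary stays inside the array
  e2 <- array(FALSE, dims); e2[1, 1, 1] <- TRUE
  m$edema <- e2
  expect_equal(sum(dilate_mask(m, "edema", 1L)$edema), 4L)
})
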