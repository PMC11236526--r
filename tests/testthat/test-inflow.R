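test_that("skew-normal model reduces to known special cases", {
  # alpha = 0: scaled Gaussian with peak amplitude/(omega sqrt(2 pi)) at xi
  expect_equal(skew_normal_model(50, 10, 50, 8, 0),
               10 / (8 * sqrt(2 * pi)))
  # symmetry about xi when alpha = 0
  tt <- seq(-20, 20, by = 0.5)
  v <- skew_normal_model(50 + tt, 3, 50, 6, 0)
  expect_equal(v, rev(v))
  # amplitude 0: pure line
  expect_equal(skew_normal_model(c(0, 10), 0, 5, 2, 3, a = 1, b = 0.5),
               c(1, 6))
  expect_error(skew_normal_model(0, 1, 0, -1, 0), "omega")
})

test_that("right HWHM has the Gaussian closed form at alpha = 0", {
  for (om in c(5, 15, 30)) {
    got <- hwhm_right(list(amplitude = 2, xi = 100, omega = om, alpha = 0))
    expect_equal(got, om * sqrt(2 * log(2)), tolerance = 1e-3)
  }
})

test_that("right HWHM agrees with a dense-grid oracle for skewed peaks", {
  set.seed(42)
  for (i in 1:12) {
    om <- runif(1, 3, 30)
    al <- runif(1, -4, 6)
    got <- hwhm_right(list(amplitude = 1, xi = 0, omega = om, alpha = al))
    expect_equal(got, dense_hwhm(om, al), tolerance = 1e-3)
  }
})

test_that("right HWHM is scale-equivariant and asymmetric under skew", {
  h1 <- hwhm_right(list(amplitude = 1, xi = 0, omega = 10, alpha = 1.5))
  h2 <- hwhm_right(list(amplitude = 1, xi = 0, omega = 20, alpha = 1.5))
  expect_equal(h2, 2 * h1, tolerance = 1e-6)
  # right-skewed peaks have a wider right than left half-width (the left
  # half-width is the right one of the mirrored, alpha-negated density)
  right <- hwhm_right(list(amplitude = 1, xi = 0, omega = 10, alpha = 2))
  left <- hwhm_right(list(amplitude = 1, xi = 0, omega = 10, alpha = -2))
  expect_gt(right, left)
  # at fixed omega skewing narrows the peak relative to the Gaussian case
  g <- 10 * sqrt(2 * log(2))
  expect_lt(right, g)
  expect_error(hwhm_right(list(amplitude = 0, xi = 0, omega = 1,
                               alpha = 0)), "amplitude")
})

test_that("noiseless skew-normal peaks are recovered to within 1%", {
  tr <- 1.05
  tt <- (0:299) * tr
  for (al in c(-2, 0, 2)) {
    for (om in c(5, 15, 30)) {
      y <- skew_normal_model(tt, amplitude = 60, xi = 150, omega = om,
                             alpha = al, a = 5, b = 0.01)
      fit <- fit_inflow_peak(y, tr = tr, window = c(0, 299))
      expect_equal(fit$amplitude, 60, tolerance = 0.01)
      expect_equal(fit$xi, 150, tolerance = 0.01 * 150)
      expect_equal(fit$omega, om, tolerance = 0.01)
      expect_equal(fit$alpha, al, tolerance = max(0.01 * abs(al), 0.02))
      expect_equal(fit$a, 5, tolerance = 0.05)
    }
  }
})

test_that("a pure line yields a vanishing peak", {
  tr <- 1.05
  tt <- (0:199) * tr
  y <- 2 + 0.05 * tt
  fit <- fit_inflow_peak(y, tr = tr, window = c(0, 199))
  peak_h <- max(predict(fit, component = "peak"))
  expect_lt(peak_h, 0.05 * diff(range(y)) + 1e-6)
  expect_equal(fit$b, 0.05, tolerance = 0.02)
})

test_that("the baseline never leaks into the HWHM", {
  tr <- 1.05
  tt <- (0:299) * tr
  base0 <- fit_inflow_peak(
    skew_normal_model(tt, 60, 150, 12, 2), tr = tr, window = c(0, 299))
  with_base <- fit_inflow_peak(
    skew_normal_model(tt, 60, 150, 12, 2, a = 30, b = -0.04),
    tr = tr, window = c(0, 299))
  expect_equal(with_base$hwhm_right, base0$hwhm_right, tolerance = 1e-4)
})

test_that("fit window preconditions are enforced", {
  expect_error(fit_inflow_peak(rnorm(100), tr = 1, window = c(0, 4)),
               "at least 7")
  expect_error(fit_inflow_peak(rnorm(100), window = c(0, 99)), "tr")
})

test_that("inflow_fit methods are coherent", {
  tr <- 1.05
  tt <- (0:299) * tr
  y <- skew_normal_model(tt, 60, 150, 12, 1.5, a = 8, b = 0.01) +
    rnorm(300, sd = 0.02)
  fit <- fit_inflow_peak(y, tr = tr, window = c(0, 299))
  expect_named(coef(fit), c("amplitude", "xi", "omega", "alpha", "a", "b"))
  expect_equal(fitted(fit) + residuals(fit), fit$data$y)
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-9)
  expect_output(print(fit), "HWHM")
  expect_output(print(summary(fit)), "skew-normal")
})

test_that("inflow voxels are selected by contrast in the bottom slices", {
  set.seed(9)
  dims <- c(6L, 6L, 4L)
  n <- 64L
  arr <- array(rnorm(prod(dims) * n, sd = 0.01), c(dims, n))
  peak <- exp(-((1:n) - 32)^2 / 18)
  # one strong inflow voxel in slice 1, a weaker one in slice 2
  arr[2, 3, 1, ] <- arr[2, 3, 1, ] + 10 * peak
  arr[5, 5, 2, ] <- arr[5, 5, 2, ] + 6 * peak
  b <- bold_series(arr, 1.05)
  sel <- select_inflow_voxels(b, n_bottom_slices = 2L, k_voxels = 1L,
                              denoise = FALSE)
  expect_equal(sel$voxels$x, c(2, 5))
  expect_equal(sel$voxels$y, c(3, 5))
  # final trace is the average of the two per-slice traces
  expect_equal(sel$trace, rowMeans(sel$per_slice))
  expect_equal(max(sel$trace), 8, tolerance = 0.2)
})

test_that("contrast ties break deterministically and k is clipped", {
  dims <- c(3L, 3L, 2L)
  arr <- array(1, c(dims, 16L))       # all-flat: every contrast ties at 0
  b <- bold_series(arr, 1)
  sel <- select_inflow_voxels(b, n_bottom_slices = 1L, k_voxels = 2L,
                              denoise = FALSE)
  expect_equal(sel$voxels[, c("x", "y")],
               data.frame(x = c(1, 2), y = c(1, 1)))
  expect_warning(
    select_inflow_voxels(b, n_bottom_slices = 1L, k_voxels = 99L,
                         denoise = FALSE),
    "clipping")
  expect_error(select_inflow_voxels(bold_series(rnorm(50), 1)), "4-D")
})
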