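test_that("exponential convolution behaves as a unit-gain low-pass", {
  tr <- 1.05
  # constant input passes through (steady state)
  out <- convolve_exponential(rep(3, 500), 20, tr)
  expect_equal(out[300:500], rep(3, 201), tolerance = 1e-6)
  # tau much smaller than TR: kernel is effectively a delta
  x <- sin((1:200) / 10)
  expect_equal(convolve_exponential(x, 0.01, tr), x, tolerance = 1e-6)
  # first-order step response: 1 - exp(-1) of the plateau at t = tau
  step <- c(rep(0, 100), rep(10, 400))
  y <- convolve_exponential(step, 21, tr)   # tau = 20 TRs exactly
  expect_equal(y[100 + 20], 10 * (1 - exp(-1)), tolerance = 0.03)
  expect_error(convolve_exponential(x, 0, tr), "tau")
  expect_error(convolve_exponential(x, -3, tr), "tau")
})

test_that("tau grid fit matches an independent per-tau OLS oracle", {
  sim <- compact_sim(tau_true = 15, noise_sd = 0.3, seed = 2)
  fit <- fit_tau(sim$bold, sim$co2, window = compact_window,
                 tau_grid = compact_grid)
  # oracle: lm() on the public convolution, evaluated on a grid subset
  win <- (compact_window[1]:compact_window[2]) + 1L
  for (tau in c(5, 15, 40)) {
    reg <- convolve_exponential(sim$co2, tau, sim$proto$tr)[win]
    rss_lm <- sum(residuals(lm(sim$bold$data[win] ~ reg))^2)
    expect_equal(fit$rss_grid[which(compact_grid == tau)], rss_lm,
                 tolerance = 1e-8)
  }
  # the reported tau attains the grid minimum
  expect_equal(fit$rss, min(fit$rss_grid))
  expect_equal(fit$tau, fit$tau_grid[which.min(fit$rss_grid)])
})

test_that("noiseless forward-model round trip recovers tau exactly", {
  for (tau in c(5, 20, 45)) {
    sim <- compact_sim(tau_true = tau, noise_sd = 0)
    fit <- fit_tau(sim$bold, sim$co2, window = compact_window,
                   tau_grid = compact_grid)
    expect_equal(fit$tau, tau)
    expect_lt(fit$rss, 1e-6)
    expect_equal(fit$beta1, sim$pars$cvr_amplitude, tolerance = 1e-4)
  }
})

test_that("an exactly linear-in-regressor signal gives zero rss", {
  sim <- compact_sim(tau_true = 10, noise_sd = 0)
  reg <- convolve_exponential(sim$co2, 25, sim$proto$tr)
  y <- 4 + 0.7 * reg
  fit <- fit_tau(y, sim$co2, tr = sim$proto$tr, window = compact_window,
                 tau_grid = compact_grid)
  expect_equal(fit$tau, 25)
  expect_lt(fit$rss, 1e-10)
  expect_equal(fit$beta0, 4, tolerance = 1e-5)
  expect_equal(fit$beta1, 0.7, tolerance = 1e-6)
})

test_that("rss ties break toward the smaller tau", {
  # pure-noise signal uncorrelated with the regressor: grid search must
  # still return a unique, reproducible answer; equal-rss ties go low
  y <- rep(c(1, 2), 100)
  co2 <- rep(5, 200)
  expect_error(fit_tau(y, co2, tr = 1, window = c(10, 150),
                       tau_grid = c(1, 2)), "constant")
})

test_that("fit window and grid are validated", {
  sim <- compact_sim(tau_true = 10)
  expect_error(fit_tau(sim$bold, sim$co2, window = c(100, 600),
                       tau_grid = compact_grid), "window")
  expect_error(fit_tau(sim$bold, sim$co2, window = c(60, 240),
                       tau_grid = numeric(0)), "tau_grid")
  expect_error(fit_tau(sim$bold, sim$co2, window = c(60, 240),
                       tau_grid = c(-1, 5)), "tau_grid")
  expect_error(fit_tau(sim$bold$data, sim$co2, window = c(60, 240)),
               "tr")
})

test_that("tau_fit methods are coherent", {
  sim <- compact_sim(tau_true = 18, noise_sd = 0.2, seed = 4)
  fit <- fit_tau(sim$bold, sim$co2, window = compact_window,
                 tau_grid = compact_grid)
  cf <- coef(fit)
  expect_named(cf, c("tau", "beta0", "beta1"))
  expect_equal(unname(cf["tau"]), fit$tau)
  expect_length(fitted(fit), diff(compact_window) + 1L)
  expect_equal(fitted(fit) + residuals(fit), fit$data$y)
  # whole-series prediction from the fitted model
  pred <- predict(fit, newdata = sim$co2)
  expect_length(pred, sim$proto$n_volumes)
  win <- (compact_window[1]:compact_window[2]) + 1L
  expect_equal(pred[win], fitted(fit), tolerance = 1e-9)
  s <- summary(fit)
  expect_s3_class(s, "summary.tau_fit")
  expect_gt(s$r_squared, 0.9)
  expect_output(print(fit), "tau")
  expect_output(print(s), "CVR")
})

test_that("parabolic refinement can leave the grid and never hurts", {
  sim <- compact_sim(tau_true = 17.4, noise_sd = 0)
  coarse <- seq(2, 60, by = 4)
  f0 <- fit_tau(sim$bold, sim$co2, window = compact_window,
                tau_grid = coarse)
  f1 <- fit_tau(sim$bold, sim$co2, window = compact_window,
                tau_grid = coarse, refine = TRUE)
  expect_lte(f1$rss, f0$rss)
  expect_lt(abs(f1$tau - 17.4), abs(f0$tau - 17.4) + 1e-9)
})

test_that("tau estimation error grows with the noise level", {
  taus <- sapply(c(0.2, 1, 4), function(sd_) {
    errs <- sapply(1:12, function(s) {
      sim <- compact_sim(tau_true = 20, noise_sd = sd_, seed = 100 + s)
      abs(fit_tau(sim$bold, sim$co2, window = compact_window,
                  tau_grid = compact_grid)$tau - 20)
    })
    median(errs)
  })
  expect_true(all(diff(taus) >= 0))
})
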