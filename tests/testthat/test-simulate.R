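test_that("noiseless BOLD reaches the conserved plateau level", {
  proto <- compact_protocol()
  trc <- render_traces(proto, transition_time = 0)
  pars <- forward_model_params(tau_true = 5, cvr_amplitude = 0.3,
                               noise_sd = 0)
  b <- simulate_bold(trc$co2, pars, proto)
  # block is 63-123 s; by its end the plateau is fully developed
  plateau_vol <- round(118 / proto$tr)
  expect_equal(b$data[plateau_vol] - pars$bold_baseline,
               0.3 * 10, tolerance = 0.01)
  # baseline before the challenge stays at s0
  expect_equal(b$data[1:50], rep(pars$bold_baseline, 50), tolerance = 1e-9)
})

test_that("tau to zero degenerates to a scaled copy of the CO2 input", {
  proto <- compact_protocol()
  trc <- render_traces(proto, transition_time = 0)
  pars <- forward_model_params(tau_true = 1e-4, cvr_amplitude = 0.2,
                               noise_sd = 0)
  b <- simulate_bold(trc$co2, pars, proto)
  dco2 <- resample_trace(trc$co2, proto$tr, proto$n_volumes) - 40
  expect_equal(b$data - 100, 0.2 * dco2, tolerance = 1e-6)
})

test_that("simulation is bit-identical under a fixed seed", {
  proto <- compact_protocol()
  trc <- render_traces(proto)
  pars <- forward_model_params(noise_sd = 0.5, seed = 33)
  b1 <- simulate_bold(trc$co2, pars, proto)
  b2 <- simulate_bold(trc$co2, pars, proto)
  expect_identical(b1$data, b2$data)
  i1 <- simulate_csf_inflow(b1, pars)
  i2 <- simulate_csf_inflow(b2, pars)
  expect_identical(i1$data, i2$data)
})

test_that("inflow responds only to falling BOLD", {
  pars <- forward_model_params(noise_sd = 0)
  # constant BOLD: baseline only
  flat <- bold_series(rep(100, 200), 1.05)
  expect_equal(simulate_csf_inflow(flat, pars)$data,
               rep(pars$inflow_baseline, 200))
  # monotonically increasing BOLD: rectified term identically zero
  up <- bold_series(100 + cumsum(runif(200, 0.1, 0.5)), 1.05)
  expect_equal(simulate_csf_inflow(up, pars)$data,
               rep(pars$inflow_baseline, 200))
  # nonnegativity: inflow never dips below baseline
  proto <- compact_protocol()
  trc <- render_traces(proto)
  b <- simulate_bold(trc$co2, pars, proto)
  infl <- simulate_csf_inflow(b, pars)
  expect_true(all(infl$data >= pars$inflow_baseline - 1e-12))
})

test_that("hyperoxia with zero vasoactivity produces no inflow", {
  proto <- default_protocol(n_volumes = 900L)
  trc <- render_traces(proto)
  pars <- forward_model_params(tau_true = 20, noise_sd = 0,
                               o2_amplitude = 0)
  b <- simulate_bold(trc$co2, pars, proto, o2 = trc$o2)
  infl <- simulate_csf_inflow(b, pars, noiseless = TRUE)
  ep <- protocol_epochs(proto)
  hyper <- ep[ep$kind == "hyperoxic_block", ]
  hv <- (floor(hyper$start_volume):(ceiling(hyper$end_volume) + 20)) + 1L
  hv <- hv[hv <= length(infl$data)]
  expect_lt(max(infl$data[hv]) - pars$inflow_baseline,
            0.01 * max(infl$data - pars$inflow_baseline))
})

test_that("the noiseless inflow peak never precedes the CBV-change peak", {
  proto <- compact_protocol()
  trc <- render_traces(proto)
  pars <- forward_model_params(tau_true = 15, noise_sd = 0)
  b <- simulate_bold(trc$co2, pars, proto)
  infl <- simulate_csf_inflow(b, pars, noiseless = TRUE)
  w <- inflow_window_from_protocol(proto)
  wi <- (w[1]:w[2]) + 1L
  d <- temporal_derivative(b$data, proto$tr)
  expect_gte(which.max(infl$data[wi]), which.min(d[wi]))
})

test_that("skew warp stretches the falling flank proportionally", {
  proto <- compact_protocol()
  trc <- render_traces(proto)
  b <- simulate_bold(trc$co2,
                     forward_model_params(tau_true = 15, noise_sd = 0),
                     proto)
  h0 <- true_inflow_hwhm(b, forward_model_params(tau_true = 15,
                                                 inflow_skew = 0))
  h1 <- true_inflow_hwhm(b, forward_model_params(tau_true = 15,
                                                 inflow_skew = 1))
  expect_equal(h1 / h0, 2, tolerance = 0.01)
})

test_that("synthetic masks hit the requested edema load", {
  m <- simulate_masks(c(20L, 20L, 12L), edema_fraction_target = 0.05,
                      seed = 5)
  nb <- sum(m$brain)
  expect_equal(sum(m$edema), round(0.05 * nb))
  expect_lte(abs(edema_fraction(m) - 0.05), 1 / nb)
  # determinism and the empty case
  m2 <- simulate_masks(c(20L, 20L, 12L), 0.05, seed = 5)
  expect_identical(m$edema, m2$edema)
  m0 <- simulate_masks(c(10L, 10L, 6L), 0, seed = 1)
  expect_equal(sum(m0$edema), 0L)
  expect_error(simulate_masks(c(10L, 10L, 6L), 1), "edema_fraction")
  # tissue partition stays inside the brain
  expect_true(all(m$gm | m$wm | m$csf | !m$brain))
  expect_false(any((m$gm & m$wm) | (m$gm & m$csf) | (m$wm & m$csf)))
})

test_that("full dataset assembly is consistent and deterministic", {
  proto <- compact_protocol()
  pars <- forward_model_params(tau_true = 15, noise_sd = 0.2, seed = 21)
  ds <- simulate_dataset(proto, pars, shape = c(10L, 10L, 4L),
                         edema_fraction_target = 0.04)
  expect_s3_class(ds, "csf_dataset")
  expect_equal(dim(ds$bold$data)[4], proto$n_volumes)
  expect_equal(ds$bold$n_volumes, proto$n_volumes)
  expect_lte(abs(ds$truth$edema_fraction - 0.04), 1 / sum(ds$masks$brain))
  expect_true(is.finite(ds$truth$hwhm_right))
  ds2 <- simulate_dataset(proto, pars, shape = c(10L, 10L, 4L),
                          edema_fraction_target = 0.04)
  expect_identical(ds$bold$data, ds2$bold$data)
})
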