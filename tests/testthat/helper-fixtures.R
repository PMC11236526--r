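# Shared fixtures: a compact gas-challenge protocol (shorter epochs, fewer
# volumes) keeps grid-search fits cheap in unit tests; the acceptance suite
# uses the full-scale defaults.

compact_protocol <- function(n_volumes = 400L, tr = 1.05) {
  default_protocol(lead_baseline = 63, block_duration = 60,
                   ramp_duration = 60, hyperoxia_duration = 60,
                   interleave_baseline = 60,
                   n_volumes = n_volumes, tr = tr)
}

compact_grid <- seq(1, 60, by = 1)
compact_window <- c(60L, 240L)   # block offset + decay + ramp onset

compact_sim <- function(tau_true, noise_sd = 0, seed = 1L,
                        proto = compact_protocol(), transition_time = 10,
                        cvr_amplitude = 0.2) {
  trc <- render_traces(proto, transition_time = transition_time)
  pars <- forward_model_params(tau_true = tau_true, noise_sd = noise_sd,
                               cvr_amplitude = cvr_amplitude, seed = seed)
  bold <- simulate_bold(trc$co2, pars, proto)
  list(bold = bold,
       co2 = resample_trace(trc$co2, proto$tr, proto$n_volumes),
       proto = proto, pars = pars, traces = trc)
}

# brute-force shifted-correlation oracle, written independently of the
# package's search: correlation of x[t] with y[t + k] over the overlap
brute_xcorr <- function(x, y, max_lag_vol) {
  n <- length(x)
  ks <- -max_lag_vol:max_lag_vol
  r <- sapply(ks, function(k) {
    if (k >= 0) suppressWarnings(cor(x[1:(n - k)], y[(1 + k):n]))
    else suppressWarnings(cor(x[(1 - k):n], y[1:(n + k)]))
  })
  r[is.na(r)] <- -Inf
  best <- which(r == max(r))
  best <- best[which.min(abs(ks[best]))]
  list(lag = ks[best], r = r[best])
}

# dense-grid oracle for the right-sided HWHM of the skew-normal component;
# the half-height crossing is linearly interpolated between grid points so
# the oracle resolves well below the grid step
dense_hwhm <- function(omega, alpha, xi = 0, amplitude = 1,
                       n_grid = 2e6) {
  tt <- seq(xi - 4 * omega, xi + 8 * omega, length.out = n_grid)
  f <- amplitude * (2 / omega) * dnorm((tt - xi) / omega) *
    pnorm(alpha * (tt - xi) / omega)
  ip <- which.max(f)
  half <- f[ip] / 2
  below <- ip + which(f[(ip + 1):length(f)] <= half)[1]
  frac <- (f[below - 1] - half) / (f[below - 1] - f[below])
  t_half <- tt[below - 1] + frac * (tt[below] - tt[below - 1])
  t_half - tt[ip]
}
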