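test_that("adaptive cycle count ramps linearly from 3 to 10", {
  expect_equal(cycles_for_frequency(1), 3)
  expect_equal(cycles_for_frequency(25), 10)
  expect_equal(cycles_for_frequency(13), 6.5)
  expect_error(cycles_for_frequency(0.5), "\\[1, 25\\]")
  expect_error(cycles_for_frequency(30), "\\[1, 25\\]")
})

test_that("wavelet family has the right widths, peaks and spectra", {
  fam <- build_wavelets(1:25, 125)
  # sigma = s / (2 pi f), hand-evaluated at 4 Hz where s = 3.875
  expect_equal(fam$sigma[4], 3.875 / (2 * pi * 4), tolerance = 1e-12)
  # Gaussian peak at t = 0 has unit modulus before normalization
  for (fi in c(1, 6, 25)) {
    k <- fam$kernels[[fi]]
    expect_equal(Mod(k[(length(k) + 1) / 2]), 1, tolerance = 1e-12)
    # support covers at least +/- 3 sigma
    expect_gte(max(fam$t[[fi]]), 3 * fam$sigma[fi] - 1e-9)
  }
  # spectral peak of each sampled kernel is at its nominal frequency
  for (fi in c(2, 6, 12)) {
    k <- fam$kernels[[fi]]
    n <- 4096
    spec <- Mod(fft(c(k, rep(0, n - length(k)))))^2
    fgrid <- (0:(n - 1)) * 125 / n
    expect_equal(fgrid[which.max(spec[fgrid <= 62.5])], fam$frequencies[fi],
                 tolerance = 0.2)
  }
  expect_error(build_wavelets(1:25, 40), "Nyquist")
  expect_error(build_wavelets(c(2, 2, 3), 125), "increasing")
})

test_that("convolution is linear and localizes a pure sinusoid in frequency", {
  ep <- sine_epochs(function(t, tr) sin(2 * pi * 6 * t),
                    t_start = -2000, t_end = 2000)
  fam <- build_wavelets(1:12, 125)
  co <- convolve_epochs(ep, fam)
  pw <- Re(co$coef)^2 + Im(co$coef)^2
  mid <- pw[1, , co$valid & co$times > -200 & co$times < 700, 1]
  band_power <- rowMeans(mid)
  expect_equal(which.max(band_power), 6)
  for (f in seq_along(band_power)) {
    if (abs(f - 6) >= 2) expect_gt(band_power[6], band_power[f])
  }

  # zero input -> zero coefficients; doubling the input doubles |z|
  ep0 <- sine_epochs(function(t, tr) 0 * t, t_start = -2000, t_end = 2000)
  expect_true(all(Mod(convolve_epochs(ep0, fam)$coef) == 0))
  ep2 <- sine_epochs(function(t, tr) 2 * sin(2 * pi * 6 * t),
                     t_start = -2000, t_end = 2000)
  co2 <- convolve_epochs(ep2, fam)
  expect_equal(Mod(co2$coef), 2 * Mod(co$coef), tolerance = 1e-10)
})

test_that("convolution errors name the offending condition", {
  short <- sine_epochs(function(t, tr) sin(2 * pi * 6 * t),
                       t_start = 0, t_end = 400)
  fam <- build_wavelets(1:25, 125)
  expect_error(convolve_epochs(short, fam), "1 Hz")
  ep <- sine_epochs(function(t, tr) sin(2 * pi * 6 * t))
  expect_error(convolve_epochs(ep, fam, channels = "Oz"), "Oz")
})

test_that("wavelet power agrees with a discrete-Fourier oracle on a long sinusoid", {
  fs <- 125
  ep <- sine_epochs(function(t, tr) 3 * sin(2 * pi * 6 * t),
                    t_start = -4000, t_end = 4000)
  fam <- build_wavelets(4:8, fs)
  co <- convolve_epochs(ep, fam)
  mid <- co$valid & abs(co$times) < 2000
  # steady-state wavelet power at the matching bin
  w_pow <- mean(Re(co$coef[1, 3, mid, 1])^2 + Im(co$coef[1, 3, mid, 1])^2)
  # oracle: analytic steady-state response of the truncated Morlet kernel to
  # a unit sinusoid is |K(f0)| / 2 in amplitude, via the DFT of the kernel
  k <- fam$kernels[[3]]
  n <- 2^15
  K <- fft(c(k, rep(0, n - length(k))))
  fgrid <- (0:(n - 1)) * fs / n
  K6 <- Mod(K[which.min(abs(fgrid - 6))])
  oracle <- (3 * K6 / 2)^2
  expect_equal(w_pow, oracle, tolerance = 0.05 * oracle)
})

test_that("ERSP reproduces dB ratios and is scale invariant", {
  # amplitude 1 in the baseline, 2 after +100 ms: 20*log10(2) ~ 6.02 dB
  step2 <- function(t, tr) ifelse(t > 0.1, 2, 1) * sin(2 * pi * 6 * t)
  ep <- sine_epochs(step2)
  fam <- build_wavelets(4:8, 125)
  co <- convolve_epochs(ep, fam)
  e <- ersp(co)
  sel <- co$times >= 250 & co$times <= 450
  expect_equal(mean(e$db[1, 3, sel]), 20 * log10(2), tolerance = 0.5)

  # power ratio 10 -> 10 dB
  step10 <- function(t, tr) ifelse(t > 0.1, sqrt(10), 1) * sin(2 * pi * 6 * t)
  e10 <- ersp(convolve_epochs(sine_epochs(step10), fam))
  expect_equal(mean(e10$db[1, 3, sel]), 10, tolerance = 0.5)

  # stationary signal -> ~0 dB everywhere valid
  flat <- ersp(convolve_epochs(sine_epochs(function(t, tr)
    sin(2 * pi * 6 * t)), fam))
  expect_lt(max(abs(flat$db[1, 3, flat$valid])), 0.2)

  # global positive rescaling cancels in the baseline ratio
  e_scaled <- ersp(convolve_epochs(sine_epochs(function(t, tr)
    7 * step2(t, tr)), fam))
  expect_equal(e_scaled$db, e$db, tolerance = 1e-9)

  expect_error(ersp(convolve_epochs(sine_epochs(function(t, tr) 0 * t), fam)),
               "baseline power")
})

test_that("ITC spans identical, antiphase and uniform-phase regimes", {
  fam <- build_wavelets(4:8, 125)
  # identical trials -> ITC = 1 everywhere
  ep_id <- sine_epochs(function(t, tr) sin(2 * pi * 6 * t), n_trials = 5)
  it <- itc(convolve_epochs(ep_id, fam))
  expect_equal(max(abs(it$itc - 1)), 0, tolerance = 1e-9)
  expect_true(all(it$itc >= 0 & it$itc <= 1))

  # two trials in antiphase -> phasors cancel
  ep_anti <- sine_epochs(function(t, tr)
    sin(2 * pi * 6 * t + (tr - 1) * pi), n_trials = 2)
  it2 <- itc(convolve_epochs(ep_anti, fam))
  expect_lt(max(it2$itc[1, 3, it2$valid]), 1e-6)

  # uniform random phases: E[ITC] ~ sqrt(pi) / (2 sqrt(n)); white-noise
  # trials give independent uniform phases at well-separated time cells, so
  # averaging over cells is a Monte-Carlo mean of the resultant length
  n <- 16
  set.seed(99)
  ep_u <- sine_epochs(function(t, tr) rnorm(length(t)), n_trials = n,
                      t_start = -4000, t_end = 4000)
  it3 <- itc(convolve_epochs(ep_u, fam))
  mean_itc <- mean(it3$itc[1, , it3$valid])
  expect_equal(mean_itc, sqrt(pi) / (2 * sqrt(n)), tolerance = 0.1)

  # ITC invariant to positive per-trial rescaling
  ep_sc <- ep_u
  for (tr in seq_len(n)) ep_sc$data[, , tr] <- tr * ep_u$data[, , tr]
  it4 <- itc(convolve_epochs(ep_sc, fam))
  expect_equal(it4$itc, it3$itc, tolerance = 1e-9)
})

test_that("high phase jitter drives burst-window ITC to the uniform floor", {
  cfg <- small_config(
    n_trials = 40,
    burst = list(amplitude_control = 1, amplitude_target = 1,
                 phase_jitter_control = 50, phase_jitter_target = 50,
                 subject_amp_sd = 0),
    noise = list(amplitude = 0))
  sub <- generate_subject(cfg, 1)
  fam <- build_wavelets(4:8, 125)
  co <- convolve_epochs(sub$epochs[["conflict.control"]], fam,
                        channels = "FCz")
  it <- itc(co)
  sel <- co$times >= 250 & co$times <= 400
  expect_lt(mean(it$itc[1, 3, sel]), 2 * sqrt(pi / (4 * 40)))
})

test_that("subsampling equalizes the eight conditions at the minimum count", {
  cfg <- small_config()
  # emulate heterogeneous rounded condition means
  tc <- cfg$trial_counts
  tc$mean <- c(286, 68, 267, 20, 165, 33, 114, 101); tc$sd <- 0
  cfg$trial_counts <- tc
  cfg$epoch_window <- c(-1200, 1500)
  sub <- generate_subject(cfg, 1)
  expect_equal(min_condition_count(sub$epochs), 20L)
  eq <- subsample_equalize(sub$epochs, seed = 4L)
  expect_true(all(vapply(eq, n_trials, integer(1)) == 20L))
  # determinism of the draw
  eq2 <- subsample_equalize(sub$epochs, seed = 4L)
  expect_identical(eq[["proactive.control"]]$data,
                   eq2[["proactive.control"]]$data)
  # already equal counts pass through unchanged
  cfg2 <- small_config(n_trials = 15)
  sub2 <- generate_subject(cfg2, 1)
  eq3 <- subsample_equalize(sub2$epochs, seed = 1L)
  expect_identical(eq3[["reactive.target"]]$data,
                   sub2$epochs[["reactive.target"]]$data)
})

test_that("conditions below the inclusion floor flag the subject", {
  cfg <- small_config(n_trials = 12)
  sub <- generate_subject(cfg, 1)
  sub$epochs[["reactive.target"]]$data <-
    sub$epochs[["reactive.target"]]$data[, , 1:6, drop = FALSE]
  expect_error(subsample_equalize(sub$epochs), "inclusion floor")
})
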