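test_that("spectral peaks are located and measured correctly", {
  tt <- seq_len(3000)
  # a pure 100 Hz line: one peak, window-limited half-width (~1.44/T Hz)
  pk <- fft_peaks(sin(2 * pi * 100 * tt / 1000))
  expect_equal(nrow(pk$peaks), 1)
  expect_equal(pk$peaks$freq_hz, 100, tolerance = 1 / 3)
  expect_equal(pk$peaks$half_width_hz, 0.48, tolerance = 0.1)
  # two tones resolve into two peaks
  pk2 <- fft_peaks(sin(2 * pi * 40 * tt / 1000) +
                     0.5 * sin(2 * pi * 250.5 * tt / 1000))
  expect_equal(sort(pk2$peaks$freq_hz), c(40, 250.5), tolerance = 0.2)
  # all-zero signal: empty peak set, not an error
  pk0 <- fft_peaks(numeric(2000))
  expect_equal(nrow(pk0$peaks), 0)
  expect_error(fft_peaks(1), "short")
})

test_that("pulse-train drive produces a harmonic comb, sinusoidal drive does not", {
  p <- waking_params()
  sh <- c(100, 100)
  el <- electrode(c(60, 50), 2.5, id = "eeg")
  n_harm <- function(stim) {
    run <- run_model(sh, p, 3000, stim, electrodes = list(el))
    pk <- fft_peaks(run$recordings[, 1])
    sum(vapply(seq(14, 490, by = 7), function(h)
      any(abs(pk$peaks$freq_hz - h) < 0.5), TRUE))
  }
  h_pulse <- n_harm(make_pulse_train(7, 3000, node = c(20, 50), amplitude = 5))
  h_sine <- n_harm(make_sinusoid(7, 3000, node = c(20, 50), amplitude = 5))
  expect_gte(h_pulse, 20)
  expect_lte(h_sine, h_pulse / 2)
})

test_that("the STFT tracks stationary tones and chirps", {
  tt <- seq_len(2000)
  s <- stft(sin(2 * pi * 150 * tt / 1000))
  ridge <- s$f[apply(s$power, 2, which.max)]
  expect_true(all(abs(ridge - 150) < 8))
  # a rising chirp produces a monotone ridge trajectory
  f_inst <- 50 + 0.15 * tt
  chirp <- sin(2 * pi * cumsum(f_inst) / 1000)
  sc <- stft(chirp)
  ridge_c <- sc$f[apply(sc$power, 2, which.max)]
  expect_gt(stats::cor(ridge_c, seq_along(ridge_c)), 0.95)
  expect_error(stft(numeric(50), window = 128), "window")
})

test_that("coherence behaves like a magnitude-squared coherence estimator", {
  set.seed(23)
  x <- rnorm(4000)
  # identical recordings: coherence 1 at every frequency
  cc <- coherence(x, x)
  expect_true(all(cc$coherence > 1 - 1e-10))
  expect_true(all(cc$coherence <= 1 + 1e-12))
  # independent noise: mean coherence near the 1/n_segments estimator bias
  c0 <- coherence(rnorm(16000), rnorm(16000))
  expect_equal(mean(c0$coherence), 1 / attr(c0, "n_segments"),
               tolerance = 0.5)
  expect_error(coherence(rnorm(10), rnorm(12)), "length")
  expect_error(coherence(rnorm(100), rnorm(100), window = 100), "segments")
})

test_that("model coherence declines with distance and a tone restores it", {
  p <- waking_params()
  sh <- c(80, 80)
  base <- c(8, 40)
  els <- c(list(electrode(base, 0.25, id = "base")),
           lapply(c(0.5, 8, 32), function(d)
             electrode(base + c(d / 0.5, 0), 0.25, id = sprintf("d%g", d))))
  noise <- make_noise(sd = 0.5, seed = 3, n_steps = 4000)
  rn <- run_model(sh, p, 4000, noise, electrodes = els)
  band_mean <- function(i, lo, hi) {
    cc <- coherence(rn$recordings[, 1], rn$recordings[, i])
    mean(cc$coherence[cc$freq_hz >= lo & cc$freq_hz <= hi])
  }
  # decline with distance (low band) and with frequency (far pair)
  lo_by_dist <- vapply(2:4, band_mean, 0, lo = 4, hi = 40)
  expect_lt(lo_by_dist[3], lo_by_dist[1])
  expect_lt(band_mean(4, 200, 400), band_mean(4, 4, 40) + 0.05)
  # adding a 100 Hz sinusoid restores coherence at 100 Hz across 32 mm
  rr <- run_model(sh, p, 4000,
                  stimulus_combine(noise, make_sinusoid(100, 4000,
                                                        node = c(40, 40),
                                                        amplitude = 100)),
                  electrodes = els)
  at100 <- function(run, i) {
    cc <- coherence(run$recordings[, 1], run$recordings[, i])
    cc$coherence[which.min(abs(cc$freq_hz - 100))]
  }
  expect_gt(at100(rr, 4), 0.7)
  expect_gt(at100(rr, 4), at100(rn, 4) + 0.3)
})

test_that("wave speed is measured from first arrival and grows with coupling", {
  speeds <- vapply(c(0.7, 1.4, 2.6), function(c2) {
    p <- model_params(c2 = c2, f = 0.01, g = 1e-4, neighborhood = "moore-8",
                      boundary = "torus")
    wave_speed(p, shape = c(220, 20), source = c(10, 10),
               probe = c(110, 10), n_steps = 1500)$speed_mm_per_ms
  }, 0)
  expect_true(all(diff(speeds) > 0))
  # near the stability bound the front runs at the analytic group speed
  p <- model_params(c2 = 2.6, f = 0.01, g = 1e-4, neighborhood = "moore-8",
                    boundary = "torus")
  ws <- wave_speed(p, shape = c(220, 20), source = c(10, 10),
                   probe = c(110, 10), n_steps = 1500)
  d <- dispersion(p, c(220, 20))
  kx <- d[d$ky_index == 0, ]; kx <- kx[order(kx$kx_index), ][1:110, ]
  vg <- max(diff(kx$omega_rad_per_step)) / (2 * pi / 220) * 0.5
  expect_equal(ws$speed_mm_per_ms, vg, tolerance = 0.15)
  # zero-amplitude input never arrives
  expect_error(wave_speed(p, shape = c(220, 20), source = c(10, 10),
                          probe = c(110, 10), n_steps = 300, amplitude = 0),
               "timeout")
})

test_that("correlation networks match the direct formula and flag degeneracy", {
  set.seed(29)
  X <- matrix(rnorm(600), 100, 6)
  X[, 2] <- X[, 1] # identical signals correlate at exactly 1
  net <- correlation_network(X, rho_plus = 0.07)
  expect_equal(net$r[1, 2], 1)
  expect_true(isSymmetric(net$r))
  expect_equal(diag(net$r), rep(1, 6))
  expect_true(all(abs(net$r) <= 1 + 1e-12))
  # Eq-style direct computation: <xy> - <x><y> over sigma_x sigma_y
  direct <- function(a, b) {
    n <- length(a)
    s <- function(v) sqrt(mean(v^2) - mean(v)^2)
    (mean(a * b) - mean(a) * mean(b)) / (s(a) * s(b))
  }
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(net$r[i, j], direct(X[, i], X[, j]), tolerance = 1e-12)
  expect_equal(sum(net$pk$count), 6)
  expect_equal(net$degrees[1] >= 1, TRUE) # at least its twin
  X[, 3] <- 2
  expect_error(correlation_network(X), "zero variance")
})

test_that("degree distributions grow heavier tails as coupling increases", {
  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  nodes <- as.list(data.frame(t(as.matrix(expand.grid(seq(5, 60, 5),
                                                      seq(5, 60, 5))))))
  sk <- vapply(c(0.5, 2.6), function(c2) {
    p <- model_params(c2 = c2, f = 0.01, g = 1e-4, neighborhood = "moore-8",
                      boundary = "torus")
    run <- run_model(c(60, 60), p, 3000,
                     make_noise(sd = 0.5, seed = 5, n_steps = 3000),
                     record_nodes = nodes)
    skew(correlation_network(run$node_recordings)$degrees)
  }, 0)
  expect_gt(sk[2], sk[1])
})

test_that("Lempel-Ziv phrase counting matches hand-parsed sequences", {
  # manual LZ76 parses: 0|000000000 and 0|1|01010101
  expect_equal(lzc(rep(0, 10))$complexity, 2)
  expect_equal(lzc(rep(c(0, 1), 5))$complexity, 3)
  expect_equal(lzc(c(0, 0, 1, 0, 1, 1, 0, 1, 0))$complexity, 4) # 0|01|011|010
  z <- lzc(rep(0, 10))
  expect_equal(z$normalized, 2 * log2(10) / 10)
  # constant numeric signal: degenerate binarization flagged
  zc <- lzc(rep(3.2, 50))
  expect_true(zc$degenerate)
  expect_equal(zc$complexity, 2)
  # random signals approach normalized complexity ~1
  set.seed(31)
  expect_gt(lzc(rnorm(5000))$normalized, 0.8)
  expect_error(lzc(1), "short")
})

test_that("envelope demodulation recovers a known AM modulation", {
  # carrier power (not amplitude) modulated at 15 Hz, so the band-averaged
  # power envelope is sinusoidal at exactly the modulation frequency
  tt <- seq_len(32000)
  am <- sqrt(1 + 0.8 * sin(2 * pi * 15 * tt / 1000)) *
    sin(2 * pi * 400 * tt / 1000)
  onsets <- 1001 + (0:9) * 3000
  g <- grating_analysis(am, onsets, evoked_block = 3)
  band <- g$demod$freq_hz >= 8 & g$demod$freq_hz <= 30
  expect_equal(g$demod$freq_hz[band][which.max(g$demod$induced_post[band])],
               15, tolerance = 1)
  expect_equal(g$demod$freq_hz[band][which.max(g$demod$induced_pre[band])],
               15, tolerance = 1)
})

test_that("a stimulus-free session yields a flat TFR with no post-onset peak", {
  rec <- rep(2, 40000) # constant session: nothing is stimulus-locked
  g <- grating_analysis(rec, 2001 + (0:10) * 3000)
  expect_lt(max(abs(g$tfr_induced)), 1e-12)
  expect_lt(max(abs(g$hf_envelope_induced)), 1e-12)
  band <- g$demod$freq_hz >= 5 & g$demod$freq_hz <= 30
  expect_lt(sum(g$demod$induced_post[band]), 1e-12)
  expect_error(grating_analysis(rec, c(2001, 5001)), "10 trials")
  expect_error(grating_analysis(rec[1:5000], 2001 + (0:10) * 3000),
               "exceed")
})
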