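test_that("encoding is linear and the analytic path matches simulation", {
  p <- model_params(c2 = 1, f = 0.001, g = 0.001, boundary = "torus")
  sh <- c(16, 16)
  # zero stimulus encodes to zero
  z <- encode_stimulus(stimulus_point(c(1, 1), numeric(10)), p, sh, 50)
  expect_true(all(z == 0))
  # two images encoded together equal the sum of individual encodings
  i1 <- make_random_image(sh, seed = 1); i2 <- make_random_image(sh, seed = 2)
  e1 <- encode_stimulus(stimulus_separable(i1, 1), p, sh, 80)
  e2 <- encode_stimulus(stimulus_separable(i2, 1), p, sh, 80)
  e12 <- encode_stimulus(stimulus_separable(i1 + i2, 1), p, sh, 80)
  expect_equal(e12, e1 + e2, tolerance = 1e-12)
  # analytic and simulated interference patterns agree
  es <- encode_stimulus(stimulus_separable(i1, 1), p, sh, 80,
                        method = "simulate")
  expect_lt(max(abs(e1 - es)) / max(abs(es)), 1e-10)
  # the spatial spectrum at any time is the per-mode filtered image spectrum
  tbar <- 60
  s <- wavelattice:::mode_exposure_response(p, sh, 1, tbar)
  Ak_pred <- as.vector(stats::fft(i1)) * s
  Ak_got <- as.vector(stats::fft(e1[, , 1] * 0 +
    encode_stimulus(stimulus_separable(i1, 1), p, sh, tbar)[, , 1]))
  expect_equal(Ak_got, Ak_pred, tolerance = 1e-10)
})

test_that("static images decode exactly from a single late snapshot", {
  p <- model_params(c2 = 1, f = 0.001, g = 0.001, boundary = "torus")
  sh <- c(64, 64)
  img <- make_random_image(sh, seed = 7)
  stim <- stimulus_separable(img, 1)
  # round trip at 500 steps
  snap <- encode_stimulus(stim, p, sh, 500)
  dec <- decode_static_image(snap[, , 1], 1, p, 500, reference = img)
  expect_gte(dec$fidelity, 0.999999)
  expect_equal(dec$I_hat, img, tolerance = 1e-9)
  # all-zero snapshot decodes to an all-zero image
  dec0 <- decode_static_image(matrix(0, 64, 64), 1, p, 500)
  expect_true(all(dec0$I_hat == 0))
  # holographic property: snapshots at different times give the same image,
  # still intact around 10000 ms with these weak dampings
  for (tbar in c(200, 2000, 10000)) {
    snap <- encode_stimulus(stim, p, sh, tbar)
    dec <- decode_static_image(snap[, , 1], 1, p, tbar, reference = img)
    expect_gte(dec$fidelity, 0.999999)
  }
})

test_that("rectangular exposure windows decode as well as impulses", {
  p <- model_params(c2 = 1, f = 0.002, g = 0.001, boundary = "torus")
  sh <- c(32, 32)
  img <- make_random_image(sh, seed = 3)
  expo <- rep(1, 20) # 20-step fixed exposure window
  stim <- stimulus_separable(img, expo)
  snap <- encode_stimulus(stim, p, sh, 400)
  dec <- decode_static_image(snap[, , 1], expo, p, 400, reference = img)
  expect_gte(dec$fidelity, 0.999999)
})

test_that("ill-conditioned decodes are reported, not silently amplified", {
  # with c2 = 2 the shortest-wavelength mode oscillates at omega = pi, so a
  # two-step exposure (1, 1) cancels its response exactly: s_k = 0 there
  p <- model_params(c2 = 2, f = 0, g = 0, boundary = "torus")
  sh <- c(16, 16)
  img <- make_random_image(sh, seed = 9)
  expo <- c(1, 1)
  snap <- encode_stimulus(stimulus_separable(img, expo), p, sh, 300)
  expect_error(decode_static_image(snap[, , 1], expo, p, 300, tol = 1e-6),
               "ill-conditioned")
  dec <- decode_static_image(snap[, , 1], expo, p, 300, tol = 1e-6,
                             on_illconditioned = "zero")
  expect_gt(dec$n_illconditioned, 0)
  expect_true(all(is.finite(dec$I_hat)))
})

test_that("dynamic stimuli deconvolve exactly from the dense output", {
  set.seed(13)
  p <- model_params(c2 = 1.2, f = 0.01, g = 0.001, boundary = "torus")
  sh <- c(16, 16)
  # three spatial modes, 200 random time steps, read out with a margin
  xi <- outer(0:15, rep(1, 16)); yj <- outer(rep(1, 16), 0:15)
  flds <- lapply(list(c(2, 3), c(5, 1), c(8, 8)), function(m)
    cos(2 * pi * (m[1] * xi + m[2] * yj) / 16))
  v <- array(0, c(16, 16, 240))
  for (tt in 1:200) {
    s <- rnorm(3)
    v[, , tt] <- s[1] * flds[[1]] + s[2] * flds[[2]] + s[3] * flds[[3]]
  }
  run <- run_model(sh, p, 240, stimulus_dense(v), keep_history = TRUE)
  dec <- decode_dynamic(run$history, p)
  expect_lt(max(abs(dec$v[, , 1:200] - v[, , 1:200])), 1e-6)
  # zero output decodes to a zero stimulus
  dec0 <- decode_dynamic(array(0, c(8, 8, 30)), p)
  expect_true(all(dec0$v == 0))
})

test_that("decimated outputs recover stimuli supported on the coarse grid", {
  set.seed(17)
  p <- model_params(c2 = 1.1, f = 0.02, g = 0.005, boundary = "torus")
  v <- array(0, c(12, 12, 160))
  for (tt in seq(2, 120, by = 2)) v[, , tt] <- matrix(rnorm(144), 12, 12)
  run <- run_model(c(12, 12), p, 160, stimulus_dense(v), keep_history = TRUE)
  dec <- decode_dynamic(run$history[, , seq(2, 160, by = 2)], p, stride = 2)
  expect_lt(max(abs(dec$v[, , 1:60] - v[, , seq(2, 120, by = 2)])), 1e-6)
})

test_that("audio travels through the lattice with its spectrum intact", {
  # single tone: the dominant STFT ridge at every site is the input tone
  tone <- sin(2 * pi * 100 * seq_len(1500) / 1000)
  ar <- audio_roundtrip(tone, shape = c(80, 80), inject_node = c(1, 1),
                        record_nodes = list(c(41, 1), c(1, 41), c(41, 41)))
  for (i in 1:3) {
    s <- ar$stfts[[i]]
    ridge <- s$f[apply(s$power, 2, which.max)]
    expect_lt(stats::median(abs(ridge - 100)), 10)
  }
  # silence in, silence out
  ar0 <- audio_roundtrip(numeric(400), shape = c(40, 40),
                         record_nodes = list(c(21, 1), c(1, 21), c(21, 21)))
  expect_true(all(ar0$recordings == 0))
  expect_error(audio_roundtrip(numeric(0)), "empty")
})

test_that("the synthetic song fixture survives the inject/record protocol", {
  song <- make_synthetic_song(seed = 1)
  ar <- audio_roundtrip(song, shape = c(120, 120))
  expect_true(all(is.finite(ar$spectrogram_correlation)))
  expect_true(all(ar$spectrogram_correlation > 0.3))
  # every tone fundamental below 500 Hz is present in each recorded
  # spectrogram: energy at its bin well above the site's median level
  fund <- attr(song, "fundamentals_hz")
  for (i in 1:3) {
    s <- ar$stfts[[i]]
    present <- vapply(fund, function(f0) {
      b <- which.min(abs(s$f - f0))
      max(s$power[b, ]) > 5 * stats::median(s$power)
    }, TRUE)
    expect_true(all(present))
  }
})

test_that("image ingestion maps grey values topographically", {
  img <- matrix(seq(0, 1, length.out = 64), 8, 8)
  f <- image_to_field(img, c(8, 8), range = c(0, 2))
  expect_equal(dim(f), c(8, 8))
  expect_equal(min(f), 0); expect_equal(max(f), 2)
  # nearest-neighbor downsampling keeps corner values
  f2 <- image_to_field(img, c(4, 4))
  expect_equal(f2[1, 1], 0)
  expect_equal(f2[4, 4], 1)
  # png round trip through a temp file
  tf <- tempfile(fileext = ".png")
  field_to_image(img, tf)
  back <- image_to_field(tf, c(8, 8))
  expect_equal(back, img / max(img), tolerance = 0.01)
})
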