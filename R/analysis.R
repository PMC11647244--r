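#' Spectral peak statistics of a recording
#'
#' Computes the magnitude spectrum of a recording (Hann-windowed by default,
#' zero-padded for sub-bin interpolation) and extracts local maxima exceeding
#' a multiple of the median spectral magnitude (the noise-floor estimate).
#' Each peak's half-width is its half-power (-3 dB) width, measured by
#' linear interpolation on the interpolated power spectrum; for a 3-s Hann
#' window the window-limited half-width of a pure line is about 0.48 Hz.
#'
#' @param x Numeric recording (fs samples per second).
#' @param fs Sampling rate in Hz (default 1000).
#' @param threshold Peak threshold as a multiple of the median magnitude
#'   (default 5).
#' @param window `"hann"` (default) or `"rect"`.
#' @param pad_factor Zero-padding factor for interpolation (default 8).
#' @param fmin Ignore frequencies below this (default 1 Hz, excludes DC
#'   leakage).
#' @param local_window_hz Sidelobe-masking span: a candidate within this
#'   range of a peak at least 10 times stronger is treated as that peak's
#'   sidelobe and dropped (default 5 Hz).
#' @param min_frac_of_max Absolute dynamic-range floor, as a fraction of the
#'   spectrum maximum (default 1e-6, i.e. -120 dB): noiseless signals have a
#'   structured numerical leakage floor that a median threshold alone does
#'   not reject.
#' @return A list of class `wl_peaks`: `peaks` (data frame `freq_hz`,
#'   `power`, `half_width_hz`), `noise_floor`, `freq`, `magnitude`,
#'   `resolution_hz`.
#' @export
fft_peaks <- function(x, fs = 1000, threshold = 5, window = c("hann", "rect"),
                      pad_factor = 8L, fmin = 1, local_window_hz = 5,
                      min_frac_of_max = 1e-6) {
  window <- match.arg(window)
  n <- length(x)
  if (n < 2) stop("recording too short", call. = FALSE)
  x <- x - mean(x)
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)) else rep(1, n)
  xw <- x * w
  # peak detection on the unpadded spectrum: zero-padding interpolates the
  # leakage skirt into ripple maxima that would be miscounted as peaks
  mag <- Mod(stats::fft(xw))[seq_len(n %/% 2 + 1L)]
  freq <- (seq_along(mag) - 1) * fs / n
  keep <- freq >= fmin
  floor_est <- stats::median(mag[keep])
  empty <- data.frame(freq_hz = numeric(0), power = numeric(0),
                      half_width_hz = numeric(0))
  if (floor_est == 0) # all-zero signal
    return(structure(list(peaks = empty, noise_floor = 0, freq = freq,
                          magnitude = mag, resolution_hz = fs / n),
                     class = "wl_peaks"))
  m <- length(mag)
  is_max <- c(FALSE, mag[2:(m - 1)] > mag[1:(m - 2)] &
                mag[2:(m - 1)] >= mag[3:m], FALSE)
  cand <- which(is_max & keep & mag > threshold * floor_est &
                  mag > min_frac_of_max * max(mag[keep]))
  # a dominant line's window sidelobes are local maxima too: drop any
  # candidate within `local_window_hz` of a >= 10x stronger peak
  if (length(cand) > 1) {
    ord <- cand[order(-mag[cand])]
    span <- local_window_hz * n / fs
    kept <- integer(0)
    for (i in ord) {
      if (!any(abs(kept - i) < span & mag[kept] > 10 * mag[i]))
        kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  # half-power (-3 dB) widths, interpolated on the zero-padded spectrum
  xp <- c(xw, numeric((pad_factor - 1L) * n))
  magp <- Mod(stats::fft(xp))[seq_len(length(xp) %/% 2 + 1L)]
  freqp <- (seq_along(magp) - 1) * fs / length(xp)
  mp <- length(magp)
  hw <- vapply(cand, function(i0) {
    i <- (i0 - 1L) * pad_factor + 1L
    # re-center on the padded local maximum
    lo <- max(1L, i - pad_factor); hi <- min(mp, i + pad_factor)
    i <- lo + which.max(magp[lo:hi]) - 1L
    half <- magp[i] / sqrt(2)
    l <- i; while (l > 1 && magp[l] > half) l <- l - 1
    r <- i; while (r < mp && magp[r] > half) r <- r + 1
    fl <- if (l == i) freqp[i] else
      freqp[l] + (freqp[l + 1] - freqp[l]) * (half - magp[l]) /
        (magp[l + 1] - magp[l])
    fr <- if (r == i) freqp[i] else
      freqp[r - 1] + (freqp[r] - freqp[r - 1]) * (magp[r - 1] - half) /
        (magp[r - 1] - magp[r])
    fr - fl
  }, 0)
  structure(list(
    peaks = data.frame(freq_hz = freq[cand], power = mag[cand]^2,
                       half_width_hz = hw),
    noise_floor = floor_est, freq = freq, magnitude = mag,
    resolution_hz = fs / n), class = "wl_peaks")
}

#' @export
print.wl_peaks <- function(x, ...) {
  cat(sprintf("<wl_peaks> %d peak(s) above %s; resolution %.3g Hz\n",
              nrow(x$peaks), "threshold * median floor", x$resolution_hz))
  if (nrow(x$peaks)) print(utils::head(x$peaks, 10))
  invisible(x)
}

#' Short-time Fourier transform
#'
#' Hann-windowed STFT (a thin wrapper around [signal::specgram()]) returning
#' frequencies, window-center times and the complex and power matrices.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (default 1000).
#' @param window Window length in samples (default 128).
#' @param overlap Overlap in samples (default `window / 2`).
#' @return A list: `f` (Hz), `t` (s), `S` (complex, `length(f) x n_windows`),
#'   `power`.
#' @export
stft <- function(x, fs = 1000, window = 128L, overlap = window %/% 2L) {
  if (window > length(x)) stop("window longer than the signal", call. = FALSE)
  sp <- signal::specgram(x, n = window, Fs = fs,
                         window = signal::hanning(window), overlap = overlap)
  list(f = as.numeric(sp$f), t = as.numeric(sp$t), S = sp$S,
       power = Mod(sp$S)^2)
}

#' Magnitude-squared coherence (Welch)
#'
#' Welch-averaged magnitude-squared coherence between two equal-length
#' recordings: signals are cut into Hann-windowed overlapping segments,
#' auto- and cross-spectra are averaged across segments, and
#' `C = |Pxy|^2 / (Pxx Pyy)` is returned per frequency. Values lie in
#' `[0, 1]`; for independent noise the estimator's expected bias is about
#' `1 / n_segments`.
#'
#' @param x,y Numeric recordings of equal length.
#' @param fs Sampling rate (default 1000).
#' @param window Segment length (default 256).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A data frame `freq_hz`, `coherence`, with attribute `n_segments`.
#' @export
coherence <- function(x, y, fs = 1000, window = 256L, overlap = 0.5) {
  if (length(x) != length(y)) stop("recordings differ in length", call. = FALSE)
  n <- length(x)
  step <- max(1L, round(window * (1 - overlap)))
  starts <- seq(1L, n - window + 1L, by = step)
  if (length(starts) < 2L)
    stop("need at least 2 segments; shorten the window", call. = FALSE)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(window) / (window + 1))
  nf <- window %/% 2L + 1L
  Pxx <- Pyy <- numeric(nf); Pxy <- complex(nf)
  for (s in starts) {
    xs <- (x[s:(s + window - 1L)] - mean(x[s:(s + window - 1L)])) * w
    ys <- (y[s:(s + window - 1L)] - mean(y[s:(s + window - 1L)])) * w
    X <- stats::fft(xs)[seq_len(nf)]
    Y <- stats::fft(ys)[seq_len(nf)]
    Pxx <- Pxx + Mod(X)^2; Pyy <- Pyy + Mod(Y)^2
    Pxy <- Pxy + X * Conj(Y)
  }
  coh <- Mod(Pxy)^2 / pmax(Pxx * Pyy, 1e-300)
  out <- data.frame(freq_hz = (seq_len(nf) - 1) * fs / window, coherence = coh)
  attr(out, "n_segments") <- length(starts)
  out
}

#' Wave propagation speed
#'
#' Drives the lattice from a source node and measures how long the wavefront
#' takes to reach a probe node: the arrival is the first step at which the
#' probe activation exceeds a stated fraction of the source amplitude
#' (default 0.5 %). Speed is the source-probe distance over the arrival time.
#'
#' @param params A `wl_params`.
#' @param shape Grid shape.
#' @param source,probe Nodes `c(i, j)` (defaults: corner source, probe 100
#'   columns = 50 mm along x).
#' @param n_steps Maximum steps to wait (default 2000).
#' @param amplitude Source pulse amplitude.
#' @param f0 Pulse-train rate in Hz driving the source (default 7).
#' @param threshold_frac Arrival threshold as a fraction of `amplitude`
#'   (default 0.005).
#' @return A list: `speed_mm_per_ms`, `arrival_step`, `distance_mm`.
#' @export
wave_speed <- function(params, shape = c(120L, 12L), source = c(1L, 1L),
                       probe = c(101L, 1L), n_steps = 2000L, amplitude = 1,
                       f0 = 7, threshold_frac = 0.005) {
  stim <- make_pulse_train(f0, n_steps, node = source, amplitude = amplitude,
                           fs = sampling_rate(params))
  run <- run_model(shape, params, n_steps, stim, record_nodes = list(probe))
  trace <- abs(run$node_recordings[, 1])
  hit <- which(trace > threshold_frac * abs(amplitude))
  if (!length(hit))
    stop("wavefront did not reach the probe within `n_steps` (timeout)",
         call. = FALSE)
  arrival <- hit[1]
  dist_mm <- sqrt(sum((probe - source)^2)) * params$column_pitch_mm
  list(speed_mm_per_ms = dist_mm / (arrival * params$dt_ms),
       arrival_step = arrival, distance_mm = dist_mm)
}

#' Thresholded positive correlation network
#'
#' Pearson correlations between node signals, thresholded at `rho_plus`
#' (default 0.07) to form the positive correlation network, with node
#' degrees and the degree distribution `P(k)`. Long-tailed `P(k)` indicates
#' a highly integrated state.
#'
#' @param X Signal matrix, time in rows, one column per node (typically
#'   3000 ms of samples).
#' @param rho_plus Edge threshold on `r` (default 0.07).
#' @return A list of class `wl_corrnet`: `r` (correlation matrix),
#'   `adjacency`, `degrees`, `pk` (data frame `k`, `count`, `p`),
#'   `rho_plus`.
#' @export
correlation_network <- function(X, rho_plus = 0.07) {
  stopifnot(is.matrix(X), ncol(X) >= 2)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("undefined correlation: node(s) %s have zero variance",
                 paste(which(sds == 0), collapse = ", ")), call. = FALSE)
  r <- stats::cor(X)
  adj <- r >= rho_plus
  diag(adj) <- FALSE
  deg <- colSums(adj)
  tab <- table(factor(deg, levels = 0:max(deg)))
  pk <- data.frame(k = as.integer(names(tab)), count = as.integer(tab))
  pk$p <- pk$count / sum(pk$count)
  structure(list(r = r, adjacency = adj, degrees = deg, pk = pk,
                 rho_plus = rho_plus), class = "wl_corrnet")
}

#' Lempel-Ziv complexity of a recording
#'
#' Binarizes the signal against its median (values above the median map to
#' 1) and counts Lempel-Ziv (LZ76, exhaustive-history) phrases. The
#' normalized variant `c * log2(n) / n` compares sequences of different
#' lengths; random sequences approach 1, regular ones fall toward 0.
#'
#' @param x Numeric recording, or a logical/0-1 vector taken as an already
#'   binarized sequence.
#' @return A list: `complexity` (phrase count), `normalized`, `n`,
#'   `degenerate` (TRUE when the signal was constant, in which case the
#'   complexity of the all-equal string is returned).
#' @export
lzc <- function(x) {
  if (length(x) < 2) stop("recording too short", call. = FALSE)
  degenerate <- FALSE
  if (is.logical(x) || all(x %in% c(0, 1))) {
    s <- as.integer(x)
  } else {
    med <- stats::median(x)
    if (all(x == x[1])) degenerate <- TRUE
    s <- as.integer(x > med)
  }
  c76 <- lz76_count(s)
  n <- length(s)
  list(complexity = c76, normalized = c76 * log2(n) / n, n = n,
       degenerate = degenerate)
}

# LZ76 exhaustive-history phrase counting (Kaspar & Schuster convention)
lz76_count <- function(s) {
  n <- length(s)
  c_count <- 1L; l <- 1L; i <- 0L; k <- 1L; kmax <- 1L
  repeat {
    if (s[i + k] == s[l + k]) {
      k <- k + 1L
      if (l + k > n) { c_count <- c_count + 1L; break }
    } else {
      if (k > kmax) kmax <- k
      i <- i + 1L
      if (i == l) {
        c_count <- c_count + 1L
        l <- l + kmax
        if (l + 1L > n) break
        i <- 0L; k <- 1L; kmax <- 1L
      } else k <- 1L
    }
  }
  c_count
}

# Sliding Hann-tapered FFT power at fixed target frequencies.
# x: one trial's samples; window_len in samples; step 1 sample.
# Returns matrix n_freq x n_centers; centers are window-center indices.
sliding_tfr <- function(x, freqs, fs, window_len) {
  n <- length(x)
  n_win <- n - window_len + 1L
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(window_len) / (window_len + 1))
  # all windows as a matrix (window_len x n_win)
  idx <- outer(seq_len(window_len), seq_len(n_win) - 1L, `+`)
  M <- matrix(x[idx], window_len, n_win) * w
  X <- stats::mvfft(M)
  bins <- round(freqs * window_len / fs) + 1L
  if (any(bins > window_len)) stop("target frequency above the window Nyquist")
  P <- Mod(X[bins, , drop = FALSE])^2
  rownames(P) <- freqs
  P
}

#' Frequency demodulation of a slow power envelope
#'
#' Spectrum of a (slow) amplitude envelope: demeaned, Hann-tapered,
#' zero-padded to `pad_to_s` seconds, magnitude-squared FFT. Used to reveal
#' slow (alpha/beta-range) modulation of the high-frequency power envelope.
#'
#' @param env Envelope samples.
#' @param fs Sampling rate (default 1000).
#' @param pad_to_s Zero-pad target duration in s (default 3).
#' @return A data frame `freq_hz`, `power`.
#' @export
envelope_spectrum <- function(env, fs = 1000, pad_to_s = 3) {
  n <- length(env)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  xp <- c((env - mean(env)) * w, numeric(max(0, round(pad_to_s * fs) - n)))
  np <- length(xp)
  p <- Mod(stats::fft(xp))[seq_len(np %/% 2 + 1L)]^2
  data.frame(freq_hz = (seq_len(np %/% 2 + 1L) - 1) * fs / np, power = p)
}

#' Induced and evoked high-frequency power of a grating session
#'
#' The model-side grating analysis: trials are cut around each onset,
#' time-frequency power is computed with a sliding Hann-tapered FFT (50 ms
#' windows, 1 ms steps, 20-500 Hz in 20 Hz steps), averaged across trials
#' either after the power step (induced) or before it on the time-domain
#' trial average (evoked), and baseline-corrected as relative change against
#' the -0.25 to -0.1 s window. The high-frequency envelope is the mean power
#' over 250-450 Hz; its slow modulation is measured by frequency
#' demodulation (Hann taper, zero-padded to 3 s) separately for the
#' prestimulus (-0.6 to -0.1 s) and poststimulus (-0.1 to 0.4 s) windows.
#' The latency of the main power increase is the first post-onset crossing
#' of half the poststimulus envelope maximum.
#'
#' @param recording Session recording (one electrode).
#' @param onsets Step indices of the grating onsets (e.g.
#'   `attr(make_grating(...), "trial_onsets")`).
#' @param fs Sampling rate (default 1000).
#' @param freqs Target frequencies in Hz (default `seq(20, 500, 20)`).
#' @param window_ms TFR window length (default 50 ms).
#' @param trial_window_s Trial cut around onset in s (default `c(-1, 2)`).
#' @param baseline_s Baseline window in s (default `c(-0.25, -0.1)`).
#' @param pre_s,post_s Demodulation windows in s (defaults `c(-0.6, -0.1)`
#'   and `c(-0.1, 0.4)`).
#' @param hf_band_hz Envelope band (default `c(250, 450)`).
#' @param evoked_block Trials per average for the evoked-variance blocks
#'   (default 10).
#' @return A list of class `wl_hfpower`: `tfr_induced`, `tfr_evoked`
#'   (baseline-corrected, `n_freq x n_times`), `times_s`, `freqs`,
#'   `hf_envelope_induced`, `hf_envelope_evoked`, `demod` (data frame with
#'   `freq_hz` and the four pre/post x induced/evoked spectra),
#'   `latency_ms`, `n_trials`.
#' @export
grating_analysis <- function(recording, onsets, fs = 1000,
                             freqs = seq(20, 500, by = 20), window_ms = 50L,
                             trial_window_s = c(-1, 2),
                             baseline_s = c(-0.25, -0.1),
                             pre_s = c(-0.6, -0.1), post_s = c(-0.1, 0.4),
                             hf_band_hz = c(250, 450), evoked_block = 10L) {
  if (length(onsets) < 10) stop("need at least 10 trials", call. = FALSE)
  # half-open cut [lo, hi): a (-1, 2) window on 3-s trials tiles exactly
  lo <- round(trial_window_s[1] * fs); hi <- round(trial_window_s[2] * fs) - 1L
  ok <- onsets + lo >= 1 & onsets + hi <= length(recording)
  if (!all(ok)) stop("trial windows exceed the session", call. = FALSE)
  trials <- vapply(onsets, function(o) recording[(o + lo):(o + hi)],
                   numeric(hi - lo + 1))
  win <- as.integer(window_ms * fs / 1000)
  # window-center times relative to onset, in s
  n_c <- nrow(trials) - win + 1L
  times_s <- (lo + (seq_len(n_c) - 1L) + (win - 1) / 2) / fs
  P_ind <- 0
  for (tr in seq_len(ncol(trials)))
    P_ind <- P_ind + sliding_tfr(trials[, tr], freqs, fs, win)
  P_ind <- P_ind / ncol(trials)
  P_evo <- sliding_tfr(rowMeans(trials), freqs, fs, win)

  rel_baseline <- function(P) {
    bsel <- times_s >= baseline_s[1] & times_s <= baseline_s[2]
    b <- rowMeans(P[, bsel, drop = FALSE])
    (P - b) / pmax(b, 1e-300)
  }
  T_ind <- rel_baseline(P_ind); T_evo <- rel_baseline(P_evo)
  hf <- freqs >= hf_band_hz[1] & freqs <= hf_band_hz[2]
  env_ind <- colMeans(T_ind[hf, , drop = FALSE])
  env_evo <- colMeans(T_evo[hf, , drop = FALSE])

  seg <- function(env, wdw) env[times_s >= wdw[1] & times_s <= wdw[2]]
  dm <- function(env, wdw) envelope_spectrum(seg(env, wdw), fs = fs)
  d_pre_i <- dm(env_ind, pre_s); d_post_i <- dm(env_ind, post_s)
  d_pre_e <- dm(env_evo, pre_s); d_post_e <- dm(env_evo, post_s)
  demod <- data.frame(freq_hz = d_pre_i$freq_hz,
                      induced_pre = d_pre_i$power, induced_post = d_post_i$power,
                      evoked_pre = d_pre_e$power, evoked_post = d_post_e$power)

  post <- env_ind[times_s >= 0]
  latency_ms <- if (max(post) > 0)
    (which(post >= max(post) / 2)[1] - 1) * 1000 / fs else NA_real_

  structure(list(tfr_induced = T_ind, tfr_evoked = T_evo, times_s = times_s,
                 freqs = freqs, hf_envelope_induced = env_ind,
                 hf_envelope_evoked = env_evo, demod = demod,
                 latency_ms = latency_ms, n_trials = ncol(trials)),
            class = "wl_hfpower")
}

#' @export
print.wl_hfpower <- function(x, ...) {
  cat(sprintf("<wl_hfpower> %d trials, %d freqs x %d times; HF latency %.0f ms\n",
              x$n_trials, length(x$freqs), length(x$times_s), x$latency_ms))
  invisible(x)
}
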