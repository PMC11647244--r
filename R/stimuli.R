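#' Stimulus objects
#'
#' A `wl_stimulus` describes the external input `v(x, t)` added to the
#' activation field before each step. Stimuli are stored sparsely (a point
#' source with a time series, a separable static field times a time profile,
#' a dense array, or per-step generated noise) and can be summed with
#' [stimulus_combine()]. All generators are deterministic given their seed.
#'
#' @name wl_stimulus
NULL

new_stimulus <- function(components) {
  structure(list(components = components), class = "wl_stimulus")
}

#' Point-source stimulus
#'
#' @param node Node `c(i, j)` (1-based column indices).
#' @param values Numeric vector: injected amplitude at each step `1..length(values)`.
#' @return A `wl_stimulus`.
#' @export
stimulus_point <- function(node, values) {
  stopifnot(length(node) == 2, all(is.finite(values)))
  new_stimulus(list(list(type = "point", node = as.integer(node),
                         values = as.double(values))))
}

#' Separable stimulus `v(x, t) = I(x) f(t)`
#'
#' The static-image special case: a fixed spatial field `I` scaled by a time
#' profile `f`. With an impulse profile the field is injected once; a
#' rectangular profile models a fixed exposure window.
#'
#' @param I Spatial field (matrix).
#' @param f Time profile: numeric vector, `f[t]` applied at step `t`.
#' @return A `wl_stimulus`.
#' @export
stimulus_separable <- function(I, f) {
  stopifnot(is.matrix(I), all(is.finite(I)), all(is.finite(f)))
  new_stimulus(list(list(type = "separable", I = I, f = as.double(f))))
}

#' Dense stimulus
#' @param v Array `nx x ny x T` of injected values.
#' @return A `wl_stimulus`.
#' @export
stimulus_dense <- function(v) {
  stopifnot(length(dim(v)) == 3, all(is.finite(v)))
  new_stimulus(list(list(type = "dense", v = v)))
}

#' Spatiotemporal white-noise stimulus
#'
#' Independent Gaussian input at every node and step, generated on the fly
#' (reproducibly from `seed`) so long sessions need no dense storage. A
#' stand-in for "chaotic" broadband drive.
#'
#' @param sd Noise standard deviation per node and step.
#' @param seed Integer seed.
#' @param n_steps Number of steps the noise lasts (from step 1).
#' @return A `wl_stimulus`.
#' @export
make_noise <- function(sd = 1, seed = 1L, n_steps = Inf) {
  new_stimulus(list(list(type = "noise", sd = sd, seed = as.integer(seed),
                         n_steps = n_steps)))
}

#' Sum several stimuli
#' @param ... `wl_stimulus` objects.
#' @return A `wl_stimulus` whose injection is the sum of the parts.
#' @export
stimulus_combine <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, TRUE, "wl_stimulus")))
  new_stimulus(do.call(c, lapply(parts, `[[`, "components")))
}

#' @export
print.wl_stimulus <- function(x, ...) {
  cat(sprintf("<wl_stimulus> %d component(s): %s\n", length(x$components),
              paste(vapply(x$components, `[[`, "", "type"), collapse = ", ")))
  invisible(x)
}

# Compile a stimulus into a per-step sampler closure: sampler(t) returns a
# field matrix or NULL. Noise components carry their own RNG stream so the
# run is reproducible and does not disturb the caller's RNG.
stim_sampler <- function(stimulus, shape, n_steps) {
  stopifnot(inherits(stimulus, "wl_stimulus"))
  comps <- stimulus$components
  # private RNG streams for noise components
  streams <- lapply(comps, function(cmp) {
    if (cmp$type != "noise") return(NULL)
    withr_seed(cmp$seed, get(".Random.seed", envir = globalenv()))
  })
  for (cmp in comps) {
    if (cmp$type == "point") {
      if (any(cmp$node < 1L) || cmp$node[1] > shape[1] || cmp$node[2] > shape[2])
        stop("stimulus node lies off the grid", call. = FALSE)
    } else if (cmp$type == "separable") {
      if (!all(dim(cmp$I) == shape))
        stop("stimulus field shape does not match the grid", call. = FALSE)
    } else if (cmp$type == "dense") {
      if (!all(dim(cmp$v)[1:2] == shape))
        stop("stimulus array shape does not match the grid", call. = FALSE)
    }
  }
  env <- environment()
  function(tt) {
    out <- NULL
    for (i in seq_along(comps)) {
      cmp <- comps[[i]]
      add <- switch(cmp$type,
        point = {
          if (tt <= length(cmp$values) && cmp$values[tt] != 0) {
            m <- matrix(0, shape[1], shape[2])
            m[cmp$node[1], cmp$node[2]] <- cmp$values[tt]
            m
          }
        },
        separable = {
          if (tt <= length(cmp$f) && cmp$f[tt] != 0) cmp$I * cmp$f[tt]
        },
        dense = if (tt <= dim(cmp$v)[3]) cmp$v[, , tt],
        noise = {
          if (tt <= cmp$n_steps) {
            old <- get(".Random.seed", envir = globalenv())
            assign(".Random.seed", streams[[i]], envir = globalenv())
            m <- matrix(stats::rnorm(prod(shape), sd = cmp$sd),
                        shape[1], shape[2])
            streams[[i]] <<- get(".Random.seed", envir = globalenv())
            assign(".Random.seed", old, envir = globalenv())
            m
          }
        })
      if (!is.null(add)) out <- if (is.null(out)) add else out + add
    }
    out
  }
}

#' Periodic 1-ms rectangular pulse train
#'
#' Single-step rectangular pulses at a stated fundamental frequency,
#' injected at one node. Non-integer step periods are realized by
#' accumulated-phase scheduling (pulse m falls at step
#' `onset + floor(m * fs / f0)`), so the average rate is exact; a 7 Hz train
#' over 3000 steps carries exactly 21 pulses.
#'
#' @param fundamental_hz Pulse rate in Hz (must be below fs/2).
#' @param n_steps Length of the stimulus in steps.
#' @param node Injection node `c(i, j)`.
#' @param amplitude Pulse amplitude (default 1).
#' @param onset First possible pulse step (default 1).
#' @param fs Sampling rate in Hz (default 1000).
#' @return A `wl_stimulus`.
#' @export
make_pulse_train <- function(fundamental_hz, n_steps, node = c(1L, 1L),
                             amplitude = 1, onset = 1L, fs = 1000) {
  if (fundamental_hz > fs / 2)
    stop("pulse fundamental exceeds the Nyquist frequency", call. = FALSE)
  vals <- numeric(n_steps)
  m <- 0
  repeat {
    tt <- onset + floor(m * fs / fundamental_hz)
    if (tt > n_steps) break
    vals[tt] <- vals[tt] + amplitude
    m <- m + 1
  }
  stimulus_point(node, vals)
}

#' Superimposed pulse trains at several fundamentals
#'
#' @inheritParams make_pulse_train
#' @param fundamentals_hz Vector of pulse rates in Hz.
#' @return A `wl_stimulus` (single point component with the summed train).
#' @export
make_multi_pulse_train <- function(fundamentals_hz, n_steps, node = c(1L, 1L),
                                   amplitude = 1, onset = 1L, fs = 1000) {
  parts <- lapply(fundamentals_hz, make_pulse_train, n_steps = n_steps,
                  node = node, amplitude = amplitude, onset = onset, fs = fs)
  vals <- Reduce(`+`, lapply(parts, function(p) p$components[[1]]$values))
  stimulus_point(node, vals)
}

#' Sinusoidal stimulus at one node
#'
#' @param f0 Frequency in Hz.
#' @inheritParams make_pulse_train
#' @return A `wl_stimulus`.
#' @export
make_sinusoid <- function(f0, n_steps, node = c(1L, 1L), amplitude = 1,
                          fs = 1000) {
  if (f0 > fs / 2) stop("frequency exceeds Nyquist", call. = FALSE)
  tt <- seq_len(n_steps)
  stimulus_point(node, amplitude * sin(2 * pi * f0 * tt / fs))
}

#' Static circular grating stimulus and trial session
#'
#' A non-moving grating disc: eight equal-width parallel stripes clipped to
#' a circular aperture, four at +10 mV and four at -9 mV, injected as
#' constant input during each trial's on-period. The default session follows
#' the in-silico grating protocol: 1 s pre-stimulus silence, 1 s grating,
#' 1 s post-stimulus silence, repeated over `n_trials` trials (100 trials =
#' a 300 s session).
#'
#' @param shape Grid shape `c(nx, ny)` (default `c(150, 150)`, i.e. 75 x 75 mm).
#' @param center Grating center node `c(i, j)`; defaults to the grid center.
#' @param radius_mm Aperture radius in mm (default 10).
#' @param stripe_values Length-2 vector of alternating stripe amplitudes
#'   (default `c(10, -9)` mV).
#' @param n_stripes Number of stripes (default 8).
#' @param orientation Stripe orientation in radians (default 0: stripes
#'   parallel to the y axis).
#' @param on_ms,pre_ms,post_ms Trial timing in ms (defaults 1000 each).
#' @param n_trials Number of trials (default 100).
#' @param pitch_mm Column pitch in mm (default 0.5).
#' @return A `wl_stimulus` with attributes `trial_onsets` (step indices of
#'   grating onsets), `trial_ms` and `field`.
#' @export
make_grating <- function(shape = c(150L, 150L), center = NULL, radius_mm = 10,
                         stripe_values = c(10, -9), n_stripes = 8L,
                         orientation = 0, on_ms = 1000L, pre_ms = 1000L,
                         post_ms = 1000L, n_trials = 100L, pitch_mm = 0.5) {
  if (is.null(center)) center <- round(shape / 2)
  nx <- shape[1]; ny <- shape[2]
  r_cols <- radius_mm / pitch_mm
  if (center[1] - r_cols < 1 || center[1] + r_cols > nx ||
      center[2] - r_cols < 1 || center[2] + r_cols > ny)
    stop("grating aperture exceeds the grid", call. = FALSE)
  xi <- (seq_len(nx) - center[1])
  yj <- (seq_len(ny) - center[2])
  dx <- outer(xi, rep(1, ny)); dy <- outer(rep(1, nx), yj)
  inside <- dx^2 + dy^2 < r_cols^2
  # coordinate across the stripes (normal to their orientation)
  u <- dx * cos(orientation) + dy * sin(orientation)
  width <- 2 * r_cols / n_stripes
  band <- pmin(pmax(floor((u + r_cols) / width), 0), n_stripes - 1)
  I <- matrix(0, nx, ny)
  I[inside] <- stripe_values[(band[inside] %% 2) + 1]
  trial <- c(rep(0, pre_ms), rep(1, on_ms), rep(0, post_ms))
  f <- rep(trial, n_trials)
  st <- stimulus_separable(I, f)
  attr(st, "trial_onsets") <- pre_ms + (seq_len(n_trials) - 1L) * length(trial) + 1L
  attr(st, "trial_ms") <- length(trial)
  attr(st, "field") <- I
  st
}

#' Complex burst stimuli: HF bursts riding on a low-frequency wave
#'
#' The shared probe input for state comparisons: `n_stimuli` events, each a
#' low-frequency wave segment with a short high-frequency burst superimposed,
#' at a random onset and a random node. Reproducible from `seed`.
#'
#' @param shape Grid shape.
#' @param n_steps Session length in steps.
#' @param n_stimuli Number of events (default 50).
#' @param seed Integer seed.
#' @param lf_hz Low-frequency wave frequency (default 5 Hz).
#' @param hf_hz Burst carrier frequency (default 300 Hz).
#' @param event_ms Event duration (default 200 ms).
#' @param burst_ms Burst duration within the event (default 50 ms).
#' @param amplitude Event amplitude scale (default 1).
#' @param fs Sampling rate (default 1000).
#' @return A `wl_stimulus`.
#' @export
make_complex_bursts <- function(shape, n_steps, n_stimuli = 50L, seed = 1L,
                                lf_hz = 5, hf_hz = 300, event_ms = 200L,
                                burst_ms = 50L, amplitude = 1, fs = 1000) {
  draws <- withr_seed(seed, {
    data.frame(
      i = sample.int(shape[1], n_stimuli, replace = TRUE),
      j = sample.int(shape[2], n_stimuli, replace = TRUE),
      onset = sample.int(max(n_steps - event_ms, 1L), n_stimuli, replace = TRUE))
  })
  parts <- lapply(seq_len(n_stimuli), function(s) {
    tt <- seq_len(event_ms)
    wave <- amplitude * sin(2 * pi * lf_hz * tt / fs)
    b0 <- (event_ms - burst_ms) %/% 2
    burst_idx <- seq.int(b0 + 1, b0 + burst_ms)
    wave[burst_idx] <- wave[burst_idx] +
      amplitude * sin(2 * pi * hf_hz * tt[burst_idx] / fs)
    vals <- numeric(min(n_steps, draws$onset[s] + event_ms - 1L))
    span <- draws$onset[s]:min(n_steps, draws$onset[s] + event_ms - 1L)
    vals[span] <- wave[seq_along(span)]
    stimulus_point(c(draws$i[s], draws$j[s]), vals)
  })
  do.call(stimulus_combine, parts)
}

#' Random grey-value image
#' @param shape Image shape `c(nx, ny)`.
#' @param seed Integer seed.
#' @return A matrix of grey values in `[0, 1]`.
#' @export
make_random_image <- function(shape, seed = 1L) {
  withr_seed(seed, matrix(stats::runif(prod(shape)), shape[1], shape[2]))
}

#' Synthetic multi-tone "song" fixture
#'
#' A generated audio waveform standing in for a real recording: a sequence
#' of harmonic tone stacks (distinct fundamentals with overtones, all below
#' 500 Hz) interleaved with frequency chirps, sampled at 1000 Hz. Contains
#' at least 10 distinct fundamentals in 0-500 Hz and is reproducible from
#' `seed`.
#'
#' @param seed Integer seed.
#' @param duration_ms Length in ms (default 3000).
#' @param fs Sampling rate (default 1000).
#' @return A numeric waveform in `[-1, 1]` with attribute `fundamentals_hz`.
#' @export
make_synthetic_song <- function(seed = 1L, duration_ms = 3000L, fs = 1000) {
  # fundamentals stay below ~450 Hz: near the Nyquist edge the lattice's
  # passband (set by the coupling) no longer carries the tone
  notes <- c(55, 73, 98, 131, 165, 196, 220, 262, 294, 330, 392, 440)
  wave <- numeric(duration_ms)
  n_seg <- 12L
  seg_len <- duration_ms %/% n_seg
  order <- withr_seed(seed, sample(notes))
  tt <- seq_len(seg_len) / fs
  for (s in seq_len(n_seg)) {
    f0 <- order[((s - 1L) %% length(order)) + 1L]
    seg <- sin(2 * pi * f0 * tt)
    for (h in 2:3) if (h * f0 < fs / 2) seg <- seg + 0.4 / h * sin(2 * pi * h * f0 * tt)
    env <- sin(pi * seq_len(seg_len) / seg_len) # fade in/out
    span <- ((s - 1L) * seg_len + 1L):(s * seg_len)
    wave[span] <- wave[span] + seg * env
  }
  # one slow chirp underneath, 100 -> 400 Hz
  tt_all <- seq_len(duration_ms) / fs
  f_inst <- 100 + (400 - 100) * (tt_all / max(tt_all))
  phase <- 2 * pi * cumsum(f_inst) / fs
  wave <- wave + 0.3 * sin(phase)
  wave <- wave / max(abs(wave))
  attr(wave, "fundamentals_hz") <- sort(notes)
  wave
}
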