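#' Encode a stimulus into a lattice interference pattern
#'
#' Runs the stimulus through the lattice and returns the resulting
#' activation field(s): the wave-interference pattern that spreads over all
#' columns. Two routes are available: the stepping simulation (any topology)
#' and the analytic normal-mode solution (torus only); on a torus they agree
#' to near machine precision.
#'
#' @param stimulus A `wl_stimulus`.
#' @param params A `wl_params`.
#' @param shape Grid shape `c(nx, ny)`.
#' @param n_steps Number of steps to evolve.
#' @param method `"analytic"` (default; requires torus boundary) or
#'   `"simulate"`.
#' @param times Step indices at which to return snapshots (default: the last
#'   step only).
#' @return An array `nx x ny x length(times)` with attribute `times`.
#' @export
encode_stimulus <- function(stimulus, params, shape, n_steps,
                            method = c("analytic", "simulate"), times = NULL) {
  method <- match.arg(method)
  if (is.null(times)) times <- n_steps
  if (method == "analytic") {
    out <- evolve_analytic(shape, params, n_steps, stimulus, times = times)$A
  } else {
    run <- run_model(shape, params, n_steps, stimulus, keep_history = TRUE)
    out <- run$history[, , times, drop = FALSE]
  }
  attr(out, "times") <- times
  out
}

# per-mode response scalar s_k(tbar) = sum_tau h_k(tbar - tau + 1) f(tau)
# for a separable stimulus v(x,t) = I(x) f(t)
mode_exposure_response <- function(params, shape, exposure, tbar) {
  mu <- as.vector(mode_mu(shape, params$neighborhood))
  roots <- mode_roots(mu, params)
  s <- numeric(length(mu))
  idx <- which(exposure != 0)
  if (!length(idx)) return(s)
  for (tau in idx) {
    j <- tbar - tau + 1L
    if (j >= 1L) s <- s + exposure[tau] * mode_impulse_response(roots, j)
  }
  s
}

#' Decode a static image from a single activation snapshot
#'
#' For a separable stimulus `v(x, t) = I(x) f(t)` on a torus, each spatial
#' mode of the snapshot is the image mode scaled by a known per-mode
#' response scalar `s_k(tbar)`; dividing them out and inverse-transforming
#' recovers the image exactly, up to floating-point conditioning. With weak
#' damping the pattern stays decodable at arbitrarily late snapshot times:
#' fidelity is lost only once mode amplitudes decay toward machine
#' precision, at which point the offending modes are reported.
#'
#' @param snapshot Activation matrix `A(x, tbar)`.
#' @param exposure Time profile `f(t)`: numeric vector (e.g. `1` for an
#'   impulse at step 1, or `rep(1, w)` for a rectangular window).
#' @param params A `wl_params` (torus).
#' @param snapshot_time The step index `tbar` of the snapshot.
#' @param reference Optional original image; if given, the Pearson
#'   correlation between decode and reference is reported as `fidelity`.
#' @param tol Conditioning threshold: modes with
#'   `|s_k| < tol * max |s_k|` are ill-conditioned.
#' @param on_illconditioned `"error"` (default) or `"zero"` (drop those
#'   modes and flag them).
#' @return A list of class `wl_decoded_image`: `I_hat`, `fidelity` (or NA),
#'   `snapshot_time`, `n_illconditioned`, `illconditioned_modes`.
#' @export
decode_static_image <- function(snapshot, exposure, params, snapshot_time,
                                reference = NULL, tol = 1e-12,
                                on_illconditioned = c("error", "zero")) {
  on_illconditioned <- match.arg(on_illconditioned)
  stopifnot(is.matrix(snapshot))
  shape <- dim(snapshot)
  s <- mode_exposure_response(params, shape, exposure, snapshot_time)
  bad <- abs(s) < tol * max(abs(s))
  if (any(bad) && on_illconditioned == "error") {
    km <- which(bad)[seq_len(min(5, sum(bad)))]
    stop(sprintf(
      "ill-conditioned decode: %d mode(s) with |s_k| below %g * max (first: %s)",
      sum(bad), tol, paste(km, collapse = ", ")), call. = FALSE)
  }
  Ak <- as.vector(stats::fft(snapshot))
  s_safe <- s; s_safe[bad] <- 1
  Ik <- Ak / s_safe
  Ik[bad] <- 0
  I_hat <- Re(stats::fft(matrix(Ik, shape[1], shape[2]), inverse = TRUE)) /
    prod(shape)
  fidelity <- if (!is.null(reference))
    stats::cor(as.vector(I_hat), as.vector(reference)) else NA_real_
  structure(list(I_hat = I_hat, fidelity = fidelity,
                 snapshot_time = snapshot_time,
                 n_illconditioned = sum(bad),
                 illconditioned_modes = which(bad)),
            class = "wl_decoded_image")
}

#' @export
print.wl_decoded_image <- function(x, ...) {
  cat(sprintf("<wl_decoded_image> snapshot at t = %d; fidelity = %s; %d ill-conditioned mode(s)\n",
              x$snapshot_time,
              if (is.na(x$fidelity)) "NA" else sprintf("%.6f", x$fidelity),
              x$n_illconditioned))
  invisible(x)
}

#' Decode a time-varying stimulus from the dense output
#'
#' Back-calculates the input `v(x, t)` from the activation history on a
#' torus by exact per-mode deconvolution. Each mode obeys the second-order
#' recurrence `A_t = tr A_{t-1} - det A_{t-2} + m11 v_t - det v_{t-1}`; the
#' local combination `w_t = m11 v_t - det v_{t-1}` is computed directly from
#' the history and then unwound for `v_t`. The unwinding direction is chosen
#' per mode for numerical stability: forward where the deconvolution filter
#' is minimum-phase (`|m11| >= det`), backward (anti-causal) otherwise --
#' the forward recursion would amplify rounding error geometrically there.
#' Backward modes assume the stimulus has ended by the final sample; any
#' residue decays by a factor `|m11|/det` per step away from the end, so
#' provide a short stimulus-free tail of the output (a few tens of steps)
#' for full accuracy.
#'
#' If the output is only known on every `stride`-th step, the same scheme is
#' applied with the `stride`-step transfer map; the stimulus is then
#' recovered on that coarser time grid (it must be supported there --
#' information between samples is lost to the coarser Nyquist band).
#'
#' @param history Activation array `nx x ny x T` (zero initial state
#'   presumed), sampled every `stride` steps.
#' @param params A `wl_params` (torus).
#' @param stride Sampling stride of the history in steps (default 1).
#' @param floor_tol Relative floor on the per-mode divisor (default 1e-12);
#'   floored modes are flagged rather than silently amplified.
#' @return A list: `v` (array like `history`), `flagged_modes` (indices
#'   floored), `backward_modes` (indices unwound anti-causally), `stride`.
#' @export
decode_dynamic <- function(history, params, stride = 1L, floor_tol = 1e-12) {
  stopifnot(length(dim(history)) == 3)
  shape <- dim(history)[1:2]; Tn <- dim(history)[3]
  mu <- as.vector(mode_mu(shape, params$neighborhood))
  e <- mode_map_entries(mu, params)
  n_modes <- length(mu)
  m12 <- rep(e$m12, n_modes); m22 <- rep(e$m22, n_modes)
  # stride-step map M^s, per mode, by iterated 2x2 multiplication
  s11 <- e$m11; s12 <- m12; s21 <- e$m21; s22 <- m22
  if (stride > 1L) for (i in 2:stride) {
    t11 <- s11 * e$m11 + s12 * e$m21
    t12 <- s11 * m12 + s12 * m22
    t21 <- s21 * e$m11 + s22 * e$m21
    t22 <- s21 * m12 + s22 * m22
    s11 <- t11; s12 <- t12; s21 <- t21; s22 <- t22
  }
  trc <- s11 + s22
  dts <- s11 * s22 - s12 * s21
  # sampled recurrence: A_i = trc A_{i-1} - dts A_{i-2} + c0 u_i + c1 u_{i-1}
  # with input entering one micro-step before each sample (b = M e1)
  c0 <- e$m11
  c1 <- s12 * e$m21 - s22 * e$m11
  N <- prod(shape)
  Ak <- matrix(0 + 0i, N, Tn)
  for (tt in seq_len(Tn)) Ak[, tt] <- as.vector(stats::fft(history[, , tt]))
  W <- matrix(0 + 0i, N, Tn)
  W[, 1] <- Ak[, 1]
  if (Tn >= 2) W[, 2] <- Ak[, 2] - trc * Ak[, 1]
  if (Tn >= 3)
    for (tt in 3:Tn)
      W[, tt] <- Ak[, tt] - trc * Ak[, tt - 1] + dts * Ak[, tt - 2]
  fwd <- abs(c0) >= abs(c1)
  flag <- (fwd & abs(c0) < floor_tol * max(abs(c0))) |
    (!fwd & abs(c1) < floor_tol * max(abs(c1)))
  c0s <- ifelse(flag & fwd, floor_tol * max(abs(c0)), c0)
  c1s <- ifelse(flag & !fwd, floor_tol * max(abs(c1)), c1)
  U <- matrix(0 + 0i, N, Tn)
  if (any(fwd)) {
    u <- rep(0 + 0i, sum(fwd))
    for (tt in seq_len(Tn)) {
      u <- (W[fwd, tt] - c1s[fwd] * u) / c0s[fwd]
      U[fwd, tt] <- u
    }
  }
  if (any(!fwd)) {
    # anti-causal unwind u_{t-1} = (w_t - c0 u_t)/c1, seeded with u_Tn = 0
    # (stimulus assumed over by the last sample; seeding error decays
    # backward by |c0/c1| per step)
    bk <- !fwd
    u <- rep(0 + 0i, sum(bk))
    U[bk, Tn] <- u
    if (Tn >= 2)
      for (tt in Tn:2) {
        u <- (W[bk, tt] - c0s[bk] * u) / c1s[bk]
        U[bk, tt - 1] <- u
      }
  }
  v <- array(NA_real_, dim(history))
  for (tt in seq_len(Tn))
    v[, , tt] <- Re(stats::fft(matrix(U[, tt], shape[1], shape[2]),
                               inverse = TRUE)) / N
  list(v = v, flagged_modes = which(flag), backward_modes = which(!fwd),
       stride = stride)
}

#' Audio encode/record round trip
#'
#' The audio protocol: a waveform sampled at 1000 Hz is injected at one
#' node, the lattice is run for the signal duration, and recordings are
#' taken at three distant sites. Short-time Fourier transforms (Hann window,
#' default size 128) of input and recordings are compared over 0-500 Hz via
#' spectrogram correlation per site.
#'
#' @param waveform Numeric waveform at 1000 Hz (use [resample_audio()] for
#'   other rates).
#' @param params A `wl_params` (defaults to [waking_params()]).
#' @param shape Grid shape (default `c(150, 150)`).
#' @param inject_node Injection node (default `c(1, 1)`, i.e. a corner, the
#'   protocol's `(x = 0, y = 0)`).
#' @param record_nodes List of recording nodes; default the protocol's three
#'   sites `(50, 0)`, `(0, 50)`, `(50, 50)` in 0-based grid coordinates.
#' @param window STFT window size (default 128).
#' @param amplitude Scale applied to the waveform before injection.
#' @return A list of class `wl_audio_roundtrip`: `recordings` (matrix
#'   `T x 3`), `input`, `stft_input`, `stfts`, `spectrogram_correlation`
#'   (one value per site).
#' @export
audio_roundtrip <- function(waveform, params = waking_params(),
                            shape = c(150L, 150L), inject_node = c(1L, 1L),
                            record_nodes = list(c(51L, 1L), c(1L, 51L),
                                                c(51L, 51L)),
                            window = 128L, amplitude = 1) {
  waveform <- as.numeric(waveform)
  if (!length(waveform)) stop("empty waveform", call. = FALSE)
  n_steps <- length(waveform)
  stim <- stimulus_point(inject_node, amplitude * waveform)
  run <- run_model(shape, params, n_steps, stim, record_nodes = record_nodes)
  rec <- run$node_recordings
  colnames(rec) <- vapply(record_nodes, function(nd)
    sprintf("x%d_y%d", nd[1] - 1L, nd[2] - 1L), "")
  fs <- sampling_rate(params)
  s_in <- stft(waveform, fs = fs, window = window)
  s_out <- lapply(seq_len(ncol(rec)), function(i)
    stft(rec[, i], fs = fs, window = window))
  corr <- vapply(s_out, function(s) {
    nt <- min(ncol(s$power), ncol(s_in$power))
    a <- as.vector(log10(s_in$power[, seq_len(nt)] + 1e-300))
    b <- as.vector(log10(s$power[, seq_len(nt)] + 1e-300))
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 0)
  names(corr) <- colnames(rec)
  structure(list(recordings = rec, input = waveform, stft_input = s_in,
                 stfts = s_out, spectrogram_correlation = corr),
            class = "wl_audio_roundtrip")
}

#' Convert a grey image to a stimulus field
#'
#' Reads a PNG (or takes a matrix), converts to grey by standard luminance
#' weights (0.2126 R + 0.7152 G + 0.0722 B), rescales linearly to an
#' amplitude range, and resamples to the grid size by nearest neighbor, so
#' pixel positions map topographically onto columns.
#'
#' @param image A file path to a PNG, or a numeric matrix/array.
#' @param shape Target grid shape.
#' @param range Output amplitude range (default `c(0, 1)`).
#' @return A numeric matrix `shape[1] x shape[2]`.
#' @export
image_to_field <- function(image, shape, range = c(0, 1)) {
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) == 3) {
    nc <- dim(image)[3]
    image <- if (nc >= 3)
      0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
    else image[, , 1]
  }
  ri <- round(seq(1, nrow(image), length.out = shape[1]))
  ci <- round(seq(1, ncol(image), length.out = shape[2]))
  out <- image[ri, ci, drop = FALSE]
  lo <- min(out); hi <- max(out)
  if (hi > lo) out <- (out - lo) / (hi - lo)
  range[1] + out * (range[2] - range[1])
}

#' Write a field as a grey PNG
#' @param field Numeric matrix.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
field_to_image <- function(field, path) {
  lo <- min(field); hi <- max(field)
  img <- if (hi > lo) (field - lo) / (hi - lo) else field * 0
  png::writePNG(img, path)
  invisible(path)
}
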