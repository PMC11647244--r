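#' Named activity-state presets
#'
#' Parameter regimes reproducing the simulated (patho)physiological states:
#'
#' * `waking`: the printed calibration `c2 = 2.6655, f = 0.01, g = 1e-4`
#'   on a 150 x 150 grid (Moore-8 neighborhood; the coupling sits just below
#'   that neighborhood's stability bound, the regime of near-maximal
#'   information integration).
#' * `sws` (slow-wave sleep): waking with the lateral feedback coupling
#'   halved, pushing resonance into the low-frequency band.
#' * `anesthesia`: waking with a general damping increase (`f` x 10,
#'   `g` x 100).
#' * `alzheimer`: waking plus a random lesion mask (default 4 % of columns).
#' * `schizophrenia`: waking plus randomized symmetric per-edge coupling
#'   jitter (uncorrelated transmission between neighbors).
#' * `seizure`: coupling raised 5 % above the stability bound; running it
#'   triggers unbounded, resonance-catastrophe growth (a `wl_instability`
#'   error).
#'
#' The sws/anesthesia/alzheimer/schizophrenia multipliers are documented
#' approximations relative to waking, not printed values.
#'
#' @param name One of `"waking"`, `"sws"`, `"anesthesia"`, `"alzheimer"`,
#'   `"schizophrenia"`, `"seizure"`.
#' @param shape Grid shape (default `c(150, 150)`).
#' @param seed Seed for the preset's stochastic perturbation (lesion mask /
#'   edge jitter), if any.
#' @param lesion_fraction Lesion fraction for `"alzheimer"` (default 0.04).
#' @param jitter_magnitude Edge-jitter magnitude for `"schizophrenia"`
#'   (default 0.3).
#' @return A list of class `wl_preset`: `name`, `params`, `shape`, `lesion`
#'   (or NULL), `jitter` (or NULL), `seed`.
#' @export
get_preset <- function(name = c("waking", "sws", "anesthesia", "alzheimer",
                                "schizophrenia", "seizure"),
                       shape = c(150L, 150L), seed = 1L,
                       lesion_fraction = 0.04, jitter_magnitude = 0.3) {
  name <- match.arg(name)
  wak <- waking_params()
  params <- switch(name,
    waking = ,
    alzheimer = ,
    schizophrenia = wak,
    sws = model_params(c2 = wak$c2 * 0.5, f = wak$f, g = wak$g,
                       neighborhood = wak$neighborhood, boundary = wak$boundary),
    anesthesia = model_params(c2 = wak$c2, f = wak$f * 10, g = wak$g * 100,
                              neighborhood = wak$neighborhood,
                              boundary = wak$boundary),
    seizure = model_params(
      c2 = 1.05 * stability_max_coupling(wak$f, wak$g, wak$neighborhood),
      f = wak$f, g = wak$g, neighborhood = wak$neighborhood,
      boundary = wak$boundary))
  # absorbing lesions: the excising variant renormalizes local averages and
  # can push the near-critical waking coupling past the stability bound
  lesion <- if (name == "alzheimer" && lesion_fraction > 0)
    lesion_mask(shape, lesion_fraction, seed = seed, mode = "absorb") else NULL
  jitter <- if (name == "schizophrenia")
    edge_jitter(shape, jitter_magnitude, seed = seed,
                neighborhood = params$neighborhood) else NULL
  structure(list(name = name, params = params, shape = shape,
                 lesion = lesion, jitter = jitter, seed = seed),
            class = "wl_preset")
}

#' @export
print.wl_preset <- function(x, ...) {
  cat(sprintf("<wl_preset> '%s' on %d x %d\n", x$name, x$shape[1], x$shape[2]))
  print(x$params)
  if (!is.null(x$lesion))
    cat(sprintf("  lesion fraction %.3g (seed %d)\n", x$lesion$fraction,
                x$lesion$seed))
  if (!is.null(x$jitter))
    cat(sprintf("  edge jitter magnitude %.3g (seed %d)\n",
                x$jitter$magnitude, x$jitter$seed))
  invisible(x)
}

#' Run a preset against a shared input and collect state metrics
#'
#' Applies the same complex-burst stimulus (seed-shared across presets) to
#' each named state and summarizes an LFP-scale electrode recording (radius
#' 1 mm by default; the field-potential scale separates the states'
#' complexity most cleanly) per state:
#' normalized Lempel-Ziv complexity, number of spectral peaks, dominant
#' frequency, and the low/high-frequency band power split. The seizure
#' preset, if requested, is reported with `diverged = TRUE` and NA metrics.
#'
#' @param names Character vector of preset names (default waking, sws,
#'   anesthesia).
#' @param shape Grid shape shared by all runs (default `c(60, 60)` for a
#'   desk-scale comparison).
#' @param n_steps Run length (default 3000 steps = 3 s).
#' @param input_seed Seed of the shared burst fixture.
#' @param record_node Node recorded from (default grid center).
#' @param radius_mm Recording electrode radius in mm (default 1, LFP scale).
#' @param n_stimuli Number of burst events (default 50).
#' @param preset_seed Seed passed to each preset's perturbation.
#' @return A data frame, one row per state: `state`, `lzc`, `n_peaks`,
#'   `dominant_freq_hz`, `centroid_hz` (spectral centroid), `lf_power`,
#'   `hf_power`, `diverged`.
#' @export
compare_states <- function(names = c("waking", "sws", "anesthesia"),
                           shape = c(60L, 60L), n_steps = 3000L,
                           input_seed = 1L, record_node = NULL,
                           radius_mm = 1, n_stimuli = 50L, preset_seed = 1L) {
  if (length(names) < 2) stop("need at least two presets", call. = FALSE)
  if (is.null(record_node)) record_node <- pmax(round(shape / 2), 1L)
  stim <- make_complex_bursts(shape, n_steps, n_stimuli = n_stimuli,
                              seed = input_seed)
  el <- electrode(record_node, radius_mm, id = "probe")
  rows <- lapply(names, function(nm) {
    pr <- get_preset(nm, shape = shape, seed = preset_seed)
    rec <- tryCatch({
      run <- run_model(shape, pr$params, n_steps, stim, lesion = pr$lesion,
                       jitter = pr$jitter, electrodes = list(el))
      run$recordings[, 1]
    }, wl_instability = function(e) NULL)
    if (is.null(rec))
      return(data.frame(state = nm, lzc = NA, n_peaks = NA,
                        dominant_freq_hz = NA, centroid_hz = NA,
                        lf_power = NA, hf_power = NA, diverged = TRUE))
    pk <- fft_peaks(rec)
    dom <- if (nrow(pk$peaks)) pk$peaks$freq_hz[which.max(pk$peaks$power)]
           else NA_real_
    sel <- pk$freq >= 1
    pw <- pk$magnitude[sel]^2
    centroid <- sum(pk$freq[sel] * pw) / sum(pw)
    lf <- sum(pk$magnitude[pk$freq >= 1 & pk$freq < 30]^2)
    hf <- sum(pk$magnitude[pk$freq >= 100]^2)
    data.frame(state = nm, lzc = lzc(rec)$normalized,
               n_peaks = nrow(pk$peaks), dominant_freq_hz = dom,
               centroid_hz = centroid, lf_power = lf, hf_power = hf,
               diverged = FALSE)
  })
  do.call(rbind, rows)
}

#' Stable resonance count as a function of model size
#'
#' Drives square periodic grids of increasing size with the same random
#' brief-peak input and counts the stable spectral peaks in a 3-s
#' center-node recording. Larger lattices support more distinct normal-mode
#' frequencies, so the count grows with size until neighboring mode
#' frequencies fall closer than the recording's spectral resolution
#' (1/3 Hz for 3 s) and merge; the analytic distinct-frequency count keeps
#' growing. A 1 x 1 grid (an isolated node) has no lateral feedback and
#' yields zero resonances.
#'
#' @param sizes Vector of square grid sizes (default `c(3, 7, 34, 151)`).
#' @param params A `wl_params`; the boundary is forced to torus so the
#'   resonances are the normal modes.
#' @param n_steps Recording length (default 3000).
#' @param n_impulses Number of random unit peaks injected in the first
#'   500 ms (default 5).
#' @param seed Seed for the peak placement.
#' @return A data frame `size`, `n_peaks`, `n_distinct_mode_freqs` (the
#'   analytic count of distinct oscillatory mode frequencies, for
#'   comparison).
#' @export
resonance_vs_size <- function(sizes = c(3L, 7L, 34L, 151L),
                              params = model_params(boundary = "torus"),
                              n_steps = 3000L, n_impulses = 5L, seed = 1L) {
  params$boundary <- "torus"
  rows <- lapply(sizes, function(sz) {
    if (sz == 1L)
      return(data.frame(size = 1L, n_peaks = 0L, n_distinct_mode_freqs = 0L))
    shape <- c(sz, sz)
    draws <- withr_seed(seed, data.frame(
      i = sample.int(sz, n_impulses, replace = TRUE),
      j = sample.int(sz, n_impulses, replace = TRUE),
      t = sample.int(500L, n_impulses, replace = TRUE)))
    parts <- lapply(seq_len(n_impulses), function(s) {
      vals <- numeric(draws$t[s]); vals[draws$t[s]] <- 1
      stimulus_point(c(draws$i[s], draws$j[s]), vals)
    })
    stim <- do.call(stimulus_combine, parts)
    ctr <- pmax(round(shape / 2), 1L)
    run <- run_model(shape, params, n_steps, stim, record_nodes = list(ctr))
    pk <- fft_peaks(run$node_recordings[, 1])
    disp <- dispersion(params, shape)
    nfr <- length(unique(round(disp$freq_hz[disp$oscillatory &
                                              disp$freq_hz > 0.5], 1)))
    data.frame(size = sz, n_peaks = nrow(pk$peaks),
               n_distinct_mode_freqs = nfr)
  })
  do.call(rbind, rows)
}
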