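#' Model parameters for the lattice field
#'
#' Bundles the tunable constants of the coupled-oscillator lattice: the
#' lateral feedback coupling `c2`, the two damping constants `f` (damping of
#' the lateral feedback, i.e. of the time-integrated grid Laplacian) and `g`
#' (damping of the activation itself), the neighborhood and boundary rule of
#' the grid, and the physical calibration (one column = 0.5 mm, one step =
#' 1 ms, so the sampling rate is 1000 Hz by default).
#'
#' `c2` multiplies the grid-Laplacian contribution to the lateral feedback and
#' acts like an excitatory transmission efficacy: it controls the highest
#' temporal frequency the lattice can carry, the speed of travelling waves,
#' and -- past a neighborhood-dependent bound (see
#' [stability_max_coupling()]) -- the onset of unbounded, seizure-like
#' growth. `f` and `g` are inhibition analogues; for small values the signal
#' amplitude decays on a timescale of roughly `2/(f+g)` steps (energy on
#' `1/(f+g)` steps).
#'
#' @param c2 Lateral feedback coupling (dimensionless, > 0).
#' @param f Damping of the lateral feedback (>= 0).
#' @param g Damping of the activation (>= 0).
#' @param neighborhood `"von-neumann-4"` (default) or `"moore-8"`.
#' @param boundary `"clamped-edge"` (default; each node averages over its
#'   actual neighbor count) or `"torus"` (periodic; required by the analytic
#'   normal-mode solution).
#' @param column_pitch_mm Physical width of one column in mm (default 0.5).
#' @param dt_ms Duration of one simulation step in ms (default 1; fs = 1000 Hz).
#' @return An object of class `wl_params`.
#' @examples
#' p <- model_params(c2 = 2.6655, f = 0.01, g = 1e-4, neighborhood = "moore-8")
#' p
#' @seealso [waking_params()], [stability_max_coupling()]
#' @export
model_params <- function(c2 = 1, f = 0, g = 0,
                         neighborhood = c("von-neumann-4", "moore-8"),
                         boundary = c("clamped-edge", "torus"),
                         column_pitch_mm = 0.5, dt_ms = 1) {
  neighborhood <- match.arg(neighborhood)
  boundary <- match.arg(boundary)
  if (!is.numeric(c2) || length(c2) != 1L || !is.finite(c2) || c2 <= 0)
    stop("`c2` must be a single finite number > 0", call. = FALSE)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f < 0)
    stop("`f` must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g < 0)
    stop("`g` must be a single finite number >= 0", call. = FALSE)
  if (column_pitch_mm <= 0 || dt_ms <= 0)
    stop("`column_pitch_mm` and `dt_ms` must be > 0", call. = FALSE)
  structure(
    list(c2 = c2, f = f, g = g,
         neighborhood = neighborhood, boundary = boundary,
         column_pitch_mm = column_pitch_mm, dt_ms = dt_ms),
    class = "wl_params")
}

#' Waking-state parameters
#'
#' The printed waking-state calibration: `c2 = 2.6655`, `f = 0.01`,
#' `g = 0.0001`. This coupling sits just below the Moore-8 stability bound
#' `(2 + f)(2 + g) / 1.5` (about 2.6801; the undamped bound is 8/3), so the
#' preset pins the Moore-8 neighborhood -- under a 4-neighborhood the same
#' coupling would exceed the bound (2 when undamped) and diverge.
#'
#' The waking preset defaults to the periodic (torus) boundary: under
#' clamped edges the renormalized edge averaging stretches the operator
#' spectrum slightly past the bound and the printed coupling diverges
#' slowly, so the near-critical calibration is only meaningful on the
#' wrapped grid.
#'
#' @param boundary Boundary rule, `"torus"` by default (see Details).
#' @return A `wl_params` object.
#' @export
waking_params <- function(boundary = c("torus", "clamped-edge")) {
  model_params(c2 = 2.6655, f = 0.01, g = 1e-4,
               neighborhood = "moore-8", boundary = match.arg(boundary))
}

#' @export
print.wl_params <- function(x, ...) {
  d <- damping_deltas(x)
  cat("<wl_params>\n")
  cat(sprintf("  c2 = %g, f = %g, g = %g  (delta1 = %.4g, delta2 = %.4g)\n",
              x$c2, x$f, x$g, d$delta1, d$delta2))
  cat(sprintf("  %s, %s; pitch %g mm, dt %g ms (fs = %g Hz)\n",
              x$neighborhood, x$boundary, x$column_pitch_mm, x$dt_ms,
              1000 / x$dt_ms))
  invisible(x)
}

#' Damping factors delta1 = f/(1+f), delta2 = g/(1+g)
#'
#' The per-step fractional suppression of the lateral feedback and of the
#' activation. Both lie in `[0, 1)` for any `f, g >= 0`.
#'
#' @param params A `wl_params` object.
#' @return A list with `delta1`, `delta2` and `d = (1+f)(1+g)`.
#' @export
damping_deltas <- function(params) {
  stopifnot(inherits(params, "wl_params"))
  list(delta1 = params$f / (1 + params$f),
       delta2 = params$g / (1 + params$g),
       d = (1 + params$f) * (1 + params$g))
}

#' Sampling frequency implied by the step duration
#' @param params A `wl_params` object.
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(params) 1000 / params$dt_ms

neighbor_offsets <- function(neighborhood) {
  von4 <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (neighborhood == "von-neumann-4") return(von4)
  c(von4, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
}
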