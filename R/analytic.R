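#' Laplacian eigenvalues of the periodic lattice
#'
#' On a torus the grid Laplacian is diagonal in the discrete Fourier basis.
#' For mode indices `(kx, ky)` (0-based, angles `theta = 2*pi*k/n`) the
#' eigenvalue is
#' `mu = (cos(tx) + cos(ty))/2 - 1` for the 4-neighborhood (range `[-2, 0]`)
#' and `mu = (2 cos(tx) + 2 cos(ty) + 4 cos(tx) cos(ty))/8 - 1` for the
#' 8-neighborhood (range `[-1.5, 0]`).
#'
#' @param shape Grid shape `c(nx, ny)`.
#' @param neighborhood `"von-neumann-4"` or `"moore-8"`.
#' @return An `nx` by `ny` matrix of eigenvalues, indexed like the output of
#'   [stats::fft()] (mode `(kx, ky)` at entry `[kx + 1, ky + 1]`).
#' @export
mode_mu <- function(shape, neighborhood = c("von-neumann-4", "moore-8")) {
  neighborhood <- match.arg(neighborhood)
  nx <- shape[1]; ny <- shape[2]
  cx <- cos(2 * pi * (seq_len(nx) - 1) / nx)
  cy <- cos(2 * pi * (seq_len(ny) - 1) / ny)
  if (neighborhood == "von-neumann-4")
    outer(cx, cy, function(a, b) (a + b) / 2 - 1)
  else
    outer(cx, cy, function(a, b) (2 * a + 2 * b + 4 * a * b) / 8 - 1)
}

mu_min_of <- function(neighborhood)
  if (neighborhood == "von-neumann-4") -2 else -1.5

# Entries of the per-mode 2x2 transfer map acting on (A_k, Delta_k):
#   Delta' = (Delta + c2 * mu * A) / (1 + f)
#   A'     = (A + Delta') / (1 + g)
# Vectorized over mu. det = 1 / ((1+f)(1+g)) for every mode.
mode_map_entries <- function(mu, params) {
  f <- params$f; g <- params$g; c2 <- params$c2
  m21 <- c2 * mu / (1 + f)
  m22 <- 1 / (1 + f)
  m11 <- (1 + m21) / (1 + g)
  m12 <- 1 / ((1 + f) * (1 + g))
  list(m11 = m11, m12 = m12, m21 = m21, m22 = m22,
       tr = m11 + m22, det = m12) # det = m11*m22 - m12*m21 simplifies to m12
}

#' Per-mode 2x2 transfer map
#'
#' The linear map advancing a single spatial Fourier mode's `(A_k, Delta_k)`
#' pair by one step. Its eigenvalues `z` determine the mode's temporal
#' damping rate `lambda = -log|z|` and angular frequency `omega = |arg z|`
#' per step; the determinant is `1/((1+f)(1+g))` for every mode, so all
#' oscillatory modes share the same damping.
#'
#' @param mu Laplacian eigenvalue of the mode (scalar).
#' @param params A `wl_params`.
#' @return A 2x2 numeric matrix (rows/cols ordered `A`, `Delta`).
#' @export
mode_map <- function(mu, params) {
  e <- mode_map_entries(mu, params)
  matrix(c(e$m11, e$m21, e$m12, e$m22), 2, 2)
}

# complex eigenvalue pair of each mode map, vectorized over mu
mode_roots <- function(mu, params) {
  e <- mode_map_entries(mu, params)
  disc <- as.complex(e$tr^2 - 4 * e$det)
  sq <- sqrt(disc)
  list(zp = (e$tr + sq) / 2, zm = (e$tr - sq) / 2, entries = e)
}

#' Dispersion relation: damping and frequency per mode
#'
#' Tabulates, for every spatial Fourier mode of a periodic grid, the
#' Laplacian eigenvalue `mu`, the temporal damping rate `lambda` (per step),
#' the angular frequency `omega` (radians per step) and the corresponding
#' frequency in Hz. Modes whose transfer-map eigenvalues are real are flagged
#' `oscillatory = FALSE` and reported with `omega = 0` and their two decay
#' rates.
#'
#' @param params A `wl_params` (the boundary entry is ignored: the mode
#'   decomposition presumes a torus).
#' @param shape Grid shape `c(nx, ny)`.
#' @return A data frame with columns `kx_index`, `ky_index` (0-based), `mu`,
#'   `lambda`, `lambda2`, `omega_rad_per_step`, `freq_hz`, `oscillatory`.
#' @export
dispersion <- function(params, shape) {
  mu <- mode_mu(shape, params$neighborhood)
  r <- mode_roots(as.vector(mu), params)
  osc <- abs(Im(r$zp)) > 1e-12
  lam <- ifelse(Mod(r$zp) > 0, -log(Mod(r$zp)), Inf)
  lam2 <- ifelse(Mod(r$zm) > 0, -log(Mod(r$zm)), Inf)
  omega <- ifelse(osc, abs(Arg(r$zp)), 0)
  fs <- sampling_rate(params)
  data.frame(
    kx_index = rep(seq_len(shape[1]) - 1L, times = shape[2]),
    ky_index = rep(seq_len(shape[2]) - 1L, each = shape[1]),
    mu = as.vector(mu), lambda = lam, lambda2 = lam2,
    omega_rad_per_step = omega, freq_hz = omega / (2 * pi) * fs,
    oscillatory = osc)
}

#' Largest stable lateral feedback coupling
#'
#' The largest `c2` for which every mode's transfer map has spectral radius
#' at most 1. The binding constraint sits at the most negative Laplacian
#' eigenvalue `mu_min` where a real eigenvalue crosses -1, giving the closed
#' form
#' \deqn{c^2_{max} = (2 + f)(2 + g) / |\mu_{min}|,}
#' i.e. 2 for the undamped 4-neighborhood (`mu_min = -2`) and 8/3 for the
#' undamped 8-neighborhood (`mu_min = -1.5`). Damping enlarges the bound.
#' Couplings above it produce unbounded, seizure-like growth (a resonance
#' catastrophe) seeded by the shortest-wavelength modes.
#'
#' @param f,g Damping constants (>= 0).
#' @param neighborhood `"von-neumann-4"` or `"moore-8"`.
#' @return The bound (a single number).
#' @export
stability_max_coupling <- function(f = 0, g = 0,
                                   neighborhood = c("von-neumann-4", "moore-8")) {
  neighborhood <- match.arg(neighborhood)
  stopifnot(f >= 0, g >= 0)
  (2 + f) * (2 + g) / abs(mu_min_of(neighborhood))
}

#' Closed-form normal-mode solution coefficients
#'
#' Decomposes an initial state on a periodic grid into spatial Fourier modes
#' and returns, per mode, the damped-oscillation representation
#' `A_k(t) = exp(-lambda_k t) (p_k cos(omega_k t) + q_k sin(omega_k t))`
#' (for oscillatory modes; overdamped modes carry the two real roots
#' instead). The two-root coefficients `alpha, beta` with
#' `A_k(t) = alpha z_+^t + beta z_-^t` are always returned and are what
#' [evolve_analytic()] uses.
#'
#' @param state A `wl_state` on a torus-topology grid.
#' @param params A `wl_params`.
#' @return A list with the mode matrices `Ak0`, `Ak1`, roots `zp`, `zm`,
#'   coefficients `alpha`, `beta`, and the data frame `modes` from
#'   [dispersion()] augmented with `p_k`, `q_k`.
#' @export
mode_solution <- function(state, params) {
  shape <- state$shape
  mu <- mode_mu(shape, params$neighborhood)
  r <- mode_roots(as.vector(mu), params)
  Ak0 <- as.vector(stats::fft(state$A))
  Dk0 <- as.vector(stats::fft(state$Delta))
  e <- r$entries
  Ak1 <- e$m11 * Ak0 + e$m12 * Dk0
  dz <- r$zp - r$zm
  deg <- Mod(dz) < 1e-12
  alpha <- ifelse(deg, NA_complex_, (Ak1 - r$zm * Ak0) / dz)
  beta <- Ak0 - alpha
  tab <- dispersion(params, shape)
  rmod <- Mod(r$zp)
  p <- Ak0
  q <- ifelse(tab$oscillatory,
              (Ak1 / rmod - Ak0 * cos(tab$omega_rad_per_step)) /
                sin(pmax(tab$omega_rad_per_step, 1e-300)),
              NA_complex_)
  tab$p_k <- p; tab$q_k <- q
  list(Ak0 = Ak0, Ak1 = Ak1, zp = r$zp, zm = r$zm,
       alpha = alpha, beta = beta, degenerate = deg,
       entries = e, shape = shape, modes = tab)
}

# A_k(t) for every mode at integer t >= 0, from a mode_solution
mode_amplitude_at <- function(sol, t) {
  out <- sol$alpha * sol$zp^t + sol$beta * sol$zm^t
  if (any(sol$degenerate)) {
    i <- sol$degenerate
    z <- sol$zp[i]
    out[i] <- z^t * (sol$Ak0[i] + t * (sol$Ak1[i] / z - sol$Ak0[i]))
  }
  out
}

# Per-mode impulse response h_k(j) = [M^j]_{11}, j >= 1: the activation
# response at lag j to a unit injection into A. Vectorized over modes.
mode_impulse_response <- function(roots, j) {
  zp <- roots$zp; zm <- roots$zm; m11 <- roots$entries$m11
  dz <- zp - zm
  deg <- Mod(dz) < 1e-12
  a <- ifelse(deg, NA_complex_, (m11 - zm) / dz)
  b <- 1 - a
  out <- Re(a * zp^j + b * zm^j)
  if (any(deg)) {
    z <- zp[deg]
    out[deg] <- Re(z^j * (1 + j * (m11[deg] / z - 1)))
  }
  out
}

#' Exact evolution by normal-mode decomposition
#'
#' Evolves an initial state on a periodic grid analytically: each spatial
#' Fourier mode follows its closed-form damped oscillation, and a stimulus
#' (if given) adds the particular solution, accumulated per mode. This is
#' the independent oracle for the stepping simulation: the two must agree to
#' near machine precision on any torus grid.
#'
#' @param init A `wl_state` (torus presumed), or a shape for a zero state.
#' @param params A `wl_params`; `boundary` must be `"torus"`.
#' @param n_steps Number of steps.
#' @param stimulus Optional `wl_stimulus`, same timing convention as
#'   [run_model()] (injected before the step at each index).
#' @param times Integer vector of step indices (in `1:n_steps`) at which to
#'   return the activation field. Defaults to `n_steps` only. Without a
#'   stimulus any sparse set of times is cheap (closed form); with one, the
#'   particular solution is accumulated step-by-step in mode space.
#' @return A list: `A` (array `nx x ny x length(times)`), `times`, and the
#'   `mode_solution` of the initial state.
#' @export
evolve_analytic <- function(init, params, n_steps, stimulus = NULL,
                            times = NULL) {
  if (params$boundary != "torus")
    stop("the normal-mode solution requires `boundary = \"torus\"`", call. = FALSE)
  state <- if (inherits(init, "wl_state")) init else grid_state(init[1], init[2])
  shape <- state$shape
  if (is.null(times)) times <- n_steps
  times <- as.integer(times)
  stopifnot(all(times >= 1), all(times <= n_steps))
  sol <- mode_solution(state, params)
  N <- prod(shape)
  out <- array(NA_real_, c(shape, length(times)))

  if (is.null(stimulus)) {
    for (i in seq_along(times)) {
      Ak <- mode_amplitude_at(sol, times[i])
      out[, , i] <- Re(stats::fft(matrix(Ak, shape[1], shape[2]),
                                  inverse = TRUE)) / N
    }
  } else {
    # mode-space recursion: s_t = M (s_{t-1} + e1 v_t), vectorized over modes
    e <- sol$entries
    sampler <- stim_sampler(stimulus, shape, n_steps)
    Ak <- sol$Ak0
    Dk <- as.vector(stats::fft(state$Delta))
    ti <- 1L
    for (tt in seq_len(max(times))) {
      v <- sampler(tt)
      if (!is.null(v)) Ak <- Ak + as.vector(stats::fft(v))
      Dk_new <- e$m22 * Dk + e$m21 * Ak
      Ak <- e$m11 * Ak + e$m12 * Dk
      Dk <- Dk_new
      while (ti <= length(times) && times[ti] == tt) {
        out[, , ti] <- Re(stats::fft(matrix(Ak, shape[1], shape[2]),
                                     inverse = TRUE)) / N
        ti <- ti + 1L
      }
    }
  }
  list(A = out, times = times, solution = sol)
}
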