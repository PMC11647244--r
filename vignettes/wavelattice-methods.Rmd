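---
title: "The wavelattice model: dynamics, exact solution, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The wavelattice model: dynamics, exact solution, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavelattice)
```

## The model

`wavelattice` simulates a deliberately reductionistic neuronal field: a 2D
lattice of virtual oscillators, each standing for a cortical column of
500 µm, updated once per millisecond (fs = 1000 Hz). Each node carries an
activation $A(x,t)$ and a lateral-feedback accumulator $\Delta(x,t)$. One
update step is

1. grid Laplacian: $\Delta'(x) = \frac{1}{k}\sum_{n \in N(x)} (A_n - A_x)$,
   the average activation difference over the $k$ neighbors;
2. $\Delta \leftarrow (\Delta + c^2 \Delta')/(1+f)$;
3. $A \leftarrow (A + \Delta)/(1+g)$.

So the activation is the twice-integrated grid Laplacian — a discrete
damped wave equation. With $c^2 = 1$ and $f = g = 0$ the update reduces
bit-for-bit to the plain three-step algorithm. Stimuli are injected
additively into $A$ *before* the step at their time index; electrodes read
$A$ *after* the step.

The three constants are biologically interpretable: $c^2$ is an excitatory
transmission efficacy (it sets the frequency ceiling, wave speed and
stability), and $f, g$ are inhibition analogues damping the feedback and
the activation. Writing $\delta_1 = f/(1+f)$, $\delta_2 = g/(1+g)$,
$d = (1+f)(1+g)$, the per-node dynamics obey a second-order difference
equation whose damping is shared by all oscillatory modes:
$\lambda = \tfrac{1}{2}\log d \approx (f+g)/2$ per step, i.e. amplitude
decays on a $2/(f+g)$-step timescale and energy on $1/(f+g)$ steps.

## Exact solution by normal modes

On a periodic (torus) grid the Laplacian is diagonal in the spatial Fourier
basis. For mode indices $(k_x, k_y)$ with $\theta_i = 2\pi k_i/n_i$ the
eigenvalues are

* 4-neighborhood: $\mu = \tfrac{1}{2}(\cos\theta_x + \cos\theta_y) - 1 \in [-2, 0]$;
* 8-neighborhood: $\mu = \tfrac{1}{8}(2\cos\theta_x + 2\cos\theta_y +
  4\cos\theta_x\cos\theta_y) - 1 \in [-1.5, 0]$.

Each mode's $(A_k, \Delta_k)$ pair evolves by a $2\times2$ map with
determinant $1/d$; its eigenvalues $z_\pm = e^{-\lambda \pm i\omega_k}$ give
the damped oscillation
$A_k(t) = e^{-\lambda t}(p_k\cos\omega_k t + q_k\sin\omega_k t)$.
`dispersion()` tabulates $(\mu, \lambda, \omega, f)$ per mode (overdamped
modes are flagged and carry their two real decay rates), and
`evolve_analytic()` reconstructs full trajectories, including a particular
solution for arbitrary stimuli. This analytic engine is the package's
internal oracle: `run_model()` and `evolve_analytic()` agree to better than
$10^{-8}$ relative error on every torus grid, which is asserted in the test
suite.

### Stability

A real eigenvalue crosses $-1$ first at the most negative $\mu$, giving the
closed-form coupling bound

$$c^2_{\max} = \frac{(2+f)(2+g)}{|\mu_{\min}|},$$

i.e. 2 for the undamped 4-neighborhood and $8/3 \approx 2.667$ for the
undamped 8-neighborhood. Above the bound the shortest-wavelength modes grow
without limit — the seizure-like resonance catastrophe exercised by the
`seizure` preset.

### Why the waking calibration pins the 8-neighborhood torus

The waking calibration is $c^2 = 2.6655$, $f = 0.01$, $g = 10^{-4}$. Under
a 4-neighborhood this exceeds the bound (2.0101) and diverges; under the
8-neighborhood the bound is $(2.01)(2.0001)/1.5 \approx 2.6801$, so the
calibration sits 0.5 % below it — exactly the "coupling approaches its
maximum" regime that yields high-frequency processing up to the ~480 Hz
band edge. The boundary matters for the same reason: with clamped edges the
per-node renormalized averaging stretches the operator spectrum slightly
(numerically $\mu_{\min} \approx -1.5236$ on a Moore grid), past the
$|\mu| = 1.5082$ instability threshold of this coupling, and the lattice
diverges slowly. `waking_params()` therefore defaults to the wrapped
(torus) grid, where $\mu_{\min} = -1.5$ exactly. Smaller couplings run
fine under either boundary.

## Encoding and decoding by wave interference

Because the dynamics are linear and translation invariant, every spatial
mode of an input evolves independently — inputs become interference
patterns that superpose exactly, and the full frequency signature of every
input is readable at every node (the "holographic" property).

* **Static images.** For $v(x,t) = I(x)f(t)$, the snapshot at time
  $\bar t$ satisfies $A_k(\bar t) = s_k(\bar t) I_k$ with a known per-mode
  scalar $s_k(\bar t) = \sum_j h_k(j) f(\bar t - j + 1)$, $h_k(j) =
  [M^j]_{11}$. `decode_static_image()` divides the snapshot spectrum by
  $s_k$ and inverse-transforms; this is exact up to floating-point
  conditioning, so with weak damping ($f \sim g \sim 0.001$) images decode
  with $r > 0.999999$ even 10000+ steps after exposure, and decodes at
  different snapshot times agree. Modes whose $|s_k|$ falls under a
  relative threshold (default $10^{-12}$) are reported as ill-conditioned
  rather than amplified — the machine-precision failure mode of very late
  or pathological decodes.
* **Time-varying stimuli.** Per mode the output obeys
  $A_t = \mathrm{tr}\,A_{t-1} - \det A_{t-2} + m_{11} v_t - \det v_{t-1}$.
  `decode_dynamic()` computes the left side locally and unwinds for $v_t$.
  A subtlety: the forward recursion is numerically unstable wherever
  $|m_{11}| < \det$ (a non-minimum-phase deconvolution filter; rounding
  error grows geometrically). Those modes are unwound *backward*
  (anti-causally), which is stable; the backward pass assumes the stimulus
  has ended by the final sample, so callers should provide a short
  stimulus-free tail of output. With that convention round trips are exact
  to ~1e-14, including decimated outputs (stride > 1) for stimuli supported
  on the coarse time grid.
* **Audio.** `audio_roundtrip()` implements the inject/record protocol:
  a 1000 Hz waveform (3000 ms by default) enters at one node, three distant
  sites are recorded, and Hann STFTs (window 128) verify that the 0–500 Hz
  time–frequency structure survives. The bundled `make_synthetic_song()`
  fixture is a generated stand-in for real music — harmonic note stacks
  plus a chirp; its fundamentals stay at or below 440 Hz because the
  waking-state passband ends near 476 Hz (the $\mu = -1.5$ band edge), so
  near-Nyquist tones physically do not propagate.

## Virtual electrodes

An electrode covers every column whose center lies strictly within its
radius: unit = 0.25 mm (one column), LFP = 1 mm, EEG = 10 mm, grating EEG =
2.5 mm. The reading is the spatial **mean** over covered columns (a sum
option exists), so amplitudes are comparable across sizes; the mean of a
disc attenuates short-wavelength modes, which is why large electrodes mask
high-frequency activity and why low-frequency content is best read at
EEG scale. The suite asserts the exact averaging identity (big electrode =
mean of its unit recordings) and the checkerboard attenuation.

## Analysis suite: conventions that matter

* **Spectral peaks** (`fft_peaks`): Hann window, detection on the
  *unpadded* spectrum (zero-padding interpolates leakage skirts into
  spurious ripple maxima), threshold 5x the median magnitude (configurable)
  plus a -120 dB dynamic-range floor, and masking of candidates within 5 Hz
  of a >= 10x stronger peak (window sidelobes). Half-widths are half-power
  (-3 dB) widths interpolated on an 8x zero-padded spectrum; a pure line in
  a 3-s Hann window measures 0.48 Hz. The half-*magnitude* convention would
  read 0.67 Hz; the half-power convention matches the ~0.5 Hz figure the
  calibration targets.
* **Coherence**: hand-rolled Welch magnitude-squared coherence (Hann
  segments, 50 % overlap); for independent signals the estimator's bias is
  ~1/(number of segments), which the tests use as the null expectation.
* **Wave speed**: first crossing of 0.5 % of the source amplitude at a
  probe 50 mm away. (At 1 % the dispersed front of weakly coupled lattices
  peaks just *under* threshold at that distance.) Near the stability bound
  the measured front speed matches the analytic maximum group velocity
  within a few percent; at low coupling the threshold front lags the group
  velocity — that is dispersion, so the group-velocity assertion is made at
  high coupling and only monotonicity in $c^2$ is asserted across the sweep.
* **Correlation networks**: Pearson correlations over 3000 ms, edges at
  $r \ge \rho_+ = 0.07$. As $c^2$ grows, mean degree *falls* (HF-rich
  signals decorrelate in space) while the degree distribution becomes
  right-skewed; the "short-tailed to long-tailed" transition is therefore
  quantified by the skewness of $P(k)$.
* **Lempel–Ziv complexity**: median binarization then LZ76
  exhaustive-history phrase counting (Kaspar–Schuster convention;
  `0000000000` parses to 2 phrases, `0101010101` to 3), with the
  normalized variant $c\log_2 n/n$ for cross-length comparison. Constant
  signals are flagged degenerate.
* **Grating analysis**: trials cut half-open at $[-1, 2)$ s around each
  onset; sliding Hann 50 ms windows in 1 ms steps at 20–500 Hz in 20 Hz
  steps; *induced* power averages single-trial power, *evoked* power is the
  power of the time-domain trial average; relative baseline correction
  against $[-0.25, -0.1]$ s; the HF envelope averages 250–450 Hz and is
  frequency-demodulated (Hann, zero-padded to 3 s) separately for the
  prestimulus ($[-0.6, -0.1]$ s) and poststimulus ($[-0.1, 0.4]$ s)
  windows. One analysis caveat the tests encode: a sinusoidal *amplitude*
  modulation of a carrier demodulates at twice its frequency after
  band-averaged *power* envelope extraction (the linear beat terms cancel
  across sidebands), so the oracle fixture modulates carrier power.

## State presets

`waking` is the printed calibration; the others are documented
approximations relative to it (exact non-waking values are not printed):
`sws` halves $c^2$ (resonance drops to the low-frequency band),
`anesthesia` multiplies $f$ by 10 and $g$ by 100, `alzheimer` adds a random
lesion mask, `schizophrenia` adds symmetric per-edge coupling jitter
($w_e = 1 - m\,u_e$, $u_e \sim U(0,1)$, shared by both edge directions),
and `seizure` sets $c^2$ 5 % above the stability bound. `compare_states()`
drives all states with one seed-shared complex-burst fixture (50 events of
a 5 Hz wave segment carrying a 300 Hz burst, random nodes and onsets) and
records through an LFP-scale electrode — at unit scale the waking and SWS
binarized sequences are about equally complex, while at the 1 mm scale the
expected ordering (waking > SWS, waking > anesthesia) is clear.

### Lesions: absorbing, not excised

Two lesion semantics are implemented. *Excised* nodes are removed from the
neighbor averages and survivors renormalize to their live-neighbor count;
*absorbing* nodes are clamped to zero but still count. Excision looks more
physiological, but renormalization stretches the local operator spectrum
the same way clamped edges do — at the near-critical waking coupling even a
4 % excised lesion field diverges. Absorbing lesions are provably stable
(the live-node operator is a principal submatrix of the intact one, so its
spectrum interlaces). The lesion experiments and the `alzheimer` preset
therefore use absorbing lesions; `lesion_mask()` still defaults to
`"excise"` for use away from the stability edge (where e.g. the
isolated-node decay identity holds exactly).

A second measured fact shapes the lesion-robustness protocol: absorbing
lesions pin the field at random points, which removes the *long-wavelength*
modes first — so low-frequency (7–50 Hz) fundamentals stop being decodable
almost immediately, while the waking state's high-frequency information
band is robust. The robustness experiment therefore injects pulse trains at
eight fundamentals spanning 53–401 Hz and reads out at two distant sites
(any node carries the pattern) at three electrode scales. Under that
protocol every fundamental stays detectable through 4 % lesions in all
seeds, and a majority of fundamentals through 30 %.

## What the synthetic fixtures do and do not show

All inputs are generated in code: pulse trains (accumulated-phase
scheduling keeps non-integer periods exact — a 7 Hz train over 3 s carries
exactly 21 pulses), sinusoids, dense white noise, the stripe grating
(eight equal-width bars at +10/−9 mV clipped to a 10 mm disc; stripe width
and orientation are conventions, and no result asserted here depends on
them), complex bursts, random grey images, and the synthetic song. They
emulate the *protocols* of the original experiments, not real sensory
statistics: passing tests show that the lattice's encoding, spectral,
coherence and complexity behavior is as derived, not that any biological
tissue behaves this way, and the in vivo comparisons that motivated the
model are outside this package's scope (no animal data are consumed).

## Numerical choices

Double precision throughout; instability is detected by a non-finite check
every 25 steps plus a $10^{100}$ magnitude guard (runaway growth is caught
long before overflow) and raised as a classed condition carrying the step
index. Deconvolution floors divisors at $10^{-12}$ of their maximum and
flags affected modes. Dense histories are refused above ~2 GB; electrode
recording is the intended long-run memory contract. Every stochastic
element (noise, lesions, jitter, burst placement, random images) takes an
explicit seed and is reproducible from it; noise stimuli keep a private RNG
stream so runs do not disturb the caller's RNG state.

## Problem sizes

The test suite runs the full 150×150 waking lattice for the 3-s spectral
experiments and a 12-trial (36 s) grating session; state comparisons and
coherence use 60–80² grids. The acceptance script
(`scripts/acceptance.R`) uses the full protocol sizes — a 150×150 grid for
capacity, ceiling, and the 45-run lesion scan, and 64×64 for the 12-s
image-recoverability sweep — and completes in about two minutes on one CPU.
These are the package's chosen desk-scale study conditions; all analytic
results are size-independent and the stepping engine handles larger grids
linearly in nodes × steps.

## Known limitations

The model is linear: all "nonlinear" phenomenology (resonance catastrophe,
state transitions) comes from parameter changes, not from the dynamics
itself; there is no plasticity, no learning, no explicit memory, and no
biological decoding layer (decoding is Fourier inversion). The analytic
engine requires the torus; clamped-edge grids are simulated only. Disease
presets are qualitative regimes, not clinical models.
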