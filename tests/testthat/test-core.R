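test_that("grid Laplacian matches direct definitions", {
  p <- model_params()
  # constant field has no gradients
  st <- grid_state(5, 6, A = 3.7, Delta = 2)
  expect_equal(grid_laplacian(st, p), matrix(0, 5, 6))
  # degenerate clamped topology (an isolated node has no neighbors)
  expect_error(grid_laplacian(grid_state(1, 1), p), "degenerate")
  # 1D two-node chain: each node has one neighbor
  st2 <- grid_state(2, 1, A = matrix(c(1, 0), 2, 1))
  expect_equal(grid_laplacian(st2, p), matrix(c(-1, 1), 2, 1))
  # torus Fourier mode is an eigenvector, eigenvalue checked against the
  # dense matrix oracle
  for (nb in c("von-neumann-4", "moore-8")) {
    pt <- model_params(neighborhood = nb, boundary = "torus")
    nx <- 8; ny <- 6
    A <- outer(cos(2 * pi * 2 * (0:(nx - 1)) / nx), rep(1, ny))
    st <- grid_state(nx, ny, A = A)
    lap <- grid_laplacian(st, pt)
    M <- dense_torus_operator(nx, ny, nb)
    expect_equal(as.vector(lap), as.vector(M %*% as.vector(A)),
                 tolerance = 1e-12)
    # eigenvalue read off the mode table
    mu <- mode_mu(c(nx, ny), nb)[3, 1]
    expect_equal(lap, mu * A, tolerance = 1e-12)
  }
})

test_that("one step equals the literal loop transcription of the update", {
  set.seed(11)
  for (nb in c("von-neumann-4", "moore-8")) {
    for (bd in c("clamped-edge", "torus")) {
      p <- model_params(c2 = 1.7, f = 0.03, g = 0.002, neighborhood = nb,
                        boundary = bd)
      A <- matrix(rnorm(64), 8, 8); D <- matrix(rnorm(64), 8, 8)
      st <- step_lattice(grid_state(8, 8, A = A, Delta = D), p)
      ref <- naive_step(A, D, p$c2, p$f, p$g, nb, bd)
      expect_equal(st$A, ref$A, tolerance = 1e-14)
      expect_equal(st$Delta, ref$Delta, tolerance = 1e-14)
      expect_equal(st$t, 1L)
    }
  }
})

test_that("modulated update with c2=1, f=g=0 reduces to the plain algorithm", {
  # bit-for-bit on integer-valued fields: steps 2-5 become exact identities
  p <- model_params(c2 = 1, f = 0, g = 0, boundary = "torus")
  A <- matrix(c(4, 0, 0, 0), 2, 2) # integer multiples of k keep /k exact
  st <- grid_state(2, 2, A = A)
  st1 <- step_lattice(st, p)
  # manual Eq: lap = mean(neighbors) - A; Delta = lap; A = A + Delta
  lap <- grid_laplacian(st, p)
  expect_identical(st1$Delta, lap)
  expect_identical(st1$A, A + lap)
})

test_that("two-node chain with unit coupling oscillates with period 4", {
  # 1D two-node chain, A0 = (1, 0), Delta0 = 0: worked by hand from the
  # three plain update steps
  p <- model_params(c2 = 1, f = 0, g = 0)
  st <- grid_state(2, 1, A = matrix(c(1, 0), 2, 1))
  traj <- list()
  for (i in 1:8) { st <- step_lattice(st, p); traj[[i]] <- as.vector(st$A) }
  expect_equal(traj[[1]], c(0, 1))
  expect_equal(traj[[2]], c(0, 1))
  expect_equal(traj[[3]], c(1, 0))
  expect_equal(traj[[4]], c(1, 0))
  for (i in 1:4) expect_equal(traj[[i + 4]], traj[[i]])
})

test_that("uniform field with zero feedback is a fixed point", {
  p <- model_params(c2 = 2, f = 0, g = 0, boundary = "torus")
  st <- grid_state(6, 6, A = 1.5)
  st2 <- run_model(st, p, 20, keep_history = TRUE)
  expect_true(all(st2$history == 1.5))
})

test_that("injection is additive and the response is linear in the stimulus", {
  set.seed(21)
  p <- model_params(c2 = 1.4, f = 0.01, g = 0.001, boundary = "torus")
  st <- grid_state(8, 8)
  v1 <- matrix(rnorm(64), 8, 8); v2 <- matrix(rnorm(64), 8, 8)
  expect_equal(inject(st, matrix(0, 8, 8)), st)
  expect_equal(inject(inject(st, v1), v2), inject(st, v1 + v2))
  expect_error(inject(st, matrix(0, 4, 4)), "shape")
  # superposition across a full run, and exact doubling
  run <- function(v) run_model(c(8, 8), p, 30,
                               stimulus_dense(array(v, c(8, 8, 1))),
                               keep_history = TRUE)$history
  h1 <- run(v1); h2 <- run(v2); h12 <- run(v1 + v2); hd <- run(2 * v1)
  expect_equal(h12, h1 + h2, tolerance = 1e-13)
  expect_equal(hd, 2 * h1, tolerance = 1e-14)
})

test_that("total activation is conserved on an undamped torus", {
  set.seed(31)
  for (nb in c("von-neumann-4", "moore-8")) {
    p <- model_params(c2 = 1.3, f = 0, g = 0, neighborhood = nb,
                      boundary = "torus")
    A0 <- matrix(rnorm(100), 10, 10)
    run <- run_model(grid_state(10, 10, A = A0), p, 100, keep_history = TRUE)
    sums <- apply(run$history, 3, sum)
    expect_equal(sums, rep(sum(A0), 100), tolerance = 1e-11)
  }
})

test_that("lesion masks hit the requested fraction and honor protection", {
  les <- lesion_mask(c(20, 20), 0.1, seed = 4, protect = list(c(1, 1), c(5, 5)))
  expect_equal(sum(les$inactive), 40)
  expect_false(les$inactive[1, 1])
  expect_false(les$inactive[5, 5])
  expect_lte(abs(mean(les$inactive) - 0.1), 1 / 400)
  # reproducible from the seed
  les2 <- lesion_mask(c(20, 20), 0.1, seed = 4, protect = list(c(1, 1), c(5, 5)))
  expect_identical(les$inactive, les2$inactive)
  expect_error(lesion_mask(c(4, 4), 1), "fraction")
})

test_that("fraction-zero lesion leaves the trajectory unchanged", {
  set.seed(41)
  p <- model_params(c2 = 1.2, f = 0.01, g = 0.001)
  A0 <- matrix(rnorm(36), 6, 6)
  les0 <- lesion_mask(c(6, 6), 0, seed = 1)
  r1 <- run_model(grid_state(6, 6, A = A0), p, 40, keep_history = TRUE)
  r2 <- run_model(grid_state(6, 6, A = A0), p, 40, lesion = les0,
                  keep_history = TRUE)
  expect_identical(r1$history, r2$history)
})

test_that("a fully isolated node decays geometrically by 1/(1+g)", {
  # excising every neighbor leaves lap = 0: A just shrinks by the damping
  p <- model_params(c2 = 1, f = 0.02, g = 0.05)
  inact <- matrix(FALSE, 5, 5); inact[2:4, 2:4] <- TRUE; inact[3, 3] <- FALSE
  les <- structure(list(inactive = inact, fraction = mean(inact), seed = 1L,
                        mode = "excise"), class = "wl_lesion")
  st <- grid_state(5, 5); st$A[3, 3] <- 1
  run <- run_model(st, p, 12, lesion = les, record_nodes = list(c(3, 3)))
  expect_equal(run$node_recordings[, 1], 1 / 1.05^(1:12), tolerance = 1e-13)
})

test_that("lesioned stepping matches the naive loop oracle in both modes", {
  set.seed(51)
  p <- model_params(c2 = 1.5, f = 0.02, g = 0.01, neighborhood = "moore-8")
  A <- matrix(rnorm(64), 8, 8); D <- matrix(rnorm(64), 8, 8)
  les <- lesion_mask(c(8, 8), 0.2, seed = 9)
  # excise: oracle excludes lesioned nodes from both sides
  st <- grid_state(8, 8, A = A * !les$inactive, Delta = D * !les$inactive)
  got <- run_model(st, p, 5, lesion = les, keep_history = TRUE)
  ref <- run_naive(st$A, st$Delta, p, 5, inactive = les$inactive)
  expect_equal(got$history[, , 5], ref$A, tolerance = 1e-13)
  # absorb: lesioned nodes clamp to zero but still count in the averages
  les$mode <- "absorb"
  got2 <- run_model(st, p, 5, lesion = les, keep_history = TRUE)
  ref2 <- list(A = st$A, Delta = st$Delta)
  for (s in 1:5) {
    r <- naive_step(ref2$A, ref2$Delta, p$c2, p$f, p$g, p$neighborhood,
                    p$boundary)
    r$A[les$inactive] <- 0; r$Delta[les$inactive] <- 0
    ref2 <- r
  }
  expect_equal(got2$history[, , 5], ref2$A, tolerance = 1e-13)
})

test_that("per-edge jitter is symmetric and matches a weighted-loop oracle", {
  set.seed(61)
  jit <- edge_jitter(c(8, 8), 0.5, seed = 7, neighborhood = "moore-8")
  p <- model_params(c2 = 1.5, f = 0.01, g = 0.001, neighborhood = "moore-8")
  A <- matrix(rnorm(64), 8, 8); D <- matrix(rnorm(64), 8, 8)
  # look up the shared weight of an (unordered) edge from the jitter object
  wfun <- function(from, to) {
    d <- to - from
    for (i in seq_along(jit$dirs)) {
      if (all(jit$dirs[[i]] == d)) return(jit$weights[[i]][from[1], from[2]])
      if (all(jit$dirs[[i]] == -d)) return(jit$weights[[i]][to[1], to[2]])
    }
    stop("unknown direction")
  }
  ref <- naive_step(A, D, p$c2, p$f, p$g, p$neighborhood, "clamped-edge",
                    weights = wfun)
  got <- step_lattice(grid_state(8, 8, A = A, Delta = D), p, jitter = jit)
  expect_equal(got$A, ref$A, tolerance = 1e-12)
})

test_that("zero initial state and stimulus give an identically zero run", {
  p <- model_params()
  run <- run_model(c(6, 6), p, 25, keep_history = TRUE)
  expect_true(all(run$history == 0))
})

test_that("runs are deterministic, including seeded noise stimuli", {
  p <- model_params(c2 = 1.2, boundary = "torus")
  noise <- make_noise(sd = 1, seed = 99, n_steps = 30)
  r1 <- run_model(c(6, 6), p, 30, noise, keep_history = TRUE)
  r2 <- run_model(c(6, 6), p, 30, noise, keep_history = TRUE)
  expect_identical(r1$history, r2$history)
})

test_that("unstable couplings raise an instability error with a step index", {
  p <- model_params(c2 = 2.6, f = 0, g = 0, boundary = "torus") # bound = 2
  st <- grid_state(8, 8); st$A[4, 4] <- 1
  err <- tryCatch(run_model(st, p, 2000), wl_instability = function(e) e)
  expect_s3_class(err, "wl_instability")
  expect_true(err$step > 0)
})

test_that("impulse energy decays on the 1/(f+g) timescale for weak damping", {
  p <- model_params(c2 = 1, f = 0.001, g = 0.001, boundary = "torus")
  run <- run_model(grid_state(24, 24, A = {
    A <- matrix(0, 24, 24); A[12, 12] <- 5; A
  }), p, 1200, keep_history = TRUE)
  E <- apply(run$history, 3, function(m) sum(m^2))
  fit <- stats::lm(log(E[200:1200]) ~ seq(200, 1200))
  tau <- -1 / stats::coef(fit)[[2]]
  expect_equal(tau, 500, tolerance = 0.05)
})
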