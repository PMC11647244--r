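# Independent oracles used across the suite.

# Literal per-node transcription of the five modulated update steps,
# intentionally loop-based and independent of the package's vectorized path.
naive_step <- function(A, Delta, c2, f, g, neighborhood, boundary,
                       inactive = NULL, weights = NULL) {
  nx <- nrow(A); ny <- ncol(A)
  offs <- if (neighborhood == "von-neumann-4") {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  } else {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
         c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  }
  dprime <- matrix(0, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (!is.null(inactive) && inactive[i, j]) next
    acc <- 0; k <- 0
    for (d in offs) {
      ii <- i + d[1]; jj <- j + d[2]
      if (boundary == "torus") {
        ii <- ((ii - 1) %% nx) + 1; jj <- ((jj - 1) %% ny) + 1
      } else if (ii < 1 || ii > nx || jj < 1 || jj > ny) next
      if (!is.null(inactive) && inactive[ii, jj]) next
      w <- if (is.null(weights)) 1 else weights(c(i, j), c(ii, jj))
      acc <- acc + w * (A[ii, jj] - A[i, j])
      k <- k + 1
    }
    if (k > 0) dprime[i, j] <- acc / k
  }
  Delta <- (Delta + c2 * dprime) / (1 + f)
  A <- (A + Delta) / (1 + g)
  if (!is.null(inactive)) { A[inactive] <- 0; Delta[inactive] <- 0 }
  list(A = A, Delta = Delta)
}

# Dense normalized adjacency-minus-identity operator on a torus, as a matrix
# (column-major node order), for the Laplacian eigenvalue oracle.
dense_torus_operator <- function(nx, ny, neighborhood) {
  offs <- if (neighborhood == "von-neumann-4") {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  } else {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
         c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  }
  N <- nx * ny
  M <- matrix(0, N, N)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    me <- (j - 1) * nx + i
    for (d in offs) {
      ii <- ((i + d[1] - 1) %% nx) + 1
      jj <- ((j + d[2] - 1) %% ny) + 1
      M[me, (jj - 1) * nx + ii] <- M[me, (jj - 1) * nx + ii] + 1 / length(offs)
    }
    M[me, me] <- M[me, me] - 1
  }
  M
}

run_naive <- function(A, Delta, params, n_steps, inactive = NULL) {
  for (s in seq_len(n_steps)) {
    st <- naive_step(A, Delta, params$c2, params$f, params$g,
                     params$neighborhood, params$boundary, inactive)
    A <- st$A; Delta <- st$Delta
  }
  list(A = A, Delta = Delta)
}
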