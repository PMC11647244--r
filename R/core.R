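#' Lattice state: activation and lateral-feedback fields
#'
#' A `wl_state` holds the paired fields of the model: the activation `A(x)`
#' (membrane-potential-like, arbitrary mV-scale units) and the lateral
#' feedback `Delta(x)` -- the running time-integral of the grid Laplacian --
#' on an `nx` by `ny` grid of columns, plus the integer step counter `t`.
#'
#' @param nx,ny Grid dimensions in columns.
#' @param A Initial activation: a scalar or an `nx` by `ny` matrix.
#' @param Delta Initial lateral feedback, same shape rules as `A`.
#' @param t Initial step counter (default 0).
#' @return An object of class `wl_state`.
#' @export
grid_state <- function(nx, ny = nx, A = 0, Delta = 0, t = 0L) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 1L || ny < 1L) stop("grid dimensions must be >= 1", call. = FALSE)
  as_field <- function(v, what) {
    if (is.matrix(v)) {
      if (!all(dim(v) == c(nx, ny)))
        stop(sprintf("`%s` must be %d x %d", what, nx, ny), call. = FALSE)
      storage.mode(v) <- "double"
      v
    } else matrix(as.double(v), nx, ny)
  }
  A <- as_field(A, "A"); Delta <- as_field(Delta, "Delta")
  if (!all(is.finite(A)) || !all(is.finite(Delta)))
    stop("initial fields must be finite", call. = FALSE)
  if (t < 0) stop("`t` must be >= 0", call. = FALSE)
  structure(list(A = A, Delta = Delta, t = as.integer(t),
                 shape = c(nx, ny)), class = "wl_state")
}

#' @export
print.wl_state <- function(x, ...) {
  cat(sprintf("<wl_state> %d x %d columns, t = %d\n", x$shape[1], x$shape[2], x$t))
  cat(sprintf("  range(A) = [%.4g, %.4g], range(Delta) = [%.4g, %.4g]\n",
              min(x$A), max(x$A), min(x$Delta), max(x$Delta)))
  invisible(x)
}

# Shifted copy of A: out[i, j] = A[i + di, j + dj]; zero fill off the edge
# under clamped boundaries, wrap-around on the torus.
shift_field <- function(A, di, dj, torus) {
  n <- nrow(A); m <- ncol(A)
  ri <- seq_len(n) + di; ci <- seq_len(m) + dj
  if (torus) {
    A[((ri - 1L) %% n) + 1L, ((ci - 1L) %% m) + 1L, drop = FALSE]
  } else {
    out <- matrix(0, n, m)
    vr <- ri >= 1L & ri <= n; vc <- ci >= 1L & ci <= m
    if (any(vr) && any(vc)) out[vr, vc] <- A[ri[vr], ci[vc], drop = FALSE]
    out
  }
}

#' Random lesion mask
#'
#' Marks a random fraction of columns as inactive. Lesioned nodes are held at
#' `A = 0`, `Delta = 0` and are excised from every neighbor average: a
#' surviving node averages over its live neighbors only (its effective
#' neighbor count shrinks). The number of lesioned nodes is
#' `round(fraction * nx * ny)`, so the realized fraction matches the request
#' to within one node.
#'
#' @param shape Grid shape `c(nx, ny)`.
#' @param fraction Fraction of columns to inactivate, in `[0, 1)`.
#' @param seed Integer seed; the mask is reproducible from `(shape, fraction,
#'   seed, protect)`.
#' @param protect Optional matrix or list of nodes (rows `c(i, j)`, 1-based)
#'   that are never lesioned, e.g. a stimulation and a recording site.
#' @param mode `"excise"` (default: live neighbors renormalize to their live
#'   neighbor count) or `"absorb"` (lesioned nodes clamp to zero but still
#'   count in the averages of their neighbors).
#' @return An object of class `wl_lesion`.
#' @export
lesion_mask <- function(shape, fraction, seed = 1L, protect = NULL,
                        mode = c("excise", "absorb")) {
  mode <- match.arg(mode)
  nx <- shape[1]; ny <- shape[2]; n <- nx * ny
  if (fraction < 0 || fraction >= 1)
    stop("`fraction` must be in [0, 1); fraction = 1 leaves no live nodes",
         call. = FALSE)
  keep <- integer(0)
  if (!is.null(protect)) {
    if (is.list(protect)) protect <- do.call(rbind, protect)
    protect <- matrix(as.integer(protect), ncol = 2)
    keep <- (protect[, 2] - 1L) * nx + protect[, 1]
  }
  n_lesion <- round(fraction * n)
  pool <- setdiff(seq_len(n), keep)
  if (n_lesion > length(pool))
    stop("too few unprotected nodes for the requested fraction", call. = FALSE)
  inactive <- matrix(FALSE, nx, ny)
  if (n_lesion > 0) {
    idx <- withr_seed(seed, sample(pool, n_lesion))
    inactive[idx] <- TRUE
  }
  structure(list(inactive = inactive, fraction = fraction, seed = seed,
                 mode = mode), class = "wl_lesion")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Per-edge coupling jitter
#'
#' Symmetric multiplicative factors on each neighbor pair's contribution to
#' the grid Laplacian, used by the jittered-coupling ("schizophrenia")
#' preset: each lattice edge weight is drawn once as `1 - magnitude * u`,
#' `u ~ U(0, 1)`, shared by both directions of the edge.
#'
#' @param shape Grid shape `c(nx, ny)`.
#' @param magnitude Maximal fractional impairment of an edge, in `[0, 1]`.
#' @param seed Integer seed.
#' @param neighborhood Neighborhood the weights are generated for.
#' @return An object of class `wl_edge_jitter`: one weight matrix per
#'   canonical edge direction.
#' @export
edge_jitter <- function(shape, magnitude, seed = 1L,
                        neighborhood = c("von-neumann-4", "moore-8")) {
  neighborhood <- match.arg(neighborhood)
  stopifnot(magnitude >= 0, magnitude <= 1)
  nx <- shape[1]; ny <- shape[2]
  dirs <- list(c(1L, 0L), c(0L, 1L))
  if (neighborhood == "moore-8") dirs <- c(dirs, list(c(1L, 1L), c(1L, -1L)))
  w <- withr_seed(seed, lapply(dirs, function(d)
    matrix(1 - magnitude * stats::runif(nx * ny), nx, ny)))
  names(w) <- vapply(dirs, function(d) paste(d, collapse = ","), "")
  structure(list(weights = w, dirs = dirs, magnitude = magnitude,
                 seed = seed, neighborhood = neighborhood),
            class = "wl_edge_jitter")
}

# Build the grid-Laplacian operator as a closure. Handles all four
# topology combinations plus lesion excision and per-edge weights.
#
# For node x with k live neighbors, lap(A)[x] = (1/k) * sum_n w_n (A_n - A_x);
# k is the unweighted live-neighbor count. Nodes with no live neighbor get 0.
build_laplacian <- function(shape, params, lesion = NULL, jitter = NULL) {
  nx <- shape[1]; ny <- shape[2]
  torus <- params$boundary == "torus"
  if (!torus && nx < 2L && ny < 2L)
    stop("degenerate topology: a clamped-edge grid needs at least 2 nodes",
         call. = FALSE)
  offs <- neighbor_offsets(params$neighborhood)
  excise <- !is.null(lesion) && lesion$mode == "excise" && any(lesion$inactive)
  live <- if (excise) 1 - lesion$inactive else NULL

  # per-offset effective weight matrices W[i,j] = weight of the edge from
  # (i,j) to (i+di, j+dj); zero where the edge does not exist or the
  # neighbor is excised
  weights <- NULL
  if (!is.null(jitter)) {
    if (jitter$neighborhood != params$neighborhood)
      stop("edge jitter was generated for a different neighborhood", call. = FALSE)
    weights <- lapply(offs, function(d) {
      hit <- vapply(jitter$dirs, function(cd) all(cd == d), logical(1))
      if (any(hit)) jitter$weights[[which(hit)]]
      else { # opposite direction: weight of edge (x, x+d) lives at x+d
        hit <- vapply(jitter$dirs, function(cd) all(cd == -d), logical(1))
        shift_field(jitter$weights[[which(hit)]], d[1], d[2], torus = TRUE)
      }
    })
  }

  plain <- is.null(weights) && !excise
  ones <- matrix(1, nx, ny)
  exist <- lapply(offs, function(d) shift_field(ones, d[1], d[2], torus))
  if (excise) {
    live_n <- lapply(offs, function(d) shift_field(live, d[1], d[2], torus))
    exist <- Map(`*`, exist, live_n)
  }
  K <- Reduce(`+`, exist)            # live-neighbor count per node
  Ksafe <- pmax(K, 1)
  if (plain && torus) {
    k <- length(offs)
    dlist <- offs
    return(function(A) {
      S <- shift_field(A, dlist[[1]][1], dlist[[1]][2], TRUE)
      for (i in 2:k) S <- S + shift_field(A, dlist[[i]][1], dlist[[i]][2], TRUE)
      S / k - A
    })
  }
  if (plain) {
    return(function(A) {
      S <- 0
      for (d in offs) S <- S + shift_field(A, d[1], d[2], FALSE)
      out <- S / Ksafe - A
      if (any(K == 0)) out[K == 0] <- 0
      out
    })
  }
  # weighted / excised general path
  W <- if (is.null(weights)) exist else Map(`*`, weights, exist)
  WS <- Reduce(`+`, W)               # sum of live weights per node
  inact <- if (excise) lesion$inactive else NULL
  function(A) {
    S <- 0
    for (i in seq_along(offs))
      S <- S + W[[i]] * shift_field(A, offs[[i]][1], offs[[i]][2], torus)
    out <- (S - A * WS) / Ksafe
    if (any(K == 0)) out[K == 0] <- 0
    if (!is.null(inact)) out[inact] <- 0
    out
  }
}

#' Grid Laplacian of the activation field
#'
#' The average activation difference at each node: `(1/k) * sum over
#' neighbors (A_neighbor - A_node)`, with `k` the node's actual neighbor
#' count under the boundary rule. Under an excising lesion, inactive nodes
#' are removed from both sides of every average.
#'
#' @param state A `wl_state`.
#' @param params A `wl_params`.
#' @param lesion Optional `wl_lesion`.
#' @param jitter Optional `wl_edge_jitter`.
#' @return A numeric matrix, same shape as the grid.
#' @export
grid_laplacian <- function(state, params, lesion = NULL, jitter = NULL) {
  lap <- build_laplacian(state$shape, params, lesion, jitter)
  lap(state$A)
}

#' Advance the lattice by one step
#'
#' One pass of the modulated update: the grid Laplacian is accumulated into
#' the lateral feedback with gain `c2`, the feedback is damped by `1/(1+f)`,
#' added to the activation, and the activation is damped by `1/(1+g)`:
#' \deqn{\Delta \leftarrow (\Delta + c^2 \Delta')/(1+f), \quad
#'       A \leftarrow (A + \Delta)/(1+g).}
#' With `c2 = 1` and `f = g = 0` this reduces exactly (bit-for-bit) to the
#' unmodulated three-step algorithm.
#'
#' @inheritParams grid_laplacian
#' @param check Check for non-finite values after the step (default TRUE);
#'   a failure signals an error of class `wl_instability` carrying the step
#'   index.
#' @return The advanced `wl_state`.
#' @export
step_lattice <- function(state, params, lesion = NULL, jitter = NULL,
                         check = TRUE) {
  lap <- build_laplacian(state$shape, params, lesion, jitter)
  st <- step_with(state, params, lap, lesion)
  if (check && !all(is.finite(st$A)))
    stop_instability(st$t)
  st
}

# hot loop body: `lap` prebuilt, no validation
step_with <- function(state, params, lap, lesion = NULL) {
  dprime <- lap(state$A)
  Delta <- (state$Delta + params$c2 * dprime) / (1 + params$f)
  A <- (state$A + Delta) / (1 + params$g)
  if (!is.null(lesion) && any(lesion$inactive)) {
    A[lesion$inactive] <- 0
    Delta[lesion$inactive] <- 0
  }
  state$A <- A; state$Delta <- Delta; state$t <- state$t + 1L
  state
}

stop_instability <- function(step) {
  stop(structure(class = c("wl_instability", "error", "condition"),
                 list(message = sprintf(
                   "non-finite activation at step %d: unstable parameter regime (c2 above the stability bound?)", step),
                   call = NULL, step = step)))
}

#' Inject a stimulus field into the activation
#'
#' Adds `v` to the activation field, leaving the lateral feedback unchanged.
#' In [run_model()] injection happens strictly *before* the step at the same
#' time index; electrode sampling reads the activation after the step.
#'
#' @param state A `wl_state`.
#' @param v A numeric matrix matching the grid shape.
#' @return The modified `wl_state`.
#' @export
inject <- function(state, v) {
  if (!is.matrix(v) || !all(dim(v) == state$shape))
    stop("stimulus field shape does not match the grid", call. = FALSE)
  state$A <- state$A + v
  state
}

#' Run the model for many steps
#'
#' Advances the lattice `n_steps` times, injecting the stimulus before each
#' step and sampling any electrodes after it. The trajectory is deterministic
#' given the initial state, parameters, stimulus (and its seed) and lesion
#' mask. By default only electrode/node recordings are kept; the dense
#' history `A(x, t)` is stored only on request (memory grows as
#' `nx * ny * n_steps` doubles).
#'
#' @param init A `wl_state`, or a shape `c(nx, ny)` for a zero initial state.
#' @param params A `wl_params`.
#' @param n_steps Number of steps (>= 1).
#' @param stimulus Optional `wl_stimulus` (see e.g. [make_pulse_train()]).
#' @param lesion Optional `wl_lesion`.
#' @param jitter Optional `wl_edge_jitter`.
#' @param electrodes Optional list of [electrode()] objects to record from.
#' @param record_nodes Optional matrix/list of nodes `c(i, j)` to record raw
#'   single-column traces from.
#' @param keep_history Keep the dense `A` history (array `nx x ny x n_steps`)?
#' @param sample_mode `"mean"` (default) or `"sum"` over an electrode's nodes.
#' @return A list of class `wl_run`: `state` (final), `recordings` (matrix
#'   `n_steps x n_electrodes`), `node_recordings`, `history` (or NULL),
#'   `params`, `n_steps`.
#' @export
run_model <- function(init, params, n_steps, stimulus = NULL, lesion = NULL,
                      jitter = NULL, electrodes = NULL, record_nodes = NULL,
                      keep_history = FALSE, sample_mode = c("mean", "sum")) {
  sample_mode <- match.arg(sample_mode)
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("`n_steps` must be >= 1", call. = FALSE)
  state <- if (inherits(init, "wl_state")) init else grid_state(init[1], init[2])
  shape <- state$shape
  if (!is.null(lesion) && !all(dim(lesion$inactive) == shape))
    stop("lesion mask shape does not match the grid", call. = FALSE)
  if (!is.null(lesion) && all(lesion$inactive))
    stop("no live nodes: lesion fraction covers the whole grid", call. = FALSE)
  if (!is.null(lesion) && any(lesion$inactive)) {
    state$A[lesion$inactive] <- 0
    state$Delta[lesion$inactive] <- 0
  }
  lap <- build_laplacian(shape, params, lesion, jitter)
  sampler <- if (!is.null(stimulus)) stim_sampler(stimulus, shape, n_steps)

  e_idx <- NULL
  if (!is.null(electrodes)) {
    if (inherits(electrodes, "wl_electrode")) electrodes <- list(electrodes)
    e_idx <- lapply(electrodes, electrode_node_index, shape = shape,
                    pitch = params$column_pitch_mm)
  }
  n_idx <- NULL
  if (!is.null(record_nodes)) {
    if (is.list(record_nodes)) record_nodes <- do.call(rbind, record_nodes)
    record_nodes <- matrix(as.integer(record_nodes), ncol = 2)
    if (any(record_nodes < 1L) || any(record_nodes[, 1] > shape[1]) ||
        any(record_nodes[, 2] > shape[2]))
      stop("record_nodes lie off the grid", call. = FALSE)
    n_idx <- (record_nodes[, 2] - 1L) * shape[1] + record_nodes[, 1]
  }
  rec <- if (!is.null(e_idx)) matrix(NA_real_, n_steps, length(e_idx))
  nrec <- if (!is.null(n_idx)) matrix(NA_real_, n_steps, length(n_idx))
  hist <- NULL
  if (keep_history) {
    if (prod(shape) * n_steps > 2.5e8)
      stop("dense history would exceed ~2 GB; record electrodes instead",
           call. = FALSE)
    hist <- array(NA_real_, c(shape, n_steps))
  }

  for (tt in seq_len(n_steps)) {
    if (!is.null(sampler)) {
      v <- sampler(tt)
      if (!is.null(v)) state$A <- state$A + v
    }
    state <- step_with(state, params, lap, lesion)
    if (tt %% 25L == 0L || tt == n_steps) {
      mx <- max(abs(state$A))
      # 1e100 also catches runaway growth long before it overflows to Inf
      if (!is.finite(mx) || mx > 1e100) stop_instability(state$t)
    }
    if (!is.null(rec))
      for (e in seq_along(e_idx)) {
        vals <- state$A[e_idx[[e]]]
        rec[tt, e] <- if (sample_mode == "mean") mean(vals) else sum(vals)
      }
    if (!is.null(nrec)) nrec[tt, ] <- state$A[n_idx]
    if (keep_history) hist[, , tt] <- state$A
  }
  if (!is.null(rec))
    colnames(rec) <- vapply(electrodes, function(e) e$id, "")
  structure(list(state = state, recordings = rec, node_recordings = nrec,
                 history = hist, params = params, n_steps = n_steps,
                 sample_mode = sample_mode),
            class = "wl_run")
}

#' @export
print.wl_run <- function(x, ...) {
  cat(sprintf("<wl_run> %d x %d grid, %d steps", x$state$shape[1],
              x$state$shape[2], x$n_steps))
  if (!is.null(x$recordings))
    cat(sprintf(", %d electrode(s)", ncol(x$recordings)))
  if (!is.null(x$history)) cat(", dense history kept")
  cat("\n")
  invisible(x)
}
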