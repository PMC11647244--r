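#' Virtual electrode
#'
#' A circular virtual electrode covering every column whose center lies
#' strictly within `radius_mm` of the electrode center (half-open disc
#' convention). Standard sizes: unit electrode `radius_mm = 0.25` (one
#' 500-um column), LFP `1.0` (2 mm diameter), EEG `10` (20 mm diameter),
#' grating-protocol EEG `2.5`.
#'
#' @param center Electrode center: node indices `c(i, j)` (1-based). Use
#'   `center_mm` to position in mm instead.
#' @param radius_mm Electrode radius in mm.
#' @param id Electrode identifier string.
#' @param center_mm Optional center in mm (node `(i, j)` sits at
#'   `((i-1) * pitch, (j-1) * pitch)`).
#' @param pitch_mm Column pitch used for `center_mm` (default 0.5).
#' @return An object of class `wl_electrode`.
#' @export
electrode <- function(center, radius_mm = 0.25, id = NULL, center_mm = NULL,
                      pitch_mm = 0.5) {
  if (!is.null(center_mm)) center <- center_mm / pitch_mm + 1
  stopifnot(length(center) == 2, radius_mm > 0)
  if (is.null(id)) id <- sprintf("e_%g_%g", center[1], center[2])
  structure(list(center = as.numeric(center), radius_mm = radius_mm, id = id),
            class = "wl_electrode")
}

#' @export
print.wl_electrode <- function(x, ...) {
  cat(sprintf("<wl_electrode> '%s' at node (%g, %g), radius %g mm\n",
              x$id, x$center[1], x$center[2], x$radius_mm))
  invisible(x)
}

# linear indices of grid nodes covered by an electrode
electrode_node_index <- function(el, shape, pitch = 0.5) {
  r_cols <- el$radius_mm / pitch
  i0 <- max(1L, ceiling(el$center[1] - r_cols))
  i1 <- min(shape[1], floor(el$center[1] + r_cols))
  j0 <- max(1L, ceiling(el$center[2] - r_cols))
  j1 <- min(shape[2], floor(el$center[2] + r_cols))
  if (i0 > i1 || j0 > j1)
    stop(sprintf("electrode '%s' lies off the grid", el$id), call. = FALSE)
  ir <- seq.int(i0, i1); jr <- seq.int(j0, j1)
  d2 <- outer((ir - el$center[1])^2, (jr - el$center[2])^2, `+`)
  keep <- which(d2 < r_cols^2, arr.ind = TRUE)
  if (nrow(keep) == 0) {
    # half-open disc smaller than one pitch: fall back to the nearest node
    keep <- cbind(which.min(abs(ir - el$center[1])),
                  which.min(abs(jr - el$center[2])))
  }
  (jr[keep[, 2]] - 1L) * shape[1] + ir[keep[, 1]]
}

#' Sample the activation field with an electrode
#'
#' The electrode reading is the spatial mean (default) or sum of the
#' activation over the covered columns. The mean keeps amplitudes comparable
#' across electrode sizes; averaging over many columns attenuates
#' short-wavelength (high-frequency) components, which is why large
#' electrodes mask HF activity.
#'
#' @param state A `wl_state` (or a plain activation matrix).
#' @param el A [electrode()].
#' @param mode `"mean"` (default) or `"sum"`.
#' @param pitch_mm Column pitch in mm.
#' @return A single number.
#' @export
sample_electrode <- function(state, el, mode = c("mean", "sum"),
                             pitch_mm = 0.5) {
  mode <- match.arg(mode)
  A <- if (inherits(state, "wl_state")) state$A else state
  idx <- electrode_node_index(el, dim(A), pitch_mm)
  if (mode == "mean") mean(A[idx]) else sum(A[idx])
}

#' Standard electrode layouts
#'
#' Deterministic placements used throughout the analyses:
#' * `"grating"`: three EEG electrodes (radius 2.5 mm) at 0, 12.5 and 40 mm
#'   from a stimulus center, along the x axis.
#' * `"coherence-pairs"`: a base unit electrode plus partners at distances
#'   0.5, 2, 4, 8, 16 and 32 mm along the x axis.
#' * `"mea"`: an `n x n` array of unit electrodes with a given spacing.
#'
#' @param layout `"grating"`, `"coherence-pairs"` or `"mea"`.
#' @param center Reference node `c(i, j)`.
#' @param pitch_mm Column pitch (default 0.5).
#' @param distances_mm Distances for `"grating"`/`"coherence-pairs"` layouts.
#' @param radius_mm Electrode radius (defaults: grating 2.5, others 0.25).
#' @param n,spacing_mm MEA array size and spacing.
#' @return A list of `wl_electrode` objects with unique ids.
#' @export
place_array <- function(layout = c("grating", "coherence-pairs", "mea"),
                        center = c(1L, 1L), pitch_mm = 0.5,
                        distances_mm = NULL, radius_mm = NULL,
                        n = 4L, spacing_mm = 1) {
  layout <- match.arg(layout)
  if (layout == "grating") {
    if (is.null(distances_mm)) distances_mm <- c(0, 12.5, 40)
    if (is.null(radius_mm)) radius_mm <- 2.5
    els <- lapply(seq_along(distances_mm), function(i)
      electrode(center + c(distances_mm[i] / pitch_mm, 0), radius_mm,
                id = sprintf("d%.1fmm", distances_mm[i])))
  } else if (layout == "coherence-pairs") {
    if (is.null(distances_mm)) distances_mm <- c(0.5, 2, 4, 8, 16, 32)
    if (is.null(radius_mm)) radius_mm <- 0.25
    els <- c(list(electrode(center, radius_mm, id = "base")),
             lapply(distances_mm, function(d)
               electrode(center + c(d / pitch_mm, 0), radius_mm,
                         id = sprintf("d%gmm", d))))
  } else {
    if (is.null(radius_mm)) radius_mm <- 0.25
    sp <- spacing_mm / pitch_mm
    els <- list()
    for (i in seq_len(n)) for (j in seq_len(n))
      els[[length(els) + 1L]] <- electrode(
        center + c((i - 1) * sp, (j - 1) * sp), radius_mm,
        id = sprintf("mea_%d_%d", i, j))
  }
  ids <- vapply(els, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("overlapping electrode ids", call. = FALSE)
  els
}

#' Recordings as a tidy data frame
#'
#' Converts the recording matrix of a [run_model()] result into long form
#' (`time_ms`, `electrode_id`, `value`), the layout used by the CSV export.
#'
#' @param run A `wl_run` with electrode recordings.
#' @return A data frame.
#' @export
recordings_df <- function(run) {
  stopifnot(inherits(run, "wl_run"), !is.null(run$recordings))
  rec <- run$recordings
  dt <- run$params$dt_ms
  data.frame(
    time_ms = rep(seq_len(nrow(rec)) * dt, times = ncol(rec)),
    electrode_id = rep(colnames(rec), each = nrow(rec)),
    value = as.vector(rec))
}
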