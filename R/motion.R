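# Trajectory smoothing, velocity series, and pairwise 3D velocity
# correlation (the movement-path correlation heatmap), plus net displacement
# and left/right convergence measures.

#' Smooth a track with a centered moving average
#'
#' Each coordinate is replaced by the mean over a centered window of
#' `window` frames; at the track ends the window shrinks asymmetrically so
#' the output has the same length as the input. `window = 1` is the
#' identity.
#'
#' @param track a track data.frame (`time`, `x`, `y`, `z`, ...) as returned
#'   by [cell_track()] or [concat_through_division()]
#' @param window odd positive integer, at most the track length
#' @return the track with smoothed coordinates
#' @export
smooth_track <- function(track, window = 5) {
  n <- nrow(track)
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window %% 2 == 0) {
    stop("parameter error: window must be an odd positive integer")
  }
  if (window > n) stop("parameter error: window exceeds track length")
  if (window == 1) return(track)
  h <- (window - 1L) / 2L
  out <- track
  for (cn in c("x", "y", "z")) {
    v <- track[[cn]]
    out[[cn]] <- vapply(seq_len(n), function(i) {
      mean(v[max(1L, i - h):min(n, i + h)])
    }, numeric(1))
  }
  out
}

#' Per-frame displacement vectors of a track
#'
#' First differences of the positions: `v_t = p_{t+1} - p_t`, in microns per
#' frame. Requires uniform frame spacing.
#'
#' @param track a track data.frame of length >= 2
#' @return list of class `velocity_series` with `cell` and `v`, a
#'   `(length - 1) x 3` matrix of displacement vectors
#' @export
velocity_series <- function(track) {
  n <- nrow(track)
  if (n < 2L) stop("parameter error: need at least 2 observations to difference")
  if (length(unique(diff(track$time))) > 1L) {
    stop("track is not uniformly sampled in time")
  }
  v <- cbind(diff(track$x), diff(track$y), diff(track$z))
  colnames(v) <- c("x", "y", "z")
  structure(list(cell = if ("cell" %in% names(track)) track$cell[1] else NA_character_,
                 v = v),
            class = "velocity_series")
}

flatten_velocity <- function(vs) {
  if (inherits(vs, "velocity_series")) as.vector(vs$v) else as.vector(vs)
}

#' Correlation of two 3D velocity series
#'
#' Pearson correlation of the two series after flattening the three spatial
#' components into a single vector of length `3 * (T - 1)`: a single r per
#' cell pair, +1 for identical motion and -1 for opposite motion.
#'
#' @param a,b [velocity_series()] objects (or `(T-1) x 3` matrices) of equal
#'   length
#' @return correlation in `[-1, 1]`, or `NA_real_` when either flattened
#'   series has zero variance (undefined-correlation sentinel)
#' @export
velocity_correlation <- function(a, b) {
  va <- flatten_velocity(a); vb <- flatten_velocity(b)
  if (length(va) != length(vb)) stop("velocity series have different lengths")
  if (length(va) < 6L) stop("parameter error: need at least 2 timesteps")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  r <- stats::cor(va, vb)
  max(-1, min(1, r))
}

#' Pairwise velocity-correlation matrix of a cell set
#'
#' For each cell: the trajectory over `[t0, t1]` is assembled through
#' divisions ([concat_through_division()]), smoothed
#' ([smooth_track()]), differenced, and the flattened 3D velocity series
#' are correlated pairwise with [velocity_correlation()].
#'
#' @param recording an [embryo_recording()]
#' @param cells character vector of cell names (matrix order)
#' @param t0,t1 analysis window
#' @param window smoothing window (odd; default 5 frames)
#' @return object of class `velocity_correlation_matrix`: list with `cells`
#'   and `r` (symmetric matrix, unit diagonal where variance is positive,
#'   `NA` entries for zero-variance cells)
#' @export
correlation_matrix <- function(recording, cells, t0, t1, window = 5) {
  if (!length(cells)) stop("parameter error: empty cell set")
  vs <- lapply(cells, function(cl) {
    tr <- concat_through_division(recording, cl, t0, t1)
    flatten_velocity(velocity_series(smooth_track(tr, window)))
  })
  X <- do.call(cbind, vs)
  colnames(X) <- cells
  sds <- apply(X, 2, stats::sd)
  r <- suppressWarnings(stats::cor(X))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- ifelse(sds > 0, 1, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  structure(list(cells = cells, r = r), class = "velocity_correlation_matrix")
}

#' @export
print.velocity_correlation_matrix <- function(x, ...) {
  cat(sprintf("<velocity_correlation_matrix> %d cells\n", length(x$cells)))
  print(round(x$r, 2))
  invisible(x)
}

#' Element-wise mean of correlation matrices across embryos
#'
#' Replicate embryos are combined by averaging their correlation matrices
#' entry by entry; all matrices must cover the same cells in the same order.
#'
#' @param matrices list of [correlation_matrix()] results
#' @return a `velocity_correlation_matrix` of the means
#' @export
average_correlation_matrices <- function(matrices) {
  if (!length(matrices)) stop("parameter error: no matrices to average")
  cells <- matrices[[1]]$cells
  for (m in matrices) {
    if (!identical(m$cells, cells)) stop("matrices cover different cell sets")
  }
  rmean <- Reduce(`+`, lapply(matrices, `[[`, "r")) / length(matrices)
  structure(list(cells = cells, r = rmean), class = "velocity_correlation_matrix")
}

#' Net displacement of a track over a window
#'
#' Euclidean distance between the positions at the window endpoints (not the
#' path length: a closed loop has net displacement zero).
#'
#' @param track a track data.frame covering `t0` and `t1`
#' @param t0,t1 endpoint frames
#' @return displacement in the track's length units
#' @export
net_displacement <- function(track, t0, t1) {
  p0 <- track_position(track, t0)
  p1 <- track_position(track, t1)
  sqrt(sum((p1 - p0)^2))
}

track_position <- function(track, time) {
  i <- match(time, track$time)
  if (is.na(i)) stop("coverage error: track has no observation at frame ", time)
  c(track$x[i], track$y[i], track$z[i])
}

#' Convergence of a left/right cell pair toward each other
#'
#' The reduction in separation over the window:
#' `||p_L(t0) - p_R(t0)|| - ||p_L(t1) - p_R(t1)||`; positive values mean the
#' pair moved toward each other.
#'
#' @param left,right track data.frames covering both endpoint frames
#' @param t0,t1 endpoint frames
#' @return converged distance (length units of the tracks)
#' @export
convergence <- function(left, right, t0, t1) {
  d0 <- sqrt(sum((track_position(left, t0) - track_position(right, t0))^2))
  d1 <- sqrt(sum((track_position(left, t1) - track_position(right, t1))^2))
  d0 - d1
}

#' Nearest pharynx cell to a neuron at a frame
#'
#' Selection helper for pairing a neuron with a pharyngeal partner (e.g. for
#' displacement comparisons): returns the pharynx-labeled cell whose nucleus
#' is closest to the neuron's at `t0`.
#'
#' @param recording a labeled [embryo_recording()]
#' @param cell neuron name
#' @param t0 frame at which proximity is evaluated
#' @return pharynx cell name
#' @export
nearest_pharynx_cell <- function(recording, cell, t0) {
  fr <- frame_obs(recording, t0)
  pharynx <- names(recording$labels)[recording$labels == "pharynx"]
  ph <- fr[fr$cell %in% pharynx, , drop = FALSE]
  if (!nrow(ph)) stop("no pharynx-labeled cells at frame ", t0)
  rep_name <- representative_at(recording, cell, t0)
  me <- fr[fr$cell == rep_name, , drop = FALSE]
  d2 <- (ph$x - me$x)^2 + (ph$y - me$y)^2 + (ph$z - me$z)^2
  ph$cell[which.min(d2)]
}
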