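# Scalar measurements and statistics: left/right separation at closest
# approach, pharynx retraction distance, ROI fluorescence quantification on
# max-projected substacks, Student t-tests, and small proportion helpers.

#' Minimum left-right separation over a window
#'
#' Per frame, the distance between the leading edges of the left and right
#' cell groups, operationalized as the closest nucleus pair between the two
#' sets; returns the minimum over the window and the frame at which it is
#' attained. By default distances are 3D; `dims` can restrict to a
#' projection (e.g. `c("x", "z")` for a ventral-view 2D measurement).
#'
#' @param recording an [embryo_recording()]
#' @param left_cells,right_cells non-empty character vectors of cell names
#' @param t0,t1 window of frames (inclusive)
#' @param dims coordinate names used in the distance (default all three)
#' @return list with `min_distance` (microns) and `frame`
#' @export
lr_separation <- function(recording, left_cells, right_cells, t0, t1,
                          dims = c("x", "y", "z")) {
  if (!length(left_cells) || !length(right_cells)) {
    stop("parameter error: empty cell set")
  }
  dims <- match.arg(dims, c("x", "y", "z"), several.ok = TRUE)
  ltr <- lapply(left_cells, concat_through_division, recording = recording,
                t_start = t0, t_end = t1)
  rtr <- lapply(right_cells, concat_through_division, recording = recording,
                t_start = t0, t_end = t1)
  best <- Inf; best_frame <- t0
  for (t in t0:t1) {
    lp <- t(vapply(ltr, function(tr) unlist(tr[tr$time == t, dims]), numeric(length(dims))))
    rp <- t(vapply(rtr, function(tr) unlist(tr[tr$time == t, dims]), numeric(length(dims))))
    d2 <- outer(rowSums(lp^2), rowSums(rp^2), `+`) - 2 * lp %*% t(rp)
    m <- sqrt(max(0, min(d2)))
    if (m < best) { best <- m; best_frame <- t }
  }
  list(min_distance = best, frame = best_frame)
}

#' Pharynx retraction distance over a window
#'
#' The distance from the embryo's anterior pole to the anterior pole of the
#' pharynx (the pharynx-labeled nucleus closest to the pole landmark),
#' evaluated at `t1` minus at `t0`. Positive values mean the pharynx moved
#' away from the pole (retracted). The measure is invariant to whole-embryo
#' translation provided the pole landmark co-translates.
#'
#' @param recording a labeled [embryo_recording()]
#' @param anterior_pole length-3 landmark in the recording's units
#'   (defaults to the landmark stored in the recording)
#' @param t0,t1 endpoint frames
#' @return retraction distance (microns)
#' @export
pharynx_retraction <- function(recording, anterior_pole = recording$anterior_pole,
                               t0, t1) {
  if (is.null(anterior_pole) || length(anterior_pole) != 3L) {
    stop("parameter error: anterior_pole landmark (length-3 numeric) required")
  }
  tip_distance <- function(t) {
    fr <- frame_obs(recording, t)
    pharynx <- names(recording$labels)[recording$labels == "pharynx"]
    ph <- fr[fr$cell %in% pharynx, , drop = FALSE]
    if (!nrow(ph)) stop("no pharynx-labeled cells at frame ", t)
    min(sqrt((ph$x - anterior_pole[1])^2 + (ph$y - anterior_pole[2])^2 +
               (ph$z - anterior_pole[3])^2))
  }
  tip_distance(t1) - tip_distance(t0)
}

#' ROI quantification on a max-projected substack
#'
#' Max-projects `slice_range` of a 3D intensity stack along z, then measures
#' the mean intensity inside `roi` and subtracts the mean inside
#' `background_roi` (a region outside the embryo).
#'
#' @param stack 3D numeric array (y, x, z)
#' @param roi logical matrix with the stack's y/x dimensions (the
#'   measurement region), or an `roi_rect()`-style mask
#' @param slice_range integer vector of z slices to project (e.g. `k:(k+3)`
#'   for a four-slice projection)
#' @param background_roi logical mask for the background region
#' @return list of class `roi_quantification`: `mean_intensity`,
#'   `background`, `net` (= mean - background) and `n_slices`
#' @export
roi_mean_minus_background <- function(stack, roi, slice_range, background_roi) {
  if (length(dim(stack)) != 3L) stop("stack must be a 3D array")
  if (any(slice_range < 1L) || any(slice_range > dim(stack)[3])) {
    stop("parameter error: slice_range outside stack")
  }
  if (length(roi) != prod(dim(stack)[1:2]) ||
      length(background_roi) != prod(dim(stack)[1:2])) {
    stop("parameter error: ROI mask dimensions must match the stack's y/x plane")
  }
  roi <- as.logical(roi); background_roi <- as.logical(background_roi)
  if (!any(roi, na.rm = TRUE)) stop("parameter error: empty ROI")
  if (!any(background_roi, na.rm = TRUE)) stop("parameter error: empty background ROI")
  sub <- stack[, , slice_range, drop = FALSE]
  proj <- apply(sub, c(1, 2), max)
  m <- mean(proj[matrix(roi, nrow(proj), ncol(proj))])
  b <- mean(proj[matrix(background_roi, nrow(proj), ncol(proj))])
  structure(list(mean_intensity = m, background = b, net = m - b,
                 n_slices = length(slice_range)),
            class = "roi_quantification")
}

#' Rectangular ROI mask
#' @param nrow,ncol mask dimensions (must match the stack's y/x dims)
#' @param rows,cols index ranges included in the region
#' @return logical matrix
#' @export
roi_rect <- function(nrow, ncol, rows, cols) {
  m <- matrix(FALSE, nrow, ncol)
  m[rows, cols] <- TRUE
  m
}

#' Student t-test between two groups
#'
#' Classical Student t (pooled variance when `equal_variance`, Welch
#' otherwise), one- or two-tailed, optionally paired. The one-tailed
#' alternative is "group a exceeds group b", so the two-tailed p equals
#' twice the one-tailed p whenever `t >= 0`.
#'
#' @param a,b numeric vectors (equal lengths when `paired`)
#' @param tails 1 or 2
#' @param paired paired test?
#' @param equal_variance pool the variances?
#' @return list of class `group_comparison`: `t`, `p`, `df`, `tails`,
#'   `paired`, `equal_variance`, `n_a`, `n_b`
#' @export
group_ttest <- function(a, b, tails = 2, paired = FALSE, equal_variance = TRUE) {
  if (!tails %in% c(1, 2)) stop("parameter error: tails must be 1 or 2")
  if (length(a) < 2L || length(b) < 2L) {
    stop("statistic undefined: need at least 2 observations per group")
  }
  if (paired && length(a) != length(b)) {
    stop("parameter error: paired test needs equal-length groups")
  }
  if (paired) {
    if (stats::sd(a - b) == 0 && stats::sd(a) == 0) {
      stop("statistic undefined: zero variance")
    }
  } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop("statistic undefined: zero variance in both groups")
  }
  alt <- if (tails == 1) "greater" else "two.sided"
  ht <- stats::t.test(a, b, alternative = alt, paired = paired,
                      var.equal = equal_variance)
  structure(list(t = unname(ht$statistic), p = unname(ht$p.value),
                 df = unname(ht$parameter), tails = tails, paired = paired,
                 equal_variance = equal_variance,
                 n_a = length(a), n_b = length(b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %.2f, p = %.4g (%d-tailed%s%s)\n",
              x$t, x$df, x$p, x$tails,
              if (x$paired) ", paired" else "",
              if (x$equal_variance) ", pooled variance" else ""))
  invisible(x)
}

#' Proportion as a percentage
#'
#' `100 * count / total`, rounded half-up to one decimal (e.g. 9 failing
#' embryos of 12 scored is 75%).
#'
#' @param count numerator (0 <= count <= total)
#' @param total denominator (> 0)
#' @return percentage in `[0, 100]`
#' @export
proportion_percent <- function(count, total) {
  if (total <= 0) stop("parameter error: total must be > 0")
  if (count < 0 || count > total) stop("parameter error: count must be in [0, total]")
  round_half_up(100 * count / total, 1L)
}

#' Group means of a measurement table
#'
#' Summarizes a per-embryo measurement table (for instance an ingested
#' separation/retraction source table, or the output of a simulated cohort)
#' by group: mean, standard deviation and n of `value_col` within each level
#' of `group_col`.
#'
#' @param table data.frame
#' @param value_col name of the numeric measurement column
#' @param group_col name of the grouping column (e.g. genotype)
#' @return data.frame with columns `group`, `mean`, `sd`, `n`
#' @export
group_summary <- function(table, value_col, group_col) {
  if (!all(c(value_col, group_col) %in% names(table))) {
    stop("schema error: table lacks column(s) ",
         paste(setdiff(c(value_col, group_col), names(table)), collapse = ", "))
  }
  v <- table[[value_col]]; g <- as.character(table[[group_col]])
  groups <- sort(unique(g))
  data.frame(group = groups,
             mean = vapply(groups, function(k) mean(v[g == k]), numeric(1)),
             sd = vapply(groups, function(k) stats::sd(v[g == k]), numeric(1)),
             n = vapply(groups, function(k) sum(g == k), numeric(1)),
             row.names = NULL)
}
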