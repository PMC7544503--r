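#' @importFrom stats complete.cases
NULL

TISSUE_LEVELS <- c("pharynx", "neuron", "amphid", "hypodermis", "other")

#' Construct a 4D embryo recording
#'
#' An `embryo_recording` bundles per-timepoint nuclear observations with the
#' spatial calibration of the acquisition, tissue labels, and lineage links.
#' It is the central container consumed by the contact-graph, screening,
#' motion and measurement functions.
#'
#' @param obs data.frame with columns `time` (integer frame index, >= 0),
#'   `cell` (non-empty character), `x`, `y`, `z` (numeric positions) and
#'   optionally `radius` (>= 0, `NA` allowed). Positions are in pixels/planes
#'   when `units = "px"` and microns when `units = "um"`.
#' @param units `"px"` (raw pixel/plane coordinates) or `"um"` (calibrated).
#' @param frame_interval_s seconds between consecutive timepoints
#'   (default 75, the lineaging acquisition interval).
#' @param xy_pixels_per_micron lateral calibration, pixels per micron
#'   (default 3).
#' @param z_step_um axial distance between z planes in microns (default 1).
#' @param labels named character vector mapping cell name to one of
#'   `"pharynx"`, `"neuron"`, `"amphid"`, `"hypodermis"`, `"other"`.
#' @param lineage named character vector mapping each child cell name to its
#'   parent's name. Names absent from the map fall back to Sulston-style
#'   prefixing (the parent of `"ABala"` is `"ABal"`) where such a cell exists.
#' @param anterior_pole optional length-3 numeric landmark (same units as
#'   positions): the anterior pole of the embryo.
#' @param midline_axis optional length-3 numeric vector normal to the
#'   left/right midline plane.
#' @return an object of class `embryo_recording`.
#' @export
embryo_recording <- function(obs, units = c("px", "um"),
                             frame_interval_s = 75,
                             xy_pixels_per_micron = 3,
                             z_step_um = 1,
                             labels = NULL, lineage = NULL,
                             anterior_pole = NULL, midline_axis = NULL) {
  units <- match.arg(units)
  required <- c("time", "cell", "x", "y", "z")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols)) {
    stop("observation table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"radius" %in% names(obs)) obs$radius <- NA_real_
  obs <- obs[, c("time", "cell", "x", "y", "z", "radius")]
  obs$time <- as.integer(obs$time)
  obs$cell <- as.character(obs$cell)
  for (cn in c("x", "y", "z", "radius")) obs[[cn]] <- as.numeric(obs[[cn]])
  if (nrow(obs)) {
    if (any(obs$time < 0L)) stop("timepoints must be >= 0")
    if (any(!nzchar(obs$cell))) stop("cell names must be non-empty")
    if (any(!is.na(obs$radius) & obs$radius < 0)) stop("radius must be >= 0")
    if (any(!is.finite(obs$x) | !is.finite(obs$y) | !is.finite(obs$z))) {
      stop("positions must be finite")
    }
    dup <- duplicated(obs[, c("cell", "time")])
    if (any(dup)) {
      d <- obs[dup, , drop = FALSE][1L, ]
      stop(sprintf("duplicate observation for cell '%s' at time %d", d$cell, d$time))
    }
  }
  if (frame_interval_s <= 0 || xy_pixels_per_micron <= 0 || z_step_um <= 0) {
    stop("calibration factors must be > 0")
  }
  labels <- validate_labels(labels)
  lineage <- validate_lineage(lineage)
  obs <- obs[order(obs$cell, obs$time), , drop = FALSE]
  rownames(obs) <- NULL
  structure(list(obs = obs, units = units,
                 frame_interval_s = frame_interval_s,
                 xy_pixels_per_micron = xy_pixels_per_micron,
                 z_step_um = z_step_um,
                 labels = labels, lineage = lineage,
                 anterior_pole = anterior_pole,
                 midline_axis = midline_axis),
            class = "embryo_recording")
}

validate_labels <- function(labels) {
  if (is.null(labels)) return(character(0))
  labels <- unlist(labels)
  if (is.null(names(labels)) || any(!nzchar(names(labels)))) {
    stop("tissue labels must be a named vector (cell name -> tissue)")
  }
  bad <- setdiff(unique(labels), TISSUE_LEVELS)
  if (length(bad)) {
    stop("unknown tissue label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(TISSUE_LEVELS, collapse = ", "), ")")
  }
  labels
}

validate_lineage <- function(lineage) {
  if (is.null(lineage)) return(character(0))
  lineage <- unlist(lineage)
  if (length(lineage) && (is.null(names(lineage)) || any(!nzchar(names(lineage))))) {
    stop("lineage must be a named vector (child -> parent)")
  }
  # acyclicity: walking parents from any child must terminate
  for (child in names(lineage)) {
    seen <- character(0)
    cur <- child
    while (cur %in% names(lineage)) {
      if (cur %in% seen) stop("lineage contains a cycle through '", child, "'")
      seen <- c(seen, cur)
      cur <- unname(lineage[cur])
    }
  }
  lineage
}

#' @export
print.embryo_recording <- function(x, ...) {
  cat(sprintf("<embryo_recording> %d cells, %d observations, frames %s, units: %s\n",
              length(unique(x$obs$cell)), nrow(x$obs),
              if (nrow(x$obs)) paste(range(x$obs$time), collapse = "..") else "-",
              x$units))
  if (length(x$labels)) {
    cat("  tissues:", paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                            collapse = " "), "\n")
  }
  invisible(x)
}

#' Cells and timepoints present in a recording
#' @param recording an [embryo_recording()]
#' @return character vector of cell names / integer vector of frames
#' @export
recording_cells <- function(recording) unique(recording$obs$cell)

#' @rdname recording_cells
#' @export
recording_times <- function(recording) sort(unique(recording$obs$time))

#' Extract the observed track of one cell
#'
#' @param recording an [embryo_recording()]
#' @param cell cell name
#' @return data.frame (`time`, `cell`, `x`, `y`, `z`, `radius`) sorted by
#'   time, with strictly increasing timepoints.
#' @export
cell_track <- function(recording, cell) {
  tr <- recording$obs[recording$obs$cell == cell, , drop = FALSE]
  if (!nrow(tr)) stop("cell '", cell, "' not present in recording")
  tr <- tr[order(tr$time), , drop = FALSE]
  rownames(tr) <- NULL
  tr
}

frame_obs <- function(recording, time) {
  recording$obs[recording$obs$time == time, , drop = FALSE]
}

#' Tissue of a set of cells
#'
#' Looks each cell up in the recording's labeling table; errors if any cell
#' used by a screen is unlabeled, since screens need a total mapping.
#' @param recording an [embryo_recording()]
#' @param cells character vector of cell names
#' @return character vector of tissues
#' @export
tissue_of <- function(recording, cells) {
  out <- recording$labels[cells]
  if (any(is.na(out))) {
    stop("no tissue label for cell(s): ",
         paste(cells[is.na(out)], collapse = ", "))
  }
  unname(out)
}

# ---- lineage ----------------------------------------------------------------

#' Parent of a cell
#'
#' Uses explicit lineage links when present, otherwise Sulston-style name
#' prefixing (dropping the final letter) when the resulting name is observed
#' in the recording.
#' @param recording an [embryo_recording()]
#' @param cell cell name
#' @return parent name, or `NA_character_` when unknown
#' @export
lineage_parent <- function(recording, cell) {
  if (cell %in% names(recording$lineage)) {
    return(unname(recording$lineage[cell]))
  }
  if (nchar(cell) > 1L) {
    cand <- substr(cell, 1L, nchar(cell) - 1L)
    if (cand %in% recording$obs$cell) return(cand)
  }
  NA_character_
}

#' Concatenate a cell's track through divisions
#'
#' Returns a single trajectory covering `[t_start, t_end]` for `cell`,
#' walking back through its ancestors where the cell itself is not yet born:
#' a cell and its mother are treated as equivalent across a division. At a
#' division frame where both mother and daughter are recorded, the
#' daughter's observation wins.
#'
#' @param recording an [embryo_recording()]
#' @param cell terminal cell name (must be observed at `t_end`)
#' @param t_start,t_end window of frames (inclusive)
#' @return data.frame (`time`, `cell`, `x`, `y`, `z`, `radius`,
#'   `source_cell`) with one row per frame and strictly increasing times;
#'   `cell` is the requested terminal name, `source_cell` says which
#'   ancestor supplied each frame.
#' @export
concat_through_division <- function(recording, cell, t_start, t_end) {
  if (t_end < t_start) stop("t_end must be >= t_start")
  want <- t_start:t_end
  pieces <- list()
  cur <- cell
  remaining <- want
  guard <- 0L
  while (length(remaining) && !is.na(cur)) {
    tr <- recording$obs[recording$obs$cell == cur & recording$obs$time %in% remaining, ,
                        drop = FALSE]
    if (nrow(tr)) {
      tr$source_cell <- cur
      pieces[[length(pieces) + 1L]] <- tr
      covered <- tr$time
      # only frames strictly before this cell's earliest observation can come
      # from an ancestor ("child's first frame wins")
      remaining <- remaining[remaining < min(covered)]
    }
    cur <- lineage_parent_restricted(recording, cur)
    guard <- guard + 1L
    if (guard > 64L) break
  }
  if (!cell %in% recording$obs$cell) stop("cell '", cell, "' not present in recording")
  out <- do.call(rbind, pieces)
  got <- if (is.null(out)) integer(0) else out$time
  missing <- setdiff(want, got)
  if (length(missing)) {
    stop("no observation of '", cell, "' or an ancestor at frame(s): ",
         paste(missing, collapse = ", "))
  }
  out <- out[order(out$time), , drop = FALSE]
  out$cell <- cell
  rownames(out) <- NULL
  out
}

# like lineage_parent() but without requiring presence for Sulston fallback
lineage_parent_restricted <- function(recording, cell) {
  lineage_parent(recording, cell)
}

#' Resolve which ancestor of a cell is present at a frame
#'
#' @param recording an [embryo_recording()]
#' @param cell terminal cell name
#' @param time frame index
#' @return the name of `cell` itself if observed at `time`, otherwise the
#'   nearest ancestor observed at `time`; errors if none is.
#' @export
representative_at <- function(recording, cell, time) {
  cur <- cell
  guard <- 0L
  while (!is.na(cur)) {
    if (any(recording$obs$cell == cur & recording$obs$time == time)) return(cur)
    cur <- lineage_parent(recording, cur)
    guard <- guard + 1L
    if (guard > 64L) break
  }
  stop("neither '", cell, "' nor an ancestor is observed at frame ", time)
}

#' Ancestor chain of a cell (self first)
#' @param recording an [embryo_recording()]
#' @param cell cell name
#' @return character vector: the cell, its parent, grandparent, ...
#' @export
ancestor_chain <- function(recording, cell) {
  out <- cell
  cur <- cell
  guard <- 0L
  repeat {
    cur <- lineage_parent(recording, cur)
    if (is.na(cur) || guard > 64L) break
    out <- c(out, cur)
    guard <- guard + 1L
  }
  out
}

# ---- calibration ------------------------------------------------------------

#' Convert a recording from pixel/plane units to microns
#'
#' Divides x and y by `xy_pixels_per_micron`, multiplies z (plane index) by
#' `z_step_um`, and converts the nuclear radius with the lateral factor.
#' Landmarks (`anterior_pole`, `midline_axis`) are converted with the same
#' factors. The operation is deliberately not idempotent: calibrating a
#' recording that is already in microns is a state error.
#'
#' @param recording an [embryo_recording()] in `"px"` units
#' @return the recording in `"um"` units
#' @export
calibrate_to_microns <- function(recording) {
  if (recording$units == "um") {
    stop("recording is already calibrated to microns")
  }
  r <- recording
  ppm <- r$xy_pixels_per_micron
  r$obs$x <- r$obs$x / ppm
  r$obs$y <- r$obs$y / ppm
  r$obs$z <- r$obs$z * r$z_step_um
  r$obs$radius <- r$obs$radius / ppm
  if (!is.null(r$anterior_pole)) {
    r$anterior_pole <- c(r$anterior_pole[1] / ppm, r$anterior_pole[2] / ppm,
                         r$anterior_pole[3] * r$z_step_um)
  }
  if (!is.null(r$midline_axis)) {
    r$midline_axis <- c(r$midline_axis[1] / ppm, r$midline_axis[2] / ppm,
                        r$midline_axis[3] * r$z_step_um)
  }
  r$units <- "um"
  r
}
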