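# Readers/writers for the two on-disk track formats:
#  * "nuclei archive": a directory (or zip) of per-timepoint files named
#    t%03d-nuclei, one comma-separated row per segmented nucleus:
#      index,valid,predecessor,successor1,successor2,x_px,y_px,z_plane,diameter_px,name
#    with -1 marking an absent link. This is a simplified, frozen dialect of
#    the per-timepoint text files emitted by automated lineage-tracing tools.
#  * flat tracks CSV: time,cell,x_um,y_um,z_um,radius_um,tissue

ARCHIVE_PATTERN <- "^t([0-9]{3})-nuclei$"

#' Read a nuclei archive into an embryo recording
#'
#' @param path directory containing `t%03d-nuclei` files, or a `.zip` of one.
#' @param frame_interval_s,xy_pixels_per_micron,z_step_um calibration
#'   metadata attached to the recording (positions stay in pixel/plane units;
#'   call [calibrate_to_microns()] to convert).
#' @return an [embryo_recording()] in `"px"` units with lineage links
#'   populated from the predecessor/successor indices. Rows flagged invalid
#'   (`valid = 0`) are dropped.
#' @export
read_nuclei_archive <- function(path, frame_interval_s = 75,
                                xy_pixels_per_micron = 3, z_step_um = 1) {
  if (length(path) != 1L || !nzchar(path)) stop("path must be a single file or directory")
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) stop("no such archive: ", path)
    exdir <- tempfile("nuclei_archive_")
    dir.create(exdir)
    on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
    utils::unzip(path, exdir = exdir)
    path <- exdir
  }
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- list.files(path, recursive = TRUE, full.names = TRUE)
  files <- files[grepl(ARCHIVE_PATTERN, basename(files))]
  if (!length(files)) stop("no t%03d-nuclei files found under ", path)
  times <- as.integer(sub(ARCHIVE_PATTERN, "\\1", basename(files)))
  ord <- order(times)
  files <- files[ord]; times <- times[ord]

  frames <- vector("list", length(files))
  for (k in seq_along(files)) {
    frames[[k]] <- parse_nuclei_file(files[k], times[k])
  }
  all_rows <- do.call(rbind, lapply(frames, `[[`, "rows"))
  obs <- all_rows[all_rows$valid == 1L,
                  c("time", "name", "x_px", "y_px", "z_plane", "radius_px")]
  names(obs) <- c("time", "cell", "x", "y", "z", "radius")
  dup <- duplicated(obs[, c("cell", "time")])
  if (any(dup)) {
    d <- obs[dup, ][1L, ]
    stop(sprintf("integrity error: cell '%s' appears twice at time %d", d$cell, d$time))
  }

  lineage <- archive_lineage(frames)
  embryo_recording(obs, units = "px",
                   frame_interval_s = frame_interval_s,
                   xy_pixels_per_micron = xy_pixels_per_micron,
                   z_step_um = z_step_um, lineage = lineage)
}

parse_nuclei_file <- function(file, time) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  rows <- data.frame(time = integer(n), index = integer(n), valid = integer(n),
                     pred = integer(n), succ1 = integer(n), succ2 = integer(n),
                     x_px = numeric(n), y_px = numeric(n), z_plane = numeric(n),
                     radius_px = numeric(n), name = character(n))
  for (i in seq_len(n)) {
    parts <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1]])
    if (length(parts) != 10L) {
      stop(sprintf("parse error in %s line %d: expected 10 comma-separated fields, got %d",
                   basename(file), i, length(parts)))
    }
    ints <- suppressWarnings(as.integer(parts[1:5]))
    nums <- suppressWarnings(as.numeric(parts[6:9]))
    if (any(is.na(ints)) || any(is.na(nums))) {
      stop(sprintf("parse error in %s line %d: non-numeric field", basename(file), i))
    }
    if (!nzchar(parts[10])) {
      stop(sprintf("parse error in %s line %d: empty cell name", basename(file), i))
    }
    rows$time[i] <- time; rows$index[i] <- ints[1]; rows$valid[i] <- ints[2]
    rows$pred[i] <- ints[3]; rows$succ1[i] <- ints[4]; rows$succ2[i] <- ints[5]
    rows$x_px[i] <- nums[1]; rows$y_px[i] <- nums[2]; rows$z_plane[i] <- nums[3]
    rows$radius_px[i] <- nums[4] / 2
    rows$name[i] <- parts[10]
  }
  list(time = time, rows = rows)
}

archive_lineage <- function(frames) {
  lineage <- character(0)
  if (length(frames) < 2L) return(lineage)
  for (k in seq_len(length(frames) - 1L)) {
    cur <- frames[[k]]$rows
    nxt <- frames[[k + 1L]]$rows
    for (i in seq_len(nrow(cur))) {
      if (cur$valid[i] != 1L) next
      for (succ in c(cur$succ1[i], cur$succ2[i])) {
        if (succ < 0L) next
        j <- match(succ, nxt$index)
        if (is.na(j)) {
          stop(sprintf("integrity error: successor index %d of '%s' (t=%d) not found at t=%d",
                       succ, cur$name[i], cur$time[i], nxt$time[1]))
        }
        if (nxt$valid[j] == 1L && nxt$name[j] != cur$name[i]) {
          lineage[nxt$name[j]] <- cur$name[i]
        }
      }
    }
  }
  lineage
}

#' Write a recording as a nuclei archive
#'
#' Inverse of [read_nuclei_archive()]: one `t%03d-nuclei` file per frame,
#' with predecessor/successor indices rebuilt from same-name continuity and
#' the recording's lineage links.
#'
#' @param recording an [embryo_recording()] in `"px"` units
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_nuclei_archive <- function(recording, dir) {
  if (recording$units != "px") {
    stop("nuclei archives store pixel/plane coordinates; recording is in microns")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  times <- recording_times(recording)
  if (any(times > 999L)) stop("t%03d file naming supports at most frame 999")
  frames <- lapply(times, function(t) {
    fr <- frame_obs(recording, t)
    fr <- fr[order(fr$cell), , drop = FALSE]
    fr$index <- seq_len(nrow(fr))
    fr
  })
  names(frames) <- as.character(times)
  for (k in seq_along(times)) {
    fr <- frames[[k]]
    pred <- rep(-1L, nrow(fr)); succ1 <- rep(-1L, nrow(fr)); succ2 <- rep(-1L, nrow(fr))
    if (k > 1L) {
      prev <- frames[[k - 1L]]
      for (i in seq_len(nrow(fr))) {
        j <- match(fr$cell[i], prev$cell)
        if (is.na(j)) {
          par <- lineage_parent(recording, fr$cell[i])
          if (!is.na(par)) j <- match(par, prev$cell)
        }
        if (!is.na(j)) pred[i] <- prev$index[j]
      }
    }
    if (k < length(times)) {
      nxt <- frames[[k + 1L]]
      nxt_parent <- vapply(nxt$cell, function(cl) {
        if (cl %in% fr$cell) cl else lineage_parent(recording, cl)
      }, character(1))
      for (i in seq_len(nrow(fr))) {
        kids <- nxt$index[!is.na(nxt_parent) & nxt_parent == fr$cell[i]]
        if (length(kids) >= 1L) succ1[i] <- kids[1L]
        if (length(kids) >= 2L) succ2[i] <- kids[2L]
      }
    }
    lines <- sprintf("%d,1,%d,%d,%d,%s,%s,%s,%s,%s",
                     fr$index, pred, succ1, succ2,
                     num6(fr$x), num6(fr$y), num6(fr$z),
                     num6(ifelse(is.na(fr$radius), 0, fr$radius * 2)), fr$cell)
    writeLines(lines, file.path(dir, sprintf("t%03d-nuclei", times[k])))
  }
  invisible(dir)
}

num6 <- function(x) {
  out <- formatC(x, format = "f", digits = 6)
  trimws(out)
}

# ---- flat CSV ---------------------------------------------------------------

TRACKS_REQUIRED <- c("time", "cell", "x_um", "y_um", "z_um")

#' Read/write flat track tables
#'
#' The CSV schema is `time,cell,x_um,y_um,z_um,radius_um,tissue` (UTF-8, dot
#' decimal separator). `radius_um` and `tissue` may be empty. A write
#' followed by a read reproduces every observation bit-exactly for values
#' representable at 6 decimal places.
#'
#' @param path CSV file path
#' @param frame_interval_s,xy_pixels_per_micron,z_step_um calibration
#'   metadata for the returned recording
#' @return [read_tracks_csv()]: an [embryo_recording()] in `"um"` units, with
#'   tissue labels populated from the `tissue` column when present.
#' @export
read_tracks_csv <- function(path, frame_interval_s = 75,
                            xy_pixels_per_micron = 3, z_step_um = 1) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  missing_cols <- setdiff(TRACKS_REQUIRED, names(tab))
  if (length(missing_cols)) {
    stop("schema error: tracks CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  obs <- data.frame(time = as.integer(tab$time), cell = tab$cell,
                    x = as.numeric(tab$x_um), y = as.numeric(tab$y_um),
                    z = as.numeric(tab$z_um),
                    radius = if ("radius_um" %in% names(tab)) {
                      suppressWarnings(as.numeric(tab$radius_um))
                    } else NA_real_)
  labels <- NULL
  if ("tissue" %in% names(tab) && nrow(tab)) {
    lab <- tab$tissue
    keep <- !is.na(lab) & nzchar(lab)
    if (any(keep)) {
      labels <- tapply(lab[keep], tab$cell[keep], function(v) v[1L])
      labels <- stats::setNames(as.character(labels), names(labels))
    }
  }
  embryo_recording(obs, units = "um",
                   frame_interval_s = frame_interval_s,
                   xy_pixels_per_micron = xy_pixels_per_micron,
                   z_step_um = z_step_um, labels = labels)
}

#' @rdname read_tracks_csv
#' @param recording an [embryo_recording()] in `"um"` units
#' @export
write_tracks_csv <- function(recording, path) {
  if (recording$units != "um") {
    stop("tracks CSV stores micron coordinates; calibrate the recording first")
  }
  obs <- recording$obs
  tissue <- rep("", nrow(obs))
  if (length(recording$labels)) {
    hit <- recording$labels[obs$cell]
    tissue[!is.na(hit)] <- hit[!is.na(hit)]
  }
  lines <- c("time,cell,x_um,y_um,z_um,radius_um,tissue",
             sprintf("%d,%s,%s,%s,%s,%s,%s", obs$time, obs$cell,
                     num6(obs$x), num6(obs$y), num6(obs$z),
                     ifelse(is.na(obs$radius), "", num6(obs$radius)), tissue))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cell-to-tissue labels CSV (`cell,tissue`)
#' @param path CSV file path
#' @return named character vector suitable for [embryo_recording()]'s
#'   `labels` argument
#' @export
read_labels_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell", "tissue") %in% names(tab))) {
    stop("schema error: labels CSV needs columns cell,tissue")
  }
  validate_labels(stats::setNames(tab$tissue, tab$cell))
}
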