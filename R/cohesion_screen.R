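# The cohesive-neuron screen: which neurons keep contact with the pharynx
# while it retracts?  For every labeled neuron we take its pharyngeal
# Delaunay neighbors at the first frame of the window and count the frames
# at which at least one of those initial neighbors (or, across divisions, a
# descendant of one) is still adjacent.  Neurons above a persistence
# threshold (75% of frames by default) are called "interface" neurons.

#' Pharyngeal neighbors of each neuron at the window start
#'
#' @param recording a labeled [embryo_recording()] in micron units
#' @param t0 first frame of the screening window
#' @param prune_factor passed to [contact_graph()]
#' @return named list: for every cell labeled `"neuron"` present at `t0`
#'   (itself or through an ancestor), the character vector of pharynx-labeled
#'   cells adjacent to it at `t0` (possibly empty)
#' @export
initial_pharyngeal_neighbors <- function(recording, t0, prune_factor = 0) {
  if (!length(recording$labels)) stop("recording has no tissue labels")
  g <- contact_graph(recording, t0, prune_factor = prune_factor)
  pharynx <- names(recording$labels)[recording$labels == "pharynx"]
  neurons <- names(recording$labels)[recording$labels == "neuron"]
  neurons <- neurons[neurons %in% recording$obs$cell]
  out <- list()
  for (nc in neurons) {
    rep_name <- representative_at(recording, nc, t0)
    nb <- neighbors_of(g, rep_name)
    out[[nc]] <- intersect(nb, pharynx)
  }
  out
}

#' Contact persistence of neurons with their initial pharyngeal neighbors
#'
#' For each labeled neuron, counts the frames in `[t0, t1]` at which its
#' contact graph neighborhood intersects its first-frame pharyngeal neighbor
#' set. Cells and their ancestors are treated as equivalent on both sides of
#' each contact (lineage concatenation), and neurons with an empty initial
#' neighbor set score zero.
#'
#' @param recording a labeled [embryo_recording()] in micron units
#' @param t0,t1 screening window (inclusive); `t1 > t0` required
#' @param prune_factor passed to [contact_graph()]
#' @return data.frame of persistence records with columns `cell`,
#'   `contact_count`, `window_length`, `percent`; the per-neuron initial
#'   neighbor sets are in the `"initial_neighbors"` attribute
#' @export
contact_persistence <- function(recording, t0, t1, prune_factor = 0) {
  if (t1 <= t0) stop("parameter error: window length must be positive (t1 > t0)")
  init <- initial_pharyngeal_neighbors(recording, t0, prune_factor = prune_factor)
  neurons <- names(init)
  counts <- stats::setNames(integer(length(neurons)), neurons)
  window <- t0:t1
  # ancestor chains are time-independent; resolve once
  chains <- lapply(stats::setNames(nm = unique(recording$obs$cell)),
                   function(cl) ancestor_chain(recording, cl))
  for (t in window) {
    g <- contact_graph(recording, t, prune_factor = prune_factor)
    for (nc in neurons) {
      ini <- init[[nc]]
      if (!length(ini)) next
      rep_name <- representative_at(recording, nc, t)
      nb <- neighbors_of(g, rep_name)
      if (!length(nb)) next
      # a neighbor counts if it, or any ancestor of it, is an initial neighbor
      hit <- any(vapply(nb, function(b) any(chains[[b]] %in% ini), logical(1)))
      if (hit) counts[nc] <- counts[nc] + 1L
    }
  }
  wlen <- length(window)
  records <- data.frame(cell = neurons,
                        contact_count = unname(counts),
                        window_length = wlen,
                        percent = vapply(unname(counts), percent_persistence,
                                         numeric(1), window_length = wlen),
                        stringsAsFactors = FALSE)
  records <- records[order(records$cell), , drop = FALSE]
  rownames(records) <- NULL
  attr(records, "initial_neighbors") <- init
  records
}

#' Persistence percentage of a contact count
#'
#' `100 * count / window_length`, rounded half-up to one decimal place (the
#' rounding used by the published persistence table).
#'
#' @param count frames in contact (0 <= count <= window_length)
#' @param window_length total frames in the window (> 0)
#' @return percentage in `[0, 100]` with one decimal
#' @export
percent_persistence <- function(count, window_length) {
  if (window_length <= 0) stop("parameter error: window_length must be > 0")
  if (count < 0 || count > window_length) {
    stop("parameter error: count must be in [0, window_length]")
  }
  round_half_up(100 * count / window_length, 1L)
}

# round half away from zero at `digits` decimals (base round() is banker's)
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Threshold persistence records into an interface-neuron set
#'
#' @param records persistence records from [contact_persistence()] (or any
#'   data.frame with `cell` and `percent` columns, e.g. an ingested
#'   published persistence table)
#' @param threshold persistence fraction in `[0, 1]`; a neuron is an
#'   interface neuron when `percent / 100 >= threshold` (default 0.75)
#' @return object of class `interface_screen`: list with `records`,
#'   `threshold` and `interface_cells`
#' @export
screen_interface <- function(records, threshold = 0.75) {
  if (!is.data.frame(records) || !all(c("cell", "percent") %in% names(records)) ||
      !nrow(records)) {
    stop("records must be a non-empty data.frame with columns cell, percent")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("parameter error: threshold must be a fraction in [0, 1]")
  }
  sel <- records$percent >= 100 * threshold
  structure(list(records = records, threshold = threshold,
                 interface_cells = sort(records$cell[sel])),
            class = "interface_screen")
}

#' @export
print.interface_screen <- function(x, ...) {
  cat(sprintf("<interface_screen> %d neurons screened, %d interface cells at >= %.0f%%\n",
              nrow(x$records), length(x$interface_cells), 100 * x$threshold))
  if (length(x$interface_cells)) {
    cat("  ", paste(x$interface_cells, collapse = " "), "\n")
  }
  invisible(x)
}

#' Read a published persistence table
#'
#' Ingests a CSV with columns `cell` (quoted names are unquoted),
#' `timepoints` (frames in contact) and `percent` (as printed), e.g. the
#' transcription shipped in `inst/extdata/table1_persistence.csv`.
#'
#' @param path CSV file path
#' @param window_length frames in the screening window the counts refer to
#'   (default 65)
#' @return data.frame with columns `cell`, `contact_count`, `window_length`,
#'   `percent` (the printed value) and `percent_recomputed`
#'   (via [percent_persistence()])
#' @export
read_persistence_table <- function(path, window_length = 65) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell", "timepoints", "percent")
  if (!all(need %in% names(tab))) {
    stop("schema error: persistence table needs columns ",
         paste(need, collapse = ","))
  }
  cell <- gsub("^'|'$", "", trimws(tab$cell))
  data.frame(cell = cell,
             contact_count = as.integer(tab$timepoints),
             window_length = window_length,
             percent = as.numeric(tab$percent),
             percent_recomputed = vapply(as.integer(tab$timepoints),
                                         percent_persistence, numeric(1),
                                         window_length = window_length),
             stringsAsFactors = FALSE)
}

#' Write persistence records in the published table layout
#' @param records persistence records (`cell`, `contact_count`, `percent`)
#' @param path output CSV path
#' @export
write_persistence_table <- function(records, path) {
  out <- data.frame(cell = records$cell, timepoints = records$contact_count,
                    percent = sprintf("%.1f", records$percent))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
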