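# in-code fixtures shared across test files

# a small hand-built recording: three generations A -> Aa -> Aap walking
# rightward, plus a static bystander B
three_generation_recording <- function() {
  obs <- rbind(
    data.frame(time = 1:3, cell = "A", x = 1:3, y = 0, z = 0, radius = 1),
    data.frame(time = 4:6, cell = "Aa", x = 4:6, y = 0, z = 0, radius = 1),
    data.frame(time = 7:9, cell = "Aap", x = 7:9, y = 0, z = 0, radius = 1),
    data.frame(time = 1:9, cell = "B", x = 0, y = 5, z = 0, radius = 1))
  embryo_recording(obs, units = "um")
}

# random recording with values representable at 6 decimals (for round trips)
random_recording <- function(n_cells = 10, n_frames = 10, seed = 1) {
  set.seed(seed)
  obs <- expand.grid(time = seq_len(n_frames),
                     cell = sprintf("c%02d", seq_len(n_cells)),
                     stringsAsFactors = FALSE)
  m <- nrow(obs)
  obs$x <- round(stats::runif(m, 0, 30), 6)
  obs$y <- round(stats::runif(m, 0, 30), 6)
  obs$z <- round(stats::runif(m, 0, 30), 6)
  obs$radius <- round(stats::runif(m, 1, 2), 6)
  embryo_recording(obs, units = "um",
                   labels = stats::setNames(
                     rep(c("pharynx", "neuron"), length.out = n_cells),
                     sprintf("c%02d", seq_len(n_cells))))
}

# write a nuclei-archive directory by hand; `rows` is a list of per-frame
# character vectors (already formatted lines)
write_archive_fixture <- function(lines_by_time) {
  dir <- tempfile("arch_")
  dir.create(dir)
  for (t in names(lines_by_time)) {
    writeLines(lines_by_time[[t]],
               file.path(dir, sprintf("t%03d-nuclei", as.integer(t))))
  }
  dir
}

table1_path <- function() {
  system.file("extdata", "table1_persistence.csv", package = "cohesiontrack")
}

# track data.frame from raw coordinates
track_df <- function(x, y = 0 * x, z = 0 * x, t = seq_along(x), cell = "T") {
  data.frame(time = t, cell = cell, x = x, y = y, z = z, radius = NA_real_)
}
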