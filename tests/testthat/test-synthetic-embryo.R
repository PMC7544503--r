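# generative model of involution kinematics

test_that("identical config and seed give bit-identical recordings", {
  cfg <- synthetic_embryo_config("wt", duration_frames = 20)
  a <- simulate_embryo(cfg, seed = 42)
  b <- simulate_embryo(cfg, seed = 42)
  expect_identical(a$recording$obs, b$recording$obs)
  expect_identical(a$truth$ideal, b$truth$ideal)
  c <- simulate_embryo(cfg, seed = 43)
  expect_false(identical(a$recording$obs, c$recording$obs))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- stats::rnorm(1)
  set.seed(99)
  invisible(simulate_embryo(synthetic_embryo_config("wt", duration_frames = 5),
                            seed = 7))
  after <- stats::rnorm(1)
  expect_identical(before, after)
})

test_that("noise-free wild type is mirror-symmetric across the midline", {
  sim <- simulate_embryo(synthetic_embryo_config("wt", noise_sd_um = 0), seed = 1)
  obs <- sim$recording$obs
  for (k in seq_along(sim$truth$chain_left)) {
    l <- obs[obs$cell == sim$truth$chain_left[k], ]
    r <- obs[obs$cell == sim$truth$chain_right[k], ]
    expect_equal(l$x, r$x)
    expect_equal(l$y, r$y)
    expect_equal(l$z, -r$z)
  }
})

test_that("fully attached interface neurons track their pharyngeal partner exactly", {
  sim <- simulate_embryo(synthetic_embryo_config("wt", noise_sd_um = 0), seed = 1)
  obs <- sim$recording$obs
  for (nc in sim$truth$interface_set) {
    partner <- sim$truth$interface_partner[nc]
    ni <- obs[obs$cell == nc, c("x", "y", "z")]
    pi_ <- obs[obs$cell == partner, c("x", "y", "z")]
    dn <- unname(apply(ni, 2, diff)); dp <- unname(apply(pi_, 2, diff))
    expect_equal(dn, dp, tolerance = 1e-10, info = nc)
    # hence identical net displacement
    tr_n <- cell_track(sim$recording, nc)
    tr_p <- cell_track(sim$recording, partner)
    expect_equal(net_displacement(tr_n, 1, 65), net_displacement(tr_p, 1, 65),
                 tolerance = 1e-10)
  }
})

test_that("detached interface neurons end far from their former partners", {
  sim <- simulate_embryo(synthetic_embryo_config("mutant", noise_sd_um = 0), seed = 5)
  obs <- sim$recording$obs
  T_ <- max(obs$time)
  for (nc in sim$truth$interface_set) {
    partner <- sim$truth$interface_partner[nc]
    ni <- obs[obs$cell == nc & obs$time == T_, c("x", "y", "z")]
    pi_ <- obs[obs$cell == partner & obs$time == T_, c("x", "y", "z")]
    gap <- sqrt(sum((ni - pi_)^2))
    expect_gt(gap, sim$truth$retraction_um)
  }
})

test_that("chain leading edges start at the configured gap and meet at contact", {
  sim <- simulate_embryo(synthetic_embryo_config("wt", noise_sd_um = 0), seed = 1)
  expect_equal(sim$truth$ideal_gap[1], 25)
  expect_equal(sim$truth$ideal_gap[65], 2, tolerance = 1e-6)
  expect_equal(sim$truth$expected_convergence, 23)
  lt <- cell_track(sim$recording, "cnL01")
  rt <- cell_track(sim$recording, "cnR01")
  expect_equal(convergence(lt, rt, 1, 65), 23, tolerance = 1e-6)
  # leaders complete their travel within the 60-minute involution phase
  expect_equal(sim$truth$n_travel_frames, 48L)
  gap49 <- sim$truth$ideal_gap[49]
  expect_equal(gap49, 2, tolerance = 1e-6)
})

test_that("static configurations produce a static embryo", {
  cfg <- synthetic_embryo_config("wt", retraction_um = 0, noise_sd_um = 0,
                                 end_gap_um = 25, start_gap_um = 25,
                                 duration_frames = 10)
  sim <- simulate_embryo(cfg, seed = 1)
  for (cl in recording_cells(sim$recording)) {
    tr <- cell_track(sim$recording, cl)
    expect_equal(net_displacement(tr, 1, 10), 0, tolerance = 1e-9, info = cl)
  }
})

test_that("zero-count populations are simply absent", {
  cfg <- synthetic_embryo_config("wt", n_chain_per_side = 0, n_amphid = 0,
                                 duration_frames = 5)
  sim <- simulate_embryo(cfg, seed = 1)
  expect_length(sim$truth$leader_cells, 0)
  expect_false(any(grepl("^cn|^am", recording_cells(sim$recording))))
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(synthetic_embryo_config("wt", attachment = 1.2), "couplings")
  expect_error(synthetic_embryo_config("wt", duration_frames = 1), "duration")
  expect_error(synthetic_embryo_config("wt", n_interface = -1), "counts")
  expect_error(synthetic_embryo_config("wt", start_gap_um = 40), "width")
  expect_error(synthetic_embryo_config("wt", start_gap_um = 1, end_gap_um = 2),
               "start_gap")
})

test_that("config JSON round-trips through read/write", {
  cfg <- synthetic_embryo_config("mutant", n_interface = 5, seed = 11)
  path <- tempfile(fileext = ".json")
  write_embryo_config(cfg, path)
  back <- read_embryo_config(path)
  expect_equal(unclass(back)[sort(names(back))], unclass(cfg)[sort(names(cfg))])
})

test_that("a scripted division exercises lineage concatenation end to end", {
  cfg <- synthetic_embryo_config("wt", duration_frames = 12, noise_sd_um = 0.1,
                                 scripted_division = list(cell = "amL01", frame = 7))
  sim <- simulate_embryo(cfg, seed = 3)
  cells <- recording_cells(sim$recording)
  expect_true(all(c("amL01a", "amL01p") %in% cells))
  expect_false(any(sim$recording$obs$cell == "amL01" & sim$recording$obs$time >= 7))
  expect_identical(unname(sim$recording$lineage["amL01a"]), "amL01")
  tr <- concat_through_division(sim$recording, "amL01a", 1, 12)
  expect_equal(tr$time, 1:12)
  expect_identical(tr$source_cell, rep(c("amL01", "amL01a"), times = c(6, 6)))
  # the daughter's frames come from the daughter even at the division frame
  d7 <- sim$recording$obs[sim$recording$obs$cell == "amL01a" &
                            sim$recording$obs$time == 7, "x"]
  expect_equal(tr$x[tr$time == 7], d7)
})

test_that("wild-type leader travel matches the convergent-motion scale", {
  sim <- simulate_embryo(synthetic_embryo_config("wt", noise_sd_um = 0), seed = 1)
  tr <- cell_track(sim$recording, "cnL01")
  steps <- velocity_series(tr)$v
  path_len <- sum(sqrt(rowSums(steps^2)))
  # each leader covers half the 25 -> 2 um gap closure along the shell within
  # the 48-frame involution phase: a path of roughly 12 um
  expect_gt(path_len, 10)
  expect_lt(path_len, 16)
  expect_equal(net_displacement(tr, 1, 49), net_displacement(tr, 1, 65),
               tolerance = 1e-9)   # no motion after arrival
})
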