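# smoothing, differencing, velocity correlation, displacement, convergence

test_that("moving-average smoothing shrinks its window at the track ends", {
  tr <- track_df(c(0, 3, 6))
  sm <- smooth_track(tr, 3)
  expect_equal(sm$x, c(1.5, 3, 4.5))   # hand arithmetic of shrinking windows
  expect_equal(smooth_track(tr, 1), tr)                 # window 1 is identity
  const <- track_df(rep(2, 9), rep(-1, 9), rep(4, 9))
  expect_equal(smooth_track(const, 5), const)           # constant unchanged
  expect_error(smooth_track(tr, 2), "odd")
  expect_error(smooth_track(tr, -3), "odd")
  expect_error(smooth_track(tr, 5), "exceeds")
})

test_that("smoothing commutes with rigid translation", {
  set.seed(4)
  tr <- track_df(stats::rnorm(20), stats::rnorm(20), stats::rnorm(20))
  shifted <- tr; shifted$x <- tr$x + 5; shifted$y <- tr$y - 3; shifted$z <- tr$z + 11
  sm <- smooth_track(tr, 5); sms <- smooth_track(shifted, 5)
  expect_equal(sms$x, sm$x + 5)
  expect_equal(sms$y, sm$y - 3)
  expect_equal(sms$z, sm$z + 11)
})

test_that("velocity series are first differences of positions", {
  lin <- velocity_series(track_df(1:6))
  expect_equal(lin$v, cbind(x = rep(1, 5), y = rep(0, 5), z = rep(0, 5)))
  stat <- velocity_series(track_df(rep(2, 4)))
  expect_true(all(stat$v == 0))
  set.seed(8)
  tr <- track_df(stats::rnorm(7), stats::rnorm(7), stats::rnorm(7))
  vs <- velocity_series(tr)
  expect_equal(vs$v[, "y"], diff(tr$y))
  expect_error(velocity_series(track_df(1)), "at least 2")
})

test_that("velocity correlation is +1 with itself, -1 with its negation", {
  set.seed(12)
  v <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(velocity_correlation(v, v), 1)
  expect_equal(velocity_correlation(v, -v), -1)
  expect_true(is.na(velocity_correlation(matrix(0, 10, 3), v)))
})

test_that("independent random walks are uncorrelated under the null", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    a <- apply(matrix(stats::rnorm(600), 200, 3), 2, cumsum)
    b <- apply(matrix(stats::rnorm(600), 200, 3), 2, cumsum)
    r <- velocity_correlation(diff(a), diff(b))
    if (abs(r) < 0.2) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("a common constant position offset leaves correlation unchanged", {
  set.seed(21)
  pa <- apply(matrix(stats::rnorm(90), 30, 3), 2, cumsum)
  pb <- apply(matrix(stats::rnorm(90), 30, 3), 2, cumsum)
  r0 <- velocity_correlation(diff(pa), diff(pb))
  r1 <- velocity_correlation(diff(pa + 7), diff(pb + 7))
  expect_equal(r1, r0)
})

test_that("mirroring x-only motion flips the correlation sign", {
  set.seed(13)
  steps <- stats::rnorm(40, mean = 1)
  tr <- track_df(cumsum(steps))
  mirrored <- tr; mirrored$x <- -mirrored$x
  r <- velocity_correlation(velocity_series(tr)$v, velocity_series(mirrored)$v)
  expect_equal(r, -1)
})

test_that("correlation matrices are symmetric, unit-diagonal, permutation-equivariant", {
  sim <- simulate_embryo(synthetic_embryo_config("wt", duration_frames = 30,
                                                 n_other = 0, n_hypodermis = 0),
                         seed = 3)
  cells <- sim$truth$ventral_cluster
  m <- correlation_matrix(sim$recording, cells, 1, 30, window = 5)
  expect_equal(m$r, t(m$r))
  expect_equal(unname(diag(m$r)), rep(1, length(cells)))
  expect_true(all(m$r >= -1 & m$r <= 1))
  perm <- rev(cells)
  mp <- correlation_matrix(sim$recording, perm, 1, 30, window = 5)
  expect_equal(mp$r[perm, perm][cells, cells], m$r[cells, cells])
  # single cell: the 1x1 matrix [1]
  m1 <- correlation_matrix(sim$recording, cells[1], 1, 30)
  expect_equal(unname(m1$r), matrix(1, 1, 1))
})

test_that("two cells moving identically correlate at 1", {
  obs <- rbind(track_df(cumsum(stats::rnorm(20, 1)), cell = "a"),
               track_df(cumsum(stats::rnorm(20, 1)), cell = "b"))
  set.seed(30)
  obs$x <- rep(cumsum(stats::rnorm(20, 1)), 2)
  obs$y <- rep(cumsum(stats::rnorm(20)), 2)
  obs$z <- rep(cumsum(stats::rnorm(20)), 2)
  obs$y[obs$cell == "b"] <- obs$y[obs$cell == "b"] + 4   # parallel offset
  rec <- embryo_recording(obs, units = "um")
  m <- correlation_matrix(rec, c("a", "b"), 1, 20, window = 1)
  expect_equal(m$r["a", "b"], 1)
})

test_that("averaging correlation matrices is element-wise over embryos", {
  mats <- lapply(1:3, function(s) {
    sim <- simulate_embryo(synthetic_embryo_config("wt", duration_frames = 25,
                                                   n_other = 0, n_hypodermis = 0),
                           seed = s)
    correlation_matrix(sim$recording, sim$truth$ventral_cluster, 1, 25)
  })
  avg <- average_correlation_matrices(mats)
  expect_equal(avg$r, (mats[[1]]$r + mats[[2]]$r + mats[[3]]$r) / 3)
  expect_error(average_correlation_matrices(list()), "no matrices")
})

test_that("net displacement is endpoint distance, not path length", {
  expect_equal(net_displacement(track_df(rep(1, 5)), 1, 5), 0)
  expect_equal(net_displacement(track_df(seq(0, 15, length.out = 6)), 1, 6), 15)
  theta <- seq(0, 2 * pi, length.out = 9)
  circle <- track_df(cos(theta), sin(theta), 0 * theta, t = 1:9)
  expect_equal(net_displacement(circle, 1, 9), 0, tolerance = 1e-12)
  expect_error(net_displacement(circle, 1, 99), "coverage")
})

test_that("convergence measures the reduction in pair separation", {
  l <- track_df(rep(0, 4), rep(0, 4), seq(-15, -1.5, length.out = 4))
  r <- track_df(rep(0, 4), rep(0, 4), seq(15, 1.5, length.out = 4))
  expect_equal(convergence(l, r, 1, 4), 27)
  s <- track_df(rep(0, 4))
  expect_equal(convergence(s, s, 1, 4), 0)
})

test_that("nearest pharynx partner selection uses first-frame proximity", {
  obs <- data.frame(time = 1, cell = c("p1", "p2", "n1"),
                    x = c(0, 10, 1.5), y = 0, z = 0, radius = 1)
  rec <- embryo_recording(obs, units = "um",
                          labels = c(p1 = "pharynx", p2 = "pharynx", n1 = "neuron"))
  expect_identical(nearest_pharynx_cell(rec, "n1", 1), "p1")
})
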