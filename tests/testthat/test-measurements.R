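# scalar measurements: separations, retraction, ROI quantification, t-tests

static_pair_recording <- function(gap = 30) {
  obs <- rbind(
    data.frame(time = rep(1:5, 2), cell = rep(c("L1", "L2"), each = 5),
               x = rep(c(0, 2), each = 5), y = 0, z = -gap / 2, radius = 1),
    data.frame(time = rep(1:5, 2), cell = rep(c("R1", "R2"), each = 5),
               x = rep(c(0, 2), each = 5), y = 0, z = gap / 2, radius = 1))
  embryo_recording(obs, units = "um")
}

test_that("left-right separation returns the closest-approach minimum and frame", {
  rec <- static_pair_recording(30)
  out <- lr_separation(rec, c("L1", "L2"), c("R1", "R2"), 1, 5)
  expect_equal(out$min_distance, 30)
  expect_equal(out$frame, 1)
  # touching sets at a known frame
  obs <- rbind(data.frame(time = 1:5, cell = "L", x = 0, y = 0,
                          z = c(-10, -5, 0, -5, -10), radius = 1),
               data.frame(time = 1:5, cell = "R", x = 0, y = 0,
                          z = c(10, 5, 0, 5, 10), radius = 1))
  rec2 <- embryo_recording(obs, units = "um")
  out2 <- lr_separation(rec2, "L", "R", 1, 5)
  expect_equal(out2$min_distance, 0)
  expect_equal(out2$frame, 3)
  expect_error(lr_separation(rec, character(0), "R1", 1, 5), "empty")
})

test_that("left-right separation is symmetric in the two groups", {
  sim <- simulate_embryo(synthetic_embryo_config("wt", duration_frames = 20),
                         seed = 2)
  a <- lr_separation(sim$recording, sim$truth$chain_left[1:3],
                     sim$truth$chain_right[1:3], 1, 20)
  b <- lr_separation(sim$recording, sim$truth$chain_right[1:3],
                     sim$truth$chain_left[1:3], 1, 20)
  expect_equal(a$min_distance, b$min_distance)
  expect_equal(a$frame, b$frame)
})

test_that("pharynx retraction is the change in pole-to-tip distance", {
  obs <- rbind(data.frame(time = 1:4, cell = "ph1", x = c(20, 18, 16, 14),
                          y = 0, z = 0, radius = 1),
               data.frame(time = 1:4, cell = "ph2", x = c(15, 13, 11, 9),
                          y = 2, z = 0, radius = 1),
               data.frame(time = 1:4, cell = "n", x = 5, y = -4, z = 0, radius = 1))
  rec <- embryo_recording(obs, units = "um",
                          labels = c(ph1 = "pharynx", ph2 = "pharynx", n = "neuron"))
  expect_equal(pharynx_retraction(rec, c(30, 0, 0), 1, 4), 6)
  # static pharynx: zero
  recs <- static_pair_recording()
  recs$labels <- c(L1 = "pharynx", L2 = "pharynx", R1 = "neuron", R2 = "neuron")
  expect_equal(pharynx_retraction(recs, c(40, 0, 0), 1, 5), 0)
  # whole-embryo translation with a co-translated pole leaves it unchanged
  shifted <- rec
  shifted$obs$x <- shifted$obs$x + 100
  expect_equal(pharynx_retraction(shifted, c(130, 0, 0), 1, 4), 6)
  expect_error(pharynx_retraction(rec, NULL, 1, 4), "landmark")
})

test_that("ROI quantification max-projects then subtracts background", {
  stack <- make_roi_fixture(c(20, 20, 8), patch_value = 100,
                            background_value = 10,
                            patch_box = c(5, 10, 6, 12, 3, 6))
  roi <- roi_rect(20, 20, 5:10, 6:12)
  bg <- roi_rect(20, 20, 15:19, 1:4)
  q <- roi_mean_minus_background(stack, roi, 3:6, bg)
  expect_equal(q$mean_intensity, 100)
  expect_equal(q$background, 10)
  expect_equal(q$net, 90)
  expect_equal(q$n_slices, 4L)
  # slices outside the projected range do not affect the measurement
  stack2 <- stack
  stack2[, , 1] <- 1e6
  q2 <- roi_mean_minus_background(stack2, roi, 3:6, bg)
  expect_equal(q2$net, q$net)
  # projection restricted to background-only slices sees no patch
  q3 <- roi_mean_minus_background(stack, roi, 1:2, bg)
  expect_equal(q3$net, 0)
  expect_error(roi_mean_minus_background(stack, roi_rect(20, 20, 0, 0), 1:2, bg),
               "empty ROI")
  expect_error(roi_mean_minus_background(stack, roi, 7:9, bg), "slice_range")
})

test_that("max projection equals the brute-force elementwise maximum", {
  set.seed(17)
  for (k in 1:5) {
    shape <- c(sample(5:12, 1), sample(5:12, 1), sample(4:8, 1))
    box <- c(sort(sample(shape[1], 2)), sort(sample(shape[2], 2)),
             sort(sample(shape[3], 2)))
    stack <- make_roi_fixture(shape, 50, 5, box)
    stack <- stack + array(stats::runif(prod(shape)), shape)
    sl <- sort(sample(shape[3], 2)); sl <- sl[1]:sl[2]
    roi <- matrix(TRUE, shape[1], shape[2])
    q <- roi_mean_minus_background(stack, roi, sl, roi)
    brute <- matrix(-Inf, shape[1], shape[2])
    for (s in sl) brute <- pmax(brute, stack[, , s])
    expect_equal(q$mean_intensity, mean(brute))
    expect_equal(q$net, 0)   # roi == background roi
  }
})

test_that("zero-size patches leave the fixture at pure background", {
  stack <- make_roi_fixture(c(6, 6, 3), 99, 7, NULL)
  expect_true(all(stack == 7))
  expect_error(make_roi_fixture(c(6, 6, 3), 1, 0, c(1, 9, 1, 2, 1, 2)), "patch_box")
})

test_that("group t-tests match the closed-form textbook computation", {
  a <- c(24.1, 27.9, 31.2, 25.4, 29.8, 26.3)
  b <- c(18.7, 22.2, 20.9, 17.5, 21.1, 19.8)
  got <- group_ttest(a, b, tails = 2, equal_variance = TRUE)
  want <- oracle_pooled_t(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df)
  expect_equal(got$p, want$p_two, tolerance = 1e-10)
  # paired variant
  gp <- group_ttest(a, b, tails = 2, paired = TRUE)
  wp <- oracle_paired_t(a, b)
  expect_equal(gp$t, wp$t, tolerance = 1e-10)
  expect_equal(gp$p, wp$p_two, tolerance = 1e-10)
  # one-tailed p is half the two-tailed p when t >= 0
  g1 <- group_ttest(a, b, tails = 1)
  expect_equal(g1$p, got$p / 2, tolerance = 1e-12)
  # swapping groups flips the sign of t
  expect_equal(group_ttest(b, a)$t, -got$t, tolerance = 1e-12)
})

test_that("degenerate t-test inputs are rejected", {
  expect_error(group_ttest(1, c(2, 3)), "at least 2")
  expect_error(group_ttest(c(2, 2), c(2, 2)), "zero variance")
  expect_error(group_ttest(c(1, 2, 3), c(1, 2), paired = TRUE), "equal-length")
  expect_error(group_ttest(c(1, 2), c(3, 4), tails = 3), "tails")
})

test_that("identical groups give t = 0 and two-tailed p = 1", {
  a <- c(1, 2, 3)
  got <- group_ttest(a, a, tails = 2)
  expect_equal(got$t, 0)
  expect_equal(got$p, 1)
})

test_that("proportions print as half-up percentages", {
  expect_equal(proportion_percent(9, 12), 75.0)
  expect_equal(proportion_percent(3, 12), 25.0)
  expect_equal(proportion_percent(0, 5), 0.0)
  expect_equal(proportion_percent(12, 12), 100.0)
  expect_error(proportion_percent(13, 12), "parameter")
})

test_that("group summaries aggregate a measurement table by group", {
  tab <- data.frame(genotype = c("wt", "wt", "mut", "mut", "mut"),
                    sep_um = c(0, 2, 26, 30, 28))
  gs <- group_summary(tab, "sep_um", "genotype")
  expect_equal(gs$mean[gs$group == "wt"], 1)
  expect_equal(gs$mean[gs$group == "mut"], 28)
  expect_equal(gs$n, c(3, 2))
  expect_error(group_summary(tab, "nope", "genotype"), "schema")
})
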