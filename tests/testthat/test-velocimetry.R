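test_that("angular-to-metric conversion follows the schematic-eye scaling", {
  expect_equal(deg_to_mm(0, 22), 0)
  expect_equal(deg_to_mm(0, 28), 0)
  expect_equal(deg_to_mm(1, 24.00), 0.01306 * (24 - 1.82))
  expect_equal(round(deg_to_mm(1, 24.00), 4), 0.2897)
  # linear in angle, increasing in axial length
  expect_equal(deg_to_mm(2.8, 24), 2.8 * deg_to_mm(1, 24))
  expect_gt(deg_to_mm(1, 26), deg_to_mm(1, 23))
  # ratio of the two group-mean axial lengths
  expect_equal(deg_to_mm(1, 25.33) / deg_to_mm(1, 23.98),
               (25.33 - 1.82) / (23.98 - 1.82))
  expect_equal(round(deg_to_mm(1, 25.33) / deg_to_mm(1, 23.98), 4), 1.0609)
  expect_error(deg_to_mm(1, 19.9), "axial_length")
  expect_error(deg_to_mm(1, 31), "axial_length")
})

test_that("motion contrast separates perfused vessel from static background", {
  # temporally constant stack -> all-zero map
  const <- structure(list(frames = array(0.5, dim = c(16, 20, 30)), fps = 64,
                          field_deg = c(0.07, 0.105), axial_length_mm = 24,
                          px_per_deg = 286), class = "video_stack")
  expect_equal(max(motion_contrast(const, register = FALSE)$map), 0)
  expect_error(motion_contrast(structure(list(
    frames = array(0.5, dim = c(4, 8, 8)), fps = 64), class = "video_stack")),
    ">= 8 frames")
  # simulated vessel video: on-centreline values exceed the off-vessel 95th
  # percentile
  sim <- simulate_capillary_video(small_video_cfg(seed = 21))
  map <- motion_contrast(sim$stack)
  cl <- round(sim$truth$centreline)
  on_idx <- unique((cl[, 2] - 1) * nrow(map$map) + cl[, 1])
  mask <- matrix(FALSE, nrow(map$map), ncol(map$map))
  mask[on_idx] <- TRUE
  # dilate the vessel mask so "off-vessel" excludes the vessel border
  off <- map$map[!dilate_mask(mask, 4)]
  expect_gt(mean(map$map[on_idx]), quantile(off, 0.95))
})

test_that("noise-only stacks yield no long high-contrast structures", {
  set.seed(8)
  frames <- array(runif(16 * 60 * 120, 0.3, 0.7), dim = c(16, 60, 120))
  stk <- structure(list(frames = frames, fps = 64, field_deg = c(0.21, 0.42),
                        axial_length_mm = 24, px_per_deg = 286),
                   class = "video_stack")
  map <- motion_contrast(stk, register = FALSE)$map
  # oracle: threshold at the 99th percentile and measure connected
  # components; i.i.d. noise must not organise into a >20 px structure
  bw <- map > quantile(map, 0.99)
  comps <- label_components(bw)
  if (max(comps) > 0) {
    sizes <- tabulate(comps)
    expect_lt(max(sizes), 20)
  } else succeed()
})

test_that("vessel tracing follows an analytic straight ridge", {
  H <- 60; W <- 200
  ridge_row <- 25.5
  m <- outer(seq_len(H), seq_len(W),
             function(r, c) exp(-(r - ridge_row)^2 / (2 * 2^2)))
  map <- perfusion_map(m, px_per_deg = 286, axial_length_mm = 24)
  path <- trace_vessel(map, rbind(c(26, 5), c(26, 196)))
  mid <- path$points[, 2] > 15 & path$points[, 2] < 185
  rms <- sqrt(mean((path$points[mid, 1] - ridge_row)^2))
  expect_lt(rms, 1)
  # metric arc length of a straight path = column extent * um/px
  expect_equal(max(path$arc_length_um),
               diff(range(path$points[, 2])) * path$um_per_px,
               tolerance = 0.02)
  expect_error(trace_vessel(map, rbind(c(26, 5), c(26, 5))), "distinct")
  expect_error(trace_vessel(map, rbind(c(5, 5), c(5, 196))), "background")
})

test_that("traced arc length matches ground truth on a curved vessel", {
  sim <- simulate_capillary_video(small_video_cfg(seed = 22))
  map <- motion_contrast(sim$stack)
  path <- trace_vessel(map, truth_seeds(sim$truth))
  true_len <- diff(range(sim$truth$arc_um[c(3, nrow(sim$truth$centreline) - 2)]))
  expect_lt(abs(max(path$arc_length_um) - true_len) / true_len, 0.05)
  expect_true(all(diff(path$arc_length_um) > 0))
})

test_that("kymograph sampling is the identity on a straight row path", {
  set.seed(2)
  frames <- array(runif(12 * 30 * 80), dim = c(12, 30, 80))
  stk <- structure(list(frames = frames, fps = 64, field_deg = c(0.1, 0.28),
                        axial_length_mm = 24, px_per_deg = 286),
                   class = "video_stack")
  um_per_px <- deg_to_mm(1 / 286, 24) * 1000
  path <- structure(list(points = cbind(rep(7, 71), 5:75),
                         arc_length_um = (0:70) * um_per_px,
                         um_per_px = um_per_px, axial_length_mm = 24),
                    class = "vessel_path")
  kym <- build_kymograph(stk, path, dx_um = um_per_px)
  expect_equal(nrow(kym$image), 12L)
  expect_equal(kym$dt_s, 1 / 64)
  for (f in c(1, 6, 12))
    expect_equal(kym$image[f, ], frames[f, 7, 5:75], tolerance = 1e-12)
  # out-of-bounds path rejected
  bad <- path; bad$points[1, 1] <- 200
  expect_error(build_kymograph(stk, bad), "bounds")
})

test_that("kymograph tracks a constant-velocity plug exactly", {
  # one plug at a time in the field (spacing > vessel length), no noise
  cfg <- small_video_cfg(true_velocity_mm_s = 1.0, pulsatility = 0,
                         noise_sd = 0, jitter_px_sd = 0,
                         plug_spacing_um = 450, seed = 23)
  sim <- simulate_capillary_video(cfg)
  map <- motion_contrast(sim$stack)
  path <- trace_vessel(map, truth_seeds(sim$truth))
  kym <- build_kymograph(sim$stack, path)
  expect_equal(nrow(kym$image), 128L)
  L <- max(path$arc_length_um)
  # rows with exactly one plug front well inside the field: the kymograph's
  # brightest column must sit inside that plug and advance with it
  peaks_um <- rep(NA_real_, 128)
  for (f in 1:128) {
    p <- sim$truth$particle_positions[, f]
    inside <- p[p > 40 & p < L - 20]
    if (length(inside) != 1) next
    peaks_um[f] <- (which.max(kym$image[f, ]) - 1) * kym$dx_um
    expect_lt(abs(peaks_um[f] - (inside - 5)), 12)  # inside the 10 um plug
  }
  drift <- diff(peaks_um)
  drift <- drift[!is.na(drift)]
  expect_equal(median(drift), 1.0 * 1000 / 64, tolerance = 0.1)
})

test_that("band detection recovers constructed slopes to within 2%", {
  for (u in c(8, 16, 31)) {   # um per frame
    kym <- make_band_kymo(u)
    bt <- detect_bands(kym)
    expect_gt(bt$n_bands, 0)
    expect_true(all(bt$bands$n_points >= 3))
    slopes <- bt$bands$slope_frames_per_um
    expect_true(all(abs(abs(1 / slopes) - u) / u < 0.02))
    # slopes of uniform sign within one kymograph
    expect_equal(length(unique(sign(slopes))), 1L)
  }
})

test_that("blank and degenerate kymographs yield an empty band trace", {
  blank <- structure(list(image = matrix(0.5, 64, 200), dt_s = 1 / 64,
                          dx_um = 1), class = "kymograph")
  expect_equal(detect_bands(blank)$n_bands, 0L)
  tiny <- structure(list(image = matrix(0.5, 2, 3), dt_s = 1 / 64, dx_um = 1),
                    class = "kymograph")
  expect_equal(detect_bands(tiny)$n_bands, 0L)
  set.seed(5)
  noisy <- structure(list(image = matrix(runif(64 * 200), 64, 200),
                          dt_s = 1 / 64, dx_um = 1), class = "kymograph")
  expect_equal(detect_bands(noisy)$n_bands, 0L)
})

test_that("parallel bands fit with consistent slopes", {
  kym <- make_band_kymo(16, length_um = 320, spacing_um = 110)
  bt <- detect_bands(kym)
  expect_gte(bt$n_bands, 3L)
  s <- abs(bt$bands$slope_frames_per_um)
  expect_lt((max(s) - min(s)) / median(s), 0.05)
})

test_that("velocity is the reciprocal of band slope", {
  kym <- make_band_kymo(16)
  # one band advancing 16 um per frame at dt = 1/64 -> 1.024 mm/s
  est <- estimate_velocity(manual_band_trace(1 / 16), kym)
  expect_equal(est$velocity_mm_s, 1.024)
  # doubling the slope halves the velocity, exactly
  est2 <- estimate_velocity(manual_band_trace(2 / 16), kym)
  expect_equal(est2$velocity_mm_s, est$velocity_mm_s / 2)
  # velocity is the mean of per-band values
  estm <- estimate_velocity(manual_band_trace(c(1 / 16, 1 / 20)), kym)
  expect_equal(estm$velocity_mm_s, mean(estm$per_band_mm_s))
  expect_equal(estm$n_bands, 2L)
  # reciprocity identity at machine precision
  bt <- manual_band_trace(c(1 / 7, 1 / 19, 1 / 44))
  est3 <- estimate_velocity(bt, kym)
  expect_equal(est3$per_band_mm_s * abs(bt$bands$slope_frames_per_um) *
                 kym$dt_s * 1000, rep(1, 3), tolerance = 1e-12)
  # empty trace: a no-measurement signal, not a zero
  none <- estimate_velocity(detect_bands(structure(
    list(image = matrix(0.5, 64, 200), dt_s = 1 / 64, dx_um = 1),
    class = "kymograph")), kym)
  expect_equal(none$n_bands, 0L)
  expect_true(is.na(none$velocity_mm_s))
})

test_that("detected slopes are invariant to intensity scaling", {
  kym <- make_band_kymo(16)
  bt1 <- detect_bands(kym)
  kym2 <- kym; kym2$image <- kym$image * 3.7
  bt2 <- detect_bands(kym2)
  expect_equal(bt2$bands$slope_frames_per_um, bt1$bands$slope_frames_per_um,
               tolerance = 1e-6)
})

test_that("reversing the path direction negates slopes, not |velocity|", {
  kym <- make_band_kymo(16)
  rev_kym <- kym; rev_kym$image <- kym$image[, ncol(kym$image):1]
  bt <- detect_bands(kym); bt_r <- detect_bands(rev_kym)
  expect_gt(bt$n_bands, 0); expect_gt(bt_r$n_bands, 0)
  expect_true(all(sign(bt_r$bands$slope_frames_per_um) ==
                    -sign(bt$bands$slope_frames_per_um)[1]))
  v <- estimate_velocity(bt, kym)$velocity_mm_s
  v_r <- estimate_velocity(bt_r, rev_kym)$velocity_mm_s
  expect_equal(v_r, v, tolerance = 0.02)
})

test_that("halving the sampling step changes the estimate by < 2%", {
  v1 <- estimate_velocity(detect_bands(make_band_kymo(16, dx_um = 1)),
                          make_band_kymo(16, dx_um = 1))$velocity_mm_s
  v2 <- estimate_velocity(detect_bands(make_band_kymo(16, dx_um = 0.5)),
                          make_band_kymo(16, dx_um = 0.5))$velocity_mm_s
  expect_lt(abs(v2 - v1) / v1, 0.02)
})

test_that("the full pipeline recovers a known velocity", {
  sim <- simulate_capillary_video(small_video_cfg(true_velocity_mm_s = 1.2,
                                                  seed = 31))
  res <- measure_video(sim$stack, truth_seeds(sim$truth))
  vbar <- mean(sim$truth$per_frame_velocity_mm_s)
  expect_gt(res$estimate$n_bands, 3)
  expect_lt(abs(res$estimate$velocity_mm_s - vbar) / vbar, 0.10)
})
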