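test_that("moments ellipse fit recovers axis lengths, angles and ambiguity", {
  for (case in list(list(a = 12, b = 6, ang = 40),
                    list(a = 15, b = 5, ang = 135),
                    list(a = 9, b = 4.5, ang = 5))) {
    px <- ellipse_pixels(60.3, 40.7, case$a, case$b, case$ang)
    fit <- fit_body_ellipse(px)
    expect_lt(min(abs(fit$axis_deg - case$ang),
                  180 - abs(fit$axis_deg - case$ang)), 2)
    expect_false(fit$ambiguous)
    expect_lt(abs(fit$major / (2 * case$a) - 1), 0.1)
    expect_lt(abs(fit$centroid[1] - 60.3), 0.7)
  }
  # a disc has no meaningful axis
  disc <- fit_body_ellipse(ellipse_pixels(30, 30, 8, 8, 0))
  expect_true(disc$ambiguous)
  expect_gte(disc$axis_deg, 0)
  expect_lt(disc$axis_deg, 180)
  expect_error(fit_body_ellipse(matrix(numeric(0), 0, 2)), "empty")
})

test_that("background subtraction finds a bee-sized blob and rejects others", {
  mask <- matrix(0.4, 90, 120)
  frame <- mask
  px <- ellipse_pixels(70.5, 45.5, 8, 4, 30)
  for (i in seq_len(nrow(px))) frame[px[i, "v"], px[i, "u"]] <- 0.05

  expect_null(detect_bee(mask, mask, 20, 400))
  det <- detect_bee(frame, mask, 20, 400)
  expect_lt(abs(det$u - 70.5), 1)
  expect_lt(abs(det$v - 45.5), 1)

  # a sub-threshold-area decoy must not win
  frame2 <- frame
  frame2[10:11, 10:11] <- 0.05
  det2 <- detect_bee(frame2, mask, 20, 400)
  expect_lt(abs(det2$u - 70.5), 1)
  expect_error(detect_bee(frame, matrix(0.4, 10, 10), 20, 400), "mismatch")
})

test_that("detection is equivariant to a common integer shift of frame and mask", {
  mask <- matrix(0.4, 80, 100)
  frame <- mask
  px <- ellipse_pixels(40, 35, 8, 4, 70)
  for (i in seq_len(nrow(px))) frame[px[i, "v"], px[i, "u"]] <- 0.05
  d0 <- detect_bee(frame, mask, 20, 400)
  shift <- function(m, dr, dc) {
    out <- matrix(0.4, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  d1 <- detect_bee(shift(frame, 7, 11), shift(mask, 7, 11), 20, 400)
  expect_equal(d1$u, d0$u + 11, tolerance = 1e-9)
  expect_equal(d1$v, d0$v + 7, tolerance = 1e-9)
})

test_that("tracking a rendered sequence recovers the trajectory within a pixel", {
  sim <- short_trial_120(31, duration_s = 12)
  ar <- test_arena()
  cam_desc <- small_top_camera(c(640, 360))
  traj <- sim$trajectory[301:500, ]
  attr(traj, "fps") <- 120
  scene <- render_frames(traj, ar, cam_desc, seed = 9)
  ab <- bee_area_bounds(mean(scene$px_per_m))
  rt <- track(scene, min_area = ab[1], max_area = ab[2])
  expect_gte(mean(!rt$missing), 0.99)
  ok <- !rt$missing
  rms <- sqrt(mean((rt$u - scene$truth_px[, 1])[ok]^2 +
                     (rt$v - scene$truth_px[, 2])[ok]^2))
  expect_lt(rms, 1)
})

test_that("frames without a bee are flagged missing and decoys do not steal the track", {
  mask <- matrix(0.4, 60, 90)
  mk_frame <- function(u, v, decoy = NULL) {
    f <- mask
    for (p in list(c(u, v), decoy)) {
      if (is.null(p)) next
      px <- ellipse_pixels(p[1], p[2], 7, 3.5, 15)
      for (i in seq_len(nrow(px))) f[px[i, "v"], px[i, "u"]] <- 0.05
    }
    f
  }
  frames <- c(lapply(1:8, function(i) mk_frame(20 + i, 30)),
              lapply(1:3, function(i) mask),              # bee out of view
              lapply(1:8, function(i) mk_frame(31 + i, 30,
                                               decoy = c(70, 15))))
  rt <- track(frames, mask, min_area = 20, max_area = 200)
  expect_true(all(rt$missing[9:11]))
  expect_true(all(!rt$missing[-(9:11)]))
  # the decoy at (70, 15) is bee-sized but far from the running track
  expect_true(all(abs(rt$v[12:19] - 30) < 2))
  expect_true(all(abs(rt$u[12:19] - (31:38 + 1)) < 3))
})

test_that("gap interpolation is collinear and smoothing preserves affine tracks", {
  n <- 40
  raw <- data.frame(frame = 1:n, u = 2 * (1:n) + 3, v = 0.5 * (1:n) - 1,
                    area = 50, major = 10, minor = 5, axis_deg = 10,
                    ambiguous = FALSE, missing = FALSE)
  raw[15:17, c("u", "v")] <- NA
  raw$missing[15:17] <- TRUE
  sm <- interpolate_and_smooth(raw, max_gap_frames = 5, window_frames = 5)
  expect_true(all(sm$interpolated[15:17]))
  inner <- 3:(n - 2)   # full windows; end windows shrink
  expect_equal(sm$u[inner], (2 * (1:n) + 3)[inner], tolerance = 1e-9)
  expect_equal(sm$v[inner], (0.5 * (1:n) - 1)[inner], tolerance = 1e-9)

  # gaps beyond max_gap split the track
  raw$missing[25:32] <- TRUE
  raw[25:32, c("u", "v")] <- NA
  sm2 <- interpolate_and_smooth(raw, max_gap_frames = 5, window_frames = 5)
  expect_true(all(is.na(sm2$u[25:32])))
  expect_equal(length(unique(na.omit(sm2$segment))), 2)
})

test_that("smoothing reduces noise and stays inside the raw point range", {
  set.seed(77)
  n <- 300
  truth_u <- 100 + 30 * sin(seq(0, 4 * pi, length.out = n))
  raw <- data.frame(frame = 1:n, u = truth_u + rnorm(n, 0, 2),
                    v = 50 + rnorm(n, 0, 2), area = 50, major = 10,
                    minor = 5, axis_deg = 0, ambiguous = FALSE,
                    missing = FALSE)
  sm <- interpolate_and_smooth(raw, window_frames = 5)
  rms_raw <- sqrt(mean((raw$u - truth_u)^2))
  rms_sm <- sqrt(mean((sm$u - truth_u)^2))
  expect_lt(rms_sm, 0.7 * rms_raw)
  # windowed convex-hull property, per coordinate
  half <- 2
  for (i in seq(10, n - 10, by = 7)) {
    win <- raw$u[(i - half):(i + half)]
    expect_gte(sm$u[i], min(win) - 1e-9)
    expect_lte(sm$u[i], max(win) + 1e-9)
  }
})

test_that("planar calibration maps reference points exactly and inverts", {
  ref_px <- rbind(c(10, 12), c(300, 8), c(15, 170), c(310, 160))
  ref_m <- rbind(c(0, 0.4), c(0.6, 0.4), c(0, 0), c(0.6, 0))
  cam <- camera_model(ref_px, ref_m, c(320, 180), 240, plane = "wall")
  expect_equal(px_to_metric(cam, ref_px), ref_m, tolerance = 1e-8)
  pts <- cbind(runif(20, 20, 300), runif(20, 20, 160))
  round_trip <- metric_to_px(cam, px_to_metric(cam, pts))
  expect_lt(max(abs(round_trip - pts)), 1e-6)
  expect_error(fit_homography(rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3)),
                              ref_m), "collinear")
})

test_that("calibration recovers the 10-cm disc diameter under projective distortion", {
  ar <- test_arena()
  cam_desc <- ar$cameras$front
  H <- keystone_homography(cam_desc$resolution, amount = 10)
  sx <- cam_desc$resolution[1] / ar$width_m
  sy <- cam_desc$resolution[2] / ar$height_m
  to_px <- function(xy)   # ideal projection + keystone, as the renderer does
    apply_homography(H, cbind(xy[, 1] * sx, (ar$height_m - xy[, 2]) * sy))
  corners_m <- rbind(c(0, ar$height_m), c(ar$width_m, ar$height_m),
                     c(0, 0), c(ar$width_m, 0))
  cam <- camera_model(to_px(corners_m), corners_m, cam_desc$resolution,
                      cam_desc$fps, plane = "wall")
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  rim <- cbind(0.225 + 0.05 * cos(th), 0.12 + 0.05 * sin(th))
  rec <- px_to_metric(cam, to_px(rim))
  diam <- max(dist(rec))
  expect_lt(abs(diam - 0.10), 0.002)
})

test_that("the metric pipeline tracks a distorted rendering within 2 mm", {
  sim <- short_trial_120(32, duration_s = 12)
  ar <- test_arena()
  cam_desc <- small_top_camera(c(640, 360))
  traj <- sim$trajectory[401:520, ]
  attr(traj, "fps") <- 120
  H <- keystone_homography(cam_desc$resolution, amount = 8)
  scene <- render_frames(traj, ar, cam_desc, seed = 5, distort = H)
  cam <- camera_model(scene$ref_points$px, scene$ref_points$metric,
                      cam_desc$resolution, 120, plane = "floor")
  tt <- track_trajectory(scene, camera = cam, window_frames = 1)
  ok <- !is.na(tt$c1_m)
  expect_gte(mean(ok), 0.99)
  err <- sqrt((tt$c1_m - traj$x_m)^2 + (tt$c2_m - traj$z_m)^2)
  expect_lt(sqrt(mean(err[ok]^2)), 0.002)
})

test_that("PNG round trip preserves the track", {
  sim <- short_trial_120(33, duration_s = 12)
  ar <- test_arena()
  traj <- sim$trajectory[101:140, ]
  attr(traj, "fps") <- 120
  scene <- render_frames(traj, ar, ar$cameras$top, seed = 2)
  dir <- withr::local_tempdir()
  write_frames(scene, dir)
  ab <- bee_area_bounds(mean(scene$px_per_m))
  rt_mem <- track(scene, min_area = ab[1], max_area = ab[2])
  rt_png <- track(dir, min_area = ab[1], max_area = ab[2])
  expect_equal(rt_png$u, rt_mem$u, tolerance = 0.1)
  expect_equal(rt_png$v, rt_mem$v, tolerance = 0.1)
})
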