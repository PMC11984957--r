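test_that("kinematics reproduce closed-form speeds", {
  still <- data.frame(x_m = rep(0.1, 50), y_m = 0.2, z_m = 0.3)
  kin <- compute_kinematics(still, 240)
  expect_true(all(kin$speed_mps == 0))

  # 0.8 mm per frame at 240 fps is 0.192 m/s
  mov <- data.frame(x_m = seq(0, by = 8e-4, length.out = 100), y_m = 0,
                    z_m = 0.05)
  expect_equal(compute_kinematics(mov, 240)$speed_mps,
               rep(0.192, 100), tolerance = 1e-12)

  # circle of radius r at angular rate w: speed r*w up to O(1/fps^2)
  fps <- 240; r <- 0.1; w <- 2 * pi
  t <- seq(0, 1, by = 1 / fps)
  circ <- data.frame(x_m = r * cos(w * t), y_m = r * sin(w * t), z_m = 0.3)
  kin <- compute_kinematics(circ, fps)
  interior <- kin$speed_mps[3:(nrow(circ) - 2)]
  expect_lt(max(abs(interior - r * w)), r * w * (w / fps)^2)

  expect_error(compute_kinematics(still[1, ], 240), "two frames")
})

test_that("axis directions resolve to the side facing the motion", {
  r <- resolve_heading(30, 35, 0.2)
  expect_equal(r$yaw_deg, 30)
  r <- resolve_heading(30, ((200 + 180) %% 360) - 180, 0.2)
  expect_equal(r$yaw_deg, -150)
  # slow frames carry the previous yaw forward
  r <- resolve_heading(c(30, 32), c(35, NA), c(0.2, 0.001))
  expect_equal(r$yaw_deg[2], 32)
  # unresolved leading frame is flagged
  r <- resolve_heading(30, NA, 0.001)
  expect_false(r$resolved[1])
})

test_that("resolved yaw matches ground truth on nearly all moving frames", {
  sim <- default_trial(11)
  traj <- sim$trajectory
  # planar (top-camera) kinematics from lightly smoothed positions, as the
  # tracking pipeline delivers them
  sm <- function(v) stats::filter(v, rep(1 / 5, 5), sides = 2)
  xs <- as.numeric(sm(traj$x_m)); zs <- as.numeric(sm(traj$z_m))
  keep <- !is.na(xs)
  kin <- compute_kinematics(data.frame(x_m = xs[keep], y_m = 0,
                                       z_m = zs[keep]), 240)
  axis <- traj$yaw_deg[keep] %% 180    # what an ellipse fit can observe
  res <- resolve_heading(axis, kin$heading_deg, kin$speed_mps)
  moving <- kin$speed_mps >= 0.02
  d <- abs(((res$yaw_deg - traj$yaw_deg[keep] + 180) %% 360) - 180)
  expect_gte(mean(d[moving & res$resolved] < 1e-6), 0.98)
})

test_that("2-means landing threshold matches exact clustering on separated data", {
  sp <- c(rep(0.01, 50), rep(0.30, 50))
  th <- landing_speed_threshold(sp)
  expect_equal(th$centers, c(0.01, 0.30), tolerance = 1e-12)
  expect_equal(th$threshold, 0.155, tolerance = 1e-12)
  expect_error(landing_speed_threshold(rep(0.1, 60)), "identical")
  expect_error(landing_speed_threshold(c(0.1, 0.2)), "at least 10")
})

test_that("2-means agrees with the brute-force optimal split and is scale-equivariant", {
  set.seed(41)
  sp <- c(rnorm(1000, 0.02, 0.005), rnorm(1000, 0.25, 0.05))
  sp <- pmax(sp, 1e-4)
  th <- landing_speed_threshold(sp)
  expect_gt(th$threshold, 0.05)
  expect_lt(th$threshold, 0.20)
  cut <- optimal_split_1d(sp)
  agree <- mean((sp < th$threshold) == (sp < cut))
  expect_gte(agree, 0.99)
  # duplication invariance and scaling equivariance
  expect_equal(landing_speed_threshold(rep(sp, 2))$threshold, th$threshold,
               tolerance = 1e-9)
  expect_equal(landing_speed_threshold(3 * sp)$threshold, 3 * th$threshold,
               tolerance = 1e-9)
})

test_that("choice detection finds true landings and ignores everything else", {
  ar <- arena_config()
  sim <- default_trial(11)
  an <- analyze_trial(sim, ar)
  truth <- sim$truth$landings
  expect_equal(nrow(an$choices), nrow(truth))
  offsets <- vapply(seq_len(nrow(truth)), function(i) {
    cand <- an$choices$frame_on[an$choices$stimulus == truth$stimulus[i]]
    min(abs(cand - truth$frame[i]))
  }, numeric(1))
  expect_true(all(offsets <= 5))

  # trajectory that never approaches a feeder
  far <- data.frame(x_m = seq(0.1, 0.5, length.out = 200), y_m = 0.2,
                    z_m = 0.3)
  kin <- compute_kinematics(far, 240)
  expect_equal(nrow(detect_choices(far, kin, ar$layout, 0.06, 240)), 0)

  # sub-dwell contact is rejected
  lay1 <- ar$layout[1, ]
  nfr <- 200
  brief <- data.frame(x_m = rep(lay1$cx, nfr), y_m = rep(lay1$cy, nfr),
                      z_m = c(rep(0.3, 90), rep(0.004, 10), rep(0.3, 100)))
  kinb <- compute_kinematics(brief, 240)
  kinb$speed_mps[] <- 0.005
  ch <- detect_choices(brief, kinb, ar$layout, 0.06, 240, min_dwell_s = 0.1)
  expect_equal(nrow(ch), 0)
})

test_that("inspection segmentation matches the ROI geometry exactly", {
  ar <- arena_config()
  lay <- ar$layout
  fps <- 240
  # constructed path: inside stimulus 2's cylinder frames 100-349
  n <- 500
  traj <- data.frame(x_m = rep(0.45, n), y_m = rep(0.35, n), z_m = rep(0.3, n))
  traj$x_m[100:349] <- lay$cx[2]
  traj$y_m[100:349] <- lay$cy[2]
  traj$z_m[100:349] <- 0.05
  kin <- compute_kinematics(traj, fps)
  ev <- segment_inspections(traj, kin, lay, detect_choices(traj, kin, lay,
                                                           0.06, fps), fps)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$stimulus, lay$id[2])
  expect_equal(ev$hover_s, 250 / 240, tolerance = 1e-9)
  expect_equal(ev$decision, "reject")

  # parallel to the wall but outside the 0.10 m depth: no events
  traj2 <- data.frame(x_m = seq(0.05, 0.55, length.out = n),
                      y_m = rep(lay$cy[1], n), z_m = rep(0.12, n))
  kin2 <- compute_kinematics(traj2, fps)
  ev2 <- segment_inspections(traj2, kin2, lay,
                             detect_choices(traj2, kin2, lay, 0.06, fps), fps)
  expect_equal(nrow(ev2), 0)

  # overlapping ROIs are a configuration error
  bad <- lay
  bad$cx[2] <- bad$cx[1] + 0.11
  expect_error(segment_inspections(traj, kin, bad, data.frame(), fps),
               "overlap")
})

test_that("segmented events agree with generator ground truth", {
  ar <- arena_config()
  sim <- default_trial(12)
  an <- analyze_trial(sim, ar)
  gt <- sim$truth$all_roi_runs
  expect_equal(nrow(an$events), nrow(gt))
  m <- merge(an$events, gt, by = "stimulus", suffixes = c("", ".gt"))
  m <- m[abs(m$frame_on - m$frame_on.gt) <= 2, ]
  expect_gte(nrow(m), 0.95 * nrow(gt))
  expect_true(all(abs(m$frame_off - m$frame_off.gt) <= 2))

  # every choice lies inside exactly one inspection event
  for (i in seq_len(nrow(an$choices))) {
    ch <- an$choices[i, ]
    hits <- sum(an$events$stimulus == ch$stimulus &
                  an$events$frame_on <= ch$frame_on &
                  an$events$frame_off >= ch$frame_on)
    expect_equal(hits, 1)
  }
  # category counts conserve the event count
  expect_equal(sum(table(an$events$category)), nrow(an$events))
})

test_that("region classification follows the partition and dominance rules", {
  centre <- c(0.3, 0.2); r <- 0.05
  ll <- classify_regions(rep(0.3 - 0.03, 40), rep(0.2 - 0.02, 40), centre, r)
  expect_equal(ll$category, "lower-left")
  both <- classify_regions(c(rep(0.3 - 0.03, 20), rep(0.3 + 0.03, 20)),
                           rep(0.2 - 0.02, 40), centre, r)
  expect_equal(both$category, "both-corners")
  expect_equal(both$visited, c("lower_left", "lower_right"))
  top <- classify_regions(rep(0.3, 30), rep(0.23, 30), centre, r)
  expect_equal(top$category, "top/other")
  # scripted categories are recovered from the positions alone
  sim <- default_trial(12)
  an <- analyze_trial(sim)
  gt <- sim$truth$events
  m <- merge(an$events, gt, by = c("stimulus", "frame_on"),
             suffixes = c("", ".gt"))
  expect_gte(mean(m$category == m$category.gt), 0.95)
  expect_gte(mean(m$decision == m$decision.gt), 0.99)
})

test_that("test summaries score the choice window correctly", {
  choices <- data.frame(stimulus = 1, pattern = "plus", valence = "rewarded",
                        frame_on = c(10, 200, 400, 600),
                        frame_off = c(20, 210, 410, 610),
                        t_on = c(1, 20, 50, 100),
                        correct = c(TRUE, TRUE, FALSE, TRUE))
  events <- data.frame(stimulus = c(2, 1), pattern = c("mult", "plus"),
                       valence = c("punished", "rewarded"),
                       frame_on = c(5, 150), frame_off = c(100, 700),
                       decision = c("reject", "accept"),
                       correct = TRUE, hover_s = 1, scan_speed_mps = 0.1,
                       category = c("lower-left", "lower-centre"))
  s <- summarize_test(events, choices, window_s = 120)
  expect_equal(s$prop_correct, 0.75)
  expect_equal(s$first_stimulus, 2)
  late <- choices; late$t_on <- late$t_on + 200
  s2 <- summarize_test(events, late, window_s = 120)
  expect_true(s2$undefined)
  expect_true(is.na(s2$prop_correct))
})

test_that("accept and reject hover times are equal when configured equal", {
  hs <- do.call(rbind, lapply(c(11, 12), function(s) {
    an <- analyze_trial(default_trial(s))
    an$events[, c("decision", "hover_s")]
  }))
  acc <- hs$hover_s[hs$decision == "accept"]
  rej <- hs$hover_s[hs$decision == "reject"]
  expect_gt(length(acc), 5)
  expect_lt(abs(mean(acc) - mean(rej)),
            3 * sqrt(var(acc) / length(acc) + var(rej) / length(rej)) + 0.15)
})
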