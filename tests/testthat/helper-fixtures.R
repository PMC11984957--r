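# shared fixtures, memoised so expensive simulations run once per session
.fix <- new.env(parent = emptyenv())

small_top_camera <- function(res = c(320, 180)) {
  camera_descriptor("top", resolution = res, fps = 120)
}

test_arena <- function() {
  arena_config(cameras = list(front = camera_descriptor("front", c(320, 180)),
                              top = small_top_camera()))
}

# full-length default trial (240 fps, >= 120 s), memoised per seed
default_trial <- function(seed) {
  key <- paste0("trial", seed)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- simulate_trial(flight_sim_config(), arena_config(),
                                  seed = seed)
  .fix[[key]]
}

# short 120-fps trial for rendering tests
short_trial_120 <- function(seed, duration_s = 10) {
  key <- paste0("t120_", seed, "_", duration_s)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- simulate_trial(
      flight_sim_config(fps = 120, duration_s = duration_s), test_arena(),
      seed = seed)
  .fix[[key]]
}

# run the flight pipeline (kinematics, threshold, choices, inspections)
# on a simulated trial
analyze_trial <- function(sim, arena = arena_config(), fps = 240) {
  traj <- sim$trajectory
  kin <- compute_kinematics(traj, fps)
  layout <- arena$layout
  near <- rep(FALSE, nrow(traj))
  for (s in seq_len(nrow(layout))) {
    d <- sqrt((traj$x_m - layout$cx[s])^2 + (traj$y_m - layout$cy[s])^2 +
                traj$z_m^2)
    near <- near | d < 0.02
  }
  thr <- landing_speed_threshold(kin$speed_mps[near])
  choices <- detect_choices(traj, kin, layout, thr$threshold, fps)
  events <- segment_inspections(traj, kin, layout, choices, fps)
  list(traj = traj, kin = kin, threshold = thr, choices = choices,
       events = events)
}

# enumerate pixels of a filled ellipse (independent of the renderer)
ellipse_pixels <- function(uc, vc, a, b, angle_deg) {
  ext <- ceiling(a) + 2
  grid <- expand.grid(u = floor(uc - ext):ceiling(uc + ext),
                      v = floor(vc - ext):ceiling(vc + ext))
  th <- angle_deg * pi / 180
  du <- grid$u - uc; dv <- grid$v - vc
  p <- du * cos(th) + dv * sin(th)
  q <- -du * sin(th) + dv * cos(th)
  as.matrix(grid[(p / a)^2 + (q / b)^2 <= 1, ])
}

# brute-force optimal 1-D 2-partition by within-cluster sum of squares
optimal_split_1d <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- NULL
  for (k in 1:(n - 1)) {
    lo <- xs[1:k]; hi <- xs[(k + 1):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (is.null(best) || ss < best$ss)
      best <- list(ss = ss, cut = (xs[k] + xs[k + 1]) / 2)
  }
  best$cut
}
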