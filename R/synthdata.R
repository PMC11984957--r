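#' Flight-simulation configuration
#'
#' Parameters of the regime-switching synthetic flight generator. Defaults
#' reproduce the behavioural regime of trained foragers in the
#' discrimination arena: entrance/traverse flight at a median of about
#' 0.20 m/s, inspection (scanning) flight at about 0.11 m/s within 1-5 cm of
#' the stimulus wall, body yaw during scans drawn from a two-component
#' mixture at roughly +27/-33 degrees to the wall normal (wider, about
#' +51/-55 degrees, while traversing), a 0.89 probability that the first
#' scanned region is in the lower half of the pattern, and a 2:1 preference
#' for the lower-left over the lower-right corner.
#'
#' @param speed_approach,speed_traverse,speed_inspect lists with `mean` and
#'   `sd` (m/s) of the per-frame speed process in each regime.
#' @param inspect_dist_m range `c(min, max)` of wall distances during
#'   inspection (metres).
#' @param yaw_inspect,yaw_traverse lists with `mu` (two component means,
#'   degrees, positive first), `sd` (common component sd, degrees) and `w`
#'   (weights summing to 1).
#' @param p_lower_first probability the first scanned region lies in the
#'   lower half of the pattern.
#' @param left_right_odds odds of choosing the lower-left over the
#'   lower-right corner when a corner is scanned first.
#' @param p_centre_given_lower probability a lower-half first scan targets
#'   the lower-centre cell rather than a corner.
#' @param p_both_corners probability a corner-first inspection continues to
#'   the opposite corner before the decision.
#' @param p_accept named accept probabilities per stimulus valence.
#' @param landing_dwell_s time spent sitting on the feeder after an accept.
#' @param inspect_path_m mean scan path length per inspection (waypoint
#'   legs within the scanned cells, excluding the in-ROI part of the entry
#'   descent and the final approach to the feeder). The default is
#'   calibrated so that the total time inside the ROI cylinder before the
#'   decision averages about 1.5 s at the default inspection speed.
#' @param fps simulation frame rate (frames per second).
#' @param duration_s minimum simulated time per trial (seconds).
#' @param seed default seed used when [simulate_trial()] is not given one.
#' @return A list of class `flight_sim_config`.
#' @export
flight_sim_config <- function(speed_approach = list(mean = 0.20, sd = 0.05),
                              speed_traverse = list(mean = 0.20, sd = 0.05),
                              speed_inspect = list(mean = 0.11, sd = 0.03),
                              inspect_dist_m = c(0.01, 0.05),
                              yaw_inspect = list(mu = c(27, -33), sd = 8,
                                                 w = c(0.5, 0.5)),
                              yaw_traverse = list(mu = c(51, -55), sd = 14,
                                                  w = c(0.5, 0.5)),
                              p_lower_first = 0.89,
                              left_right_odds = 2,
                              p_centre_given_lower = 0.5,
                              p_both_corners = 0.25,
                              p_accept = c(rewarded = 0.9, punished = 0.1,
                                           neutral = 0.5),
                              landing_dwell_s = 1.0,
                              inspect_path_m = 0.081,
                              fps = 240,
                              duration_s = 120,
                              seed = 1L) {
  cfg <- list(speed_approach = speed_approach,
              speed_traverse = speed_traverse,
              speed_inspect = speed_inspect,
              inspect_dist_m = inspect_dist_m,
              yaw_inspect = yaw_inspect, yaw_traverse = yaw_traverse,
              p_lower_first = p_lower_first,
              left_right_odds = left_right_odds,
              p_centre_given_lower = p_centre_given_lower,
              p_both_corners = p_both_corners,
              p_accept = p_accept,
              landing_dwell_s = landing_dwell_s,
              inspect_path_m = inspect_path_m,
              fps = fps, duration_s = duration_s, seed = seed)
  for (sp in cfg[c("speed_approach", "speed_traverse", "speed_inspect")])
    stopifnot(sp$sd >= 0, sp$mean > 0)
  stopifnot(cfg$yaw_inspect$sd >= 0, cfg$yaw_traverse$sd >= 0,
            abs(sum(cfg$yaw_inspect$w) - 1) < 1e-9,
            abs(sum(cfg$yaw_traverse$w) - 1) < 1e-9,
            p_lower_first >= 0, p_lower_first <= 1,
            p_both_corners >= 0, p_both_corners <= 1,
            all(p_accept >= 0), all(p_accept <= 1),
            left_right_odds > 0, fps > 0, duration_s > 0,
            inspect_dist_m[1] > 0, inspect_dist_m[2] > inspect_dist_m[1])
  class(cfg) <- "flight_sim_config"
  cfg
}

# cell centres of the 3x2 partition of a disc's bounding square,
# relative to the disc centre; radius r
.region_offsets <- function(r) {
  list(lower_left   = c(-2 * r / 3, -r / 2),
       lower_centre = c(0,          -r / 2),
       lower_right  = c(2 * r / 3,  -r / 2),
       top          = c(0,           r / 2))
}

#' Simulate one arena trial with ground truth
#'
#' Generates a regime-switching flight: an approach from the entrance,
#' then repeated cycles of traverse, inspection (scanning of one or more
#' pattern regions within the configured wall-distance band) and an
#' accept (landing on the feeder) or reject decision, until at least
#' `duration_s` of simulated time has elapsed. Per-frame speed follows a
#' first-order autoregressive process around the regime mean; body yaw is
#' drawn from the regime's two-component mixture with AR(1) temporal
#' smoothing, the component sign tied to the lateral direction of motion.
#'
#' @param config a [flight_sim_config()].
#' @param arena an [arena_config()]; its layout must contain at least one
#'   stimulus.
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @return A list with elements `trajectory` (data frame: `frame`, `time_s`,
#'   `x_m`, `y_m`, `z_m`, `yaw_deg`, `regime`) and `truth` (list with
#'   `events`, `landings`, `regime`; inspection events carry stimulus id,
#'   frame range, decision, scripted region sequence and region category).
#' @export
simulate_trial <- function(config = flight_sim_config(),
                           arena = arena_config(),
                           seed = config$seed) {
  layout <- arena$layout
  if (is.null(layout) || nrow(layout) == 0) stop("stimulus layout is empty")
  if (config$fps <= 0) stop("fps must be positive")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  fps <- config$fps
  n_target <- ceiling(config$duration_s * fps)
  zband <- config$inspect_dist_m
  cruise_z <- min(0.18, arena$depth_m * 0.5)  # outside the 0.10 m ROI depth

  # growing buffers
  cap <- n_target + 5000L
  P <- matrix(NA_real_, cap, 3)
  regime <- character(cap)
  n <- 0L
  pos <- c(arena$width_m / 2, arena$height_m / 2, arena$depth_m - 0.05)
  spd <- config$speed_approach$mean
  phi <- 0.9

  push <- function(p, reg) {
    n <<- n + 1L
    if (n > nrow(P)) {
      P <<- rbind(P, matrix(NA_real_, 5000L, 3))
      regime <<- c(regime, character(5000L))
    }
    P[n, ] <<- p
    regime[n] <<- reg
  }
  clamp_box <- function(p) {
    c(min(max(p[1], 0.005), arena$width_m - 0.005),
      min(max(p[2], 0.005), arena$height_m - 0.005),
      min(max(p[3], 0.003), arena$depth_m - 0.005))
  }
  fly_to <- function(target, sp, reg, jitter = 0.15) {
    repeat {
      innov <- stats::rnorm(1, 0, sp$sd * sqrt(1 - phi^2))
      spd <<- max(0.02, sp$mean + phi * (spd - sp$mean) + innov)
      step <- spd / fps
      d <- target - pos
      len <- sqrt(sum(d^2))
      if (len <= step) { pos <<- clamp_box(target); push(pos, reg); break }
      move <- d / len * step + stats::rnorm(3, 0, jitter * step)
      pos <<- clamp_box(pos + move)
      push(pos, reg)
      if (n >= cap + 50000L) stop("trajectory runaway")  # safety
    }
  }
  dwell <- function(n_frames, reg) {
    for (i in seq_len(n_frames)) {
      pos <<- clamp_box(pos + stats::rnorm(3, 0, 2e-5))
      push(pos, reg)
    }
    spd <<- 0.02
  }

  offsets <- .region_offsets(layout$diameter[1] / 2)
  odds <- config$left_right_odds
  p_left <- odds / (1 + odds)

  # scripted region sequence of one inspection, drawn before the bee
  # traverses so the approach heads for the intended first cell
  draw_regions <- function() {
    if (stats::runif(1) < config$p_lower_first) {
      if (stats::runif(1) < config$p_centre_given_lower) {
        regs <- "lower_centre"
      } else {
        regs <- if (stats::runif(1) < p_left) "lower_left" else "lower_right"
        if (stats::runif(1) < config$p_both_corners)
          regs <- c(regs, setdiff(c("lower_left", "lower_right"), regs))
      }
    } else {
      regs <- "top"
    }
    regs
  }

  visits <- list()
  # initial approach towards the first stimulus standoff point
  nxt <- sample(nrow(layout), 1)
  regs_next <- draw_regions()
  entry <- c(layout$cx[nxt], layout$cy[nxt]) + offsets[[regs_next[1]]]
  fly_to(c(entry, cruise_z), config$speed_approach, "approach")

  while (n < n_target) {
    s <- nxt
    r <- layout$diameter[s] / 2
    regs <- regs_next
    val <- layout$valence[s]
    p_acc <- config$p_accept[[val]]
    if (is.null(p_acc) || is.na(p_acc)) p_acc <- 0.5
    accept <- stats::runif(1) < p_acc

    # descend from cruise height into the first region's cell
    cell1 <- c(layout$cx[s], layout$cy[s]) + offsets[[regs[1]]]
    fly_to(c(cell1, mean(zband)), config$speed_traverse, "traverse")
    scan_start <- n + 1L

    # scan: waypoints inside each scripted cell, within the wall-distance
    # band; wall distance dithers slowly so the scan is dominated by
    # lateral motion, as hovering scans are
    # waypoints per scan: mean distance between two uniform points in the
    # waypoint square (side 0.7 * cell width) is ~0.52 * side, so this many
    # legs realise the configured mean scan path length
    leg <- 0.5214 * 0.7 * (2 * r / 3)
    n_wp <- max(2L, round(config$inspect_path_m / leg *
                            stats::runif(1, 0.7, 1.3)))
    per_reg <- diff(round(seq(0, n_wp, length.out = length(regs) + 1)))
    z_scan <- mean(zband)
    for (k in seq_along(regs)) {
      cell <- c(layout$cx[s], layout$cy[s]) + offsets[[regs[k]]]
      for (j in seq_len(max(1L, per_reg[k]))) {
        z_scan <- min(max(z_scan + stats::runif(1, -0.003, 0.003),
                          zband[1]), zband[2])
        wp <- c(cell + stats::runif(2, -0.35, 0.35) * (2 * r / 3), z_scan)
        fly_to(wp, config$speed_inspect, "inspect")
      }
    }
    scan_end <- n

    landing_frame <- NA_integer_
    if (accept) {
      feeder <- c(layout$cx[s], layout$cy[s], 0.004)
      # directed landing approach: steady speed, little jitter
      fly_to(feeder, list(mean = config$speed_inspect$mean, sd = 0.01),
             "land", jitter = 0.05)
      landing_frame <- n + 1L
      dwell(round(config$landing_dwell_s * fps), "land")
    }
    visits[[length(visits) + 1L]] <-
      list(stimulus = layout$id[s], anchor = scan_start,
           anchor_end = scan_end, decision = if (accept) "accept" else "reject",
           regions = regs, landing_frame = landing_frame)

    # pull out of the ROI and traverse towards the next stimulus's
    # intended first-scan cell
    fly_to(c(pos[1], pos[2], cruise_z), config$speed_traverse, "traverse")
    nxt <- if (nrow(layout) == 1) s else
      sample(setdiff(seq_len(nrow(layout)), s), 1)
    regs_next <- draw_regions()
    entry <- c(layout$cx[nxt], layout$cy[nxt]) + offsets[[regs_next[1]]]
    fly_to(c(entry, cruise_z), config$speed_traverse, "traverse")
  }

  P <- P[seq_len(n), , drop = FALSE]
  regime <- regime[seq_len(n)]
  yaw <- .simulate_yaw(P, regime, config)

  traj <- data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1) / fps,
                     x_m = P[, 1], y_m = P[, 2], z_m = P[, 3],
                     yaw_deg = yaw, regime = regime)
  class(traj) <- c("bee_trajectory", "data.frame")
  attr(traj, "fps") <- fps

  truth <- .ground_truth(traj, layout, visits, fps)
  list(trajectory = traj, truth = truth)
}

# AR(1) yaw around the regime component mean. The mixture component is the
# one whose mean is nearest the (smoothed) planar flight direction, so the
# body axis never opposes the motion — scanning bees keep one eye on the
# wall while translating laterally, and traversing bees face their flight
# direction to within the configured mixture offset.
.simulate_yaw <- function(P, regime, config) {
  n <- nrow(P)
  wrap <- function(a) ((a + 180) %% 360) - 180
  smooth7 <- function(v) {
    f <- stats::filter(v, rep(1 / 7, 7), sides = 2)
    f[is.na(f)] <- v[is.na(f)]
    as.numeric(f)
  }
  vx <- smooth7(c(P[2, 1] - P[1, 1], diff(P[, 1])))
  vz <- smooth7(c(P[2, 3] - P[1, 3], diff(P[, 3])))
  heading <- atan2(vx, -vz) * 180 / pi   # 0 deg = facing the wall
  mu <- numeric(n)
  sdv <- numeric(n)
  comp <- integer(n)   # component identity, for AR reset on switches
  for (i in seq_len(n)) {
    if (regime[i] == "inspect") {
      m <- config$yaw_inspect$mu
      comp[i] <- which.min(abs(wrap(m - heading[i])))
      mu[i] <- m[comp[i]]
      sdv[i] <- config$yaw_inspect$sd
    } else if (regime[i] == "traverse") {
      m <- config$yaw_traverse$mu
      comp[i] <- 10L + which.min(abs(wrap(m - heading[i])))
      # cap the offset from the flight direction at 60 degrees so steep
      # pull-out/pull-in legs stay resolvable from the motion
      off <- pmin(60, pmax(-60, wrap(m[comp[i] - 10L] - heading[i])))
      mu[i] <- wrap(heading[i] + off)
      sdv[i] <- config$yaw_traverse$sd
    } else if (regime[i] == "approach") {
      comp[i] <- 20L
      mu[i] <- heading[i] * 0.8
      sdv[i] <- 8
    } else {  # land: settle facing the wall
      comp[i] <- 30L
      mu[i] <- 0
      sdv[i] <- 4
    }
  }
  rho <- 0.9
  yaw <- numeric(n)
  yaw[1] <- stats::rnorm(1, mu[1], sdv[1])
  innov <- stats::rnorm(n, 0, sdv * sqrt(1 - rho^2))
  for (i in 2:n) {
    if (comp[i] != comp[i - 1]) {
      # regime/component switch: re-draw from the new component so the
      # stationary distribution stays centred on the configured means
      yaw[i] <- stats::rnorm(1, mu[i], sdv[i])
    } else {
      yaw[i] <- mu[i] + rho * (wrap(yaw[i - 1] - mu[i])) + innov[i]
    }
  }
  wrap(yaw)
}

# derive ground-truth inspection events by applying the ROI geometry to the
# true positions, then attach each scripted visit's labels to the
# geometric run containing its scan frames
.ground_truth <- function(traj, layout, visits, fps,
                          roi_diameter = 0.12, roi_depth = 0.10) {
  stim_of <- .roi_membership(traj, layout, roi_diameter, roi_depth)
  runs <- rle(stim_of)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0L
  ev <- data.frame(stimulus = runs$values[keep], frame_on = starts[keep],
                   frame_off = ends[keep])
  ev$decision <- NA_character_
  ev$category <- NA_character_
  ev$regions <- vector("list", nrow(ev))
  landings <- data.frame(stimulus = integer(), frame = integer())
  for (v in visits) {
    i <- which(ev$frame_on <= v$anchor & ev$frame_off >= v$anchor &
                 ev$stimulus == v$stimulus)
    if (length(i) != 1) next  # visit truncated at the trial end
    ev$decision[i] <- v$decision
    ev$regions[[i]] <- v$regions
    ev$category[i] <- .category_from_regions(v$regions)
    if (!is.na(v$landing_frame))
      landings <- rbind(landings, data.frame(stimulus = v$stimulus,
                                             frame = v$landing_frame))
  }
  scripted <- !is.na(ev$decision)
  list(events = ev[scripted, , drop = FALSE],
       all_roi_runs = ev[, c("stimulus", "frame_on", "frame_off")],
       landings = landings, regime = traj$regime, fps = fps)
}

.category_from_regions <- function(regs) {
  if (all(c("lower_left", "lower_right") %in% regs)) return("both-corners")
  switch(regs[1],
         lower_left = "lower-left", lower_centre = "lower-centre",
         lower_right = "lower-right", "top/other")
}

# per-frame stimulus ROI membership (0 = outside all cylinders)
.roi_membership <- function(traj, layout, roi_diameter, roi_depth) {
  stim_of <- integer(nrow(traj))
  for (s in seq_len(nrow(layout))) {
    lat <- sqrt((traj$x_m - layout$cx[s])^2 + (traj$y_m - layout$cy[s])^2)
    inroi <- lat < roi_diameter / 2 & traj$z_m < roi_depth
    stim_of[inroi] <- layout$id[s]
  }
  stim_of
}

#' Simulate training choice sequences under a logistic learning model
#'
#' Each bee's choices are Bernoulli with
#' `logit(p) = intercept + trial_slope * block + group_effect * (group == 2)
#' + colony_effect * (colony == 2) + b_bee`, where `b_bee ~ N(0, bee_sd^2)`
#' is a per-bee random intercept and `block` indexes consecutive blocks of
#' 10 choices.
#'
#' @param n_bees number of bees (at least 2); split evenly between groups
#'   and between two colonies.
#' @param n_choices choices per bee; must be a multiple of the 10-choice
#'   block size.
#' @param intercept,trial_slope,group_effect,colony_effect fixed effects on
#'   the logit scale.
#' @param bee_sd standard deviation of the per-bee random intercept (>= 0).
#' @param seed integer seed.
#' @return Data frame of choice records: `bee`, `colony`, `group`, `choice`,
#'   `block`, `correct`, `phase`.
#' @export
simulate_learning_choices <- function(n_bees, n_choices, intercept = 0,
                                      trial_slope = 0, group_effect = 0,
                                      colony_effect = 0, bee_sd = 0.5,
                                      seed = 1L) {
  if (n_bees < 2) stop("n_bees must be at least 2")
  if (n_choices %% 10 != 0) stop("n_choices must be a multiple of 10")
  if (bee_sd < 0) stop("bee_sd must be non-negative")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  group <- rep(1:2, length.out = n_bees)
  colony <- rep(rep(1:2, each = 2), length.out = n_bees)
  b <- stats::rnorm(n_bees, 0, bee_sd)
  recs <- lapply(seq_len(n_bees), function(i) {
    choice <- seq_len(n_choices)
    block <- ceiling(choice / 10)
    eta <- intercept + trial_slope * block + group_effect * (group[i] == 2) +
      colony_effect * (colony[i] == 2) + b[i]
    data.frame(bee = i, colony = colony[i], group = group[i], choice = choice,
               block = block,
               correct = stats::rbinom(n_choices, 1, stats::plogis(eta)),
               phase = "training")
  })
  do.call(rbind, recs)
}
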