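#' Per-frame flight kinematics
#'
#' Computes speed (central differences in the interior, one-sided at the
#' ends), heading relative to the wall normal, and distance from the
#' stimulus wall for a metric trajectory.
#'
#' @param traj data frame with columns `x_m`, `y_m` and optionally `z_m`
#'   (arena frame, metres).
#' @param fps frame rate of the trajectory.
#' @param wall_distance_m fallback wall distance when the trajectory has no
#'   `z_m` (front-camera tracks), taken as the centre of the scanning band.
#' @return Data frame `speed_mps`, `heading_deg` in `(-180, 180]` with 0
#'   facing the wall (`NA` without `z_m`), `wall_dist_m`.
#' @export
compute_kinematics <- function(traj, fps, wall_distance_m = 0.03) {
  n <- nrow(traj)
  if (n < 2) stop("at least two frames are required")
  has_z <- "z_m" %in% names(traj) && !all(is.na(traj$z_m))
  P <- cbind(traj$x_m, traj$y_m, if (has_z) traj$z_m else 0)
  V <- matrix(NA_real_, n, 3)
  if (n > 2) V[2:(n - 1), ] <- (P[3:n, ] - P[1:(n - 2), ]) * fps / 2
  V[1, ] <- (P[2, ] - P[1, ]) * fps
  V[n, ] <- (P[n, ] - P[n - 1, ]) * fps
  speed <- sqrt(rowSums(V^2))
  heading <- if (has_z) {
    h <- atan2(V[, 1], -V[, 3]) * 180 / pi
    ifelse(h <= -180, h + 360, h)
  } else rep(NA_real_, n)
  data.frame(speed_mps = speed, heading_deg = heading,
             wall_dist_m = if (has_z) traj$z_m else rep(wall_distance_m, n))
}

#' Resolve undirected body-axis angles into signed yaw
#'
#' A moments ellipse gives the body axis only modulo 180 degrees. Of the
#' two opposite directions, the one within 90 degrees of the current flight
#' direction is taken; below `min_speed` the direction nearest the previous
#' resolved yaw is carried forward instead — bees hover and turn without
#' flipping end for end between frames. Frames before the first resolvable
#' one are flagged unresolved. Setting `ambig_margin` above zero makes
#' near-perpendicular frames defer to temporal continuity too; the default
#' keeps the plain velocity rule, which resolves synthetic flights best.
#'
#' @param axis_deg undirected axis angles in `[0, 180)`, in the same
#'   angular convention as `velocity_deg`.
#' @param velocity_deg flight-direction angles in `(-180, 180]`.
#' @param speed_mps per-frame speeds.
#' @param min_speed speed below which the direction is uninformative.
#' @param ambig_margin degrees short of perpendicular at which the
#'   velocity rule defers to temporal continuity.
#' @return List with `yaw_deg` in `(-180, 180]` (NA where unresolved) and
#'   logical `resolved`.
#' @export
resolve_heading <- function(axis_deg, velocity_deg, speed_mps,
                            min_speed = 0.02, ambig_margin = 0) {
  n <- length(axis_deg)
  stopifnot(length(velocity_deg) == n, length(speed_mps) == n)
  wrap <- function(a) ((a + 180) %% 360) - 180
  yaw <- rep(NA_real_, n)
  prev <- NA_real_
  for (i in seq_len(n)) {
    if (is.na(axis_deg[i])) { yaw[i] <- prev; next }
    cand <- wrap(c(axis_deg[i], axis_deg[i] - 180))
    use_vel <- !is.na(speed_mps[i]) && speed_mps[i] >= min_speed &&
      !is.na(velocity_deg[i])
    if (use_vel) {
      d <- abs(wrap(cand - velocity_deg[i]))
      if (min(d) > 90 - ambig_margin && !is.na(prev)) {
        dp <- abs(wrap(cand - prev))
        yaw[i] <- cand[which.min(dp)]
      } else {
        yaw[i] <- cand[which.min(d)]
      }
    } else if (!is.na(prev)) {
      dp <- abs(wrap(cand - prev))
      yaw[i] <- cand[which.min(dp)]
    }
    prev <- yaw[i]
  }
  list(yaw_deg = yaw, resolved = !is.na(yaw))
}

#' Resolve tracked body-axis angles to wall-relative yaw
#'
#' Converts a floor-plane (top camera) metric axis angle into the two
#' candidate wall-relative yaw directions and applies [resolve_heading()]
#' using the trajectory's own velocity.
#'
#' @param traj data frame with `x_m`, `z_m` and `axis_metric_deg` (angle of
#'   the body line in the x-z plane, from +x towards +z, `[0, 180)`).
#' @param fps frame rate.
#' @param min_speed see [resolve_heading()].
#' @return Vector of yaw angles (degrees, `(-180, 180]`, 0 = facing the
#'   wall, positive counter-clockwise seen from above).
#' @export
resolve_trajectory_yaw <- function(traj, fps, min_speed = 0.02) {
  th <- traj$axis_metric_deg * pi / 180
  # body line direction (cos th, sin th) in (x, z) -> yaw = atan2(dx, -dz)
  axis_yaw <- (atan2(cos(th), -sin(th)) * 180 / pi) %% 180
  kin <- compute_kinematics(data.frame(x_m = traj$x_m, y_m = 0,
                                       z_m = traj$z_m), fps)
  resolve_heading(axis_yaw, kin$heading_deg, kin$speed_mps,
                  min_speed = min_speed)$yaw_deg
}

#' Landing speed threshold by 1-D 2-means clustering
#'
#' Clusters the near-feeder speed sample into two groups (K-means, K = 2,
#' deterministic initialisation at the sample minimum and maximum, run to
#' convergence). The slow cluster is the landing/contact regime; the
#' threshold is the midpoint of the two cluster centres.
#'
#' @param speeds numeric vector of speeds (m/s) observed near feeders.
#' @return List with `threshold`, `centers` (slow, fast) and the cluster
#'   `assignment` (1 = slow, 2 = fast) of each input speed.
#' @export
landing_speed_threshold <- function(speeds) {
  speeds <- speeds[is.finite(speeds)]
  if (length(speeds) < 10) stop("at least 10 speed samples are required")
  if (stats::var(speeds) == 0) stop("degenerate sample: all speeds identical")
  c1 <- min(speeds); c2 <- max(speeds)
  repeat {
    cut <- (c1 + c2) / 2
    g1 <- speeds < cut
    if (!any(g1) || all(g1)) stop("degenerate cluster")
    n1 <- mean(speeds[g1]); n2 <- mean(speeds[!g1])
    if (isTRUE(all.equal(c(n1, n2), c(c1, c2), tolerance = 1e-12))) break
    c1 <- n1; c2 <- n2
  }
  list(threshold = (c1 + c2) / 2, centers = c(c1, c2),
       assignment = ifelse(speeds < (c1 + c2) / 2, 1L, 2L))
}

#' Detect landing/contact choice events near feeders
#'
#' A choice is a maximal run of frames closer than `feeder_radius` to a
#' feeder (the disc centre at the wall) with speed below the landing
#' threshold, lasting at least `min_dwell_s`. Runs at the same feeder
#' separated by less than `merge_gap_s` are merged. A choice is correct
#' when its stimulus carries the rewarded pattern.
#'
#' @param traj trajectory data frame (`x_m`, `y_m`, `z_m`).
#' @param kin kinematics from [compute_kinematics()].
#' @param layout a stimulus layout ([standard_layout()]).
#' @param threshold landing speed threshold (m/s), see
#'   [landing_speed_threshold()].
#' @param fps frame rate.
#' @param feeder_radius_m proximity radius around the feeder entrance.
#' @param min_dwell_s minimum contact duration.
#' @param merge_gap_s gap below which consecutive contacts at one feeder
#'   count as a single choice.
#' @return Data frame of choices ordered by onset: `stimulus`, `pattern`,
#'   `valence`, `frame_on`, `frame_off`, `t_on`, `correct`.
#' @export
detect_choices <- function(traj, kin, layout, threshold, fps,
                           feeder_radius_m = 0.01, min_dwell_s = 0.1,
                           merge_gap_s = 0.5) {
  stopifnot(threshold > 0)
  out <- list()
  for (s in seq_len(nrow(layout))) {
    d <- sqrt((traj$x_m - layout$cx[s])^2 + (traj$y_m - layout$cy[s])^2 +
                traj$z_m^2)
    hit <- d < feeder_radius_m & kin$speed_mps < threshold
    r <- rle(hit)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    on <- starts[r$values]; off <- ends[r$values]
    if (length(on) == 0) next
    # merge runs separated by short gaps
    k <- 1L
    while (k < length(on)) {
      if ((on[k + 1] - off[k] - 1) / fps < merge_gap_s) {
        off[k] <- off[k + 1]; on <- on[-(k + 1)]; off <- off[-(k + 1)]
      } else k <- k + 1L
    }
    keep <- (off - on + 1) / fps >= min_dwell_s
    if (!any(keep)) next
    out[[length(out) + 1L]] <-
      data.frame(stimulus = layout$id[s], pattern = layout$pattern[s],
                 valence = layout$valence[s],
                 frame_on = on[keep], frame_off = off[keep])
  }
  if (length(out) == 0) {
    return(data.frame(stimulus = integer(), pattern = character(),
                      valence = character(), frame_on = integer(),
                      frame_off = integer(), t_on = numeric(),
                      correct = logical()))
  }
  ch <- do.call(rbind, out)
  ch <- ch[order(ch$frame_on), ]
  ch$t_on <- (ch$frame_on - 1) / fps
  ch$correct <- ch$valence == "rewarded"
  rownames(ch) <- NULL
  ch
}

#' Segment stimulus inspections
#'
#' An inspection event is a maximal run of frames inside one stimulus ROI
#' cylinder (diameter `roi_diameter` around the pattern centre, extending
#' `roi_depth` out from the wall). Events containing a choice are labelled
#' accept, the rest reject. Hover (inspection) time counts the in-ROI
#' frames up to the landing onset for accepts — the bee is no longer
#' hovering once it sits on the feeder — and the whole run for rejects.
#' Each event's scanned regions and region category come from
#' [classify_regions()] applied to its pre-decision frames.
#'
#' @inheritParams detect_choices
#' @param choices choice events from [detect_choices()].
#' @param roi_diameter,roi_depth ROI cylinder dimensions (metres).
#' @return Data frame of events ordered by onset: `stimulus`, `pattern`,
#'   `valence`, `frame_on`, `frame_off`, `decision`, `correct`, `hover_s`,
#'   `scan_speed_mps`, `category`, and list column `regions` (ordered
#'   region labels visited).
#' @export
segment_inspections <- function(traj, kin, layout, choices, fps,
                                roi_diameter = 0.12, roi_depth = 0.10) {
  stopifnot(roi_diameter > 0, roi_depth > 0)
  if (nrow(layout) >= 2) {
    dd <- as.matrix(stats::dist(layout[, c("cx", "cy")]))
    diag(dd) <- Inf
    if (any(dd < roi_diameter))
      stop("stimulus ROIs overlap for this layout/diameter")
  }
  stim_of <- .roi_membership(traj, layout, roi_diameter, roi_depth)
  r <- rle(stim_of)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  ev <- data.frame(stimulus = r$values[keep], frame_on = starts[keep],
                   frame_off = ends[keep])
  if (nrow(ev) == 0) {
    ev <- data.frame(stimulus = integer(), frame_on = integer(),
                     frame_off = integer(), pattern = character(),
                     valence = character(), decision = character(),
                     correct = logical(), hover_s = numeric(),
                     scan_speed_mps = numeric(), category = character())
    ev$regions <- list()
    return(ev)
  }
  li <- match(ev$stimulus, layout$id)
  ev$pattern <- layout$pattern[li]
  ev$valence <- layout$valence[li]
  ev$decision <- "reject"
  ev$hover_s <- NA_real_
  ev$scan_speed_mps <- NA_real_
  ev$category <- NA_character_
  ev$regions <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    idx <- ev$frame_on[i]:ev$frame_off[i]
    land_on <- NA_integer_
    if (nrow(choices) > 0) {
      hit <- choices$stimulus == ev$stimulus[i] &
        choices$frame_on >= ev$frame_on[i] & choices$frame_on <= ev$frame_off[i]
      if (any(hit)) {
        ev$decision[i] <- "accept"
        land_on <- min(choices$frame_on[hit])
      }
    }
    pre <- if (is.na(land_on)) idx else idx[idx < land_on]
    if (length(pre) == 0) pre <- idx[1]
    ev$hover_s[i] <- length(pre) / fps
    ev$scan_speed_mps[i] <- mean(kin$speed_mps[pre], na.rm = TRUE)
    cl <- classify_regions(traj$x_m[pre], traj$y_m[pre],
                           centre = c(layout$cx[li[i]], layout$cy[li[i]]),
                           radius = layout$diameter[li[i]] / 2)
    ev$category[i] <- cl$category
    ev$regions[[i]] <- cl$visited
  }
  ev$correct <- (ev$decision == "accept") == (ev$valence == "rewarded")
  ev <- ev[, c("stimulus", "pattern", "valence", "frame_on", "frame_off",
               "decision", "correct", "hover_s", "scan_speed_mps",
               "category", "regions")]
  rownames(ev) <- NULL
  ev
}

#' Classify the scanned regions of an inspection
#'
#' Bins pre-decision in-ROI positions (those within 1.5 disc radii of the
#' centre) into a 3-column by 2-row partition of the disc's bounding
#' square: columns are the left/centre/right thirds, rows split at the
#' horizontal midline, with the whole top row merged into "top/other".
#' The event category is `both-corners` when both lower corners hold at
#' least 10% of the frames; otherwise the plurality lower cell
#' (`lower-left`, `lower-centre`, `lower-right`); otherwise `top/other`.
#'
#' @param x,y pre-decision frame positions (metres, wall frame).
#' @param centre disc centre `c(cx, cy)`.
#' @param radius disc radius (metres).
#' @param corner_floor minimum frame share per corner for `both-corners`.
#' @return List with `labels` (per frame, NA outside 1.5 radii), `visited`
#'   (ordered unique-run sequence of labels) and `category`.
#' @export
classify_regions <- function(x, y, centre, radius, corner_floor = 0.10) {
  dx <- x - centre[1]; dy <- y - centre[2]
  near <- sqrt(dx^2 + dy^2) <= 1.5 * radius
  lab <- rep(NA_character_, length(x))
  coli <- cut(dx, c(-Inf, -radius / 3, radius / 3, Inf), labels = FALSE)
  lower <- dy < 0
  lab[near & lower & coli == 1] <- "lower_left"
  lab[near & lower & coli == 2] <- "lower_centre"
  lab[near & lower & coli == 3] <- "lower_right"
  lab[near & !lower] <- "top"
  present <- lab[!is.na(lab)]
  visited <- rle(present)$values
  n <- length(present)
  if (n == 0) {
    return(list(labels = lab, visited = character(), category = "top/other"))
  }
  share <- table(factor(present, levels = c("lower_left", "lower_centre",
                                            "lower_right", "top"))) / n
  category <- if (share[["lower_left"]] >= corner_floor &&
                  share[["lower_right"]] >= corner_floor) {
    "both-corners"
  } else {
    top_cell <- names(share)[which.max(share)]
    switch(top_cell, lower_left = "lower-left",
           lower_centre = "lower-centre", lower_right = "lower-right",
           "top/other")
  }
  list(labels = lab, visited = visited, category = category)
}

#' Per-bee test summary over the scoring window
#'
#' Scores each bee's unrewarded test: the proportion of correct choices
#' among choices starting within the first `window_s` seconds, the first
#' inspected stimulus (earliest ROI entry), and counts of inspection events
#' per region category and decision.
#'
#' @param events inspection events from [segment_inspections()]; may carry
#'   a `bee` column (single bee assumed otherwise).
#' @param choices choice events from [detect_choices()], same convention.
#' @param window_s scoring window from trial start (seconds).
#' @param fps frame rate used to time event onsets.
#' @return Data frame with one row per bee: `bee`, `n_choices`,
#'   `prop_correct` (NA and `undefined = TRUE` when the bee made no choice
#'   in the window), `first_stimulus`, `first_pattern`; category-by-decision
#'   counts in `attr(, "category_counts")`.
#' @export
summarize_test <- function(events, choices, window_s = 120, fps = 240) {
  stopifnot(window_s > 0)
  if (!"bee" %in% names(events)) events$bee <- 1L
  if (!"bee" %in% names(choices)) choices$bee <- 1L
  bees <- sort(unique(c(events$bee, choices$bee)))
  rows <- lapply(bees, function(b) {
    ch <- choices[choices$bee == b & choices$t_on < window_s, , drop = FALSE]
    evb <- events[events$bee == b, , drop = FALSE]
    first_i <- if (nrow(evb)) which.min(evb$frame_on) else NA_integer_
    data.frame(bee = b, n_choices = nrow(ch),
               prop_correct = if (nrow(ch)) mean(ch$correct) else NA_real_,
               undefined = nrow(ch) == 0,
               first_stimulus = if (is.na(first_i)) NA_integer_ else
                 evb$stimulus[first_i],
               first_pattern = if (is.na(first_i)) NA_character_ else
                 evb$pattern[first_i])
  })
  out <- do.call(rbind, rows)
  counts <- as.data.frame(table(bee = events$bee, category = events$category,
                                decision = events$decision))
  names(counts)[4] <- "n"
  attr(out, "category_counts") <- counts
  out
}
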