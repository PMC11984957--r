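#' Render synthetic camera frames for a trajectory
#'
#' Produces a bee-free mask frame (the arena scene: grey background, white
#' pattern discs with dark bars for the front camera; wall band and feeder
#' marks for the top camera) and, per trajectory frame, the same scene with
#' one filled dark ellipse at the projected bee position, rotated to the
#' body yaw, plus Gaussian pixel noise. Projection is scaled orthographic
#' onto the camera plane (front camera images the wall x-y plane, top camera
#' the x-z plane); an optional projective distortion emulates an oblique
#' mounting for calibration tests.
#'
#' Frames are generated lazily: the returned object holds a `frame(i)`
#' closure, so long sequences never live in memory at once. Each frame is a
#' deterministic function of the scene seed and the frame index.
#'
#' @param trajectory a trajectory data frame from [simulate_trial()] (columns
#'   `x_m`, `y_m`, `z_m`, `yaw_deg`), with fps attribute matching the camera.
#' @param arena an [arena_config()].
#' @param camera a [camera_descriptor()].
#' @param seed integer seed for the pixel noise.
#' @param bee_length_m body length of the rendered bee (2:1 ellipse).
#' @param noise_sd Gaussian pixel noise sd (intensity scale 0-1).
#' @param distort either `FALSE` or a 3x3 homography applied to ideal pixel
#'   coordinates (see [keystone_homography()]).
#' @return An object of class `bee_scene`: list with `mask`, `frame(i)`,
#'   `n_frames`, `camera`, `px_per_m`, ground-truth projected centroids
#'   (`truth_px`), image-plane axis angles (`truth_axis_deg`), and the
#'   reference-point calibration table (`ref_points`).
#' @export
render_frames <- function(trajectory, arena, camera, seed = 1L,
                          bee_length_m = 0.015, noise_sd = 0.02,
                          distort = FALSE) {
  fps <- attr(trajectory, "fps")
  if (!is.null(fps) && abs(fps - camera$fps) > 1e-9)
    stop("trajectory fps does not match camera fps")
  w <- camera$resolution[1]; h <- camera$resolution[2]

  # the top camera's field of view extends a little behind the wall plane
  # so a bee sitting on a feeder is never clipped at the image edge
  z_margin <- if (camera$mounting == "top") 0.02 else 0
  if (camera$mounting == "front") {
    extent <- c(arena$width_m, arena$height_m)
    # u right along the wall, v down from the wall top
    plane_uv <- cbind(trajectory$x_m, arena$height_m - trajectory$y_m)
  } else {
    extent <- c(arena$width_m, arena$depth_m + z_margin)
    # v grows away from the wall (wall just below the top image row)
    plane_uv <- cbind(trajectory$x_m, trajectory$z_m + z_margin)
  }
  sx <- w / extent[1]; sy <- h / extent[2]
  px <- cbind(plane_uv[, 1] * sx, plane_uv[, 2] * sy)

  H <- if (is.matrix(distort)) distort else NULL
  if (!is.null(H)) px <- apply_homography(H, px)

  # body axis projected into the image
  yaw <- trajectory$yaw_deg * pi / 180
  if (camera$mounting == "top") {
    du <- sin(yaw) * sx; dv <- -cos(yaw) * sy
  } else {
    # front view: body axis drawn along the in-plane motion direction
    dx <- c(diff(trajectory$x_m), 0); dy <- c(diff(trajectory$y_m), 0)
    run <- sqrt(dx^2 + dy^2)
    dx <- ifelse(run > 1e-9, dx, 1); dy <- ifelse(run > 1e-9, dy, 0)
    du <- dx * sx; dv <- -dy * sy
  }
  axis_deg <- (atan2(dv, du) * 180 / pi) %% 180

  scene <- .render_scene(arena, camera, sx, sy, H, z_margin)
  a_px <- bee_length_m / 2 * sx   # semi-major in pixels
  seed <- as.integer(seed) %% 100000L

  frame_fun <- function(i) {
    stopifnot(i >= 1, i <= nrow(trajectory))
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed * 20000L + as.integer(i))
    f <- .draw_ellipse(scene, px[i, 1], px[i, 2], a_px, a_px / 2,
                       axis_deg[i], value = 0.08)
    .clip01(f + matrix(stats::rnorm(w * h, 0, noise_sd), h, w))
  }
  mask_fun <- function() {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed * 20000L)
    .clip01(scene + matrix(stats::rnorm(w * h, 0, noise_sd), h, w))
  }

  # calibration reference points: the four corners of the imaged plane
  ref_m <- rbind(c(0, 0), c(extent[1], 0), c(0, extent[2]), extent)
  ref_px <- cbind(ref_m[, 1] * sx, ref_m[, 2] * sy)
  if (!is.null(H)) ref_px <- apply_homography(H, ref_px)
  # metric reference coordinates in the arena frame of the imaged plane
  ref_arena <- if (camera$mounting == "front") {
    cbind(ref_m[, 1], arena$height_m - ref_m[, 2])   # (x, y)
  } else {
    cbind(ref_m[, 1], ref_m[, 2] - z_margin)         # (x, z)
  }

  structure(list(mask = mask_fun(), frame = frame_fun,
                 n_frames = nrow(trajectory), camera = camera,
                 px_per_m = c(sx, sy), truth_px = px,
                 truth_axis_deg = axis_deg,
                 ref_points = list(px = ref_px, metric = ref_arena),
                 seed = seed),
            class = "bee_scene")
}

.clip01 <- function(m) { m[m < 0] <- 0; m[m > 1] <- 1; m }

# static arena scene (no bee), intensity matrix h x w in [0,1]
.render_scene <- function(arena, camera, sx, sy, H, z_margin = 0) {
  w <- camera$resolution[1]; h <- camera$resolution[2]
  m <- matrix(0.35, h, w)
  if (camera$mounting == "front") {
    uc <- col(m) - 0.5; vc <- row(m) - 0.5
    if (!is.null(H)) {
      ideal <- apply_homography(solve(H), cbind(as.vector(uc), as.vector(vc)))
      uc <- matrix(ideal[, 1], h, w); vc <- matrix(ideal[, 2], h, w)
    }
    xm <- uc / sx; ym <- arena$height_m - vc / sy
    for (s in seq_len(nrow(arena$layout))) {
      cx <- arena$layout$cx[s]; cy <- arena$layout$cy[s]
      r <- arena$layout$diameter[s] / 2
      dx <- xm - cx; dy <- ym - cy
      m[dx^2 + dy^2 <= r^2] <- 0.90
      bw <- 0.010; bl <- 0.080   # bar half-geometry drawn below
      if (arena$layout$pattern[s] == "plus") {
        m[abs(dx) <= bw / 2 & abs(dy) <= bl / 2] <- 0.15
        m[abs(dy) <= bw / 2 & abs(dx) <= bl / 2] <- 0.15
      } else {
        d1 <- (dx + dy) / sqrt(2); d2 <- (dx - dy) / sqrt(2)
        m[abs(d1) <= bw / 2 & abs(d2) <= bl / 2] <- 0.15
        m[abs(d2) <= bw / 2 & abs(d1) <= bl / 2] <- 0.15
      }
    }
  } else {
    # rear wall band fills the behind-wall margin at the top of the image
    band <- max(1, round(z_margin * sy))
    m[1:band, ] <- 0.55
    for (s in seq_len(nrow(arena$layout))) {  # feeder tube marks
      u <- round(arena$layout$cx[s] * sx)
      m[max(1, band - 4):band, max(1, u - 2):min(w, u + 2)] <- 0.85
    }
  }
  m
}

# draw an anti-aliased filled ellipse over a copy of the scene
.draw_ellipse <- function(scene, uc, vc, a, b, angle_deg, value) {
  h <- nrow(scene); w <- ncol(scene)
  ext <- ceiling(a) + 2L
  c0 <- max(1L, floor(uc) - ext); c1 <- min(w, ceiling(uc) + ext)
  r0 <- max(1L, floor(vc) - ext); r1 <- min(h, ceiling(vc) + ext)
  if (c0 > c1 || r0 > r1) return(scene)
  cols <- c0:c1; rows <- r0:r1
  du <- outer(rep(1, length(rows)), cols - 0.5 - uc)
  dv <- outer(rows - 0.5 - vc, rep(1, length(cols)))
  th <- angle_deg * pi / 180
  p <- du * cos(th) + dv * sin(th)
  q <- -du * sin(th) + dv * cos(th)
  d <- sqrt((p / a)^2 + (q / b)^2)
  alpha <- pmin(1, pmax(0, (1 - d) * b + 0.5))   # ~1-px soft edge
  patch <- scene[rows, cols]
  scene[rows, cols] <- patch * (1 - alpha) + value * alpha
  scene
}

#' Mild keystone homography for calibration tests
#'
#' Maps ideal pixel coordinates to obliquely distorted ones by displacing
#' the four image corners by a few pixels, emulating an off-axis camera.
#'
#' @param resolution image size `c(width, height)` in pixels.
#' @param amount maximum corner displacement in pixels.
#' @return A 3x3 homography matrix.
#' @export
keystone_homography <- function(resolution, amount = 12) {
  w <- resolution[1]; h <- resolution[2]
  src <- rbind(c(0, 0), c(w, 0), c(0, h), c(w, h))
  dst <- src + rbind(c(amount, amount / 2), c(-amount / 2, amount / 3),
                     c(amount / 3, -amount / 2), c(-amount, -amount / 3))
  fit_homography(src, dst)
}

#' Write a rendered scene to disk as a PNG sequence
#'
#' @param scene a `bee_scene` from [render_frames()].
#' @param dir output directory (created if needed).
#' @param indices frame indices to write (default all).
#' @return Invisibly, a list with the mask path and the frame paths.
#' @export
write_frames <- function(scene, dir, indices = seq_len(scene$n_frames)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask_path <- file.path(dir, "mask.png")
  png::writePNG(scene$mask, mask_path)
  paths <- file.path(dir, sprintf("frame_%05d.png", indices))
  for (k in seq_along(indices))
    png::writePNG(scene$frame(indices[k]), paths[k])
  invisible(list(mask = mask_path, frames = paths))
}
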