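#' Fit a planar projective transform (homography)
#'
#' Least-squares DLT fit of the 8-parameter homography mapping `src` points
#' to `dst` points. At least four non-collinear correspondences are needed.
#'
#' @param src,dst n x 2 matrices of corresponding points.
#' @return A 3x3 matrix `H` with `H[3,3] == 1`.
#' @export
fit_homography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(nrow(src) == nrow(dst), ncol(src) == 2, ncol(dst) == 2)
  if (nrow(src) < 4) stop("at least 4 reference points are required")
  if (qr(cbind(src, 1))$rank < 3) stop("reference points are collinear")
  n <- nrow(src)
  A <- matrix(0, 2 * n, 8); b <- numeric(2 * n)
  for (i in seq_len(n)) {
    x <- src[i, 1]; y <- src[i, 2]; X <- dst[i, 1]; Y <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -x * X, -y * X)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -x * Y, -y * Y)
    b[2 * i - 1] <- X; b[2 * i] <- Y
  }
  hv <- qr.solve(A, b)
  matrix(c(hv, 1), 3, 3, byrow = TRUE)
}

#' Apply a homography to points
#'
#' @param H 3x3 homography matrix.
#' @param pts n x 2 matrix (or length-2 vector) of points.
#' @return n x 2 matrix of mapped points.
#' @export
apply_homography <- function(H, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  ph <- cbind(pts, 1) %*% t(H)
  if (any(abs(ph[, 3]) < 1e-12)) stop("point maps to projective infinity")
  ph[, 1:2] / ph[, 3]
}

#' Camera calibration model
#'
#' Builds the invertible pixel-to-metric mapping for one camera from at
#' least four reference points with known pixel and metric coordinates on
#' the imaged plane (the rear wall for the front camera, the floor plane
#' for the top camera).
#'
#' @param ref_px n x 2 pixel coordinates of the reference points.
#' @param ref_m n x 2 metric coordinates (arena frame) of the same points.
#' @param resolution image size in pixels.
#' @param fps camera frame rate.
#' @param plane `"wall"` (coordinates x, y) or `"floor"` (coordinates x, z).
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(ref_px, ref_m, resolution, fps,
                         plane = c("wall", "floor")) {
  plane <- match.arg(plane)
  H <- fit_homography(ref_px, ref_m)
  Hinv <- fit_homography(ref_m, ref_px)
  structure(list(H = H, Hinv = Hinv, resolution = resolution, fps = fps,
                 plane = plane, ref_px = as.matrix(ref_px),
                 ref_m = as.matrix(ref_m)),
            class = "camera_model")
}

#' Convert pixel coordinates to metric plane coordinates
#'
#' @param camera a [camera_model()].
#' @param pts n x 2 pixel coordinates.
#' @return n x 2 metric coordinates on the imaged plane (metres).
#' @export
px_to_metric <- function(camera, pts) apply_homography(camera$H, pts)

#' Convert metric plane coordinates to pixels
#' @inheritParams px_to_metric
#' @param pts n x 2 metric coordinates.
#' @export
metric_to_px <- function(camera, pts) apply_homography(camera$Hinv, pts)

#' Pixel area bounds for a bee-sized blob
#'
#' Derives the blob-area acceptance window from the camera scale and a
#' plausible bee length range, rather than hard-coded pixel counts. The
#' rendered/observed bee is taken as a 2:1 ellipse, area pi L^2 / 8.
#'
#' @param px_per_m pixels per metre on the imaged plane.
#' @param length_range_m bee body length range in metres.
#' @return `c(min_area, max_area)` in px^2.
#' @export
bee_area_bounds <- function(px_per_m, length_range_m = c(0.012, 0.020)) {
  area <- pi * (length_range_m * px_per_m)^2 / 8
  c(0.4 * area[1], 1.8 * area[2])
}

#' Moments-based ellipse fit of a pixel blob
#'
#' Fits the second-central-moment equivalent ellipse of a set of pixels.
#' The axis angle is measured in image coordinates from the +u (column)
#' axis towards +v (row), in `[0, 180)`. Blobs with axis ratio below 1.2
#' are flagged `ambiguous`: their orientation is not reliable.
#'
#' @param blob either an n x 2 matrix of pixel coordinates `(u, v)` or a
#'   logical/0-1 matrix whose TRUE/nonzero cells form the blob.
#' @return List with `major`, `minor` (full axis lengths, px), `axis_deg`
#'   in `[0, 180)`, `centroid`, `area`, `ambiguous`.
#' @export
fit_body_ellipse <- function(blob) {
  if (is.matrix(blob) && ncol(blob) != 2) {
    idx <- which(blob != 0, arr.ind = TRUE)
    blob <- cbind(u = idx[, 2], v = idx[, 1])
  }
  blob <- as.matrix(blob)
  if (nrow(blob) == 0) stop("empty blob")
  cu <- mean(blob[, 1]); cv <- mean(blob[, 2])
  du <- blob[, 1] - cu; dv <- blob[, 2] - cv
  # +1/12: variance of the unit-pixel footprint
  m20 <- mean(du^2) + 1 / 12
  m02 <- mean(dv^2) + 1 / 12
  m11 <- mean(du * dv)
  common <- sqrt((m20 - m02)^2 + 4 * m11^2)
  l1 <- (m20 + m02 + common) / 2
  l2 <- (m20 + m02 - common) / 2
  l2 <- max(l2, 1e-9)
  angle <- (atan2(2 * m11, m20 - m02) / 2 * 180 / pi) %% 180
  list(major = 4 * sqrt(l1), minor = 4 * sqrt(l2),
       axis_deg = angle, centroid = c(cu, cv), area = nrow(blob),
       ambiguous = sqrt(l1 / l2) < 1.2)
}

# Otsu threshold on a 256-bin histogram of intensities in [0,1]
.otsu_threshold <- function(x, n_bins = 256L) {
  h <- tabulate(pmin(n_bins, floor(as.vector(x) * n_bins) + 1L), n_bins)
  p <- h / sum(h)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# all background-subtraction blob candidates within the area window
.detect_candidates <- function(frame, mask, min_area, max_area,
                               intensity_threshold = 0.1) {
  if (!all(dim(frame) == dim(mask))) stop("frame/mask resolution mismatch")
  d <- abs(frame - mask)
  thr <- max(.otsu_threshold(d), intensity_threshold)
  bin <- d > thr
  if (!any(bin)) return(NULL)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin * 1)))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  if (length(keep) == 0) return(NULL)
  out <- lapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    e <- fit_body_ellipse(cbind(idx[, 2], idx[, 1]))
    data.frame(u = e$centroid[1], v = e$centroid[2], area = e$area,
               major = e$major, minor = e$minor, axis_deg = e$axis_deg,
               ambiguous = e$ambiguous)
  })
  do.call(rbind, out)
}

#' Detect the bee in one frame by background subtraction
#'
#' Subtracts the bee-free mask, thresholds the absolute difference (Otsu's
#' threshold, clamped below by `intensity_threshold`), labels connected
#' components and returns the largest one whose area lies within the
#' bee-size window, with its moments ellipse.
#'
#' @param frame,mask numeric image matrices of identical size, intensities
#'   in 0-1.
#' @param min_area,max_area blob area acceptance window, px^2; see
#'   [bee_area_bounds()].
#' @param intensity_threshold minimum difference threshold (0-1).
#' @return A one-row data frame (`u`, `v`, `area`, `major`, `minor`,
#'   `axis_deg`, `ambiguous`), or `NULL` when no candidate survives.
#' @export
detect_bee <- function(frame, mask, min_area, max_area,
                       intensity_threshold = 0.1) {
  stopifnot(min_area < max_area)
  cand <- .detect_candidates(frame, mask, min_area, max_area,
                             intensity_threshold)
  if (is.null(cand)) return(NULL)
  cand[which.max(cand$area), , drop = FALSE]
}

#' Track the bee across a frame sequence
#'
#' Runs [detect_bee()]-style candidate detection on every frame and links
#' detections over time: on the first detected frame the largest candidate
#' is taken; afterwards the candidate nearest the previous confirmed
#' centroid wins, rejected if it jumps farther than `gate_px`.
#'
#' @param frames a `bee_scene` from [render_frames()], a list of image
#'   matrices, a directory containing `frame_*.png`, or a character vector
#'   of PNG paths.
#' @param mask bee-free mask image (taken from the scene when `frames` is a
#'   `bee_scene`; read from `mask.png` for a directory).
#' @param min_area,max_area,intensity_threshold see [detect_bee()].
#' @param gate_px maximum allowed per-frame centroid jump in pixels.
#' @return A `raw_track` data frame with one row per frame: `frame`, `u`,
#'   `v`, `area`, `major`, `minor`, `axis_deg`, `ambiguous`, `missing`.
#' @export
track <- function(frames, mask = NULL, min_area, max_area,
                  intensity_threshold = 0.1, gate_px = 50) {
  if (inherits(frames, "bee_scene")) {
    get_frame <- frames$frame
    n <- frames$n_frames
    if (is.null(mask)) mask <- frames$mask
  } else if (is.list(frames)) {
    get_frame <- function(i) frames[[i]]
    n <- length(frames)
  } else if (is.character(frames)) {
    paths <- frames
    if (length(frames) == 1 && dir.exists(frames)) {
      paths <- sort(list.files(frames, "^frame_.*\\.png$", full.names = TRUE))
      if (is.null(mask)) mask <- .read_gray(file.path(frames, "mask.png"))
    }
    get_frame <- function(i) .read_gray(paths[i])
    n <- length(paths)
  } else stop("unsupported frames input")
  if (n < 1) stop("at least one frame is required")
  if (is.null(mask)) stop("a mask frame is required")

  rows <- vector("list", n)
  prev <- NULL
  for (i in seq_len(n)) {
    cand <- .detect_candidates(get_frame(i), mask, min_area, max_area,
                               intensity_threshold)
    pick <- NULL
    if (!is.null(cand)) {
      if (is.null(prev)) {
        pick <- cand[which.max(cand$area), , drop = FALSE]
      } else {
        dd <- sqrt((cand$u - prev[1])^2 + (cand$v - prev[2])^2)
        j <- which.min(dd)
        if (dd[j] <= gate_px) pick <- cand[j, , drop = FALSE]
      }
    }
    if (is.null(pick)) {
      rows[[i]] <- data.frame(frame = i, u = NA_real_, v = NA_real_,
                              area = NA_real_, major = NA_real_,
                              minor = NA_real_, axis_deg = NA_real_,
                              ambiguous = NA, missing = TRUE)
    } else {
      prev <- c(pick$u, pick$v)
      rows[[i]] <- cbind(data.frame(frame = i), pick,
                         data.frame(missing = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("raw_track", "data.frame")
  out
}

.read_gray <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:3], c(1, 2), mean)
  img
}

# centred moving average with shrinking symmetric-as-possible end windows
.movmean <- function(x, w) {
  n <- length(x)
  if (n == 0 || w <= 1) return(x)
  half <- (w - 1) %/% 2
  cs <- c(0, cumsum(x))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Interpolate detection gaps and smooth a raw track
#'
#' Gaps of at most `max_gap_frames` missing frames are filled by linear
#' interpolation of the centroid; longer gaps split the track into
#' independent segments. Each segment's coordinates are then smoothed with
#' a centred moving average of width `window_frames` (end windows shrink
#' symmetrically), which keeps every smoothed position inside the range of
#' the raw positions that feed it.
#'
#' @param raw a `raw_track` from [track()].
#' @param max_gap_frames longest gap (frames) to bridge by interpolation.
#' @param window_frames odd moving-average width in frames.
#' @return Data frame `frame`, `u`, `v`, `axis_deg`, `ambiguous`,
#'   `interpolated`, `segment` (NA coordinates outside any segment).
#' @export
interpolate_and_smooth <- function(raw, max_gap_frames = 5,
                                   window_frames = 5) {
  stopifnot(window_frames >= 1, window_frames %% 2 == 1)
  n <- nrow(raw)
  out <- data.frame(frame = raw$frame, u = NA_real_, v = NA_real_,
                    axis_deg = raw$axis_deg, ambiguous = raw$ambiguous,
                    interpolated = FALSE, segment = NA_integer_)
  if (n == 0) return(out)
  obs <- which(!raw$missing)
  if (length(obs) == 0) return(out)

  # split at gaps longer than max_gap_frames
  gap_after <- diff(obs) - 1L
  brk <- which(gap_after > max_gap_frames)
  seg_start <- obs[c(1L, brk + 1L)]
  seg_end <- obs[c(brk, length(obs))]
  for (s in seq_along(seg_start)) {
    idx <- seg_start[s]:seg_end[s]
    oi <- obs[obs >= seg_start[s] & obs <= seg_end[s]]
    u <- stats::approx(oi, raw$u[oi], xout = idx)$y
    v <- stats::approx(oi, raw$v[oi], xout = idx)$y
    out$u[idx] <- .movmean(u, window_frames)
    out$v[idx] <- .movmean(v, window_frames)
    out$interpolated[idx] <- !(idx %in% oi)
    out$segment[idx] <- s
  }
  out
}

#' Track a scene and return a calibrated metric trajectory
#'
#' Convenience pipeline: [track()], [interpolate_and_smooth()], then
#' [px_to_metric()] conversion and metric body-axis angle. The metric axis
#' angle is the undirected body line in plane coordinates, in `[0, 180)`
#' measured from the first plane axis towards the second.
#'
#' @param frames,mask see [track()].
#' @param camera a [camera_model()].
#' @param min_area,max_area area window; default from [bee_area_bounds()]
#'   using the camera scale.
#' @param ... passed to [track()].
#' @param max_gap_frames,window_frames see [interpolate_and_smooth()].
#' @return Data frame `frame`, `time_s`, `c1_m`, `c2_m` (plane coordinates:
#'   x,y for the wall plane; x,z for the floor plane), `axis_metric_deg`,
#'   `ambiguous`, `interpolated`, `segment`.
#' @export
track_trajectory <- function(frames, mask = NULL, camera,
                             min_area = NULL, max_area = NULL, ...,
                             max_gap_frames = 5, window_frames = 5) {
  if (is.null(min_area) || is.null(max_area)) {
    sc <- .mean_scale(camera)
    ab <- bee_area_bounds(sc)
    if (is.null(min_area)) min_area <- ab[1]
    if (is.null(max_area)) max_area <- ab[2]
  }
  raw <- track(frames, mask, min_area = min_area, max_area = max_area, ...)
  sm <- interpolate_and_smooth(raw, max_gap_frames, window_frames)
  ok <- !is.na(sm$u)
  met <- matrix(NA_real_, nrow(sm), 2)
  if (any(ok)) met[ok, ] <- px_to_metric(camera, cbind(sm$u[ok], sm$v[ok]))
  axis_m <- rep(NA_real_, nrow(sm))
  ai <- which(ok & !is.na(sm$axis_deg))
  if (length(ai)) {
    th <- sm$axis_deg[ai] * pi / 180
    p0 <- cbind(sm$u[ai], sm$v[ai])
    p1 <- p0 + 5 * cbind(cos(th), sin(th))
    dm <- px_to_metric(camera, p1) - px_to_metric(camera, p0)
    # image v runs opposite to metric y on the wall plane; atan2 on metric
    # components keeps the angle convention consistent with the plane axes
    axis_m[ai] <- (atan2(dm[, 2], dm[, 1]) * 180 / pi) %% 180
  }
  data.frame(frame = sm$frame, time_s = (sm$frame - 1) / camera$fps,
             c1_m = met[, 1], c2_m = met[, 2], axis_metric_deg = axis_m,
             ambiguous = sm$ambiguous, interpolated = sm$interpolated,
             segment = sm$segment)
}

# average pixels-per-metre of a camera model, from its reference points
.mean_scale <- function(camera) {
  dpx <- stats::dist(camera$ref_px)
  dm <- stats::dist(camera$ref_m)
  mean(dpx / dm)
}
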