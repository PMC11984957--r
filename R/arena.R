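#' Arena configuration
#'
#' Describes the flight arena interior, the stimulus layout on the rear wall
#' and the camera rig. The default dimensions correspond to a 60 x 60 cm
#' footprint, 40 cm tall wooden arena whose rear wall carries eight 10-cm
#' pattern discs. Coordinates use the arena frame: `x` right along the rear
#' wall, `y` up, `z` out from the rear wall towards the entrance (all metres,
#' origin at the wall's lower-left corner).
#'
#' @param width_m arena (and rear wall) width in metres.
#' @param height_m rear wall height in metres.
#' @param depth_m distance from rear wall to entrance in metres.
#' @param layout stimulus layout data frame, see [standard_layout()].
#' @param cameras list of camera descriptors, see [camera_descriptor()].
#' @return An object of class `arena_config`.
#' @export
arena_config <- function(width_m = 0.60, height_m = 0.40, depth_m = 0.60,
                         layout = standard_layout(),
                         cameras = list(front = camera_descriptor("front"),
                                        top = camera_descriptor("top"))) {
  stopifnot(width_m > 0, height_m > 0, depth_m > 0)
  if (nrow(layout) > 0) {
    r <- layout$diameter / 2
    inside <- layout$cx - r >= 0 & layout$cx + r <= width_m &
      layout$cy - r >= 0 & layout$cy + r <= height_m
    if (!all(inside)) stop("stimulus discs must lie inside the rear wall")
  }
  structure(list(width_m = width_m, height_m = height_m, depth_m = depth_m,
                 layout = layout, cameras = cameras),
            class = "arena_config")
}

#' Camera descriptor
#'
#' @param mounting `"front"` (views the rear wall, x-y plane) or `"top"`
#'   (views the floor plane from above, x-z plane).
#' @param resolution image size in pixels, `c(width, height)`.
#' @param fps frame rate; the front camera records at 240 fps and the top
#'   camera at 120 fps by default.
#' @return A list of class `camera_descriptor`.
#' @export
camera_descriptor <- function(mounting = c("front", "top"),
                              resolution = c(1280, 720),
                              fps = NULL) {
  mounting <- match.arg(mounting)
  if (is.null(fps)) fps <- if (mounting == "front") 240 else 120
  stopifnot(length(resolution) == 2, all(resolution > 0), fps > 0)
  structure(list(mounting = mounting,
                 resolution = as.integer(resolution), fps = fps),
            class = "camera_descriptor")
}

#' Standard eight-disc stimulus layout
#'
#' Eight 10-cm laminated discs arranged in two rows of four on the rear wall,
#' four carrying a plus pattern and four a multiplication pattern. Valence
#' follows the training group: group 1 is rewarded on plus and punished on
#' multiplication, group 2 the reverse.
#'
#' @param group training group, 1 or 2.
#' @param width_m,height_m rear wall dimensions (metres).
#' @param diameter disc diameter in metres (default 0.10).
#' @param seed optional integer; when given, pattern identities are shuffled
#'   over positions reproducibly, otherwise they alternate.
#' @return Data frame with columns `id`, `pattern`, `valence`, `cx`, `cy`,
#'   `diameter` (class `stimuli_layout`).
#' @export
standard_layout <- function(group = 1, width_m = 0.60, height_m = 0.40,
                            diameter = 0.10, seed = NULL) {
  stopifnot(group %in% c(1, 2))
  cx <- rep(seq(width_m / 8, width_m * 7 / 8, length.out = 4), 2)
  cy <- rep(c(height_m * 0.3, height_m * 0.7), each = 4)
  pattern <- rep(c("plus", "mult"), 4)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    pattern <- sample(pattern)
  }
  rewarded <- if (group == 1) "plus" else "mult"
  out <- data.frame(id = seq_len(8), pattern = pattern,
                    valence = ifelse(pattern == rewarded, "rewarded", "punished"),
                    cx = cx, cy = cy, diameter = diameter)
  validate_layout(out)
  class(out) <- c("stimuli_layout", "data.frame")
  out
}

validate_layout <- function(layout) {
  stopifnot(is.data.frame(layout),
            all(c("id", "pattern", "valence", "cx", "cy", "diameter") %in%
                  names(layout)))
  if (anyDuplicated(layout$id)) stop("stimulus ids must be unique")
  if (nrow(layout) >= 2) {
    d <- as.matrix(stats::dist(layout[, c("cx", "cy")]))
    diag(d) <- Inf
    rsum <- outer(layout$diameter / 2, layout$diameter / 2, `+`)
    if (any(d < rsum)) stop("stimulus discs overlap")
  }
  invisible(layout)
}

# save/restore the global RNG state so helpers with local seeds do not
# disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
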