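#' Occupancy heatmap over a stimulus-centred window
#'
#' Bins in-ROI positions in stimulus-centred coordinates and normalises the
#' counts to a probability map, pooling frames across events, bees and
#' stimuli of the same pattern type.
#'
#' @param dx,dy positions relative to the stimulus centre (metres); or pass
#'   `x`, `y` with `centre` to have them centred here.
#' @param bin_size_m bin side length (default 5 mm).
#' @param half_extent_m half-width of the square grid; the default covers
#'   the 12-cm ROI diameter.
#' @param x,y,centre optional absolute coordinates plus disc centre.
#' @return Object of class `bee_heatmap`: list with `prob` (matrix, rows =
#'   dy bins from low to high), `xedges`, `yedges`, `n`.
#' @export
position_heatmap <- function(dx = NULL, dy = NULL, bin_size_m = 0.005,
                             half_extent_m = 0.06, x = NULL, y = NULL,
                             centre = NULL) {
  if (is.null(dx)) {
    stopifnot(!is.null(x), !is.null(y), !is.null(centre))
    dx <- x - centre[1]; dy <- y - centre[2]
  }
  keep <- is.finite(dx) & is.finite(dy) & abs(dx) <= half_extent_m &
    abs(dy) <= half_extent_m
  dx <- dx[keep]; dy <- dy[keep]
  if (length(dx) == 0) stop("no in-window positions to bin")
  edges <- seq(-half_extent_m, half_extent_m, by = bin_size_m)
  nb <- length(edges) - 1
  xi <- pmin(nb, pmax(1, findInterval(dx, edges, rightmost.closed = TRUE)))
  yi <- pmin(nb, pmax(1, findInterval(dy, edges, rightmost.closed = TRUE)))
  counts <- matrix(0, nb, nb)
  for (i in seq_along(xi)) counts[yi[i], xi[i]] <- counts[yi[i], xi[i]] + 1
  structure(list(prob = counts / sum(counts), xedges = edges, yedges = edges,
                 n = length(dx)),
            class = "bee_heatmap")
}

#' @export
plot.bee_heatmap <- function(x, ...) {
  graphics::image(x = x$xedges, y = x$yedges, z = t(x$prob),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "dx (m)", ylab = "dy (m)", asp = 1, ...)
  invisible(x)
}

#' Probability distribution summary of a kinematic variable
#'
#' Histogram normalised to probability mass, with the sample median and a
#' bootstrap standard error of the median.
#'
#' @param values numeric sample (speeds, wall distances or yaw angles).
#' @param variable name of the variable.
#' @param bin_width histogram bin width (defaults: 0.02 m/s for speed,
#'   0.005 m for wall distance, 5 degrees for yaw).
#' @param n_boot bootstrap resamples for the SEM of the median.
#' @param seed seed for the bootstrap.
#' @return Object of class `distribution_summary`: list with `variable`,
#'   `edges`, `prob`, `median`, `sem_median`, `n`.
#' @export
distribution_summary <- function(values, variable = "speed",
                                 bin_width = NULL, n_boot = 1000,
                                 seed = 1L) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("at least two values are required")
  if (is.null(bin_width))
    bin_width <- switch(variable, speed = 0.02, wall_distance = 0.005,
                        yaw = 5, diff(range(values)) / 20)
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(values, breaks = edges, plot = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  boots <- vapply(seq_len(n_boot), function(i)
    stats::median(sample(values, replace = TRUE)), numeric(1))
  structure(list(variable = variable, edges = edges,
                 prob = h$counts / sum(h$counts),
                 median = stats::median(values),
                 sem_median = stats::sd(boots), n = length(values)),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, median = %.3g (+/- %.2g SEM, bootstrap)\n",
              x$variable, x$n, x$median, x$sem_median))
  invisible(x)
}

#' @export
plot.distribution_summary <- function(x, ...) {
  mids <- (x$edges[-1] + x$edges[-length(x$edges)]) / 2
  graphics::plot(mids, x$prob, type = "h", lwd = 6, lend = 1,
                 xlab = x$variable, ylab = "probability", ...)
  graphics::abline(v = x$median, lty = 2)
  invisible(x)
}

#' Scanned-region proportions per group and decision
#'
#' For each group-by-decision cell, computes each bee's proportion of
#' inspection events per region category, then averages across bees (the
#' bee, not the event, is the unit of replication) with the standard error
#' of that mean. Cells with a single bee get `sem = NA` and are flagged;
#' empty cells are absent from the output.
#'
#' @param events inspection events with columns `bee`, `category`,
#'   `decision` and optionally `group` (a single group is assumed
#'   otherwise).
#' @return Data frame `group`, `decision`, `category`, `mean`, `sem`,
#'   `n_bees`, `single_bee` flag.
#' @export
region_proportion_table <- function(events) {
  if (!"group" %in% names(events)) events$group <- 1L
  if (!"bee" %in% names(events)) events$bee <- 1L
  cats <- c("lower-left", "lower-centre", "lower-right", "both-corners",
            "top/other")
  out <- list()
  for (g in unique(events$group)) for (d in unique(events$decision)) {
    sub <- events[events$group == g & events$decision == d, , drop = FALSE]
    if (nrow(sub) == 0) next
    per_bee <- t(vapply(split(sub$category, sub$bee), function(cc)
      as.numeric(table(factor(cc, levels = cats)) / length(cc)),
      numeric(length(cats))))
    nb <- nrow(per_bee)
    out[[length(out) + 1L]] <- data.frame(
      group = g, decision = d, category = cats,
      mean = colMeans(per_bee),
      sem = if (nb > 1) apply(per_bee, 2, stats::sd) / sqrt(nb) else NA_real_,
      n_bees = nb, single_bee = nb == 1, row.names = NULL)
  }
  do.call(rbind, out)
}
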