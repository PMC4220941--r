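# Kernel-smoothed intensity surfaces of the colony point pattern.
#
# Reproduces the computation behind the study-site density maps: an
# isotropic Gaussian kernel estimate of expected points per unit area on a
# regular grid, optionally weighted by per-colony disease-reoccurrence
# counts, with edge correction for the rectangular observation window.

#' Kernel-smoothed intensity surface of a point pattern
#'
#' Isotropic Gaussian kernel estimate of the expected number of (weighted)
#' points per unit area over a rectangular window. With the default
#' `"uniform"` edge correction the estimate at location u is divided by the
#' kernel mass falling inside the window around u; `"diggle"` instead
#' divides each point's contribution by the kernel mass around that point
#' (which conserves total mass exactly).
#'
#' @param points two-column matrix or data.frame of planar coordinates (m);
#'   a data.frame with `easting`/`northing` columns is also accepted.
#' @param window rectangle `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   bounding box of the points.
#' @param bandwidth kernel standard deviation in metres; default is the mean
#'   of the per-axis Silverman rules `1.06 sd n^(-1/5)`.
#' @param weights optional non-negative per-point weights (default 1).
#' @param grid_dim grid resolution, `c(nx, ny)` (default 128 x 128).
#' @param edge edge-correction rule: `"uniform"`, `"diggle"` or `"none"`.
#' @return object of class `wp_intensity`: list with `x`, `y` (cell-centre
#'   coordinates), `values` (nx x ny matrix, points per m^2), `bandwidth`,
#'   `weights_label` and `window`.
#' @export
kernel_intensity <- function(points, window = NULL, bandwidth = NULL,
                             weights = NULL, grid_dim = c(128, 128),
                             edge = c("uniform", "diggle", "none")) {
  edge <- match.arg(edge)
  if (is.data.frame(points)) {
    if (all(c("easting", "northing") %in% names(points)))
      points <- cbind(points$easting, points$northing)
    else points <- as.matrix(points[, 1:2])
  }
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0) stop_wp("empty point set", class = "wp_value_error")
  if (is.null(window))
    window <- c(range(points[, 1]), range(points[, 2]))
  if (is.null(bandwidth)) {
    silverman <- function(v) 1.06 * stats::sd(v) * n^(-1 / 5)
    bandwidth <- mean(c(silverman(points[, 1]), silverman(points[, 2])))
  }
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop_wp("bandwidth must be positive", class = "wp_value_error")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0))
    stop_wp("weights must be non-negative, one per point",
            class = "wp_value_error")

  nx <- grid_dim[1]; ny <- grid_dim[2]
  dx <- (window[2] - window[1]) / nx
  dy <- (window[4] - window[3]) / ny
  gx <- window[1] + (seq_len(nx) - 0.5) * dx
  gy <- window[3] + (seq_len(ny) - 0.5) * dy

  h <- bandwidth
  w_use <- weights
  if (edge == "diggle") {
    ex <- stats::pnorm((window[2] - points[, 1]) / h) -
      stats::pnorm((window[1] - points[, 1]) / h)
    ey <- stats::pnorm((window[4] - points[, 2]) / h) -
      stats::pnorm((window[3] - points[, 2]) / h)
    w_use <- weights / (ex * ey)
  }
  # separable Gaussian kernel: values = Gx diag(w) Gy'
  Gx <- outer(gx, points[, 1], function(u, x) stats::dnorm(u - x, sd = h))
  Gy <- outer(gy, points[, 2], function(u, x) stats::dnorm(u - x, sd = h))
  vals <- Gx %*% (w_use * t(Gy))
  if (edge == "uniform") {
    ex <- stats::pnorm((window[2] - gx) / h) - stats::pnorm((window[1] - gx) / h)
    ey <- stats::pnorm((window[4] - gy) / h) - stats::pnorm((window[3] - gy) / h)
    vals <- vals / outer(ex, ey)
  }
  structure(list(x = gx, y = gy, values = vals, bandwidth = bandwidth,
                 weights_label = attr(weights, "label") %||% "unweighted",
                 window = window),
            class = "wp_intensity")
}

#' Total mass of an intensity surface
#'
#' Integrates the surface over its window (cell-area times cell-value sum);
#' for a well-behaved estimate this is close to the total (weighted) point
#' count.
#'
#' @param surface a `wp_intensity`.
#' @return scalar integral of the surface.
#' @export
intensity_mass <- function(surface) {
  dx <- (surface$window[2] - surface$window[1]) / length(surface$x)
  dy <- (surface$window[4] - surface$window[3]) / length(surface$y)
  sum(surface$values) * dx * dy
}

#' Per-colony disease-reoccurrence weights
#'
#' The number of survey occasions at which each colony showed disease over
#' the study (the weights of the disease-reoccurrence intensity panel).
#' With `annualize = TRUE`, the number of calendar years in which the colony
#' showed disease at least once.
#'
#' @param panel a [survey_panel()].
#' @param annualize aggregate to years with any disease activity.
#' @return numeric vector, one count per colony, with attribute `"label"`.
#' @export
disease_reoccurrence <- function(panel, annualize = FALSE) {
  if (annualize) {
    yr <- format(panel$occasions, "%Y")
    out <- vapply(unique(yr), function(y) {
      rowSums(panel$presence[, yr == y, drop = FALSE], na.rm = TRUE) > 0
    }, logical(nrow(panel$presence)))
    out <- rowSums(out)
  } else {
    out <- rowSums(panel$presence, na.rm = TRUE)
  }
  attr(out, "label") <- "disease_reoccurrence"
  out
}

#' Export an intensity surface as a long data.frame
#' @param surface a `wp_intensity`.
#' @return data.frame with columns `x`, `y`, `value` (one row per grid cell).
#' @export
intensity_as_df <- function(surface) {
  data.frame(x = rep(surface$x, times = length(surface$y)),
             y = rep(surface$y, each = length(surface$x)),
             value = as.vector(surface$values))
}
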