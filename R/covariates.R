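# Design-matrix construction: the eight tested covariates plus intercept.
#
# Covariate order (fixed, and the order of every summary table):
#   intercept, northing, easting, colony_size, previous_incidences,
#   distance_nearest, distance_prev_infected, water_temperature,
#   solar_insolation

.wp_terms <- c("intercept", "northing", "easting", "colony_size",
               "previous_incidences", "distance_nearest",
               "distance_prev_infected", "water_temperature",
               "solar_insolation")

.wp_term_labels <- c("Intercept", "Northing", "Easting", "Colony size",
                     "Previous incidences", "Distance", "Previous distance",
                     "Water temperature", "Solar insolation")

#' Running count of previous disease incidences
#'
#' For every colony and occasion, the number of earlier occasions at which the
#' colony showed disease. Every colony starts at zero at the first occasion;
#' missing surveys contribute nothing to the count.
#'
#' @param presence colony x occasion matrix with values 0, 1 or `NA`.
#' @param episodes if `TRUE`, count distinct disease episodes (0 to 1 onsets)
#'   rather than presence-occasions. Default counts every occasion with
#'   presence (cumulative presence-months).
#' @return integer matrix of the same dimension; column 1 is all zeros.
#' @export
#' @examples
#' previous_incidences(rbind(c(1, 0, 1, 1)))  # 0 1 1 2
previous_incidences <- function(presence, episodes = FALSE) {
  presence <- as.matrix(presence)
  m <- presence
  m[is.na(m)] <- 0
  if (episodes) {
    onset <- m
    if (ncol(m) > 1)
      onset[, -1] <- pmax(m[, -1] - m[, -ncol(m)], 0)
    m <- onset
  }
  if (ncol(m) == 1) {
    out <- matrix(0, nrow(m), 1)
    dimnames(out) <- dimnames(presence)
    return(out)
  }
  cs <- t(apply(m, 1, cumsum))
  out <- cbind(0, cs[, -ncol(m), drop = FALSE])
  dimnames(out) <- dimnames(presence)
  out
}

.pairwise_dist <- function(coords) {
  as.matrix(stats::dist(coords))
}

.coords_of <- function(colonies) {
  if (is.matrix(colonies)) return(colonies[, 1:2, drop = FALSE])
  cbind(colonies$easting, colonies$northing)
}

#' Distance to the nearest neighbouring colony
#'
#' @param colonies data.frame with `easting`/`northing` columns (or a
#'   two-column coordinate matrix), one row per colony.
#' @return numeric vector of minimum Euclidean distances (m) to any other
#'   colony.
#' @export
distance_nearest_neighbor <- function(colonies) {
  xy <- .coords_of(colonies)
  if (nrow(xy) < 2)
    stop_wp("nearest-neighbour distance undefined for fewer than 2 colonies",
            class = "wp_value_error")
  if (any(!is.finite(xy)))
    stop_wp("non-finite colony coordinates", class = "wp_value_error")
  D <- .pairwise_dist(xy)
  diag(D) <- Inf
  unname(apply(D, 1, min))
}

# distances from each colony to the nearest colony infected on the previous
# occasion, given that occasion's presence vector; self excluded
.dist_prev_infected_col <- function(D, prev_presence, fill) {
  n <- nrow(D)
  inf_j <- which(!is.na(prev_presence) & prev_presence == 1)
  out <- rep(fill, n)
  if (!length(inf_j)) return(out)
  for (i in seq_len(n)) {
    cand <- setdiff(inf_j, i)
    if (length(cand)) out[i] <- min(D[i, cand])
  }
  out
}

#' Distance from a previously infected colony
#'
#' For every colony and occasion t, the Euclidean distance to the nearest
#' *other* colony that showed disease at occasion t - 1. When no colony was
#' infected at t - 1 (and at t = 1) the cell takes a fill value encoding
#' "no nearby source": the maximum observed pairwise distance, or the domain
#' diagonal.
#'
#' @param presence colony x occasion matrix with values 0, 1 or `NA`.
#' @param colonies data.frame with `easting`/`northing` (or coordinate
#'   matrix), rows aligned with `presence`.
#' @param fill fill rule, `"max-pairwise"` (default) or `"diagonal"`.
#' @return colony x occasion matrix of distances (m).
#' @export
distance_previously_infected <- function(presence, colonies,
                                         fill = c("max-pairwise", "diagonal")) {
  fill <- match.arg(fill)
  presence <- as.matrix(presence)
  xy <- .coords_of(colonies)
  D <- .pairwise_dist(xy)
  fill_val <- if (fill == "max-pairwise") max(D) else
    sqrt(diff(range(xy[, 1]))^2 + diff(range(xy[, 2]))^2)
  TT <- ncol(presence)
  out <- matrix(fill_val, nrow(presence), TT)
  if (TT > 1) for (tt in 2:TT)
    out[, tt] <- .dist_prev_infected_col(D, presence[, tt - 1], fill_val)
  dimnames(out) <- dimnames(presence)
  out
}

#' Trailing 30-day mean water temperature
#'
#' Collapses a raw logger series to one value per survey occasion: the
#' arithmetic mean of all readings in the 30 days before the survey date
#' (window `[date - days, date)`). Occasions whose window holds no readings
#' are returned as `NA` and flagged.
#'
#' @param times reading timestamps (`Date` or `POSIXct`).
#' @param values temperature readings (deg C), same length as `times`.
#' @param survey_dates survey occasion dates.
#' @param days trailing window length in days (default 30).
#' @return numeric vector, one mean per survey date; attribute `"flagged"`
#'   marks occasions with an empty window.
#' @export
temperature_trailing_mean <- function(times, values, survey_dates, days = 30) {
  if (!length(values))
    stop_wp("empty temperature series", class = "wp_value_error")
  tnum <- as.numeric(as.POSIXct(times))
  out <- vapply(survey_dates, function(d) {
    dn <- as.numeric(as.POSIXct(as.Date(d)))
    sel <- tnum >= dn - days * 86400 & tnum < dn
    if (!any(sel)) NA_real_ else mean(values[sel])
  }, numeric(1))
  attr(out, "flagged") <- which(is.na(out))
  out
}

#' Design options
#'
#' Transform and standardisation configuration for [build_design()].
#'
#' @param standardize z-score all non-intercept covariates over observed
#'   cells (default `TRUE`; posterior coefficients are then on a common
#'   per-standard-deviation scale).
#' @param log_size log10-transform colony size before standardising.
#' @param log_distance log10-transform the two distance covariates before
#'   standardising.
#' @param distance_floor lower bound (m) applied to distances before log
#'   transform, guarding coincident colonies.
#' @param prev_fill fill rule for [distance_previously_infected()].
#' @param episodes episode-based counting for [previous_incidences()].
#' @return list of class `wp_design_options`.
#' @export
design_options <- function(standardize = TRUE, log_size = TRUE,
                           log_distance = TRUE, distance_floor = 1e-3,
                           prev_fill = c("max-pairwise", "diagonal"),
                           episodes = FALSE) {
  structure(list(standardize = standardize, log_size = log_size,
                 log_distance = log_distance, distance_floor = distance_floor,
                 prev_fill = match.arg(prev_fill), episodes = episodes),
            class = "wp_design_options")
}

#' Build the standardized covariate design
#'
#' Assembles the colony x occasion x covariate array for the eight tested
#' covariates plus intercept: northing, easting, colony size (cm^3,
#' log10-transformed by default), the running count of previous disease
#' incidences, distance to the nearest neighbouring colony and distance from
#' a previously infected colony (m, log10-transformed by default), and the
#' occasion-level water temperature and solar insolation. All non-intercept
#' covariates are z-scored over observed cells; the per-covariate centre and
#' scale are recorded so coefficients remain interpretable and new data can
#' be projected onto the same scale.
#'
#' @param panel a [survey_panel()].
#' @param options a [design_options()] list.
#' @return An object of class `wp_design`: the n x T x 9 numeric array with
#'   attributes `terms`, `center`, `scale`, `transform` (per-covariate log10
#'   flag) and `options`.
#' @export
build_design <- function(panel, options = design_options()) {
  validate_panel(panel)
  n <- nrow(panel$colonies); TT <- length(panel$occasions)
  p <- length(.wp_terms)
  arr <- array(NA_real_, c(n, TT, p),
               dimnames = list(panel$colonies$colony_id,
                               format(panel$occasions), .wp_terms))
  arr[, , "intercept"] <- 1
  arr[, , "northing"] <- panel$colonies$northing
  arr[, , "easting"] <- panel$colonies$easting
  arr[, , "colony_size"] <- panel$size
  arr[, , "previous_incidences"] <-
    previous_incidences(panel$presence, episodes = options$episodes)
  arr[, , "distance_nearest"] <- distance_nearest_neighbor(panel$colonies)
  arr[, , "distance_prev_infected"] <-
    distance_previously_infected(panel$presence, panel$colonies,
                                 fill = options$prev_fill)
  arr[, , "water_temperature"] <- rep(panel$temperature, each = n)
  arr[, , "solar_insolation"] <- rep(panel$insolation, each = n)

  logged <- c(colony_size = options$log_size,
              distance_nearest = options$log_distance,
              distance_prev_infected = options$log_distance)
  for (nm in names(logged)[logged])
    arr[, , nm] <- log10(pmax(arr[, , nm], options$distance_floor))

  center <- stats::setNames(rep(0, p), .wp_terms)
  scale <- stats::setNames(rep(1, p), .wp_terms)
  if (options$standardize) {
    obs <- !is.na(panel$presence)
    for (nm in setdiff(.wp_terms, "intercept")) {
      v <- arr[, , nm][obs]
      m <- mean(v); s <- stats::sd(v)
      if (!is.finite(s) || s < 1e-12)
        stop_wp("covariate '", nm, "' has zero variance over observed cells; ",
                "cannot standardize", class = "wp_standardization_error")
      arr[, , nm] <- (arr[, , nm] - m) / s
      center[nm] <- m; scale[nm] <- s
    }
  }
  transform <- stats::setNames(rep(FALSE, p), .wp_terms)
  transform[names(logged)] <- logged
  structure(arr, terms = .wp_terms, labels = .wp_term_labels,
            center = center, scale = scale, transform = transform,
            options = options, class = "wp_design")
}

# stacked (n*T) x p design matrix, cell order i + (t-1)*n (column-major)
design_matrix <- function(design) {
  d <- dim(design)
  matrix(design, d[1] * d[2], d[3], dimnames = list(NULL, attr(design, "terms")))
}
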