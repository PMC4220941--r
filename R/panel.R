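# Survey-panel container and CSV dialect.
#
# A panel holds everything one monitoring campaign produced: the mapped
# colonies (planar UTM metres), the ordered monthly survey occasions, the
# colony x occasion presence/absence matrix (NA = colony not scored on that
# occasion), and the occasion-level environmental series (water temperature
# and solar insolation, constant across colonies within an occasion).

#' Construct a survey panel
#'
#' Assembles and validates the in-memory representation of a longitudinal
#' disease survey: a set of mapped coral colonies observed for presence or
#' absence of disease at a common sequence of survey occasions, together with
#' occasion-level environmental forcing.
#'
#' @param colonies data.frame with columns `colony_id` (unique character),
#'   `easting`, `northing` (planar UTM metres) and `initial_size`
#'   (colony size in cm^3, positive).
#' @param occasions strictly increasing vector of survey dates (`Date`).
#' @param presence numeric matrix, colonies x occasions, values 0, 1 or `NA`
#'   (missing survey for that colony-occasion).
#' @param temperature numeric vector, one value per occasion: mean water
#'   temperature (deg C) over the 30 days before the survey.
#' @param insolation numeric vector, one value per occasion: solar insolation
#'   (kW m^-2 day^-1).
#' @param size optional colonies x occasions matrix of colony sizes (cm^3);
#'   when `NULL` the initial size is used for every occasion.
#'
#' @return An object of class `survey_panel`: a list with the elements above,
#'   invisibly validated.
#' @export
#' @examples
#' col <- data.frame(colony_id = c("a", "b"), easting = c(0, 3),
#'                   northing = c(0, 4), initial_size = c(100, 200))
#' occ <- as.Date(c("2003-02-01", "2003-03-01"))
#' pr <- matrix(c(0, 1, NA, 0), 2, 2)
#' survey_panel(col, occ, pr, temperature = c(26.5, 26.9),
#'              insolation = c(4.8, 5.2))
survey_panel <- function(colonies, occasions, presence, temperature,
                         insolation, size = NULL) {
  colonies <- as.data.frame(colonies)
  needed <- c("colony_id", "easting", "northing", "initial_size")
  miss <- setdiff(needed, names(colonies))
  if (length(miss))
    stop_wp("colonies is missing column(s): ", paste(miss, collapse = ", "),
            class = "wp_schema_error")
  colonies$colony_id <- as.character(colonies$colony_id)
  occasions <- as.Date(occasions)
  presence <- as.matrix(presence)
  if (is.null(size)) {
    size <- matrix(colonies$initial_size, nrow(colonies), length(occasions))
  } else {
    size <- as.matrix(size)
  }
  dimnames(presence) <- list(colonies$colony_id, format(occasions))
  dimnames(size) <- dimnames(presence)
  panel <- structure(
    list(colonies = colonies, occasions = occasions, presence = presence,
         temperature = as.numeric(temperature),
         insolation = as.numeric(insolation), size = size),
    class = "survey_panel")
  validate_panel(panel)
  panel
}

#' Validate a survey panel
#'
#' Checks the structural invariants of a [survey_panel()]: unique colony ids,
#' finite coordinates, positive sizes, strictly increasing occasions,
#' conformable matrices, and binary (or missing) presence values.
#'
#' @param panel a `survey_panel`.
#' @return `panel`, invisibly. Errors describe the violated invariant.
#' @export
validate_panel <- function(panel) {
  col <- panel$colonies
  if (anyDuplicated(col$colony_id))
    stop_wp("duplicated colony_id in panel", class = "wp_integrity_error")
  if (!all(is.finite(col$easting)) || !all(is.finite(col$northing)))
    stop_wp("non-finite colony coordinates", class = "wp_value_error")
  if (any(!is.finite(col$initial_size)) || any(col$initial_size <= 0))
    stop_wp("initial_size must be positive and finite", class = "wp_value_error")
  occ <- panel$occasions
  if (length(occ) > 1 && any(diff(as.numeric(occ)) <= 0))
    stop_wp("occasions must be strictly increasing", class = "wp_value_error")
  d <- dim(panel$presence)
  if (d[1] != nrow(col) || d[2] != length(occ))
    stop_wp("presence matrix must be colonies x occasions (",
            nrow(col), " x ", length(occ), "), got ", d[1], " x ", d[2],
            class = "wp_value_error")
  pv <- panel$presence[!is.na(panel$presence)]
  if (length(pv) && !all(pv %in% c(0, 1)))
    stop_wp("presence values must be 0, 1 or NA", class = "wp_value_error")
  if (length(panel$temperature) != length(occ) ||
      length(panel$insolation) != length(occ))
    stop_wp("temperature and insolation must have one value per occasion",
            class = "wp_value_error")
  if (!all(dim(panel$size) == d))
    stop_wp("size matrix must match presence dimensions", class = "wp_value_error")
  invisible(panel)
}

#' Column-name map for the survey CSV dialect
#'
#' The long-format CSV carries one row per (colony, survey date). Header names
#' are site-specific, so the reader takes a configurable map from logical
#' field names to column names.
#'
#' @param colony_id,easting,northing,date,size,presence,temperature,insolation
#'   column names in the file.
#' @return named character vector used by [read_panel()] / [write_panel()].
#' @export
panel_schema <- function(colony_id = "colony_id", easting = "easting",
                         northing = "northing", date = "date", size = "size",
                         presence = "presence", temperature = "temperature",
                         insolation = "insolation") {
  c(colony_id = colony_id, easting = easting, northing = northing,
    date = date, size = size, presence = presence,
    temperature = temperature, insolation = insolation)
}

#' Read a survey panel from long-format CSV
#'
#' One row per (colony, survey date); dates ISO-8601; missing presence left
#' empty. Rows with missing presence are retained as missing cells, never
#' dropped. Temperature and insolation must be constant across colonies
#' within an occasion (they vary on scales larger than the study site).
#'
#' @param path path to a CSV file.
#' @param schema column-name map, see [panel_schema()].
#' @param verbose emit a load report (`message()`) with colony, occasion and
#'   missing-cell counts.
#' @return a validated [survey_panel()]; the load report is attached as
#'   attribute `"report"`.
#' @export
read_panel <- function(path, schema = panel_schema(), verbose = TRUE) {
  if (!file.exists(path))
    stop_wp("file not found: ", path, class = "wp_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(unname(schema), names(df))
  if (length(miss))
    stop_wp("required column(s) missing from ", path, ": ",
            paste(miss, collapse = ", "), class = "wp_schema_error")
  id <- as.character(df[[schema["colony_id"]]])
  date <- as.Date(df[[schema["date"]]])
  if (anyNA(date))
    stop_wp("unparseable survey dates (expect ISO-8601)", class = "wp_value_error")
  if (anyDuplicated(paste(id, date)))
    stop_wp("duplicated (colony, date) rows in ", path,
            class = "wp_integrity_error")
  pres <- df[[schema["presence"]]]
  if (!all(pres[!is.na(pres)] %in% c(0, 1)))
    stop_wp("non-binary presence values in ", path, class = "wp_value_error")

  ids <- unique(id)                      # order of first appearance
  occasions <- sort(unique(date))
  n <- length(ids); TT <- length(occasions)
  ri <- match(id, ids); ci <- match(date, occasions)

  first <- !duplicated(id)
  colonies <- data.frame(colony_id = ids,
                         easting = df[[schema["easting"]]][first][order(match(id[first], ids))],
                         northing = df[[schema["northing"]]][first][order(match(id[first], ids))],
                         stringsAsFactors = FALSE)
  # coordinate consistency across repeated rows of a colony
  for (f in c("easting", "northing")) {
    v <- df[[schema[f]]]
    ref <- colonies[[f]][ri]
    if (any(abs(v - ref) > 1e-6, na.rm = TRUE))
      stop_wp("colony ", f, " differs across rows for the same colony",
              class = "wp_integrity_error")
  }

  presence <- matrix(NA_real_, n, TT)
  presence[cbind(ri, ci)] <- pres
  size <- matrix(NA_real_, n, TT)
  size[cbind(ri, ci)] <- df[[schema["size"]]]
  # initial size = earliest non-missing record per colony
  init <- vapply(seq_len(n), function(i) {
    v <- size[i, ]; v[which(!is.na(v))[1]]
  }, numeric(1))
  if (anyNA(init))
    stop_wp("a colony has no recorded size", class = "wp_value_error")
  for (i in seq_len(n)) size[i, is.na(size[i, ])] <- init[i]
  colonies$initial_size <- init

  env_series <- function(field) {
    v <- df[[schema[field]]]
    out <- numeric(TT)
    for (tt in seq_len(TT)) {
      vt <- v[ci == tt]
      vt <- vt[!is.na(vt)]
      if (!length(vt))
        stop_wp("no ", field, " value for occasion ", format(occasions[tt]),
                class = "wp_value_error")
      if (diff(range(vt)) > 1e-6)
        stop_wp(field, " varies across colonies within occasion ",
                format(occasions[tt]), class = "wp_integrity_error")
      out[tt] <- vt[1]
    }
    out
  }

  panel <- survey_panel(colonies, occasions, presence,
                        temperature = env_series("temperature"),
                        insolation = env_series("insolation"), size = size)
  report <- list(n_colonies = n, n_occasions = TT,
                 n_missing = sum(is.na(presence)))
  attr(panel, "report") <- report
  if (verbose)
    message(sprintf("read_panel: %d colonies, %d occasions, %d missing cells",
                    n, TT, report$n_missing))
  panel
}

#' Write a survey panel to long-format CSV
#'
#' Inverse of [read_panel()]: one row per (colony, occasion), missing
#' presence written as an empty field. `read_panel(write_panel(p))`
#' reproduces `p` up to floating-point representation.
#'
#' @param panel a `survey_panel`.
#' @param path output path.
#' @param schema column-name map, see [panel_schema()].
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, schema = panel_schema()) {
  validate_panel(panel)
  n <- nrow(panel$colonies); TT <- length(panel$occasions)
  df <- data.frame(
    rep(panel$colonies$colony_id, each = TT),
    rep(panel$colonies$easting, each = TT),
    rep(panel$colonies$northing, each = TT),
    rep(format(panel$occasions), times = n),
    as.vector(t(panel$size)),
    as.vector(t(panel$presence)),
    rep(panel$temperature, times = n),
    rep(panel$insolation, times = n),
    stringsAsFactors = FALSE)
  names(df) <- unname(schema[c("colony_id", "easting", "northing", "date",
                               "size", "presence", "temperature", "insolation")])
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_wp("cannot write panel to ", path, ": ", conditionMessage(ok),
            class = "wp_io_error")
  invisible(path)
}

#' @export
print.survey_panel <- function(x, ...) {
  cat(sprintf("survey_panel: %d colonies x %d occasions (%s to %s), %d missing cells\n",
              nrow(x$colonies), length(x$occasions),
              format(x$occasions[1]), format(x$occasions[length(x$occasions)]),
              sum(is.na(x$presence))))
  cat(sprintf("  overall disease prevalence: %.1f%%\n",
              100 * mean(x$presence, na.rm = TRUE)))
  invisible(x)
}
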