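# Shared fixture builders: everything is generated in code at test time.

# small study-like panel via the synthetic generator (higher base rate so
# that tiny panels still contain disease)
make_small_panel <- function(n = 10, TT = 8, seed = 42, intercept = -1,
                             missing_rate = 0.05) {
  cfg <- scenario_config(
    n_colonies = n, n_occasions = TT, missing_rate = missing_rate,
    beta_true = c(intercept = intercept, northing = 0.3, colony_size = 0.3,
                  previous_incidences = 0.5, water_temperature = 0.4),
    seed = seed)
  generate_panel(cfg, seed = seed)
}

# hand-built tiny panel with explicit coordinates and presence
make_tiny_panel <- function(presence, coords = NULL, dates = NULL,
                            temperature = NULL, insolation = NULL) {
  n <- nrow(presence); TT <- ncol(presence)
  if (is.null(coords))
    coords <- cbind(seq_len(n) * 7, rev(seq_len(n)) * 11)
  if (is.null(dates))
    dates <- seq(as.Date("2003-02-01"), by = "month", length.out = TT)
  if (is.null(temperature)) temperature <- 27 + seq_len(TT) / 10
  if (is.null(insolation)) insolation <- 5 + cos(seq_len(TT))
  survey_panel(
    data.frame(colony_id = sprintf("t%02d", seq_len(n)),
               easting = coords[, 1], northing = coords[, 2],
               initial_size = 100 * seq_len(n)),
    dates, presence, temperature = temperature, insolation = insolation)
}

# minimal design array (class wp_design) from explicit covariate matrices;
# cols is a named list of n x T matrices (intercept added automatically)
make_design_array <- function(cols, n, TT) {
  terms <- c("intercept", names(cols))
  arr <- array(NA_real_, c(n, TT, length(terms)),
               dimnames = list(NULL, NULL, terms))
  arr[, , 1] <- 1
  for (nm in names(cols)) arr[, , nm] <- cols[[nm]]
  structure(arr, terms = terms, labels = terms,
            center = stats::setNames(rep(0, length(terms)), terms),
            scale = stats::setNames(rep(1, length(terms)), terms),
            transform = stats::setNames(rep(FALSE, length(terms)), terms),
            options = design_options(), class = "wp_design")
}

panels_equal <- function(a, b, tol = 1e-8) {
  expect_equal(a$colonies$colony_id, b$colonies$colony_id)
  expect_equal(a$colonies$easting, b$colonies$easting, tolerance = tol)
  expect_equal(a$colonies$northing, b$colonies$northing, tolerance = tol)
  expect_equal(a$colonies$initial_size, b$colonies$initial_size, tolerance = tol)
  expect_equal(a$occasions, b$occasions)
  expect_equal(is.na(a$presence), is.na(b$presence), ignore_attr = TRUE)
  expect_equal(a$presence, b$presence, tolerance = tol, ignore_attr = TRUE)
  expect_equal(a$temperature, b$temperature, tolerance = tol)
  expect_equal(a$insolation, b$insolation, tolerance = tol)
  expect_equal(a$size, b$size, tolerance = tol, ignore_attr = TRUE)
}
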