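# Covariate engineering: disease history, distances, trailing means, and
# the standardized design.

test_that("previous_incidences counts prior disease occasions", {
  expect_equal(previous_incidences(rbind(c(1, 0, 1, 1)))[1, ], c(0, 1, 1, 2),
               ignore_attr = TRUE)
  expect_equal(previous_incidences(rbind(rep(0, 5)))[1, ], rep(0, 5),
               ignore_attr = TRUE)
  # brute-force loop oracle on a random matrix with missing cells
  set.seed(11)
  m <- matrix(rbinom(200, 1, 0.3), 10, 20)
  m[sample(200, 15)] <- NA
  got <- previous_incidences(m)
  for (i in 1:10) for (tt in 1:20) {
    prior <- m[i, seq_len(tt - 1)]
    expect_equal(got[i, tt], sum(prior == 1, na.rm = TRUE))
  }
  # first occasion is always zero (colonies start the study at zero)
  expect_true(all(got[, 1] == 0))
})

test_that("episode counting collapses runs of consecutive presence", {
  row <- rbind(c(1, 1, 1, 0, 1, 1))
  expect_equal(previous_incidences(row)[1, ], c(0, 1, 2, 3, 3, 4),
               ignore_attr = TRUE)
  expect_equal(previous_incidences(row, episodes = TRUE)[1, ],
               c(0, 1, 1, 1, 1, 2), ignore_attr = TRUE)
})

test_that("nearest-neighbour distances match brute force", {
  expect_equal(distance_nearest_neighbor(cbind(c(0, 3), c(0, 4))), c(5, 5))
  expect_equal(distance_nearest_neighbor(cbind(c(0, 1, 10), c(0, 0, 0))),
               c(1, 1, 9))
  set.seed(4)
  xy <- cbind(runif(50, 0, 200), runif(50, 0, 500))
  got <- distance_nearest_neighbor(xy)
  for (i in 1:50) {
    dd <- sqrt((xy[i, 1] - xy[-i, 1])^2 + (xy[i, 2] - xy[-i, 2])^2)
    expect_equal(got[i], min(dd))
  }
  expect_error(distance_nearest_neighbor(cbind(1, 1)), class = "wp_value_error")
})

test_that("distance to previously infected colony: contract and oracle", {
  # two colonies 5 m apart; colony 2 diseased at t-1
  xy <- cbind(c(0, 3), c(0, 4))
  pres <- rbind(c(0, 0), c(1, 0))
  got <- distance_previously_infected(pres, xy)
  expect_equal(got[1, 2], 5)
  # self-exclusion: colony 2 sees no *other* infected colony -> fill
  expect_equal(got[2, 2], 5)     # fill = max pairwise = 5 here
  # no colony diseased at t-1 -> fill everywhere; t = 1 always fill
  none <- distance_previously_infected(matrix(0, 2, 3), xy)
  expect_true(all(none == 5))
  # triple-loop oracle on a random panel
  set.seed(9)
  n <- 20; TT <- 10
  xy <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  pres <- matrix(rbinom(n * TT, 1, 0.2), n, TT)
  pres[sample(n * TT, 10)] <- NA
  D <- as.matrix(dist(xy))
  fill <- max(D)
  got <- distance_previously_infected(pres, xy)
  for (i in seq_len(n)) for (tt in seq_len(TT)) {
    expected <- fill
    if (tt > 1) {
      best <- Inf
      for (j in seq_len(n))
        if (j != i && !is.na(pres[j, tt - 1]) && pres[j, tt - 1] == 1)
          best <- min(best, D[i, j])
      if (is.finite(best)) expected <- best
    }
    expect_equal(got[i, tt], expected)
  }
})

test_that("distance covariates are invariant to translation and relabeling", {
  set.seed(21)
  xy <- cbind(runif(12, 0, 50), runif(12, 0, 50))
  pres <- matrix(rbinom(60, 1, 0.3), 12, 5)
  shift <- cbind(xy[, 1] + 1000, xy[, 2] - 250)
  expect_equal(distance_nearest_neighbor(xy), distance_nearest_neighbor(shift))
  expect_equal(distance_previously_infected(pres, xy),
               distance_previously_infected(pres, shift))
  perm <- sample(12)
  expect_equal(distance_nearest_neighbor(xy)[perm],
               distance_nearest_neighbor(xy[perm, ]))
  expect_equal(distance_previously_infected(pres, xy)[perm, ],
               distance_previously_infected(pres[perm, ], xy[perm, ]))
})

test_that("trailing 30-day temperature mean matches direct window averages", {
  dates <- seq(as.Date("2003-02-01"), by = "month", length.out = 4)
  # constant series
  tm <- seq(as.Date("2002-12-01"), as.Date("2003-06-01"), by = "day")
  expect_equal(unname(temperature_trailing_mean(tm, rep(28, length(tm)), dates)),
               rep(28, 4), ignore_attr = TRUE)
  # linear ramp: mean over the window is the midpoint value
  vals <- as.numeric(tm - tm[1]) * 0.1
  got <- temperature_trailing_mean(tm, vals, dates[1])
  win <- tm >= dates[1] - 30 & tm < dates[1]
  expect_equal(unname(got[1]), mean(vals[win]))
  # 10-minute logger with a seasonal sinusoid vs brute-force filter
  tt <- seq(as.POSIXct("2003-01-01", tz = "UTC"),
            as.POSIXct("2003-06-30", tz = "UTC"), by = 600)
  vv <- 28 + 2 * sin(as.numeric(tt) / 5e6)
  got <- temperature_trailing_mean(tt, vv, dates)
  for (k in seq_along(dates)) {
    dn <- as.numeric(as.POSIXct(dates[k]))
    sel <- as.numeric(tt) >= dn - 30 * 86400 & as.numeric(tt) < dn
    expect_equal(unname(got[k]), mean(vv[sel]))
  }
  # empty window flagged, empty series an error
  early <- temperature_trailing_mean(tm, rep(28, length(tm)),
                                     as.Date("2002-01-01"))
  expect_true(is.na(early[1]))
  expect_identical(attr(early, "flagged"), 1L)
  expect_error(temperature_trailing_mean(numeric(0), numeric(0), dates),
               class = "wp_value_error")
})

test_that("build_design assembles 9 standardized covariates", {
  gen <- make_small_panel(n = 15, TT = 12, seed = 3)
  d <- build_design(gen$panel)
  expect_identical(dim(d), c(15L, 12L, 9L))
  expect_identical(attr(d, "terms")[1], "intercept")
  expect_true(all(d[, , "intercept"] == 1))
  obs <- !is.na(gen$panel$presence)
  for (nm in setdiff(attr(d, "terms"), "intercept")) {
    v <- d[, , nm][obs]
    expect_lt(abs(mean(v)), 1e-8)
    expect_lt(abs(sd(v) - 1), 1e-8)
  }
  # previous incidences non-decreasing over time for every colony
  pi_raw <- d[, , "previous_incidences"]
  expect_true(all(apply(pi_raw, 1, function(r) all(diff(r) >= -1e-12))))
  # deterministic
  d2 <- build_design(gen$panel)
  expect_identical(d, d2)
})

test_that("build_design reports zero-variance covariates by name", {
  gen <- make_small_panel(n = 6, TT = 5, seed = 8)
  p <- gen$panel
  p$temperature[] <- 28
  expect_error(build_design(p), "water_temperature",
               class = "wp_standardization_error")
})
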