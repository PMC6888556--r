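grid3 <- make_grid(0, 0, 3, 3, 1000)

flat_surface <- function(grid, days, value) {
  hours <- hourly_grid_times(days)
  make_surface(grid, hours,
               matrix(value, mobexpo:::n_cells(grid), nrow(hours)))
}

stationary_hourly <- function(days, x = 500, y = 500, uid = "u1") {
  g <- hourly_grid_times(days)
  data.frame(user_id = uid, day = g$day, hour = g$hour, x = x, y = y,
             provenance = "observed", stringsAsFactors = FALSE)
}

test_that("cell location follows the half-open convention with clamping", {
  expect_equal(as.integer(locate_cell(0, 0, grid3)), 1L)
  expect_equal(as.integer(locate_cell(1000, 0, grid3)), 2L)
  expect_equal(as.integer(locate_cell(999.999, 0, grid3)), 1L)
  out <- locate_cell(13000, -5000, grid3)
  expect_equal(as.integer(out), 3L)  # clamped to the bottom-right cell
  expect_equal(attr(out, "n_outside"), 1L)
})

test_that("health categories partition concentrations left-closed", {
  expect_equal(health_category(c(0, 34.99, 35, 69.9, 70, 114, 115, 149,
                                 150, 500)),
               c("Excellent", "Excellent", "Good", "Good",
                 "LightlyPolluted", "LightlyPolluted",
                 "ModeratelyPolluted", "ModeratelyPolluted",
                 "SeverelyPolluted", "SeverelyPolluted"))
  set.seed(1)
  pm <- runif(500, 0, 400)
  cats <- health_category(pm)
  expect_false(anyNA(cats))
  oracle <- c("Excellent", "Good", "LightlyPolluted",
              "ModeratelyPolluted", "SeverelyPolluted")[
    cut(pm, c(0, 35, 70, 115, 150, Inf), right = FALSE, labels = FALSE)]
  expect_equal(cats, oracle)
})

test_that("hourly exposure integrates concentration over occupied cells", {
  s <- flat_surface(grid3, 1, 80)
  es <- exposure_series(stationary_hourly(1), s)
  expect_equal(cumulative_exposure(es), 24 * 80)
  expect_true(all(es$category == "LightlyPolluted"))

  # microenvironment reduction: one environment, ME = TP = 1
  me1 <- data.frame(day = rep(1, 24), hour = 0:23, me = 1, tp = 1)
  expect_equal(cumulative_exposure(exposure_series(stationary_hourly(1),
                                                   s, me1)),
               cumulative_exposure(es))

  # two microenvironments: 100 * (0.6 * 0.5 + 1.0 * 0.5) = 80
  s100 <- flat_surface(grid3, 1, 100)
  me2 <- rbind(data.frame(day = 1, hour = 0:23, me = 0.6, tp = 0.5),
               data.frame(day = 1, hour = 0:23, me = 1.0, tp = 0.5))
  es2 <- exposure_series(stationary_hourly(1), s100, me2)
  expect_equal(es2$contribution[1], 80)
  expect_equal(cumulative_exposure(es2), 24 * 80)

  bad <- data.frame(day = 1, hour = 0:23, me = 1, tp = 0.7)
  expect_error(exposure_series(stationary_hourly(1), s100, bad),
               "sum to 1")
})

test_that("ME = 1, TP = 1 reduces to the plain sum on random worlds", {
  set.seed(17)
  for (k in 1:100) {
    days <- sample(1:2, 1)
    hours <- hourly_grid_times(days)
    vals <- matrix(runif(9 * nrow(hours), 0, 200), 9, nrow(hours))
    s <- make_surface(grid3, hours, vals)
    h <- stationary_hourly(days, x = runif(1, 0, 3000),
                           y = runif(1, 0, 3000))
    me <- data.frame(day = hours$day, hour = hours$hour, me = 1, tp = 1)
    expect_equal(cumulative_exposure(exposure_series(h, s, me)),
                 cumulative_exposure(exposure_series(h, s)))
  }
})

test_that("exposure is additive over disjoint day windows", {
  set.seed(19)
  hours <- hourly_grid_times(3)
  vals <- matrix(runif(9 * 72, 0, 150), 9, 72)
  s <- make_surface(grid3, hours, vals)
  h <- stationary_hourly(3, x = 1500, y = 2500)
  total <- cumulative_exposure(exposure_series(h, s))
  per_day <- vapply(1:3, function(d)
    cumulative_exposure(exposure_series(h[h$day == d, ], s)), numeric(1))
  expect_equal(total, sum(per_day))
})

test_that("the K-S comparison equals the brute-force ECDF sup", {
  expect_equal(ks_compare(1:5, 1:5)$statistic, 0)
  expect_equal(ks_compare(c(1, 2, 3), c(1, 2, 3, 100))$statistic, 0.25)
  expect_error(ks_compare(numeric(0), 1:3), "empty")
  set.seed(23)
  for (k in 1:25) {
    a <- rnorm(sample(3:50, 1)); b <- rnorm(sample(3:50, 1), mean = 0.3)
    expect_equal(ks_compare(a, b)$statistic, ks_stat_brute(a, b),
                 tolerance = 1e-12)
  }
})

test_that("paired differences summarize by day type with type-6 quartiles", {
  est_a <- data.frame(user_id = rep(letters[1:5], 2),
                      day = rep(1:2, each = 5),
                      exposure = c(1:5, 11:15))
  est_b <- est_a
  est_b$exposure <- est_a$exposure - c(-2, -1, 0, 1, 2, -2, -1, 0, 1, 2)
  out <- paired_differences(est_a, est_b,
                            day_types = c(`1` = "workday",
                                          `2` = "weekend"))
  # differences are {-2,-1,0,1,2} in both groups
  expect_equal(out$median, c(0, 0))
  expect_equal(out$q1, c(-1.5, -1.5))
  expect_equal(out$q3, c(1.5, 1.5))
  # quartiles match direct type-6 computation
  expect_equal(out$q1[1], unname(quantile(c(-2, -1, 0, 1, 2), 0.25,
                                          type = 6)))
  # identical estimates -> all-zero differences
  z <- paired_differences(est_a, est_a, c(`1` = "workday",
                                          `2` = "weekend"))
  expect_true(all(z$median == 0 & z$iqr == 0))
  # mismatched user sets are rejected
  expect_error(paired_differences(est_a[-1, ], est_b,
                                  c(`1` = "workday", `2` = "weekend")),
               "differ")
})

test_that("home inference takes the modal nighttime location", {
  t_night <- c(rep(23 * 3600, 10), rep(2 * 3600, 2))
  tr <- make_traj(t = t_night, x = c(rep(100, 10), rep(900, 2)),
                  y = rep(0, 12))
  h <- infer_home(tr)
  expect_equal(unname(h["x"]), 100)

  # 21:59 is outside the night window
  tr2 <- make_traj(t = c(21 * 3600 + 59 * 60, 23 * 3600),
                   x = c(1, 2), y = c(0, 0))
  expect_equal(unname(infer_home(tr2)["x"]), 2)

  # deterministic tie-break on 5-vs-5 ties
  tr3 <- make_traj(t = rep(c(23 * 3600, 23 * 3600 + 60), 5),
                   x = rep(c(10, 20), 5), y = rep(0, 10))
  expect_identical(infer_home(tr3), infer_home(tr3))

  # no night records falls back to the overall mode, flagged
  tr4 <- make_traj(t = c(10, 11, 11) * 3600, x = c(1, 5, 5),
                   y = c(0, 0, 0))
  h4 <- infer_home(tr4)
  expect_equal(unname(h4["x"]), 5)
  expect_true(attr(h4, "fallback"))
})

test_that("three-way estimates coincide for a stationary home-bound user", {
  s <- flat_surface(grid3, 1, 60)
  n <- 30
  set.seed(29)
  tr <- make_traj(t = sort(sample(0:86399, n)), x = rep(500, n),
                  y = rep(500, n))
  hourly <- stationary_hourly(1)
  est <- three_way_estimates(tr, hourly, s, days = 1)
  expect_equal(est$tr_ee, est$rec_ee)
  expect_equal(est$rec_ee, est$sl_ee)
  expect_equal(est$sl_ee, 24 * 60)
})

test_that("exposure series export carries running cumulative totals", {
  s <- flat_surface(grid3, 1, 50)
  es <- exposure_series(stationary_hourly(1), s)
  p <- tempfile(fileext = ".csv")
  write_exposure_csv(list(u1 = es), p)
  back <- read.csv(p)
  expect_equal(nrow(back), 24)
  expect_equal(back$cum, cumsum(rep(50, 24)))
  expect_equal(back$cum[24], cumulative_exposure(es))
})

test_that("top-20% selection and zone percentages behave as specified", {
  days <- 1
  s <- flat_surface(grid3, days, 40)
  series <- list(); homes <- list()
  for (i in 1:10) {
    uid <- sprintf("u%02d", i)
    h <- stationary_hourly(days, x = 500 + 1000 * (i %% 2), y = 500,
                           uid = uid)
    es <- exposure_series(h, s)
    # manufacture distinct totals by truncating hours
    series[[uid]] <- es[seq_len(2 * i), ]
    homes[[uid]] <- c(x = 500 + 1000 * (i %% 2), y = 500)
  }
  zones <- make_grid_zones(grid3, 1L)
  zs <- high_exposure_zone_summary(series, homes, zones, grid3,
                                   top_frac = 0.2)
  # exactly the two users with the largest totals (u09, u10) are selected
  expect_equal(sum(zs$n_residents), 2)
  pct <- as.matrix(zs[, grep("^pct_", names(zs))])
  expect_equal(unname(rowSums(pct)), rep(100, nrow(zs)),
               tolerance = 0.01)
  expect_error(high_exposure_zone_summary(series[1:3], homes, zones,
                                          grid3), ">= 5")
})

test_that("uniform fields tie away-exposure share to away-time share", {
  days <- 1
  s <- flat_surface(grid3, days, 55)
  series <- list(); homes <- list()
  set.seed(31)
  for (i in 1:8) {
    uid <- sprintf("u%02d", i)
    away_hours <- sample(0:23, 6 + i)
    g <- hourly_grid_times(days)
    x <- ifelse(g$hour %in% away_hours, 2500, 500 + 1000 * (i %% 3))
    h <- data.frame(user_id = uid, day = g$day, hour = g$hour, x = x,
                    y = 500, provenance = "observed")
    series[[uid]] <- exposure_series(h, s)
    homes[[uid]] <- c(x = 500 + 1000 * (i %% 3), y = 500)
  }
  zs <- high_exposure_zone_summary(series, homes,
                                   make_grid_zones(grid3, 1L), grid3,
                                   top_frac = 1)
  rel <- away_exposure_relation(zs)
  expect_equal(zs$exposure_away_pct, zs$time_away_pct, tolerance = 1e-9)
  expect_equal(rel$slope, 1, tolerance = 1e-6)
  expect_equal(rel$r, 1, tolerance = 1e-6)
  expect_error(away_exposure_relation(zs[1, , drop = FALSE]), ">= 2")
})
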