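test_that("reader parses an operator-style trace and splits users", {
  rows <- data.frame(
    user_id = "1EF53",
    day = c(1, 1, 1, 7, 7),
    time = c("02:14:25", "08:15:11", "09:17:12", "10:00:00", "21:13:06"),
    x = c(121130, 121130, 121120, 121300, 121440),
    y = c(31060, 31020, 31020, 31100, 31080),
    event_type = c("Regular update", "Call (inbound)",
                   "Cellular handover", "sms", "Call (outbound)"))
  trajs <- read_trajectories(write_trace_csv(rows))
  expect_length(trajs, 1)
  tr <- trajs[[1]]
  expect_equal(nrow(tr), 5)
  expect_equal(tr$event_type[1], "regular_update")
  expect_equal(tr$event_type[5], "call_out")
  expect_equal(tr$t[1], 2 * 3600 + 14 * 60 + 25)

  # header-only file -> empty list
  empty <- write_trace_csv(rows[0, ])
  expect_length(read_trajectories(empty), 0)

  # two interleaved users with 3 + 2 rows
  rows2 <- rows
  rows2$user_id <- c("a", "b", "a", "b", "a")
  trajs2 <- read_trajectories(write_trace_csv(rows2))
  expect_equal(vapply(trajs2, nrow, integer(1)), c(a = 3L, b = 2L))
})

test_that("reader rejects malformed rows and unknown event types", {
  rows <- data.frame(user_id = "u", day = 1, time = "99:99:99",
                     x = 0, y = 0, event_type = "sms")
  expect_error(read_trajectories(write_trace_csv(rows)), "line")
  rows$time <- "01:00:00"; rows$event_type <- "carrier_pigeon"
  expect_error(read_trajectories(write_trace_csv(rows)), "accepted")
})

test_that("planar read -> write -> read round-trips every field", {
  rows <- data.frame(user_id = c("u1", "u2"), day = c(1, 2),
                     time = c("04:30:00", "23:59:59"),
                     x = c(1234.5, 9876.25), y = c(400.125, 88.5),
                     event_type = c("sms", "handover"))
  t1 <- read_trajectories(write_trace_csv(rows))
  out <- tempfile(fileext = ".csv")
  write_trajectories(t1, out)
  t2 <- read_trajectories(out)
  for (u in names(t1))
    expect_identical(t1[[u]][, c("day", "t", "x", "y", "event_type")],
                     t2[[u]][, c("day", "t", "x", "y", "event_type")])
})

test_that("oscillation suppression collapses A-B-A within the window", {
  tr <- make_traj(t = c(0, 60, 120),
                  x = c(0, 200, 0), y = c(0, 0, 0))
  out <- suppress_oscillation(tr, window_s = 300, max_jump_m = 2000)
  expect_equal(out$t, c(0, 120))
  expect_equal(out$x, c(0, 0))

  # monotone path untouched
  tr2 <- make_traj(t = c(0, 60, 120), x = c(0, 200, 400), y = c(0, 0, 0))
  expect_equal(nrow(suppress_oscillation(tr2, 300, 2000)), 3)

  # distance guard: far B survives
  tr3 <- make_traj(t = c(0, 60, 120), x = c(0, 5000, 0), y = c(0, 0, 0))
  expect_equal(nrow(suppress_oscillation(tr3, 300, 2000)), 3)

  # time guard: slow A-B-A survives
  tr4 <- make_traj(t = c(0, 4000, 8000), x = c(0, 200, 0), y = c(0, 0, 0))
  expect_equal(nrow(suppress_oscillation(tr4, 300, 2000)), 3)

  expect_error(suppress_oscillation(tr, window_s = -1), "non-negative")
})

test_that("oscillation suppression is idempotent and keeps a subsequence", {
  set.seed(7)
  for (k in 1:20) {
    n <- sample(5:25, 1)
    xs <- sample(c(0, 300, 5000), n, replace = TRUE)
    tr <- make_traj(t = sort(sample(0:7200, n)), x = xs, y = rep(0, n))
    once <- suppress_oscillation(tr, 600, 2000)
    twice <- suppress_oscillation(once, 600, 2000)
    expect_equal(once, twice)
    expect_lte(nrow(once), nrow(tr))
    # subsequence: every surviving (t, x) pair appears in the input order
    expect_true(all(once$t %in% tr$t))
  }
})

test_that("hourly grid times cover 24 hours per day in order", {
  g <- hourly_grid_times(7)
  expect_equal(nrow(g), 168)
  g1 <- hourly_grid_times(1)
  expect_equal(nrow(g1), 24)
  expect_equal(unlist(g1[1, ]), c(day = 1, hour = 0))
  expect_equal(unlist(g1[24, ]), c(day = 1, hour = 23))
  expect_equal(unlist(hourly_grid_times(2)[25, ]), c(day = 2, hour = 0))
  expect_error(hourly_grid_times(0), "days")
})

test_that("observed/missing hour split snaps to the nearest record", {
  # a record at 08:15:11 sits 911 s after the hour mark: observed iff
  # the tolerance covers it (hard boundary)
  tr <- make_traj(t = c(8 * 3600 + 15 * 60 + 11), x = 5, y = 6)
  sp <- split_observed_hours(tr, days = 1, snap_tol_s = 911)
  expect_true(any(sp$observed$hour == 8))
  spb <- split_observed_hours(tr, days = 1, snap_tol_s = 900)
  expect_false(any(spb$observed$hour == 8))
  expect_equal(nrow(sp$observed) + nrow(sp$missing), 24)

  # no records -> all missing
  sp0 <- split_observed_hours(make_traj(t = numeric(0), x = numeric(0),
                                        y = numeric(0)), days = 1)
  expect_equal(nrow(sp0$missing), 24)

  # equidistant records at 07:59 and 08:01 -> tie resolves to earlier
  tr2 <- make_traj(t = c(7 * 3600 + 59 * 60, 8 * 3600 + 60),
                   x = c(1, 2), y = c(0, 0))
  sp2 <- split_observed_hours(tr2, days = 1, snap_tol_s = 900)
  obs8 <- sp2$observed[sp2$observed$hour == 8, ]
  expect_equal(obs8$x, 1)

  expect_error(split_observed_hours(tr, days = 1, snap_tol_s = 3600),
               "snap_tol_s")
})

test_that("hour partition is complete for random sparse users", {
  set.seed(11)
  for (k in 1:10) {
    n <- sample(1:40, 1); days <- sample(1:3, 1)
    tr <- make_traj(day = sample(seq_len(days), n, replace = TRUE),
                    t = sample(0:86399, n), x = rnorm(n), y = rnorm(n))
    sp <- split_observed_hours(tr, days = days)
    expect_equal(nrow(sp$observed) + nrow(sp$missing), 24 * days)
  }
})

test_that("lon/lat input is projected to metric planar coordinates", {
  rows <- data.frame(user_id = "u", day = 1,
                     time = c("01:00:00", "02:00:00"),
                     x = c(121.0, 121.01), y = c(31.0, 31.0),
                     event_type = "sms")
  tr <- read_trajectories(write_trace_csv(rows), crs_mode = "lonlat")[[1]]
  d <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  # 0.01 deg longitude at 31N is ~953 m
  expect_equal(d, 953, tolerance = 0.01)
})
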