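#' @name exposure
#' @title Individual exposure integration and comparison
#'
#' @description
#' Hourly trajectories are joined with the hourly concentration surface:
#' for each hour the occupied 1-km cell's PM2.5 concentration is looked up
#' and accumulated. By default the cumulative exposure is the plain sum of
#' hourly outdoor concentrations over the period (units ug/m3 * h, one-hour
#' steps); when a microenvironment table is supplied, each hour contributes
#' `sum_n AP * ME_n * TP_n` instead, with `ME_n` the microenvironment /
#' outdoor concentration ratio and `TP_n` the time fraction spent in
#' microenvironment `n` (the `TP_n` must sum to 1 within the hour).
NULL

HEALTH_CATEGORIES <- data.frame(
  name = c("Excellent", "Good", "LightlyPolluted", "ModeratelyPolluted",
           "SeverelyPolluted"),
  lower = c(0, 35, 70, 115, 150),
  upper = c(35, 70, 115, 150, Inf),
  stringsAsFactors = FALSE)

#' Health category of PM2.5 concentrations
#'
#' Five categories on left-closed, right-open bins partitioning `[0, Inf)`:
#' Excellent `[0,35)`, Good `[35,70)`, LightlyPolluted `[70,115)`,
#' ModeratelyPolluted `[115,150)`, SeverelyPolluted `[150,Inf)`. Boundary
#' values fall in the upper bin.
#'
#' @param pm PM2.5 concentrations, ug/m3.
#' @return Character vector of category names.
#' @export
health_category <- function(pm) {
  idx <- findInterval(pm, HEALTH_CATEGORIES$lower)
  idx[pm < 0] <- NA_integer_
  HEALTH_CATEGORIES$name[idx]
}

#' Hourly exposure series for one user
#'
#' @param hourly hourly trajectory ([reconstruct_hourly()] layout:
#'   `user_id, day, hour, x, y`).
#' @param surface a `mob_surface` covering every (day, hour) of `hourly`.
#' @param me_tp optional microenvironment table with columns `day`, `hour`,
#'   `me`, `tp` (one row per microenvironment per hour; `tp` sums to 1
#'   within each hour).
#' @return A `mob_exposure` data.frame `user_id, day, hour, cell, ap,
#'   category, contribution` with the cumulative total in the
#'   `"cumulative"` attribute.
#' @export
exposure_series <- function(hourly, surface, me_tp = NULL) {
  cell <- locate_cell(hourly$x, hourly$y, surface$grid)
  ap <- surface_value(surface, cell, hourly$day, hourly$hour)
  contribution <- ap
  if (!is.null(me_tp)) {
    key <- paste(me_tp$day, me_tp$hour)
    tps <- tapply(me_tp$tp, key, sum)
    if (any(abs(tps - 1) > 1e-8))
      stop_param("microenvironment time fractions must sum to 1 per hour")
    wsum <- tapply(me_tp$me * me_tp$tp, key, sum)
    w <- as.numeric(wsum[paste(hourly$day, hourly$hour)])
    if (anyNA(w))
      stop_param("me_tp table does not cover every trajectory hour")
    contribution <- ap * w
  }
  out <- data.frame(user_id = hourly$user_id, day = hourly$day,
                    hour = hourly$hour, cell = as.integer(cell),
                    ap = ap, category = health_category(ap),
                    contribution = contribution,
                    stringsAsFactors = FALSE)
  attr(out, "cumulative") <- sum(contribution)
  class(out) <- c("mob_exposure", "data.frame")
  out
}

#' Cumulative exposure of a series
#'
#' @param series a `mob_exposure`.
#' @return Total exposure, ug/m3 * h.
#' @export
cumulative_exposure <- function(series) sum(series$contribution)

#' Infer the home location from nighttime records
#'
#' The distinct location with the most records in the nighttime window
#' `[22:00, 24:00) U [00:00, 06:00)`. Ties resolve by the count of records
#' in the latest night hours (05, 04, ..., 23, 22), then lexicographically.
#' With no nighttime records, the overall modal location is used and
#' flagged via the `"fallback"` attribute.
#'
#' @param traj a `mob_trajectory`.
#' @param night_start,night_end window bounds in hours (defaults 22 and 6).
#' @return Named numeric vector `c(x=, y=)`.
#' @export
infer_home <- function(traj, night_start = 22, night_end = 6) {
  hr <- traj$t %/% 3600
  night <- hr >= night_start | hr < night_end
  recs <- traj[night, , drop = FALSE]
  fallback <- FALSE
  if (nrow(recs) == 0) { recs <- traj; fallback <- TRUE }
  key <- paste(recs$x, recs$y)
  cnt <- table(key)
  top <- names(cnt)[cnt == max(cnt)]
  if (length(top) > 1) {
    # latest-night-hour majority: hours ordered 5,4,...,0,23,22
    ord_hours <- c(night_end - seq_len(night_end),
                   rev(seq(night_start, 23)))
    for (h in ord_hours) {
      sub <- table(key[recs$t %/% 3600 == h])
      sub <- sub[names(sub) %in% top]
      if (length(sub) && max(sub) > 0) {
        best <- names(sub)[sub == max(sub)]
        if (length(best) == 1) { top <- best; break }
        top <- best
      }
    }
    top <- sort(top)[1]
  }
  i <- match(top, key)
  out <- c(x = recs$x[i], y = recs$y[i])
  attr(out, "fallback") <- fallback
  out
}

# Hourly trajectory from recorded points only: last observation carried
# forward over the hour grid (leading hours back-filled from the first
# record).
recorded_hourly <- function(traj, days) {
  grid <- hourly_grid_times(days)
  marks <- (grid$day - 1) * 86400 + grid$hour * 3600
  idx <- findInterval(marks, traj$abs_t)
  idx[idx < 1] <- 1L
  data.frame(user_id = traj$user_id[1], day = grid$day, hour = grid$hour,
             x = traj$x[idx], y = traj$y[idx],
             provenance = "recorded", stringsAsFactors = FALSE)
}

static_hourly <- function(uid, home, days) {
  grid <- hourly_grid_times(days)
  data.frame(user_id = uid, day = grid$day, hour = grid$hour,
             x = home[["x"]], y = home[["y"]],
             provenance = "static", stringsAsFactors = FALSE)
}

#' Three-way exposure estimates for one user
#'
#' Computes the cumulative exposure using (1) the reconstructed hourly
#' trajectory (TR-EE), (2) the recorded trajectory held between records by
#' last-observation-carried-forward (REC-EE), and (3) the static inferred
#' home location for all hours (SL-EE).
#'
#' @param traj the user's recorded `mob_trajectory`.
#' @param hourly the reconstructed hourly trajectory.
#' @param surface a `mob_surface`.
#' @param days number of days.
#' @param home optional home location (default: [infer_home()] on `traj`).
#' @return list with `tr_ee`, `rec_ee`, `sl_ee` (totals) and the three
#'   series.
#' @export
three_way_estimates <- function(traj, hourly, surface, days, home = NULL) {
  home <- home %||% infer_home(traj)
  tr <- exposure_series(hourly, surface)
  rec <- exposure_series(recorded_hourly(traj, days), surface)
  sl <- exposure_series(static_hourly(traj$user_id[1], home, days), surface)
  list(tr_ee = cumulative_exposure(tr),
       rec_ee = cumulative_exposure(rec),
       sl_ee = cumulative_exposure(sl),
       series = list(tr = tr, rec = rec, sl = sl))
}

#' Two-sample Kolmogorov-Smirnov comparison of exposure distributions
#'
#' Statistic `sup |ECDF_a - ECDF_b|` with the asymptotic p-value.
#'
#' @param sample_a,sample_b numeric vectors of exposure totals (nonempty).
#' @return list with `statistic` and `p_value`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop_param("ks_compare: empty sample")
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Paired per-user differences between two estimates, by day type
#'
#' @param est_a,est_b data.frames `user_id, day, exposure` over the same
#'   users and days.
#' @param day_types named character vector mapping day index to
#'   `"workday"`/`"weekend"`.
#' @return data.frame per day type: `median`, `q1`, `q3`, `iqr`, `n`.
#'   Quartiles use linear interpolation of order statistics at `(n+1)p`
#'   (quantile type 6).
#' @export
paired_differences <- function(est_a, est_b, day_types) {
  ka <- paste(est_a$user_id, est_a$day)
  kb <- paste(est_b$user_id, est_b$day)
  missing_users <- setdiff(union(ka, kb), intersect(ka, kb))
  if (length(missing_users))
    stop_param("paired_differences: user/day sets differ: ",
               paste(utils::head(missing_users, 5), collapse = ", "))
  diff <- est_a$exposure - est_b$exposure[match(ka, kb)]
  type <- unname(day_types[as.character(est_a$day)])
  out <- do.call(rbind, lapply(unique(type), function(tp) {
    d <- diff[type == tp]
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
    data.frame(day_type = tp, median = q[2], q1 = q[1], q3 = q[3],
               iqr = q[3] - q[1], n = length(d))
  }))
  rownames(out) <- NULL
  out
}

#' Write per-user hourly exposure series to CSV
#'
#' Long format: `user_id, day, hour, cell, ap, category, cum`, where `cum`
#' is the running cumulative exposure within each user.
#'
#' @param series_list named list of `mob_exposure` series.
#' @param path output CSV path.
#' @export
write_exposure_csv <- function(series_list, path) {
  rows <- do.call(rbind, lapply(series_list, function(s) {
    s$cum <- cumsum(s$contribution)
    s[, c("user_id", "day", "hour", "cell", "ap", "category", "cum")]
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Zone-level summary of high-exposure residents
#'
#' Selects the `ceiling(top_frac * n)` users with the largest cumulative
#' exposure, locates their homes in zones, and summarizes each selected
#' zone: resident count, the percentage of person-hours in each health
#' category, the percentage of hours spent away from the home cell, and
#' the percentage of exposure accrued in those away hours.
#'
#' @param series_list named list of `mob_exposure` series (one per user).
#' @param homes named list/section of home locations (`c(x=,y=)` per user).
#' @param zones a `mob_zones` object (grid-cell fallback via
#'   [make_grid_zones()]).
#' @param grid the analysis [make_grid()] (for home-cell comparison).
#' @param top_frac fraction of users to select (default 0.2).
#' @return data.frame, one row per zone containing high-exposure
#'   residents: `zone_id, n_residents, pct_<category>..., time_away_pct,
#'   exposure_away_pct`.
#' @export
high_exposure_zone_summary <- function(series_list, homes, zones, grid,
                                       top_frac = 0.2) {
  n <- length(series_list)
  if (n < 5) stop_param("high_exposure_zone_summary: need >= 5 users")
  totals <- vapply(series_list, cumulative_exposure, numeric(1))
  k <- ceiling(top_frac * n)
  sel <- names(sort(totals, decreasing = TRUE))[seq_len(k)]
  hx <- vapply(homes[sel], `[[`, numeric(1), "x")
  hy <- vapply(homes[sel], `[[`, numeric(1), "y")
  zid <- zone_of(hx, hy, zones)
  home_cell <- locate_cell(hx, hy, grid)
  rows <- lapply(sort(unique(zid)), function(z) {
    users <- sel[zid == z]
    ser <- do.call(rbind, lapply(users, function(u) {
      s <- series_list[[u]]
      s$away <- s$cell != home_cell[match(u, sel)]
      s
    }))
    pct <- vapply(HEALTH_CATEGORIES$name, function(cat)
      100 * mean(ser$category == cat), numeric(1))
    data.frame(zone_id = z, n_residents = length(users),
               t(pct),
               time_away_pct = 100 * mean(ser$away),
               exposure_away_pct = 100 * sum(ser$ap[ser$away]) /
                 sum(ser$ap),
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[3:7] <- paste0("pct_", HEALTH_CATEGORIES$name)
  rownames(out) <- NULL
  out
}

#' Relation between time away from home and exposure away from home
#'
#' Ordinary least-squares fit of away-exposure percentage on away-time
#' percentage across zones.
#'
#' @param zone_summary output of [high_exposure_zone_summary()] (>= 2
#'   zones).
#' @return list with `pairs` (data.frame `zone_id, time_away_pct,
#'   exposure_away_pct`), `slope`, `intercept`, `r`.
#' @export
away_exposure_relation <- function(zone_summary) {
  if (nrow(zone_summary) < 2)
    stop_param("away_exposure_relation: need >= 2 zones")
  fit <- stats::lm(exposure_away_pct ~ time_away_pct, data = zone_summary)
  list(pairs = zone_summary[, c("zone_id", "time_away_pct",
                                "exposure_away_pct")],
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(zone_summary$time_away_pct,
                      zone_summary$exposure_away_pct))
}
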