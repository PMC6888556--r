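#' @name trajectory-io
#' @title Mobility-trace input, preprocessing and hourly resampling targets
#'
#' @description
#' A *trajectory* is one user's time-ordered sequence of location records.
#' Records arrive as sparse, event-driven rows (call-detail and actively
#' generated network events): `user_id`, 1-based `day`, `time` (HH:MM:SS or
#' seconds since midnight), planar `x`/`y` in meters (or lon/lat, projected
#' at read time), and an `event_type`. Internally a trajectory is a
#' data.frame of class `mob_trajectory` with columns
#' `user_id, day, t, x, y, event_type, abs_t` where `t` is seconds since the
#' day's start and `abs_t = (day-1)*86400 + t`.
NULL

EVENT_TYPES <- c("call_in", "call_out", "sms",
                 "regular_update", "periodic_update", "handover")
CDR_EVENTS <- c("call_in", "call_out", "sms")

# Accept the canonical tokens plus the human-readable labels used in raw
# operator exports ("Call (inbound)", "Regular update", ...).
normalize_event_type <- function(ev) {
  key <- gsub("[^a-z]+", "_", tolower(trimws(ev)))
  key <- gsub("^_|_$", "", key)
  map <- c(call_in = "call_in", call_inbound = "call_in",
           call_out = "call_out", call_outbound = "call_out",
           sms = "sms", text_message = "sms",
           regular_update = "regular_update",
           periodic_update = "periodic_update",
           handover = "handover", cellular_handover = "handover")
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(ev[is.na(out)])
    stop_param("unknown event_type ", paste(sQuote(bad), collapse = ", "),
               "; accepted values: ", paste(EVENT_TYPES, collapse = ", "))
  }
  out
}

parse_day_time <- function(time) {
  if (is.numeric(time)) return(as.numeric(time))
  parts <- strsplit(as.character(time), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (length(p) == 3) p[1] * 3600 + p[2] * 60 + p[3]
    else if (length(p) == 2) p[1] * 3600 + p[2] * 60
    else NA_real_
  }, numeric(1))
}

as_trajectory <- function(df) {
  df$abs_t <- (df$day - 1) * 86400 + df$t
  o <- order(df$abs_t)   # stable: ties keep input order
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("mob_trajectory", "data.frame")
  df
}

#' @export
print.mob_trajectory <- function(x, ...) {
  cat(sprintf("<mob_trajectory> user %s: %d records over day(s) %s\n",
              x$user_id[1], nrow(x),
              paste(range(x$day), collapse = "-")))
  invisible(x)
}

#' Read mobility traces from CSV
#'
#' Expects columns `user_id, day, time, x, y, event_type` (`time` as
#' `HH:MM:SS` or numeric seconds since midnight). With
#' `crs_mode = "lonlat"`, `x`/`y` are longitude/latitude degrees and are
#' projected once to planar meters via an equirectangular projection about
#' the data centroid, because all distance thresholds downstream are metric.
#'
#' @param path CSV file path.
#' @param crs_mode `"planar"` (meters, default) or `"lonlat"`.
#' @return Named list of `mob_trajectory` objects, one per user, each
#'   time-sorted.
#' @export
read_trajectories <- function(path, crs_mode = c("planar", "lonlat")) {
  crs_mode <- match.arg(crs_mode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("user_id", "day", "time", "x", "y", "event_type")
  if (!all(need %in% names(df)))
    stop_param("trace CSV must have columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0) return(list())
  t_s <- parse_day_time(df$time)
  bad <- which(is.na(t_s) | t_s < 0 | t_s >= 86400 |
                 !is.finite(df$x) | !is.finite(df$y) | is.na(df$day))
  if (length(bad))
    stop_param("malformed trace row at line ", bad[1] + 1L,
               " of ", path)
  ev <- normalize_event_type(df$event_type)
  x <- df$x; y <- df$y
  if (crs_mode == "lonlat") {
    pr <- project_lonlat(x, y)
    x <- pr$x; y <- pr$y
  }
  recs <- data.frame(user_id = as.character(df$user_id),
                     day = as.integer(df$day), t = t_s,
                     x = x, y = y, event_type = ev,
                     stringsAsFactors = FALSE)
  out <- lapply(split(recs, recs$user_id), as_trajectory)
  out[order(names(out))]
}

# Equirectangular projection about the centroid; adequate at city scale,
# where the metric thresholds (500 m, 1 km) downstream apply.
project_lonlat <- function(lon, lat, lon0 = mean(lon), lat0 = mean(lat)) {
  R <- 6371008.8
  list(x = R * cos(lat0 * pi / 180) * (lon - lon0) * pi / 180,
       y = R * (lat - lat0) * pi / 180,
       lon0 = lon0, lat0 = lat0)
}

#' Write trajectories back to CSV
#'
#' Inverse of [read_trajectories()] for planar data; the round-trip
#' preserves every field.
#'
#' @param trajs list of `mob_trajectory` objects.
#' @param path output CSV path.
#' @export
write_trajectories <- function(trajs, path) {
  df <- do.call(rbind, lapply(trajs, function(tr)
    tr[, c("user_id", "day", "t", "x", "y", "event_type")]))
  names(df)[names(df) == "t"] <- "time"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Suppress signal-oscillation artefacts
#'
#' Cell-tower handover ping-pong shows up as rapid A-B-A location flips.
#' Every maximal A-B-A pattern whose two transitions both occur within
#' `window_s` seconds and whose A-B distance is at most `max_jump_m` meters
#' is collapsed by deleting the middle B record(s). Surviving records are a
#' subsequence of the input; the operation is idempotent.
#'
#' @param traj a `mob_trajectory`.
#' @param window_s time window in seconds (default 300).
#' @param max_jump_m distance guard in meters (default 2000).
#' @return The filtered `mob_trajectory`.
#' @export
suppress_oscillation <- function(traj, window_s = 300, max_jump_m = 2000) {
  if (window_s < 0 || max_jump_m < 0)
    stop_param("window_s and max_jump_m must be non-negative")
  n <- nrow(traj)
  if (n < 3) return(traj)
  keep <- rep(TRUE, n)
  repeat {
    idx <- which(keep)
    loc <- paste(traj$x[idx], traj$y[idx])
    # runs of identical consecutive locations among surviving records
    r <- rle(loc)
    if (length(r$lengths) < 3) break
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    changed <- FALSE
    for (j in 2:(length(r$lengths) - 1L)) {
      if (r$values[j - 1] != r$values[j + 1]) next
      if (r$values[j] == r$values[j - 1]) next
      a_last <- idx[ends[j - 1]]; b_first <- idx[starts[j]]
      b_last <- idx[ends[j]]; a_next <- idx[starts[j + 1]]
      if (traj$abs_t[b_first] - traj$abs_t[a_last] > window_s) next
      if (traj$abs_t[a_next] - traj$abs_t[b_last] > window_s) next
      d <- euclid(traj$x[a_last], traj$y[a_last],
                  traj$x[b_first], traj$y[b_first])
      if (d > max_jump_m) next
      keep[idx[starts[j]:ends[j]]] <- FALSE
      changed <- TRUE
      break
    }
    if (!changed) break
  }
  out <- traj[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(traj)
  out
}

#' Hourly resampling target grid
#'
#' One target per wall-clock hour (00:00 ... 23:00) per day, matching the
#' temporal granularity of hourly air-quality monitoring.
#'
#' @param days number of days (>= 1).
#' @return data.frame with columns `day`, `hour` (24 x days rows, ascending).
#' @export
hourly_grid_times <- function(days) {
  if (days < 1) stop_param("days must be >= 1")
  data.frame(day = rep(seq_len(days), each = 24L),
             hour = rep(0:23, times = days))
}

#' Partition the hourly grid into observed and missing hours
#'
#' An hour counts as observed iff at least one record lies within
#' `snap_tol_s` seconds of the hour mark; the nearest such record supplies
#' the location (ties resolve to the earlier record).
#'
#' @param traj a `mob_trajectory`.
#' @param days number of days in the study window.
#' @param snap_tol_s snap tolerance in seconds (default 900, max 1800).
#' @return list with `observed` (data.frame day, hour, x, y) and `missing`
#'   (data.frame day, hour).
#' @export
split_observed_hours <- function(traj, days, snap_tol_s = 900) {
  if (snap_tol_s > 1800) stop_param("snap_tol_s must be <= 1800")
  grid <- hourly_grid_times(days)
  marks <- (grid$day - 1) * 86400 + grid$hour * 3600
  obs <- vector("list", nrow(grid))
  is_obs <- logical(nrow(grid))
  if (nrow(traj) > 0) {
    for (i in seq_len(nrow(grid))) {
      off <- abs(traj$abs_t - marks[i])
      j <- which(off <= snap_tol_s)
      if (length(j)) {
        jj <- j[which.min(off[j])]   # which.min takes the first on ties
        is_obs[i] <- TRUE
        obs[[i]] <- c(traj$x[jj], traj$y[jj])
      }
    }
  }
  observed <- cbind(grid[is_obs, , drop = FALSE],
                    do.call(rbind, obs[is_obs]) %||%
                      matrix(numeric(0), 0, 2))
  if (nrow(observed)) names(observed)[3:4] <- c("x", "y")
  else observed <- data.frame(day = integer(0), hour = integer(0),
                              x = numeric(0), y = numeric(0))
  list(observed = observed, missing = grid[!is_obs, , drop = FALSE])
}
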