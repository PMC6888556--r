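#' @name synthetic
#' @title Seeded synthetic worlds with known ground truth
#'
#' @description
#' The generator emulates the structure of operator mobility data and urban
#' pollution fields at desk scale: agents follow anchor-structured daily
#' schedules (home overnight, a cluster-specific workplace on workdays,
#' a short leisure outing on weekend days) with per-agent jitter; sparse
#' records are drawn from a bursty heavy-tailed renewal process and
#' labelled as call-detail (34%) or actively generated (66%) events; and
#' PM2.5 is a linear function of meteorological covariates with smooth,
#' spatially varying coefficients plus Gaussian cell noise, observed at
#' sparse station sites. Every stage is deterministic given `(seed,
#' config)`, so true trajectories and true surfaces serve as exact oracles
#' downstream.
NULL

default_day_types <- function(days) {
  # one-week rhythm: days 6 and 7 of each week are weekend; a 2-day world
  # gets one workday and one weekend day so both regimes are represented
  if (days == 2) return(c("workday", "weekend"))
  ifelse(((seq_len(days) - 1) %% 7) >= 5, "weekend", "workday")
}

#' Generate anchor-structured agents with true hourly trajectories
#'
#' Each cluster owns a home block in the west of the grid and a work block
#' in the east; agents inherit the cluster schedule (home 20:00-08:00,
#' work 09:00-17:00, transit interpolated; weekend: home with a 14:00-16:00
#' leisure outing) with spatial jitter of up to `jitter_cells` cells and a
#' departure-time jitter of up to `jitter_hours` hours.
#'
#' @param n number of agents (>= n_clusters).
#' @param n_clusters number of movement-pattern clusters.
#' @param grid a [make_grid()] object.
#' @param days number of simulated days.
#' @param day_types character vector of length `days`
#'   (`"workday"`/`"weekend"`); default: one-week rhythm, and for a 2-day
#'   world one of each.
#' @param jitter_cells,jitter_hours per-agent jitter amplitudes (0 makes
#'   all agents of a cluster identical).
#' @param seed RNG seed.
#' @return list of agents: each has `user_id`, `cluster`, `home`, `work`,
#'   `leisure` (named xy vectors) and `true_hourly` (data.frame
#'   `day, hour, x, y`).
#' @export
generate_agents <- function(n, n_clusters, grid, days = 2,
                            day_types = default_day_types(days),
                            jitter_cells = 1, jitter_hours = 1,
                            seed = 1) {
  if (n < n_clusters) stop_param("generate_agents: n < n_clusters")
  stopifnot(length(day_types) == days)
  cm <- grid$cell_m
  # cluster anchor cells at the centers of 8-cell zone blocks: homes in the
  # westmost block column, work in the eastmost, vertically spread over
  # distinct block rows so clusters occupy disjoint zones even after
  # per-agent jitter
  zb <- 8L
  nbr <- max(1L, grid$n_rows %/% zb)
  brows <- round(seq(0, nbr - 1, length.out = n_clusters))
  rows <- pmin(brows * zb + zb %/% 2, grid$n_rows - 1)
  home_c <- cbind(col = min(zb %/% 2, grid$n_cols - 1), row = rows)
  work_c <- cbind(col = min((max(1L, grid$n_cols %/% zb) - 1L) * zb +
                              zb %/% 2, grid$n_cols - 1), row = rows)
  cell_xy <- function(col, row)
    c(x = grid$origin_x + (col + 0.5) * cm,
      y = grid$origin_y + (row + 0.5) * cm)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      cl <- as.integer((i - 1) %% n_clusters) + 1L
      jx <- function() if (jitter_cells > 0)
        sample(-jitter_cells:jitter_cells, 1) else 0L
      home <- cell_xy(home_c[cl, "col"] + jx(), home_c[cl, "row"] + jx())
      work <- cell_xy(work_c[cl, "col"] + jx(), work_c[cl, "row"] + jx())
      leis <- cell_xy(home_c[cl, "col"] + 2 + jx(),
                      home_c[cl, "row"] + 2 + jx())
      dh <- if (jitter_hours > 0)
        sample(-jitter_hours:jitter_hours, 1) else 0L
      rows_day <- lapply(seq_len(days), function(d) {
        hrs <- 0:23
        pos <- matrix(NA_real_, 24, 2)
        if (day_types[d] == "workday") {
          dep <- 8 + dh; ret <- 18 + dh    # commute windows
          for (h in hrs) {
            p <- if (h < dep || h >= ret + 2) home
            else if (h == dep) home + (work - home) * 0.5
            else if (h == ret) home + (work - home) * (2 / 3)
            else if (h == ret + 1) home + (work - home) * (1 / 3)
            else work
            pos[h + 1, ] <- p
          }
        } else {
          out0 <- 14 + dh
          for (h in hrs) {
            p <- if (h %in% (out0:(out0 + 2))) leis
            else if (h == out0 - 1 || h == out0 + 3)
              home + (leis - home) * 0.5
            else home
            pos[h + 1, ] <- p
          }
        }
        data.frame(day = d, hour = hrs, x = pos[, 1], y = pos[, 2])
      })
      list(user_id = sprintf("u%03d", i), cluster = cl,
           home = home, work = work, leisure = leis,
           true_hourly = do.call(rbind, rows_day))
    })
  })
}

# Cell-tower network: a jittered grid of towers with the given spacing.
# Recorded positions are projected to serving towers, reproducing the
# 100-1000 m gap between a user's location and the logged tower position
# and the tower ping-pong that oscillation suppression removes.
make_towers <- function(grid, spacing_m = 500, seed = 1) {
  ext_x <- grid$n_cols * grid$cell_m
  ext_y <- grid$n_rows * grid$cell_m
  nx <- ceiling(ext_x / spacing_m)
  ny <- ceiling(ext_y / spacing_m)
  with_seed(seed, {
    jx <- matrix(stats::runif(nx * ny, 0.15, 0.85), ny, nx)
    jy <- matrix(stats::runif(nx * ny, 0.15, 0.85), ny, nx)
    list(spacing = spacing_m, nx = nx, ny = ny,
         x = grid$origin_x + (col(jx) - 1 + jx) * spacing_m,
         y = grid$origin_y + (row(jy) - 1 + jy) * spacing_m)
  })
}

# Serving tower of each point: nearest tower with probability 1 - p_flip,
# otherwise the second-nearest (signal fluctuation / handover ping-pong).
# Searches the 3x3 block of tower-grid cells around the point.
project_to_towers <- function(px, py, towers, p_flip, seed) {
  n <- length(px)
  flip <- with_seed(seed, stats::runif(n) < p_flip)
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    bc <- floor(px[i] / towers$spacing) + 1
    br <- floor(py[i] / towers$spacing) + 1
    cols <- pmin(pmax(bc + (-1:1), 1), towers$nx)
    rows <- pmin(pmax(br + (-1:1), 1), towers$ny)
    idx <- as.matrix(expand.grid(r = unique(rows), c = unique(cols)))
    tx <- towers$x[idx]; ty <- towers$y[idx]
    d <- (tx - px[i])^2 + (ty - py[i])^2
    o <- order(d)
    pick <- if (flip[i] && length(o) > 1) o[2] else o[1]
    out[i, ] <- c(tx[pick], ty[pick])
  }
  out
}

# Bursty inter-event draw: Pareto(alpha) floor-60s tail mixed with an
# exponential component, truncated to [min_gap, max_gap]. Shapes a heavy
# right tail of inter-record times like operator CDR data.
draw_gaps <- function(n, pareto_alpha = 1.5, pareto_min = 60,
                      exp_mean = 5400, p_pareto = 0.6,
                      min_gap = 60, max_gap = 43200) {
  isp <- stats::runif(n) < p_pareto
  g <- numeric(n)
  g[isp] <- pareto_min * (1 - stats::runif(sum(isp)))^(-1 / pareto_alpha)
  g[!isp] <- stats::rexp(sum(!isp), rate = 1 / exp_mean)
  pmin(pmax(g, min_gap), max_gap)
}

#' Sample sparse event-driven records from a true trajectory
#'
#' Event times follow a heavy-tailed renewal process; each event takes the
#' agent's true position for the hour containing it and is labelled
#' call-detail (`call_in`/`call_out`/`sms`) with probability `cdr_share`
#' and actively generated (`regular_update`/`periodic_update`/`handover`)
#' otherwise.
#'
#' @param agent an agent from [generate_agents()].
#' @param days number of days.
#' @param cdr_share probability a record is a call-detail event (default
#'   0.34).
#' @param gap_args list of overrides for the inter-event distribution.
#' @param towers optional tower network; recorded positions are then the
#'   serving tower's location (nearest tower, or the second-nearest with
#'   probability `p_flip`), not the true position.
#' @param p_flip serving-tower fluctuation probability (default 0.2).
#' @param seed RNG seed.
#' @return A `mob_trajectory`.
#' @export
sample_records <- function(agent, days, cdr_share = 0.34,
                           gap_args = list(), towers = NULL, p_flip = 0.2,
                           seed = 1) {
  stopifnot(cdr_share > 0)
  horizon <- days * 86400
  mean_gap <- do.call(mean_gap_of, gap_args)
  if (horizon / mean_gap < 1)
    stop_param("sample_records: event rate implies ~0 records")
  with_seed(seed, {
    times <- numeric(0); t <- 0
    repeat {
      gaps <- do.call(draw_gaps, c(list(n = 256), gap_args))
      tt <- t + cumsum(gaps)
      times <- c(times, tt[tt < horizon])
      t <- tt[length(tt)]
      if (t >= horizon) break
    }
    n <- length(times)
    day <- pmin(as.integer(times %/% 86400) + 1L, days)
    hr <- as.integer((times %% 86400) %/% 3600)
    th <- agent$true_hourly
    pos <- th[match(paste(day, hr), paste(th$day, th$hour)), c("x", "y")]
    if (!is.null(towers)) {
      pr <- project_to_towers(pos$x, pos$y, towers, p_flip,
                              child_seed(seed, 31L))
      pos$x <- pr[, 1]; pos$y <- pr[, 2]
    }
    is_cdr <- stats::runif(n) < cdr_share
    ev <- character(n)
    ev[is_cdr] <- sample(CDR_EVENTS, sum(is_cdr), replace = TRUE)
    ev[!is_cdr] <- sample(c("regular_update", "periodic_update",
                            "handover"),
                          sum(!is_cdr), replace = TRUE,
                          prob = c(0.5, 0.3, 0.2))
    as_trajectory(data.frame(user_id = agent$user_id, day = day,
                             t = times %% 86400, x = pos$x, y = pos$y,
                             event_type = ev, stringsAsFactors = FALSE))
  })
}

mean_gap_of <- function(pareto_alpha = 1.5, pareto_min = 60,
                        exp_mean = 5400, p_pareto = 0.6,
                        min_gap = 60, max_gap = 43200) {
  # truncated Pareto mean
  a <- pareto_alpha
  pm_mean <- a * pareto_min / (a - 1) *
    (1 - (pareto_min / max_gap)^(a - 1))
  p_pareto * pm_mean + (1 - p_pareto) * exp_mean
}

# ---- pollutant field -------------------------------------------------------

# Smooth spatially varying coefficient fields and meteorological covariate
# fields with diurnal cycles; defaults sized for a ~40 km urban domain with
# the polluted core in the east (where the work anchors sit).

#' Default coefficient fields for the synthetic world
#'
#' Intercept rising west to east (polluted core near the work anchors),
#' visibility coefficient strengthening eastward, constant wind and
#' temperature effects.
#'
#' @return list of coefficient functions of normalized coordinates
#'   `(u, v)` in `[0,1]^2`.
#' @export
default_coef_spec <- function() {
  list(beta0 = function(u, v) 40 + 70 * u,
       beta1 = function(u, v) -(0.001 + 0.006 * u),     # VIS (m)
       beta2 = function(u, v) rep(-3, length(u)),       # WS (m/s)
       beta3 = function(u, v) rep(0.8, length(u)))      # TEM (degC)
}

#' Coefficient fields for the parameter-recovery experiment
#'
#' Only the visibility coefficient varies (linearly west to east); the
#' others are constant, so the experiment isolates recovery of one
#' spatially varying coefficient.
#'
#' @return list of coefficient functions (see [default_coef_spec()]).
#' @export
recovery_coef_spec <- function() {
  list(beta0 = function(u, v) rep(140, length(u)),
       beta1 = function(u, v) -(0.001 + 0.011 * u),
       beta2 = function(u, v) rep(-3, length(u)),
       beta3 = function(u, v) rep(0.8, length(u)))
}

#' Default meteorological covariate fields
#'
#' Smooth long-wavelength (about 20 km) spatial structure plus diurnal
#' cycles: visibility with two interfering patterns, wind with a
#' north-south trend, temperature with gentle coastal-style gradients.
#'
#' @return list of field functions `f(u, v, x, y, hour)`.
#' @export
default_met_spec <- function() {
  list(vis = function(u, v, x, y, hour)
         7000 + 3000 * sin(x / 3200) * cos(y / 3600) +
           3000 * cos(x / 4300) * sin(y / 3100) +
           800 * sin(2 * pi * (hour - 15) / 24),
       ws = function(u, v, x, y, hour)
         2.5 + 1.2 * v + 0.8 * sin(x / 3800) * cos(y / 4200) +
           1.2 * sin(2 * pi * (hour - 14) / 24),
       tem = function(u, v, x, y, hour)
         14 + 1.5 * sin(y / 4500) + 1.2 * cos(x / 5000) +
           6 * sin(2 * pi * (hour - 14) / 24))
}

# Stratified station placement: one cell per randomly jittered block of a
# ceiling(sqrt(n)) x ceiling(sqrt(n)) partition, mirroring the coverage
# design of real monitoring networks (and avoiding the large gaps of
# uniform placement).
stratified_cells <- function(grid, n, seed) {
  nb <- ceiling(sqrt(n))
  with_seed(seed, {
    blocks <- sample.int(nb * nb, n)
    br <- (blocks - 1) %/% nb
    bc <- (blocks - 1) %% nb
    rw <- pmin(floor((br + stats::runif(n)) * grid$n_rows / nb),
               grid$n_rows - 1)
    cl <- pmin(floor((bc + stats::runif(n)) * grid$n_cols / nb),
               grid$n_cols - 1)
    as.integer(rw * grid$n_cols + cl + 1)
  })
}

#' Generate the true pollutant field and station observations
#'
#' True PM2.5 per cell-hour is the spatially-varying-coefficient linear
#' model `beta0 + beta1*VIS + beta2*WS + beta3*TEM` plus Gaussian cell
#' noise of standard deviation `sigma`. Pollution and meteorology stations
#' are placed by seeded stratified sampling of grid cells (one per jittered
#' block, emulating a coverage-designed monitoring network) and observe the
#' true cell values.
#'
#' @param grid a [make_grid()] object.
#' @param days number of days.
#' @param sigma noise standard deviation, ug/m3 (default 5).
#' @param n_stations_pm,n_stations_met station counts (defaults 60).
#' @param coef_spec,met_spec optional lists of coefficient / covariate
#'   field functions (see source for the defaults' shapes).
#' @param seed RNG seed.
#' @return list with `true_surface` (a `mob_surface`), `beta_fields`
#'   (per-cell matrix, columns beta0..beta3), `met_fields` (list of
#'   cells x hours matrices), `pm_obs`, `met_obs` (station observation
#'   tables), `pm_stations`, `met_stations`.
#' @export
generate_field <- function(grid, days = 2, sigma = 5,
                           n_stations_pm = 60, n_stations_met = 60,
                           coef_spec = default_coef_spec(),
                           met_spec = default_met_spec(), seed = 1) {
  if (sigma < 0) stop_param("generate_field: sigma must be >= 0")
  cc <- cell_centers(grid)
  ext_x <- grid$n_cols * grid$cell_m
  ext_y <- grid$n_rows * grid$cell_m
  u <- (cc$x - grid$origin_x) / ext_x
  v <- (cc$y - grid$origin_y) / ext_y
  B <- cbind(beta0 = coef_spec$beta0(u, v), beta1 = coef_spec$beta1(u, v),
             beta2 = coef_spec$beta2(u, v), beta3 = coef_spec$beta3(u, v))
  hours <- hourly_grid_times(days)
  nh <- nrow(hours); nc <- nrow(cc)
  met_fields <- list(vis = matrix(0, nc, nh), ws = matrix(0, nc, nh),
                     tem = matrix(0, nc, nh))
  values <- matrix(0, nc, nh)
  noise <- with_seed(seed, matrix(stats::rnorm(nc * nh, 0, sigma), nc, nh))
  for (i in seq_len(nh)) {
    h <- hours$hour[i]
    vis <- met_spec$vis(u, v, cc$x, cc$y, h)
    ws <- met_spec$ws(u, v, cc$x, cc$y, h)
    tem <- met_spec$tem(u, v, cc$x, cc$y, h)
    met_fields$vis[, i] <- vis
    met_fields$ws[, i] <- ws
    met_fields$tem[, i] <- tem
    values[, i] <- B[, 1] + B[, 2] * vis + B[, 3] * ws + B[, 4] * tem +
      noise[, i]
  }
  pm_cells <- stratified_cells(grid, n_stations_pm, child_seed(seed, 11L))
  met_cells <- stratified_cells(grid, n_stations_met,
                                child_seed(seed, 13L))
  pm_obs <- do.call(rbind, lapply(seq_len(nh), function(i)
    data.frame(station_id = sprintf("pm%03d", seq_along(pm_cells)),
               day = hours$day[i], hour = hours$hour[i],
               x = cc$x[pm_cells], y = cc$y[pm_cells],
               value = values[pm_cells, i], stringsAsFactors = FALSE)))
  met_obs <- do.call(rbind, lapply(seq_len(nh), function(i) {
    base <- data.frame(station_id = sprintf("me%03d",
                                            seq_along(met_cells)),
                       day = hours$day[i], hour = hours$hour[i],
                       x = cc$x[met_cells], y = cc$y[met_cells],
                       stringsAsFactors = FALSE)
    rbind(cbind(base, variable = "vis",
                value = met_fields$vis[met_cells, i]),
          cbind(base, variable = "ws",
                value = met_fields$ws[met_cells, i]),
          cbind(base, variable = "tem",
                value = met_fields$tem[met_cells, i]))
  }))
  list(true_surface = make_surface(grid, hours, values),
       beta_fields = B, met_fields = met_fields,
       pm_obs = pm_obs, met_obs = met_obs,
       pm_stations = data.frame(station_id = sprintf("pm%03d",
                                                     seq_along(pm_cells)),
                                cell = pm_cells,
                                x = cc$x[pm_cells], y = cc$y[pm_cells]),
       met_stations = data.frame(cell = met_cells, x = cc$x[met_cells],
                                 y = cc$y[met_cells]))
}

#' Generate a complete synthetic world
#'
#' Default study conditions: a 40 x 40 km grid of 1-km cells, 200 agents in
#' 4 movement clusters over 2 simulated days (one workday, one weekend
#' day), 60 pollution and 60 meteorology stations, field noise sigma = 5
#' ug/m3, call-detail share 34%.
#'
#' @param n_agents,n_clusters,days,sigma,n_stations see above.
#' @param grid analysis grid (default 40 x 40 cells of 1 km).
#' @param day_types per-day labels; default one-week rhythm.
#' @param jitter_cells,jitter_hours agent jitter.
#' @param cdr_share call-detail record share (default 0.34).
#' @param gap_args inter-event distribution overrides.
#' @param tower_spacing_m cell-tower network spacing (default 500 m;
#'   `NA` disables tower projection and records true positions).
#' @param p_flip serving-tower fluctuation probability (default 0.2).
#' @param seed master RNG seed (all stages derive child seeds from it).
#' @return A `mob_world`: list with `grid`, `zones` (8-cell grid blocks),
#'   `agents`, `trajs` (sampled `mob_trajectory` list), `field` (from
#'   [generate_field()]), `day_types`, `params`.
#' @export
generate_world <- function(n_agents = 200, n_clusters = 4, days = 2,
                           sigma = 5, n_stations = 60,
                           grid = make_grid(0, 0, 40, 40, 1000),
                           day_types = default_day_types(days),
                           jitter_cells = 1, jitter_hours = 1,
                           cdr_share = 0.34, gap_args = list(),
                           tower_spacing_m = 500, p_flip = 0.2,
                           seed = 1) {
  agents <- generate_agents(n_agents, n_clusters, grid, days, day_types,
                            jitter_cells, jitter_hours,
                            seed = child_seed(seed, 1L))
  towers <- if (is.na(tower_spacing_m)) NULL
            else make_towers(grid, tower_spacing_m, child_seed(seed, 3L))
  trajs <- lapply(seq_along(agents), function(i)
    sample_records(agents[[i]], days, cdr_share, gap_args,
                   towers = towers, p_flip = p_flip,
                   seed = child_seed(seed, 100L + i)))
  names(trajs) <- vapply(agents, `[[`, character(1), "user_id")
  field <- generate_field(grid, days, sigma, n_stations, n_stations,
                          seed = child_seed(seed, 7L))
  structure(list(grid = grid, zones = make_grid_zones(grid, 8L),
                 agents = agents, trajs = trajs, towers = towers,
                 field = field,
                 day_types = stats::setNames(day_types,
                                             seq_len(days)),
                 params = list(n_agents = n_agents,
                               n_clusters = n_clusters, days = days,
                               sigma = sigma, n_stations = n_stations,
                               cdr_share = cdr_share, seed = seed)),
            class = "mob_world")
}

#' @export
print.mob_world <- function(x, ...) {
  cat(sprintf(
    "<mob_world> %d agents / %d clusters, %d day(s), %d-cell grid, sigma=%g\n",
    x$params$n_agents, x$params$n_clusters, x$params$days,
    n_cells(x$grid), x$params$sigma))
  invisible(x)
}

#' True exposure of an agent (exact oracle)
#'
#' Cumulative exposure of the agent's true hourly trajectory on the true
#' synthetic surface.
#'
#' @param agent an agent from [generate_agents()].
#' @param world the `mob_world` (uses `world$field$true_surface`).
#' @return Total exposure, ug/m3 * h.
#' @export
true_exposure <- function(agent, world) {
  th <- agent$true_hourly
  th$user_id <- agent$user_id
  cumulative_exposure(exposure_series(th, world$field$true_surface))
}
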