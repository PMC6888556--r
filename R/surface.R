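#' Read hourly station pollutant observations
#'
#' CSV columns: `station_id, day, time, x, y, pm25` (`time` as `HH:MM` /
#' `HH:MM:SS` or an integer hour).
#'
#' @param path CSV path.
#' @return data.frame `station_id, day, hour, x, y, value`.
#' @export
read_pollution_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "day", "time", "x", "y", "pm25")
  if (!all(need %in% names(df)))
    stop_param("pollution CSV must have columns ",
               paste(need, collapse = ", "))
  hour <- if (is.numeric(df$time)) as.integer(df$time)
          else as.integer(parse_day_time(df$time) %/% 3600)
  data.frame(station_id = as.character(df$station_id),
             day = as.integer(df$day), hour = hour,
             x = df$x, y = df$y, value = df$pm25,
             stringsAsFactors = FALSE)
}

#' Read hourly station meteorology
#'
#' CSV columns: `station_id, day, time, x, y, wind_speed, visibility,
#' temperature`.
#'
#' @param path CSV path.
#' @return Long data.frame `station_id, day, hour, x, y, variable, value`
#'   with variables `ws`, `vis`, `tem`.
#' @export
read_met_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "day", "time", "x", "y",
            "wind_speed", "visibility", "temperature")
  if (!all(need %in% names(df)))
    stop_param("meteorology CSV must have columns ",
               paste(need, collapse = ", "))
  hour <- if (is.numeric(df$time)) as.integer(df$time)
          else as.integer(parse_day_time(df$time) %/% 3600)
  base <- data.frame(station_id = as.character(df$station_id),
                     day = as.integer(df$day), hour = hour,
                     x = df$x, y = df$y, stringsAsFactors = FALSE)
  rbind(cbind(base, variable = "ws",  value = df$wind_speed),
        cbind(base, variable = "vis", value = df$visibility),
        cbind(base, variable = "tem", value = df$temperature))
}

#' Attach kriged meteorological covariates to pollution stations
#'
#' Each pollution station receives, per variable, the mean of the kriged
#' cell values whose centers lie within `radius_m` of it. A station with no
#' cell center in radius takes the nearest cell's value and is flagged.
#'
#' @param stations data.frame with station `x`, `y` (one row per station).
#' @param met_surfaces named list of per-cell value vectors (`vis`, `ws`,
#'   `tem`) on `grid`.
#' @param grid the [make_grid()] object the surfaces live on.
#' @param radius_m averaging radius in meters (default 1000).
#' @return `stations` with covariate columns appended and a logical
#'   `fallback` column marking nearest-cell stations.
#' @export
attach_covariates <- function(stations, met_surfaces, grid,
                              radius_m = 1000) {
  cc <- cell_centers(grid)
  out <- stations
  out$fallback <- FALSE
  for (v in names(met_surfaces)) out[[v]] <- NA_real_
  for (i in seq_len(nrow(stations))) {
    d <- euclid(stations$x[i], stations$y[i], cc$x, cc$y)
    sel <- which(d <= radius_m)
    if (length(sel) == 0) {
      sel <- which.min(d)
      out$fallback[i] <- TRUE
    }
    for (v in names(met_surfaces))
      out[[v]][i] <- mean(met_surfaces[[v]][sel])
  }
  out
}

#' Predict the hourly concentration surface from a fitted GWR model
#'
#' Local coefficients are obtained by refitting the weighted regression at
#' each cell center; the concentration is
#' `beta0 + beta1*VIS + beta2*WS + beta3*TEM` with the cell's kriged
#' covariates. Negative predictions are floored at 0 (physical constraint)
#' and counted in the `"n_floored"` attribute.
#'
#' @param model a `mob_gwr` fit.
#' @param met_surfaces named list of per-cell covariate vectors (`vis`,
#'   `ws`, `tem`).
#' @param grid the [make_grid()] object.
#' @return Numeric vector of per-cell concentrations (cell-id order).
#' @export
predict_surface <- function(model, met_surfaces, grid) {
  for (v in c("vis", "ws", "tem"))
    if (is.null(met_surfaces[[v]]))
      stop_param("predict_surface: missing covariate surface ", v)
  cc <- cell_centers(grid)
  B <- gwr_coefficients_at(model, cc$x, cc$y)
  conc <- B[, 1] + B[, 2] * met_surfaces$vis +
    B[, 3] * met_surfaces$ws + B[, 4] * met_surfaces$tem
  n_floor <- sum(conc < 0)
  conc[conc < 0] <- 0
  attr(conc, "n_floored") <- n_floor
  conc
}

#' Build a pollution surface for every hour of the study period
#'
#' For each (day, hour): kriges the three meteorological variables to the
#' grid, attaches covariates to the pollution stations, fits the hourly GWR
#' model, and predicts the cell surface. Emits per-hour fit diagnostics.
#'
#' @param pm_obs pollution observations ([read_pollution_csv()] layout).
#' @param met_obs meteorology observations ([read_met_csv()] layout).
#' @param grid a [make_grid()] object.
#' @param kernel,adaptive,bandwidth passed to [fit_gwr_hour()].
#' @param allow_missing skip hours lacking pollution observations with a
#'   warning instead of erroring.
#' @return A `mob_surface` object: list with `grid`, `hours` (data.frame
#'   `day`, `hour`), `values` (cells x hours matrix), `diagnostics`
#'   (per-hour `r2`, `aic`, `rmse` plus a summary row), `models`.
#' @export
fit_all_hours <- function(pm_obs, met_obs, grid,
                          kernel = "bisquare", adaptive = TRUE,
                          bandwidth = "select", allow_missing = FALSE) {
  hours <- unique(met_obs[, c("day", "hour")])
  hours <- hours[order(hours$day, hours$hour), , drop = FALSE]
  rownames(hours) <- NULL
  vals <- matrix(NA_real_, n_cells(grid), nrow(hours))
  diags <- list(); models <- list()
  keep <- logical(nrow(hours))
  for (i in seq_len(nrow(hours))) {
    d <- hours$day[i]; h <- hours$hour[i]
    pm_h <- pm_obs[pm_obs$day == d & pm_obs$hour == h, , drop = FALSE]
    if (nrow(pm_h) == 0) {
      if (allow_missing) {
        warning("no pollution observations for day ", d, " hour ", h,
                "; skipped", call. = FALSE)
        next
      }
      stop_param("no pollution observations for day ", d, " hour ", h)
    }
    met_h <- met_obs[met_obs$day == d & met_obs$hour == h, , drop = FALSE]
    surf <- lapply(stats::setNames(c("vis", "ws", "tem"),
                                   c("vis", "ws", "tem")), function(v) {
      ob <- met_h[met_h$variable == v, , drop = FALSE]
      krige_meteorology(ob, grid)
    })
    st <- attach_covariates(pm_h[, c("station_id", "x", "y")], surf, grid)
    rows <- data.frame(pm = pm_h$value, vis = st$vis, ws = st$ws,
                       tem = st$tem, x = pm_h$x, y = pm_h$y)
    model <- fit_gwr_hour(rows, kernel = kernel, adaptive = adaptive,
                          bandwidth = bandwidth, day = d, hour = h)
    vals[, i] <- predict_surface(model, surf, grid)
    keep[i] <- TRUE
    models[[i]] <- model
    diags[[i]] <- data.frame(day = d, hour = h, r2 = model$r2,
                             aic = model$aic, rmse = model$rmse,
                             bandwidth = model$bandwidth)
  }
  diagnostics <- do.call(rbind, diags)
  if (!is.null(diagnostics) && nrow(diagnostics)) {
    summary_row <- data.frame(day = NA_integer_, hour = NA_integer_,
                              r2 = mean(diagnostics$r2),
                              aic = mean(diagnostics$aic),
                              rmse = mean(diagnostics$rmse),
                              bandwidth = mean(diagnostics$bandwidth))
    diagnostics <- rbind(diagnostics, summary_row)
  }
  structure(list(grid = grid, hours = hours[keep, , drop = FALSE],
                 values = vals[, keep, drop = FALSE],
                 diagnostics = diagnostics,
                 models = models[keep]),
            class = "mob_surface")
}

#' Construct a pollution surface from per-hour cell values
#'
#' Used for synthetic ground-truth fields and tests.
#'
#' @param grid a [make_grid()] object.
#' @param hours data.frame `day`, `hour`.
#' @param values cells x hours matrix (cell-id order).
#' @return A `mob_surface` object.
#' @export
make_surface <- function(grid, hours, values) {
  stopifnot(nrow(values) == n_cells(grid), ncol(values) == nrow(hours))
  structure(list(grid = grid, hours = hours, values = values,
                 diagnostics = NULL, models = NULL),
            class = "mob_surface")
}

#' @export
print.mob_surface <- function(x, ...) {
  cat(sprintf("<mob_surface> %d cells x %d hour(s)",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$diagnostics)) {
    s <- x$diagnostics[nrow(x$diagnostics), ]
    cat(sprintf("; mean R2=%.3f RMSE=%.2f", s$r2, s$rmse))
  }
  cat("\n")
  invisible(x)
}

# Concentration at (cell, day, hour); vectorized over cells/days/hours.
surface_value <- function(surface, cell, day, hour) {
  col <- match(paste(day, hour), paste(surface$hours$day,
                                       surface$hours$hour))
  if (anyNA(col))
    stop_param("surface does not cover day ", day[which(is.na(col))[1]],
               " hour ", hour[which(is.na(col))[1]])
  surface$values[cbind(cell, col)]
}

#' Export a surface as a long CSV
#'
#' @param surface a `mob_surface`.
#' @param path output CSV path.
#' @export
write_surface_csv <- function(surface, path) {
  cc <- cell_centers(surface$grid)
  rows <- do.call(rbind, lapply(seq_len(nrow(surface$hours)), function(i)
    data.frame(day = surface$hours$day[i], hour = surface$hours$hour[i],
               row = cc$row, col = cc$col, x = cc$x, y = cc$y,
               value = surface$values[, i])))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
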