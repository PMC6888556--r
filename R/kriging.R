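#' Empirical semivariogram
#'
#' Method-of-moments estimate `gamma(h) = mean(0.5 * (z_i - z_j)^2)` over
#' distance bins.
#'
#' @param x,y,value station coordinates (m) and observed values.
#' @param n_bins number of distance bins (default 12).
#' @param max_dist maximum pair distance considered (default: half the
#'   largest pairwise distance).
#' @return data.frame with columns `h` (bin mean distance), `gamma`, `n`
#'   (pair count).
#' @export
empirical_variogram <- function(x, y, value, n_bins = 12, max_dist = NULL) {
  n <- length(x)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- euclid(x[ij[, 1]], y[ij[, 1]], x[ij[, 2]], y[ij[, 2]])
  g <- 0.5 * (value[ij[, 1]] - value[ij[, 2]])^2
  if (is.null(max_dist)) max_dist <- max(d) / 2
  keep <- d > 0 & d <= max_dist
  d <- d[keep]; g <- g[keep]
  br <- seq(0, max_dist, length.out = n_bins + 1)
  bin <- cut(d, br, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    h = as.numeric(tapply(d, bin, mean)),
    gamma = as.numeric(tapply(g, bin, mean)),
    n = as.integer(tapply(g, bin, length)))
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Fit a variogram model by weighted least squares
#'
#' Models: exponential `gamma(h) = nugget + sill * (1 - exp(-h/range))` or
#' gaussian `gamma(h) = nugget + sill * (1 - exp(-(h/range)^2))`. The
#' nugget is fixed at 0 by default so kriging stays an exact interpolator
#' at the stations. Bins are weighted by their pair counts. Empirical
#' variograms of smooth fields underestimate the range (hole effects), so
#' [krige_ordinary()] can refine the fitted range by leave-one-out
#' cross-validation.
#'
#' @param emp empirical variogram from [empirical_variogram()].
#' @param model `"gaussian"` (default; suits smooth meteorological
#'   surfaces) or `"exponential"`.
#' @param nugget fixed nugget (default 0).
#' @return list with `nugget`, `sill`, `range`, `model`, and `degenerate`
#'   (TRUE when the field is constant).
#' @export
fit_variogram <- function(emp, model = c("gaussian", "exponential"),
                          nugget = 0) {
  model <- match.arg(model)
  if (nrow(emp) == 0 || all(emp$gamma < 1e-12))
    return(list(nugget = 0, sill = 0, range = 1, model = model,
                degenerate = TRUE))
  shape <- if (model == "gaussian") function(h, a) 1 - exp(-(h / a)^2)
           else function(h, a) 1 - exp(-h / a)
  obj <- function(p) {
    g <- nugget + p[1] * shape(emp$h, p[2])
    sum(emp$n * (emp$gamma - g)^2)
  }
  init <- c(max(emp$gamma), max(emp$h) / 3)
  fit <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(1e-10, max(emp$h) * 1e-4),
                      upper = c(max(emp$gamma) * 10, max(emp$h) * 100))
  list(nugget = nugget, sill = fit$par[1], range = fit$par[2],
       model = model, degenerate = FALSE)
}

vgm_gamma <- function(h, vgm) {
  g <- if (vgm$model == "gaussian")
    vgm$nugget + vgm$sill * (1 - exp(-(h / vgm$range)^2))
  else vgm$nugget + vgm$sill * (1 - exp(-h / vgm$range))
  g[h == 0] <- 0   # exact interpolation at zero lag (nugget acts off-site)
  g
}

# Leave-one-out kriging RMSE for a candidate variogram.
krige_loo_rmse <- function(x, y, value, vgm) {
  n <- length(x)
  err <- vapply(seq_len(n), function(i) {
    p <- krige_ordinary(x[-i], y[-i], value[-i], x[i], y[i], vgm = vgm)
    p - value[i]
  }, numeric(1))
  sqrt(mean(err^2))
}

# The WLS range estimate is unreliable for smooth fields (hole-effect
# empirical variograms); choose the range by LOO cross-validation over a
# log-spaced grid of fractions of the domain size, keeping the WLS
# candidate in the running (deterministic).
refine_variogram_range <- function(x, y, value, vgm,
                                   fractions = exp(seq(log(0.03),
                                                       log(0.45),
                                                       length.out = 8))) {
  if (vgm$degenerate) return(vgm)
  dmax <- sqrt(diff(range(x))^2 + diff(range(y))^2)
  cand <- unique(c(vgm$range, fractions * dmax))
  scores <- vapply(cand, function(a) {
    v <- vgm; v$range <- a
    krige_loo_rmse(x, y, value, v)
  }, numeric(1))
  vgm$range <- cand[which.min(scores)]
  vgm
}

#' Ordinary kriging prediction
#'
#' Solves the ordinary-kriging system (semivariogram form, unbiasedness
#' constraint) once and predicts at all target points. With a zero nugget
#' the predictor is exact at station locations, and a constant field is
#' reproduced everywhere.
#'
#' @param x,y,value station coordinates and observations (>= 3 distinct
#'   stations).
#' @param px,py prediction point coordinates.
#' @param vgm fitted variogram (default: fitted from the data via
#'   [empirical_variogram()] + [fit_variogram()]).
#' @param refine_range refine the fitted range by leave-one-out
#'   cross-validation (only when `vgm` is NULL; default FALSE).
#' @return Numeric vector of predictions at `(px, py)`.
#' @export
krige_ordinary <- function(x, y, value, px, py, vgm = NULL,
                           refine_range = FALSE) {
  key <- paste(x, y)
  if (anyDuplicated(key)) {
    sp <- split(value, key)
    if (any(vapply(sp, function(v) length(unique(v)) > 1, logical(1))))
      stop_param("duplicate station coordinates with conflicting values")
    first <- !duplicated(key)
    x <- x[first]; y <- y[first]; value <- value[first]
  }
  n <- length(x)
  if (n < 3) stop_param("ordinary kriging needs >= 3 distinct stations")
  if (stats::var(value) < 1e-20) return(rep(value[1], length(px)))
  if (is.null(vgm)) {
    vgm <- fit_variogram(empirical_variogram(x, y, value))
    if (refine_range) vgm <- refine_variogram_range(x, y, value, vgm)
  }
  if (vgm$degenerate) return(rep(mean(value), length(px)))
  D <- as.matrix(stats::dist(cbind(x, y)))
  A <- rbind(cbind(vgm_gamma(D, vgm), 1), c(rep(1, n), 0))
  # small diagonal jitter only if singular
  g0 <- vapply(seq_along(px), function(k)
    c(vgm_gamma(euclid(px[k], py[k], x, y), vgm), 1),
    numeric(n + 1))
  lam <- tryCatch(solve(A, g0),
                  error = function(e)
                    solve(A + diag(1e-8 * max(vgm$sill, 1), n + 1), g0))
  as.numeric(crossprod(lam[seq_len(n), , drop = FALSE], value))
}

#' Krige one meteorological variable to the grid
#'
#' @param obs data.frame with columns `x`, `y`, `value` for one variable
#'   and one hour.
#' @param grid a [make_grid()] object.
#' @param vgm optional pre-fitted variogram.
#' @return Numeric vector of length `n_rows * n_cols` (cell-id order).
#' @export
krige_meteorology <- function(obs, grid, vgm = NULL) {
  cc <- cell_centers(grid)
  krige_ordinary(obs$x, obs$y, obs$value, cc$x, cc$y, vgm = vgm,
                 refine_range = TRUE)
}
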