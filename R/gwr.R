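#' @name gwr
#' @title Geographically weighted regression of hourly PM2.5
#'
#' @description
#' For each hour, station PM2.5 is regressed on kriged meteorological
#' covariates (visibility, wind speed, temperature) with spatially local
#' weighted least squares: at a regression point `s`, each station `j` gets
#' kernel weight `w_j(s)` decaying with distance, and
#' `beta(s) = (X' W X)^{-1} X' W y`. Coefficients therefore vary smoothly in
#' space. Bandwidth is chosen by minimizing the corrected Akaike criterion
#' (AICc) via golden-section search; larger bandwidths approach ordinary
#' least squares.
NULL

gwr_kernel_weights <- function(d, kernel, bw, adaptive) {
  if (adaptive) {
    k <- max(2L, min(round(bw), length(d)))
    b <- sort(d, partial = k)[k]
    if (b <= 0) b <- max(d, 1e-9)
  } else b <- bw
  if (kernel == "bisquare") {
    w <- ifelse(d < b, (1 - (d / b)^2)^2, 0)
  } else {                       # gaussian
    w <- exp(-0.5 * (d / b)^2)
  }
  w
}

gwr_local_fit <- function(X, y, w) {
  sw <- sqrt(w)
  Xw <- X * sw
  XtX <- crossprod(Xw)
  XtWy <- crossprod(Xw, y * sw)
  M <- tryCatch(solve(XtX), error = function(e) NULL)
  if (is.null(M)) return(NULL)
  list(beta = as.numeric(M %*% XtWy), M = M)
}

# Fit at the n data locations; returns coefficients, hat diagonal, fitted.
gwr_fit_points <- function(X, y, coords, kernel, bw, adaptive,
                           targets = coords, need_hat = TRUE) {
  n <- nrow(X); m <- nrow(targets)
  B <- matrix(NA_real_, m, ncol(X))
  hat <- numeric(m); fitted <- numeric(m)
  for (i in seq_len(m)) {
    d <- euclid(targets[i, 1], targets[i, 2], coords[, 1], coords[, 2])
    w <- gwr_kernel_weights(d, kernel, bw, adaptive)
    if (sum(w > 0) < ncol(X) + 1) {
      # too few in-kernel stations: widen to gaussian fallback weights
      w <- exp(-0.5 * (d / max(d))^2)
    }
    lf <- gwr_local_fit(X, y, w)
    if (is.null(lf))
      stop_param("singular local design in GWR (collinear covariates)")
    B[i, ] <- lf$beta
    if (need_hat) {
      xi <- X[i, ]
      ri <- as.numeric(xi %*% lf$M %*% t(X * w))   # hat row
      hat[i] <- ri[i]
      fitted[i] <- sum(ri * y)
    } else {
      fitted[i] <- NA_real_
    }
  }
  list(beta = B, hat = hat, fitted = fitted)
}

gwr_aicc <- function(y, fitted, trS) {
  n <- length(y)
  rss <- sum((y - fitted)^2)
  sig <- sqrt(rss / n)
  denom <- n - 2 - trS
  if (denom <= 0) return(Inf)
  2 * n * log(sig) + n * log(2 * pi) + n * (n + trS) / denom
}

golden_section <- function(f, lo, hi, tol = 0.01, max_iter = 60) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  for (i in seq_len(max_iter)) {
    if (abs(b - a) < tol * (abs(a) + abs(b) + 1e-9)) break
    if (f1 < f2) { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2) }
  }
  if (f1 < f2) c1 else c2
}

#' Fit one hourly GWR model
#'
#' @param rows data.frame with columns `pm`, `vis`, `ws`, `tem`, `x`, `y`
#'   (one row per pollution station, covariates already attached).
#' @param kernel `"bisquare"` (default) or `"gaussian"`.
#' @param adaptive logical; `TRUE` (default) interprets the bandwidth as a
#'   nearest-neighbour count, `FALSE` as a fixed distance in meters.
#' @param bandwidth numeric bandwidth, or `"select"` (default) to minimize
#'   AICc by golden-section search.
#' @param day,hour bookkeeping labels stored on the fit.
#' @return A `mob_gwr` object: per-station coefficients (columns
#'   `beta0..beta3`), `r2`, `aic` (AICc), `rmse`, `bandwidth`, residuals.
#' @export
fit_gwr_hour <- function(rows, kernel = c("bisquare", "gaussian"),
                         adaptive = TRUE, bandwidth = "select",
                         day = NA_integer_, hour = NA_integer_) {
  kernel <- match.arg(kernel)
  need <- c("pm", "vis", "ws", "tem", "x", "y")
  if (!all(need %in% names(rows)))
    stop_param("fit_gwr_hour: rows must have columns ",
               paste(need, collapse = ", "))
  n <- nrow(rows)
  p <- 3L
  if (n < p + 2) stop_param("fit_gwr_hour: need >= ", p + 2, " stations",
                            if (!is.na(hour)) paste0(" (hour ", hour, ")"))
  # standardize covariates for numerical conditioning; coefficients are
  # transformed back to the raw scale below
  sc <- covariate_scaling(rows)
  X <- scaled_design(rows, sc)
  y <- rows$pm
  coords <- cbind(rows$x, rows$y)
  if (identical(bandwidth, "select")) {
    score <- function(bw) {
      ft <- tryCatch(gwr_fit_points(X, y, coords, kernel, bw, adaptive),
                     error = function(e) NULL)
      if (is.null(ft)) return(Inf)
      gwr_aicc(y, ft$fitted, sum(ft$hat))
    }
    if (adaptive) bandwidth <- golden_section(score, p + 2, n)
    else {
      dmax <- max(stats::dist(coords))
      bandwidth <- golden_section(score, dmax / 20, dmax * 2)
    }
  }
  ft <- gwr_fit_points(X, y, coords, kernel, bandwidth, adaptive)
  res <- y - ft$fitted
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  beta <- unscale_beta(ft$beta, sc)
  structure(list(day = day, hour = hour, kernel = kernel,
                 adaptive = adaptive, bandwidth = bandwidth,
                 scaling = sc,
                 coefficients = beta,
                 fitted = ft$fitted, residuals = res,
                 r2 = r2, aic = gwr_aicc(y, ft$fitted, sum(ft$hat)),
                 rmse = sqrt(mean(res^2)),
                 rows = rows),
            class = "mob_gwr")
}

#' @export
print.mob_gwr <- function(x, ...) {
  cat(sprintf(
    "<mob_gwr> day %s hour %s: n=%d, bw=%.3g (%s %s), R2=%.3f, AICc=%.1f\n",
    x$day, x$hour, nrow(x$rows), x$bandwidth,
    if (x$adaptive) "adaptive" else "fixed", x$kernel, x$r2, x$aic))
  invisible(x)
}

#' Coefficients of a fitted GWR model at new locations
#'
#' Refits the local regression at each target point with the stored kernel
#' and bandwidth.
#'
#' @param model a `mob_gwr` fit.
#' @param px,py target coordinates.
#' @return Matrix (length(px) x 4) of local coefficients.
#' @export
gwr_coefficients_at <- function(model, px, py) {
  X <- scaled_design(model$rows, model$scaling)
  y <- model$rows$pm
  coords <- cbind(model$rows$x, model$rows$y)
  ft <- gwr_fit_points(X, y, coords, model$kernel, model$bandwidth,
                       model$adaptive, targets = cbind(px, py),
                       need_hat = FALSE)
  unscale_beta(ft$beta, model$scaling)
}

covariate_scaling <- function(rows) {
  m <- c(vis = mean(rows$vis), ws = mean(rows$ws), tem = mean(rows$tem))
  s <- c(vis = stats::sd(rows$vis), ws = stats::sd(rows$ws),
         tem = stats::sd(rows$tem))
  s[!is.finite(s) | s == 0] <- 1
  list(mean = m, sd = s)
}

scaled_design <- function(rows, sc) {
  cbind(1, (rows$vis - sc$mean["vis"]) / sc$sd["vis"],
        (rows$ws - sc$mean["ws"]) / sc$sd["ws"],
        (rows$tem - sc$mean["tem"]) / sc$sd["tem"])
}

unscale_beta <- function(B, sc) {
  out <- cbind(
    beta0 = B[, 1] - B[, 2] * sc$mean["vis"] / sc$sd["vis"] -
      B[, 3] * sc$mean["ws"] / sc$sd["ws"] -
      B[, 4] * sc$mean["tem"] / sc$sd["tem"],
    beta1 = B[, 2] / sc$sd["vis"],
    beta2 = B[, 3] / sc$sd["ws"],
    beta3 = B[, 4] / sc$sd["tem"])
  rownames(out) <- NULL
  out
}
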