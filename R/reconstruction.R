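#' @name reconstruction
#' @title Cluster-pooled GBDT trajectory reconstruction
#'
#' @description
#' Missing hourly locations are predicted from the two nearest observed
#' records with a gradient-boosted regression-tree model (CART weak
#' learners) trained on all trajectories of a movement-pattern cluster.
#' Each training vector is
#' `[x_{n-1}, y_{n-1}, t_{n-1}, t_n, x_{n+1}, y_{n+1}, t_{n+1}, ROG, Ent]`
#' with label `[x_n, y_n]`, built from consecutive point triples of
#' trajectories resampled at several time intervals. Times are absolute
#' seconds from the start of day 1.
NULL

FEATURE_NAMES <- c("x_prev", "y_prev", "t_prev", "t_target",
                   "x_next", "y_next", "t_next", "rog_m", "entropy_bits")

# Resample a trajectory to ~interval_s spacing: walk the time grid anchored
# at the first record, taking the nearest record within interval_s/2 of
# each grid time, deduplicating consecutive picks.
resample_records <- function(traj, interval_s) {
  n <- nrow(traj)
  if (n == 0) return(integer(0))
  t0 <- traj$abs_t[1]; t1 <- traj$abs_t[n]
  grid <- seq(t0, t1, by = interval_s)
  picked <- integer(0)
  for (g in grid) {
    off <- abs(traj$abs_t - g)
    j <- which.min(off)
    if (off[j] <= interval_s / 2) picked <- c(picked, j)
  }
  picked[!duplicated(picked)]
}

#' Build a cluster's training set of consecutive point triples
#'
#' @param trajs list of `mob_trajectory` objects belonging to one cluster.
#' @param features [mobility_features()] table covering their users.
#' @param resample_intervals_s resampling intervals in seconds (default
#'   half-hour to 3 hours).
#' @return data.frame with the nine feature columns plus labels `x_target`,
#'   `y_target` and a `user_id` column.
#' @export
build_training_set <- function(trajs, features,
                               resample_intervals_s = c(1800, 3600, 7200, 10800)) {
  rows <- list()
  for (tr in trajs) {
    if (nrow(tr) < 3) next
    uid <- tr$user_id[1]
    f <- features[features$user_id == uid, , drop = FALSE]
    if (nrow(f) != 1)
      stop_param("build_training_set: no mobility features for user ", uid)
    for (iv in resample_intervals_s) {
      sel <- resample_records(tr, iv)
      if (length(sel) < 3) next
      s <- tr[sel, , drop = FALSE]
      m <- length(sel)
      mid <- 2:(m - 1)
      rows[[length(rows) + 1L]] <- data.frame(
        x_prev = s$x[mid - 1], y_prev = s$y[mid - 1],
        t_prev = s$abs_t[mid - 1], t_target = s$abs_t[mid],
        x_next = s$x[mid + 1], y_next = s$y[mid + 1],
        t_next = s$abs_t[mid + 1],
        rog_m = f$rog_m, entropy_bits = f$entropy_bits,
        x_target = s$x[mid], y_target = s$y[mid],
        user_id = uid, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    stop_param("build_training_set: no trajectory with >= 3 records")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the cluster's gradient-boosted reconstruction model
#'
#' Two independent boosted-tree regressors (one per coordinate), CART weak
#' learners via xgboost. Deterministic given the seed (single thread, no
#' subsampling by default).
#'
#' @param examples training set from [build_training_set()].
#' @param nrounds,max_depth,eta,subsample boosting hyperparameters
#'   (defaults 400 trees, depth 7, learning rate 0.1, no subsampling).
#' @param min_train_examples minimum training-set size (default 10).
#' @param seed RNG seed for the boosters.
#' @param cluster_id bookkeeping label.
#' @return A `mob_gbdt` object.
#' @export
fit_gbdt <- function(examples, nrounds = 400, max_depth = 7, eta = 0.1,
                     subsample = 1, min_train_examples = 10, seed = 1,
                     cluster_id = NA) {
  if (nrow(examples) < min_train_examples)
    stop_param("fit_gbdt: cluster ", cluster_id, " has only ",
               nrow(examples), " examples (need ", min_train_examples, ")")
  X <- as.matrix(examples[, FEATURE_NAMES])
  fit1 <- function(label) {
    dtrain <- xgboost::xgb.DMatrix(X, label = label, nthread = 1)
    with_seed(seed, xgboost::xgb.train(
      params = list(max_depth = max_depth, eta = eta,
                    subsample = subsample, objective = "reg:squarederror",
                    nthread = 1, seed = seed),
      data = dtrain, nrounds = nrounds, verbose = 0))
  }
  structure(list(cluster_id = cluster_id,
                 model_x = fit1(examples$x_target),
                 model_y = fit1(examples$y_target),
                 hyperparams = list(nrounds = nrounds, max_depth = max_depth,
                                    eta = eta, subsample = subsample,
                                    seed = seed),
                 n_train = nrow(examples)),
            class = "mob_gbdt")
}

#' @export
print.mob_gbdt <- function(x, ...) {
  cat(sprintf("<mob_gbdt> cluster %s: %d examples, %d trees, depth %d\n",
              x$cluster_id, x$n_train, x$hyperparams$nrounds,
              x$hyperparams$max_depth))
  invisible(x)
}

#' Save / load a reconstruction model
#'
#' The boosters are serialized through xgboost's raw format (stable across
#' sessions) together with the hyperparameters and training-set size;
#' reloading reproduces predictions exactly.
#'
#' @param model a `mob_gbdt`.
#' @param path file path.
#' @return `save_gbdt` the path, invisibly; `load_gbdt` the `mob_gbdt`.
#' @export
save_gbdt <- function(model, path) {
  obj <- list(cluster_id = model$cluster_id,
              raw_x = xgboost::xgb.save.raw(model$model_x),
              raw_y = xgboost::xgb.save.raw(model$model_y),
              hyperparams = model$hyperparams,
              n_train = model$n_train)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_gbdt
#' @export
load_gbdt <- function(path) {
  obj <- readRDS(path)
  structure(list(cluster_id = obj$cluster_id,
                 model_x = xgboost::xgb.load.raw(obj$raw_x),
                 model_y = xgboost::xgb.load.raw(obj$raw_y),
                 hyperparams = obj$hyperparams,
                 n_train = obj$n_train),
            class = "mob_gbdt")
}

#' Predict target locations with a fitted reconstruction model
#'
#' @param model a `mob_gbdt`.
#' @param feats matrix or data.frame with the nine feature columns.
#' @return Two-column matrix of predicted `(x, y)`.
#' @export
predict_gbdt <- function(model, feats) {
  X <- xgboost::xgb.DMatrix(
    as.matrix(as.data.frame(feats)[, FEATURE_NAMES]), nthread = 1)
  cbind(x = stats::predict(model$model_x, X),
        y = stats::predict(model$model_y, X))
}

# Build prediction features for target absolute times from observed
# records: nearest observed record before and after each target.
context_features <- function(traj, target_abs_t, rog, ent) {
  ti <- traj$abs_t
  prev_i <- findInterval(target_abs_t, ti)        # last record <= target
  next_i <- prev_i + 1L
  prev_i[prev_i < 1] <- 1L
  next_i[next_i > nrow(traj)] <- nrow(traj)
  data.frame(x_prev = traj$x[prev_i], y_prev = traj$y[prev_i],
             t_prev = ti[prev_i], t_target = target_abs_t,
             x_next = traj$x[next_i], y_next = traj$y[next_i],
             t_next = ti[next_i], rog_m = rog, entropy_bits = ent)
}

#' Reconstruct a full hourly trajectory
#'
#' Observed hours (within the snap tolerance) pass through unchanged; each
#' interior missing hour is predicted from its nearest observed neighbours
#' before and after; missing hours before the first / after the last
#' observation take the nearest observed location.
#'
#' @param traj a `mob_trajectory`.
#' @param model a `mob_gbdt` for the user's cluster (may be `NULL`:
#'   interior hours then also use nearest-record filling).
#' @param features one-row slice of [mobility_features()] for this user.
#' @param days number of days in the study window.
#' @param snap_tol_s hour snap tolerance (default 900 s).
#' @return data.frame `user_id, day, hour, x, y, provenance` with exactly
#'   `24 * days` rows; `provenance` is `"observed"` or `"reconstructed"`.
#' @export
reconstruct_hourly <- function(traj, model, features, days,
                               snap_tol_s = 900) {
  grid <- hourly_grid_times(days)
  uid <- traj$user_id[1]
  if (nrow(traj) < 2) {
    out <- cbind(user_id = uid, grid,
                 x = traj$x[1], y = traj$y[1], provenance = "reconstructed")
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  sp <- split_observed_hours(traj, days, snap_tol_s)
  marks <- (grid$day - 1) * 86400 + grid$hour * 3600
  obs_marks <- (sp$observed$day - 1) * 86400 + sp$observed$hour * 3600
  x <- numeric(nrow(grid)); y <- numeric(nrow(grid))
  prov <- rep("reconstructed", nrow(grid))
  oi <- match(marks, obs_marks)
  hit <- !is.na(oi)
  x[hit] <- sp$observed$x[oi[hit]]
  y[hit] <- sp$observed$y[oi[hit]]
  prov[hit] <- "observed"
  miss <- which(!hit)
  if (length(miss)) {
    t0 <- traj$abs_t[1]; t1 <- traj$abs_t[nrow(traj)]
    mm <- marks[miss]
    interior <- mm > t0 & mm < t1
    # edge hours: nearest observed record's location
    edge <- miss[!interior]
    if (length(edge)) {
      nearest <- ifelse(marks[edge] <= t0, 1L, nrow(traj))
      x[edge] <- traj$x[nearest]; y[edge] <- traj$y[nearest]
    }
    inner <- miss[interior]
    if (length(inner)) {
      if (is.null(model)) {
        pred <- baseline_nearest(traj, marks[inner])
      } else {
        feats <- context_features(traj, marks[inner],
                                  features$rog_m, features$entropy_bits)
        pred <- predict_gbdt(model, feats)
      }
      x[inner] <- pred[, 1]; y[inner] <- pred[, 2]
    }
  }
  data.frame(user_id = uid, day = grid$day, hour = grid$hour,
             x = x, y = y, provenance = prov, stringsAsFactors = FALSE)
}

#' Nearest-record interpolation baseline
#'
#' @param traj a `mob_trajectory` (>= 1 record).
#' @param target_abs_t target times, absolute seconds.
#' @return Two-column matrix of `(x, y)`: the location of the temporally
#'   closest record (ties go to the earlier record).
#' @export
baseline_nearest <- function(traj, target_abs_t) {
  if (nrow(traj) == 0) stop_param("baseline_nearest: empty trajectory")
  idx <- vapply(target_abs_t, function(tt) {
    off <- abs(traj$abs_t - tt)
    which.min(off)          # first index on ties = earlier record
  }, integer(1))
  cbind(x = traj$x[idx], y = traj$y[idx])
}

#' Linear interpolation baseline
#'
#' Affine interpolation between the bracketing records, clamped to the
#' first/last record outside the observed span.
#'
#' @param traj a `mob_trajectory` (>= 2 records).
#' @param target_abs_t target times, absolute seconds.
#' @return Two-column matrix of `(x, y)`.
#' @export
baseline_linear <- function(traj, target_abs_t) {
  if (nrow(traj) < 2) stop_param("baseline_linear: needs >= 2 records")
  x <- stats::approx(traj$abs_t, traj$x, xout = target_abs_t,
                     method = "linear", rule = 2, ties = "ordered")$y
  y <- stats::approx(traj$abs_t, traj$y, xout = target_abs_t,
                     method = "linear", rule = 2, ties = "ordered")$y
  cbind(x = x, y = y)
}

split_holdout <- function(traj, holdout) {
  if (identical(holdout$mode, "event_type")) {
    held <- traj$event_type %in% setdiff(EVENT_TYPES, CDR_EVENTS)
  } else {
    held <- with_seed(holdout$seed,
                      stats::runif(nrow(traj)) < (holdout$frac %||% 0.66))
  }
  list(kept = traj[!held, , drop = FALSE],
       held = traj[held, , drop = FALSE])
}

#' Held-out reconstruction evaluation
#'
#' Partitions each user's records into kept and held-out sets (by event
#' type: CDR events kept, actively generated records held; or by a seeded
#' random fraction), trains the cluster-pooled GBDT on the kept records,
#' and evaluates every method on the identical held-out points. Error is
#' the Euclidean distance between predicted and true locations.
#'
#' @param trajs named list of `mob_trajectory` objects.
#' @param cluster_labels named integer vector user -> cluster id.
#' @param holdout list: `mode = "event_type"`, or `mode = "fraction"` with
#'   `frac` and `seed`.
#' @param methods subset of `c("gbdt", "nearest", "linear")`.
#' @param gbdt_args list of extra arguments to [fit_gbdt()].
#' @param resample_intervals_s passed to [build_training_set()].
#' @return A `mob_recon_report`: data.frame `method, mae_m, sd_m,
#'   n_heldout`, with per-point errors retained in the `"errors"`
#'   attribute.
#' @export
evaluate_holdout <- function(trajs, cluster_labels = NULL,
                             holdout = list(mode = "event_type"),
                             methods = c("gbdt", "nearest", "linear"),
                             gbdt_args = list(),
                             resample_intervals_s = c(1800, 3600, 7200, 10800)) {
  parts <- lapply(trajs, split_holdout, holdout = holdout)
  names(parts) <- names(trajs)
  usable <- vapply(parts, function(p)
    nrow(p$held) > 0 && nrow(p$kept) >= 2, logical(1))
  if (!any(vapply(parts, function(p) nrow(p$held) > 0, logical(1))))
    stop_param("evaluate_holdout: empty held-out set")
  parts <- parts[usable]
  if (is.null(cluster_labels)) {
    cluster_labels <- stats::setNames(rep(1L, length(trajs)), names(trajs))
  }
  kept_trajs <- lapply(parts, function(p) p$kept)
  feats <- mobility_features(kept_trajs)
  models <- list()
  if ("gbdt" %in% methods) {
    for (cl in unique(cluster_labels[names(parts)])) {
      users <- names(parts)[cluster_labels[names(parts)] == cl]
      ex <- tryCatch(build_training_set(kept_trajs[users], feats,
                                        resample_intervals_s),
                     error = function(e) NULL)
      models[[as.character(cl)]] <-
        if (is.null(ex)) NULL
        else do.call(fit_gbdt, c(list(examples = ex, cluster_id = cl),
                                 gbdt_args))
    }
  }
  errs <- stats::setNames(vector("list", length(methods)), methods)
  for (uid in names(parts)) {
    kept <- parts[[uid]]$kept; held <- parts[[uid]]$held
    f <- feats[feats$user_id == uid, , drop = FALSE]
    tt <- held$abs_t
    for (m in methods) {
      pred <- switch(m,
        nearest = baseline_nearest(kept, tt),
        linear = baseline_linear(kept, tt),
        gbdt = {
          mod <- models[[as.character(cluster_labels[[uid]])]]
          if (is.null(mod)) baseline_nearest(kept, tt)
          else predict_gbdt(mod, context_features(kept, tt, f$rog_m,
                                                  f$entropy_bits))
        })
      errs[[m]] <- c(errs[[m]],
                     euclid(pred[, 1], pred[, 2], held$x, held$y))
    }
  }
  report <- do.call(rbind, lapply(methods, function(m)
    data.frame(method = m, mae_m = mean(errs[[m]]),
               sd_m = stats::sd(errs[[m]]),
               n_heldout = length(errs[[m]]))))
  attr(report, "errors") <- errs
  class(report) <- c("mob_recon_report", "data.frame")
  report
}
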