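#' @name studies
#' @title Seeded evaluation studies on synthetic worlds
#'
#' @description
#' Two pre-specified experiments used to validate the method end to end:
#' a parameter-recovery study for the spatially varying visibility
#' coefficient of the hourly concentration model, and an
#' estimator-comparison study reproducing the method ranking
#' (cluster-pooled boosted-tree reconstruction vs interpolation baselines;
#' reconstructed- vs recorded- vs static-home-trajectory exposure).
NULL

#' Recovery study for the spatially varying visibility coefficient
#'
#' Generates the recovery field (only `beta1` varies, linearly west to
#' east; [recovery_coef_spec()]), kriges and attaches covariates once per
#' study hour, then refits the hourly GWR under independent Gaussian noise
#' draws for each noise level. Station-level `beta1` estimates are
#' averaged over the study hours (the coefficient fields are static, so
#' hourly fits are independent realizations).
#'
#' @param sigmas noise standard deviations, ug/m3 (default
#'   `c(20, 10, 5, 0)`).
#' @param n_rep independent noise replicates per sigma (default 12).
#' @param hours hours of day used (default `c(3, 9, 15, 21)`).
#' @param n_stations_pm,n_stations_met station counts (60 pollution
#'   stations; 100 meteorology sites, the density of an automatic
#'   weather-station network).
#' @param grid analysis grid (default 40 x 40 km).
#' @param seed master seed.
#' @return list with `per_sigma` (data.frame `sigma`, `mae`, `r`, `r2`),
#'   and `n_stations`.
#' @export
beta1_recovery_experiment <- function(sigmas = c(20, 10, 5, 0), n_rep = 12,
                                      hours = c(3, 9, 15, 21),
                                      n_stations_pm = 60,
                                      n_stations_met = 100,
                                      grid = make_grid(0, 0, 40, 40, 1000),
                                      seed = 1) {
  f0 <- generate_field(grid, days = 1, sigma = 0,
                       n_stations_pm = n_stations_pm,
                       n_stations_met = n_stations_met,
                       coef_spec = recovery_coef_spec(), seed = seed)
  cells <- f0$pm_stations$cell
  true_b1 <- f0$beta_fields[cells, "beta1"]
  n_st <- length(cells)
  # krige + attach once per hour (meteorology is noiseless)
  hour_rows <- lapply(hours, function(h) {
    met_h <- f0$met_obs[f0$met_obs$day == 1 & f0$met_obs$hour == h, ]
    surf <- lapply(stats::setNames(c("vis", "ws", "tem"),
                                   c("vis", "ws", "tem")), function(v)
      krige_meteorology(met_h[met_h$variable == v, ], grid))
    st <- attach_covariates(f0$pm_stations[, c("station_id", "x", "y")],
                            surf, grid)
    pm_lin <- f0$true_surface$values[cells, h + 1]
    data.frame(pm = pm_lin, vis = st$vis, ws = st$ws, tem = st$tem,
               x = f0$pm_stations$x, y = f0$pm_stations$y)
  })
  # bandwidth per hour fixed across the noise sweep (selected once at the
  # noisiest level) so sigma is the only varying factor
  bw_fix <- vapply(seq_along(hours), function(hi) {
    rows <- hour_rows[[hi]]
    rows$pm <- rows$pm +
      with_seed(child_seed(seed, 9000L + hi),
                stats::rnorm(n_st, 0, max(sigmas)))
    fit_gwr_hour(rows)$bandwidth
  }, numeric(1))
  per_sigma <- lapply(seq_along(sigmas), function(si) {
    sg <- sigmas[si]
    reps <- lapply(seq_len(n_rep), function(k) {
      B <- matrix(NA_real_, n_st, length(hours))
      r2s <- numeric(length(hours))
      for (hi in seq_along(hours)) {
        rows <- hour_rows[[hi]]
        rows$pm <- rows$pm +
          with_seed(child_seed(seed, 1000L * si + 10L * k + hi),
                    stats::rnorm(n_st, 0, sg))
        m <- fit_gwr_hour(rows, bandwidth = bw_fix[hi])
        B[, hi] <- m$coefficients[, "beta1"]
        r2s[hi] <- m$r2
      }
      b1 <- rowMeans(B)
      list(mae = mean(abs(B - true_b1)),   # per-hour-fit recovery error
           r = stats::cor(true_b1, b1),    # r on the hour-averaged field
           r2 = mean(r2s))
    })
    data.frame(sigma = sg,
               mae = mean(vapply(reps, `[[`, numeric(1), "mae")),
               r = reps[[1]]$r,
               r2 = mean(vapply(reps, `[[`, numeric(1), "r2")))
  })
  list(per_sigma = do.call(rbind, per_sigma),
       n_stations = c(pm = n_stations_pm, met = n_stations_met))
}

# Run clustering + reconstruction + exposure comparison on one world.
run_world_comparison <- function(world, n_clusters, gbdt_seed) {
  trajs <- world$trajs
  anchor_sets <- lapply(trajs, function(tr)
    project_anchors_to_zones(detect_anchors(tr), world$zones))
  cl <- cluster_users(anchor_similarity_matrix(anchor_sets),
                      k = n_clusters)
  labels <- cl$labels
  holdout <- evaluate_holdout(trajs, cluster_labels = labels,
                              holdout = list(mode = "event_type"))
  feats <- mobility_features(trajs)
  models <- lapply(sort(unique(labels)), function(k) {
    ex <- build_training_set(trajs[names(labels)[labels == k]], feats)
    fit_gbdt(ex, seed = child_seed(gbdt_seed, k), cluster_id = k)
  })
  names(models) <- as.character(sort(unique(labels)))
  days <- world$params$days
  est <- lapply(names(trajs), function(uid) {
    hourly <- reconstruct_hourly(trajs[[uid]],
                                 models[[as.character(labels[[uid]])]],
                                 feats[feats$user_id == uid, ], days)
    three_way_estimates(trajs[[uid]], hourly, world$field$true_surface,
                        days)
  })
  names(est) <- names(trajs)
  truth <- vapply(world$agents, true_exposure, numeric(1), world = world)
  names(truth) <- vapply(world$agents, `[[`, character(1), "user_id")
  tr <- vapply(est, `[[`, numeric(1), "tr_ee")[names(truth)]
  rec <- vapply(est, `[[`, numeric(1), "rec_ee")[names(truth)]
  sl <- vapply(est, `[[`, numeric(1), "sl_ee")[names(truth)]
  list(holdout = holdout, clustering = cl,
       estimates = data.frame(user_id = names(truth), true = truth,
                              tr_ee = tr, rec_ee = rec, sl_ee = sl),
       med_err = c(tr = stats::median(abs(tr - truth)),
                   rec = stats::median(abs(rec - truth)),
                   sl = stats::median(abs(sl - truth))))
}

#' Estimator-comparison study over seeded replicate worlds
#'
#' For each replicate world: detects anchors, clusters users, evaluates
#' held-out reconstruction (call-detail records kept, actively generated
#' records held out) for the cluster-pooled GBDT and the nearest/linear
#' interpolation baselines, and computes the three exposure estimates
#' (reconstructed TR-EE, recorded REC-EE, static-home SL-EE) against the
#' exact synthetic truth on the true surface.
#'
#' @param n_seeds number of replicate worlds (default 10).
#' @param seed master seed.
#' @param world_args list of overrides for [generate_world()].
#' @return list with `per_seed` (one row per world: per-method held-out
#'   MAE and the median absolute exposure error of TR/REC/SL) and
#'   `first_world_estimates` (the per-user estimate table of the first
#'   world, for distribution comparisons).
#' @export
estimator_comparison_study <- function(n_seeds = 10, seed = 1,
                                       world_args = list()) {
  rows <- list(); first_est <- NULL
  for (s in seq_len(n_seeds)) {
    wseed <- child_seed(seed, 7000L + s)
    world <- do.call(generate_world, c(list(seed = wseed), world_args))
    res <- run_world_comparison(world, world$params$n_clusters,
                                gbdt_seed = child_seed(wseed, 77L))
    if (is.null(first_est)) first_est <- res$estimates
    h <- res$holdout
    rows[[s]] <- data.frame(
      seed = wseed,
      mae_gbdt = h$mae_m[h$method == "gbdt"],
      mae_nearest = h$mae_m[h$method == "nearest"],
      mae_linear = h$mae_m[h$method == "linear"],
      sd_gbdt = h$sd_m[h$method == "gbdt"],
      med_err_tr = res$med_err[["tr"]],
      med_err_rec = res$med_err[["rec"]],
      med_err_sl = res$med_err[["sl"]])
  }
  list(per_seed = do.call(rbind, rows),
       first_world_estimates = first_est)
}
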