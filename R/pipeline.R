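#' Default run configuration
#'
#' Every tunable default of the pipeline, grouped by stage. Unknown keys in
#' user overrides are rejected by [read_run_config()].
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    io = list(crs_mode = "planar"),
    preprocess = list(window_s = 300, max_jump_m = 2000),
    resample = list(snap_tol_s = 900),
    anchors = list(alpha_m = 500, beta = 0.2),
    clustering = list(linkage = "average", n_clusters = 4L),
    gbdt = list(nrounds = 400L, max_depth = 7L, eta = 0.1,
                subsample = 1, min_train_examples = 10L),
    reconstruction = list(resample_intervals_s = c(1800, 3600, 7200, 10800)),
    field = list(kernel = "bisquare", adaptive = TRUE,
                 bandwidth = "select", allow_missing = FALSE,
                 grid = list(origin_x = 0, origin_y = 0, n_rows = 40L,
                             n_cols = 40L, cell_m = 1000)),
    exposure = list(top_frac = 0.2, night_start = 22L, night_end = 6L),
    synth = list(n_agents = 200L, n_clusters = 4L, days = 2L, sigma = 5,
                 n_stations = 60L, jitter_cells = 1L, jitter_hours = 1L,
                 cdr_share = 0.34)
  )
}

merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    key <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base))
      stop(structure(class = c("mob_config_error", "error", "condition"),
                     list(message = paste0("unknown config key: ", key),
                          call = NULL)))
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]], key)
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read and validate a YAML run configuration
#'
#' Missing keys take their defaults; unknown keys raise a
#' `mob_config_error`.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Resolved configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  cfg
}

#' Run the full exposure-estimation pipeline on a synthetic world
#'
#' Stages in method order: synthetic-world generation; anchor detection,
#' similarity and clustering; cluster-pooled GBDT training and hourly
#' reconstruction; hourly kriging + GWR concentration surfaces; exposure
#' integration with the three-way estimator comparison and zone summaries.
#' All outputs (CSV tables) plus a JSON manifest (input hashes, seed,
#' versions, per-stage timings) are written to `out_dir`. A resolved copy
#' of the configuration is written next to the outputs.
#'
#' @param config configuration list from [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @param seed overrides `config$seed` when non-NULL.
#' @return Invisibly, a list with the manifest and key results.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile(),
                         seed = NULL) {
  seed <- as.integer(seed %||% config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }
  sy <- config$synth
  world <- clock("synth", generate_world(
    n_agents = sy$n_agents, n_clusters = sy$n_clusters, days = sy$days,
    sigma = sy$sigma, n_stations = sy$n_stations,
    grid = do.call(make_grid, config$field$grid),
    jitter_cells = sy$jitter_cells, jitter_hours = sy$jitter_hours,
    cdr_share = sy$cdr_share, seed = seed))
  trajs <- lapply(world$trajs, suppress_oscillation,
                  window_s = config$preprocess$window_s,
                  max_jump_m = config$preprocess$max_jump_m)
  clustering <- clock("clustering", {
    anchor_sets <- lapply(trajs, function(tr)
      project_anchors_to_zones(
        detect_anchors(tr, config$anchors$alpha_m, config$anchors$beta),
        world$zones))
    S <- anchor_similarity_matrix(anchor_sets)
    cluster_users(S, k = config$clustering$n_clusters,
                  linkage = config$clustering$linkage)
  })
  feats <- mobility_features(trajs)
  recon <- clock("reconstruction", {
    labels <- clustering$labels
    models <- lapply(sort(unique(labels)), function(cl) {
      ex <- build_training_set(trajs[names(labels)[labels == cl]], feats,
                               config$reconstruction$resample_intervals_s)
      fit_gbdt(ex, nrounds = config$gbdt$nrounds,
               max_depth = config$gbdt$max_depth, eta = config$gbdt$eta,
               subsample = config$gbdt$subsample,
               min_train_examples = config$gbdt$min_train_examples,
               seed = child_seed(seed, 900L + cl), cluster_id = cl)
    })
    names(models) <- as.character(sort(unique(labels)))
    hourly <- lapply(names(trajs), function(uid) {
      reconstruct_hourly(trajs[[uid]],
                         models[[as.character(labels[[uid]])]],
                         feats[feats$user_id == uid, ], sy$days,
                         config$resample$snap_tol_s)
    })
    names(hourly) <- names(trajs)
    list(models = models, hourly = hourly)
  })
  surface <- clock("field", fit_all_hours(
    world$field$pm_obs, world$field$met_obs, world$grid,
    kernel = config$field$kernel, adaptive = config$field$adaptive,
    bandwidth = config$field$bandwidth,
    allow_missing = config$field$allow_missing))
  expo <- clock("exposure", {
    homes <- lapply(trajs, infer_home,
                    night_start = config$exposure$night_start,
                    night_end = config$exposure$night_end)
    est <- lapply(names(trajs), function(uid)
      three_way_estimates(trajs[[uid]], recon$hourly[[uid]], surface,
                          sy$days, home = homes[[uid]]))
    names(est) <- names(trajs)
    series <- lapply(est, function(e) e$series$tr)
    zs <- high_exposure_zone_summary(series, homes, world$zones,
                                     world$grid,
                                     top_frac = config$exposure$top_frac)
    tr <- vapply(est, `[[`, numeric(1), "tr_ee")
    rec <- vapply(est, `[[`, numeric(1), "rec_ee")
    sl <- vapply(est, `[[`, numeric(1), "sl_ee")
    # per-user-per-day totals for the day-type difference summaries
    daily <- function(key) do.call(rbind, lapply(names(est), function(u) {
      s <- est[[u]]$series[[key]]
      agg <- tapply(s$contribution, s$day, sum)
      data.frame(user_id = u, day = as.integer(names(agg)),
                 exposure = as.numeric(agg))
    }))
    day_types <- world$day_types
    pd <- rbind(
      cbind(pair = "tr_vs_rec",
            paired_differences(daily("tr"), daily("rec"), day_types)),
      cbind(pair = "tr_vs_sl",
            paired_differences(daily("tr"), daily("sl"), day_types)))
    list(estimates = data.frame(user_id = names(est), tr_ee = tr,
                                rec_ee = rec, sl_ee = sl),
         ks_tr_rec = ks_compare(tr, rec), ks_tr_sl = ks_compare(tr, sl),
         zone_summary = zs, paired = pd, homes = homes,
         series = series)
  })
  # ---- outputs -------------------------------------------------------------
  paths <- list(
    estimates = file.path(out_dir, "exposure_estimates.csv"),
    series = file.path(out_dir, "exposure_series.csv"),
    paired = file.path(out_dir, "paired_differences.csv"),
    zones = file.path(out_dir, "zone_summary.csv"),
    diagnostics = file.path(out_dir, "field_diagnostics.csv"),
    config = file.path(out_dir, "config_resolved.yaml"),
    manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(expo$estimates, paths$estimates, row.names = FALSE)
  write_exposure_csv(expo$series, paths$series)
  utils::write.csv(expo$paired, paths$paired, row.names = FALSE)
  utils::write.csv(expo$zone_summary, paths$zones, row.names = FALSE)
  utils::write.csv(surface$diagnostics, paths$diagnostics,
                   row.names = FALSE)
  config$seed <- seed
  yaml::write_yaml(config, paths$config)
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("mobexpo")),
    r_version = R.version.string,
    timings_s = timings,
    outputs = lapply(paths[c("estimates", "zones", "diagnostics")],
                     function(p) unname(tools::md5sum(p))),
    ks = list(tr_rec = expo$ks_tr_rec, tr_sl = expo$ks_tr_sl),
    field = list(mean_r2 = surface$diagnostics$r2[nrow(surface$diagnostics)],
                 mean_rmse =
                   surface$diagnostics$rmse[nrow(surface$diagnostics)]))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, world = world, surface = surface,
                 clustering = clustering, reconstruction = recon,
                 exposure = expo, paths = paths))
}
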