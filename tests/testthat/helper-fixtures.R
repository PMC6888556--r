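# Small in-code fixtures and brute-force oracles shared across tests.

# A trajectory from explicit record vectors (planar meters).
make_traj <- function(user = "u1", day = 1, t, x, y,
                      event = "regular_update") {
  df <- data.frame(user_id = rep_len(user, length(t)),
                   day = rep_len(day, length(t)), t = t,
                   x = x, y = y,
                   event_type = rep_len(event, length(t)),
                   stringsAsFactors = FALSE)
  mobexpo:::as_trajectory(df)
}

# Write a Table-1-style trace CSV and return its path.
write_trace_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

# Brute-force two-sample ECDF sup statistic.
ks_stat_brute <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p),
                 numeric(1))))
}

# Brute-force training-example count: for each resampled sequence, every
# interior point yields one example.
count_examples_brute <- function(trajs, intervals) {
  total <- 0L
  for (tr in trajs) {
    if (nrow(tr) < 3) next
    for (iv in intervals) {
      sel <- mobexpo:::resample_records(tr, iv)
      total <- total + max(0L, length(sel) - 2L)
    }
  }
  total
}

# A tiny two-zone GeoJSON (two unit squares sharing the x = 1000 edge).
write_two_zone_geojson <- function(path = tempfile(fileext = ".geojson")) {
  sq <- function(x0, y0, x1, y1)
    list(list(list(x0, y0), list(x1, y0), list(x1, y1), list(x0, y1),
              list(x0, y0)))
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(zone_id = 1L),
         geometry = list(type = "Polygon",
                         coordinates = sq(0, 0, 1000, 1000))),
    list(type = "Feature", properties = list(zone_id = 2L),
         geometry = list(type = "Polygon",
                         coordinates = sq(1000, 0, 2000, 1000)))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  path
}

# Small synthetic world shared by the slower integration tests.
small_world <- function(seed = 20260901, n_agents = 24, n_clusters = 2,
                        ...) {
  generate_world(n_agents = n_agents, n_clusters = n_clusters,
                 seed = seed, ...)
}
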