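test_that("world regeneration is bit-identical under the same seed", {
  w1 <- small_world(seed = 77)
  w2 <- small_world(seed = 77)
  expect_identical(w1$trajs, w2$trajs)
  expect_identical(w1$field$true_surface$values,
                   w2$field$true_surface$values)
  expect_identical(w1$field$pm_obs, w2$field$pm_obs)
  w3 <- small_world(seed = 78)
  expect_false(identical(w1$trajs, w3$trajs))
})

test_that("zero jitter makes all agents of a cluster identical", {
  grid <- make_grid(0, 0, 40, 40, 1000)
  ag <- generate_agents(6, 2, grid, days = 2, jitter_cells = 0,
                        jitter_hours = 0, seed = 4)
  expect_identical(ag[[1]]$true_hourly, ag[[3]]$true_hourly)
  expect_identical(ag[[2]]$true_hourly, ag[[4]]$true_hourly)
  expect_false(identical(ag[[1]]$true_hourly, ag[[2]]$true_hourly))
  expect_error(generate_agents(1, 2, grid), "n < n_clusters")
})

test_that("schedules are anchor-structured: home overnight, work midday", {
  grid <- make_grid(0, 0, 40, 40, 1000)
  ag <- generate_agents(4, 2, grid, days = 2,
                        day_types = c("workday", "weekend"),
                        jitter_cells = 0, jitter_hours = 0, seed = 6)
  a <- ag[[1]]
  th <- a$true_hourly
  wd <- th[th$day == 1, ]
  expect_equal(unname(c(wd$x[wd$hour == 3], wd$y[wd$hour == 3])),
               unname(a$home))
  expect_equal(unname(c(wd$x[wd$hour == 12], wd$y[wd$hour == 12])),
               unname(a$work))
  we <- th[th$day == 2, ]
  expect_equal(unname(c(we$x[we$hour == 3], we$y[we$hour == 3])),
               unname(a$home))
})

test_that("sampled records are seeded, positional and labelled", {
  grid <- make_grid(0, 0, 40, 40, 1000)
  ag <- generate_agents(2, 1, grid, days = 2, seed = 8)
  r1 <- sample_records(ag[[1]], days = 2, seed = 5)
  r2 <- sample_records(ag[[1]], days = 2, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$event_type %in%
                    c("call_in", "call_out", "sms", "regular_update",
                      "periodic_update", "handover")))
  # without towers every record sits exactly on the true trajectory
  th <- ag[[1]]$true_hourly
  key <- paste(round(r1$x, 6), round(r1$y, 6))
  expect_true(all(key %in% paste(round(th$x, 6), round(th$y, 6))))
})

test_that("tower projection moves records by less than a tower spacing", {
  grid <- make_grid(0, 0, 40, 40, 1000)
  ag <- generate_agents(2, 1, grid, days = 2, seed = 8)
  towers <- mobexpo:::make_towers(grid, 500, seed = 9)
  rt <- sample_records(ag[[1]], days = 2, towers = towers, seed = 5)
  rn <- sample_records(ag[[1]], days = 2, seed = 5)
  d <- sqrt((rt$x - rn$x)^2 + (rt$y - rn$y)^2)
  expect_true(all(d < 1600))   # nearest or second-nearest serving tower
  expect_gt(mean(d), 100)      # but a real positional gap exists
})

test_that("the call-detail share matches its configuration", {
  grid <- make_grid(0, 0, 40, 40, 1000)
  ag <- generate_agents(1, 1, grid, days = 2, seed = 10)[[1]]
  ev <- unlist(lapply(1:40, function(i)
    sample_records(ag, days = 2, seed = 1000 + i)$event_type))
  share <- mean(ev %in% c("call_in", "call_out", "sms"))
  expect_equal(share, 0.34, tolerance = 0.03)
})

test_that("a saturating event rate observes every hour", {
  grid <- make_grid(0, 0, 40, 40, 1000)
  ag <- generate_agents(1, 1, grid, days = 1, seed = 12)[[1]]
  dense <- sample_records(ag, days = 1,
                          gap_args = list(exp_mean = 120, p_pareto = 0,
                                          min_gap = 60, max_gap = 300),
                          seed = 3)
  sp <- split_observed_hours(dense, days = 1)
  expect_equal(nrow(sp$missing), 0)
  expect_error(sample_records(ag, days = 1,
                              gap_args = list(exp_mean = 1e9,
                                              p_pareto = 0)),
               "0 records")
})

test_that("cluster structure in the world is recoverable end to end", {
  # two clusters with disjoint anchor zones -> Jaccard 0 across, 2 clusters
  w <- small_world(seed = 91, n_agents = 10, n_clusters = 2)
  as <- lapply(w$trajs, function(tr)
    project_anchors_to_zones(detect_anchors(tr), w$zones))
  S <- anchor_similarity_matrix(as)
  truecl <- vapply(w$agents, `[[`, integer(1), "cluster")
  cross <- S[truecl[1] == truecl, truecl[1] != truecl]
  expect_lt(max(cross), 0.35)
  cl <- cluster_users(S, k = 2)
  purity <- sum(apply(table(cl$labels, truecl), 1, max)) / 10
  expect_equal(purity, 1)

  # single template: one cluster recovered at a coarse cut
  w1 <- small_world(seed = 92, n_agents = 8, n_clusters = 1)
  as1 <- lapply(w1$trajs, function(tr)
    project_anchors_to_zones(detect_anchors(tr), w1$zones))
  cl1 <- cluster_users(anchor_similarity_matrix(as1), h = 0.9)
  expect_equal(length(unique(cl1$labels)), 1)
})

test_that("true exposure is an exact oracle over the true surface", {
  w <- small_world(seed = 93, n_agents = 4, n_clusters = 2)
  a <- w$agents[[1]]
  manual <- 0
  for (i in seq_len(nrow(a$true_hourly))) {
    row <- a$true_hourly[i, ]
    cell <- locate_cell(row$x, row$y, w$grid)
    col <- which(w$field$true_surface$hours$day == row$day &
                   w$field$true_surface$hours$hour == row$hour)
    manual <- manual + w$field$true_surface$values[cell, col]
  }
  expect_equal(true_exposure(a, w), manual)
})
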