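feat_row <- function(trajs) mobility_features(trajs)

test_that("training-set size matches the brute-force enumerator", {
  tr <- make_traj(t = (0:4) * 3600, x = 0:4 * 100, y = rep(0, 5))
  f <- feat_row(list(u1 = tr))
  ex <- build_training_set(list(tr), f, resample_intervals_s = 3600)
  expect_equal(nrow(ex), 3)
  expect_equal(ex$x_target, c(100, 200, 300))
  expect_true(all(ex$t_prev < ex$t_target & ex$t_target < ex$t_next))

  # two records cannot form a triple
  tr2 <- make_traj(t = c(0, 3600), x = c(0, 1), y = c(0, 0))
  expect_error(build_training_set(list(tr2), feat_row(list(u1 = tr2)),
                                  3600), ">= 3")

  # pooling two users tags each example with its user's features
  trb <- make_traj(user = "u2", t = (0:2) * 3600, x = c(0, 50, 500),
                   y = c(0, 0, 0))
  fs <- feat_row(list(u1 = tr, u2 = trb))
  ex2 <- build_training_set(list(tr, trb), fs, 3600)
  expect_equal(sum(ex2$user_id == "u2"), 1)
  expect_false(ex2$rog_m[ex2$user_id == "u2"][1] ==
                 ex2$rog_m[ex2$user_id == "u1"][1])

  # brute-force count over random sparse trajectories and all intervals
  set.seed(21)
  ivs <- c(1800, 3600, 7200, 10800)
  for (k in 1:8) {
    n <- sample(3:30, 1)
    tr3 <- make_traj(t = sort(sample(0:86399, n)),
                     x = rnorm(n), y = rnorm(n))
    f3 <- feat_row(list(u1 = tr3))
    got <- tryCatch(nrow(build_training_set(list(tr3), f3, ivs)),
                    error = function(e) 0L)
    expect_equal(got, count_examples_brute(list(tr3), ivs))
  }
})

test_that("gbdt fit is deterministic and learns constants", {
  set.seed(2)
  n <- 60
  ex <- data.frame(x_prev = runif(n), y_prev = runif(n),
                   t_prev = 1:n, t_target = 1:n + 1,
                   x_next = runif(n), y_next = runif(n),
                   t_next = 1:n + 2, rog_m = 1, entropy_bits = 1,
                   x_target = 42, y_target = -7, user_id = "u")
  m <- fit_gbdt(ex, nrounds = 50, seed = 5)
  p <- predict_gbdt(m, ex[1:5, ])
  expect_equal(unname(p[, 1]), rep(42, 5), tolerance = 1e-6)
  expect_equal(unname(p[, 2]), rep(-7, 5), tolerance = 1e-6)

  m2 <- fit_gbdt(ex, nrounds = 50, seed = 5)
  expect_identical(predict_gbdt(m, ex), predict_gbdt(m2, ex))

  # persist -> reload -> identical predictions
  p5 <- tempfile(fileext = ".rds")
  save_gbdt(m, p5)
  m3 <- load_gbdt(p5)
  expect_identical(predict_gbdt(m, ex), predict_gbdt(m3, ex))
  expect_equal(m3$hyperparams, m$hyperparams)

  expect_error(fit_gbdt(ex[1:3, ], min_train_examples = 10,
                        cluster_id = 9), "cluster 9")
})

test_that("gbdt beats the centroid predictor on linear motion", {
  set.seed(4)
  # one user moving linearly, triples at varying spacing
  t <- seq(0, 86400 * 2, by = 1800)
  tr <- make_traj(day = t %/% 86400 + 1, t = t %% 86400,
                  x = t * 0.05, y = t * -0.02)
  f <- feat_row(list(u1 = tr))
  ex <- build_training_set(list(tr), f, c(3600, 7200))
  m <- fit_gbdt(ex, seed = 1)
  pred <- predict_gbdt(m, ex)
  mae_model <- mean(sqrt((pred[, 1] - ex$x_target)^2 +
                           (pred[, 2] - ex$y_target)^2))
  mae_centroid <- mean(sqrt((mean(ex$x_target) - ex$x_target)^2 +
                              (mean(ex$y_target) - ex$y_target)^2))
  expect_lt(mae_model, mae_centroid)
})

test_that("hourly reconstruction passes observed hours through", {
  # all 24 hours observed -> identity, no model needed
  tr <- make_traj(t = 0:23 * 3600, x = 0:23, y = 23:0)
  out <- reconstruct_hourly(tr, model = NULL,
                            features = feat_row(list(u1 = tr)), days = 1)
  expect_equal(nrow(out), 24)
  expect_true(all(out$provenance == "observed"))
  expect_equal(out$x, 0:23)

  # leading missing hours take the first observed location
  tr2 <- make_traj(t = c(6, 7) * 3600, x = c(10, 20), y = c(1, 2))
  out2 <- reconstruct_hourly(tr2, NULL, feat_row(list(u1 = tr2)), 1)
  expect_equal(out2$x[1:6], rep(10, 6))
  expect_equal(out2$provenance[1:6], rep("reconstructed", 6))
  expect_equal(out2$x[24], 20)

  # stationary user: interior gap reconstructed at the stationary point
  tr3 <- make_traj(t = c(1, 2, 20, 21) * 3600, x = rep(5, 4),
                   y = rep(5, 4))
  f3 <- feat_row(list(u1 = tr3))
  ex3 <- build_training_set(list(tr3), f3, c(3600, 7200))
  m3 <- fit_gbdt(ex3, nrounds = 50, min_train_examples = 2, seed = 1)
  out3 <- reconstruct_hourly(tr3, m3, f3, 1)
  expect_equal(out3$x[out3$hour == 10], 5, tolerance = 1e-3)

  # single-record fallback: every hour at that record
  tr4 <- make_traj(t = 12 * 3600, x = 9, y = 9)
  out4 <- reconstruct_hourly(tr4, NULL, NULL, 1)
  expect_equal(nrow(out4), 24)
  expect_true(all(out4$x == 9))
})

test_that("interpolation baselines follow their definitions", {
  tr <- make_traj(t = c(0, 100), x = c(0, 100), y = c(0, 0))
  expect_equal(baseline_nearest(tr, 49)[1, "x"], c(x = 0))
  expect_equal(baseline_nearest(tr, 51)[1, "x"], c(x = 100))
  expect_equal(baseline_nearest(tr, 50)[1, "x"], c(x = 0))  # tie: earlier
  expect_equal(baseline_linear(tr, 50)[1, "x"], c(x = 50))
  expect_equal(baseline_linear(tr, -10)[1, "x"], c(x = 0))  # clamped
  expect_equal(baseline_linear(tr, 500)[1, "x"], c(x = 100))
  expect_error(baseline_nearest(tr[0, ], 1), "empty")
  expect_error(baseline_linear(tr[1, ], 1), ">= 2")
})

test_that("holdout evaluation scores methods on the identical held set", {
  set.seed(6)
  # user who never moves: nearest is exact
  n <- 40
  ev <- sample(c("sms", "regular_update"), n, TRUE)
  tr <- make_traj(t = sort(sample(0:86399, n)), x = rep(1, n),
                  y = rep(2, n), event = ev)
  rep1 <- evaluate_holdout(list(u1 = tr),
                           holdout = list(mode = "event_type"),
                           methods = c("nearest", "linear"))
  expect_equal(rep1$mae_m, c(0, 0))
  expect_equal(unique(rep1$n_heldout), sum(ev != "sms"))

  # MAE/StDev recompute from the stored per-point errors
  w <- small_world(n_agents = 12)
  as <- lapply(w$trajs, function(t2)
    project_anchors_to_zones(detect_anchors(t2), w$zones))
  cl <- cluster_users(anchor_similarity_matrix(as), k = 2)
  rep2 <- evaluate_holdout(w$trajs, cluster_labels = cl$labels,
                           holdout = list(mode = "event_type"),
                           gbdt_args = list(nrounds = 60))
  errs <- attr(rep2, "errors")
  for (m in rep2$method) {
    expect_equal(rep2$mae_m[rep2$method == m], mean(errs[[m]]))
    expect_equal(rep2$sd_m[rep2$method == m], sd(errs[[m]]))
  }

  # random-fraction holdout is seeded and reproducible
  rep3 <- evaluate_holdout(list(u1 = tr),
                           holdout = list(mode = "fraction", frac = 0.5,
                                          seed = 99),
                           methods = "nearest")
  rep4 <- evaluate_holdout(list(u1 = tr),
                           holdout = list(mode = "fraction", frac = 0.5,
                                          seed = 99),
                           methods = "nearest")
  expect_identical(rep3$n_heldout, rep4$n_heldout)
})
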