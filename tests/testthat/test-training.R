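test_that("paired scans subsample the high-quality angles exactly", {
  scan <- tiny_scan()
  expect_identical(dim(scan$p_lq$data)[1], 8L)
  expect_identical(dim(scan$p_hq$data)[1], 16L)
  # LQ angle i coincides with HQ angle i * factor
  expect_equal(scan$p_lq$angles, scan$p_hq$angles[seq(1, 16, by = 2)])
})

test_that("build_pairs produces the prescribed pairs per stage", {
  scan <- tiny_scan()
  p1 <- build_pairs(scan, 1L)
  expect_length(p1$inputs, 8L)   # one pair per LQ projection
  # targets taken at matching HQ indices 0, factor, 2*factor, ...
  for (a in c(1L, 5L)) {
    expect_equal(p1$targets[[a]], scan$p_hq$data[(a - 1L) * 2L + 1L, , ])
    expect_equal(p1$inputs[[a]][, , 1], scan$p_lq$data[a, , ])
  }
  expect_error(build_pairs(scan, 2L), "stage-1 model")

  models <- list(f_p = identity_stage_model(1L))
  p2 <- build_pairs(scan, 2L, models)
  expect_length(p2$inputs, dim(scan$p_lq$data)[2])  # one pair per row
  expect_identical(dim(p2$inputs[[1]])[3], 2L)
  # stage-2 target is the HQ sinogram row, elementwise
  s_hq <- rearrange(scan$p_hq)
  expect_equal(p2$targets[[3]], s_hq$data[3, , ])
  expect_error(build_pairs(scan, 3L, models), "stage-2")

  models$f_s <- identity_stage_model(2L)
  p3 <- build_pairs(scan, 3L, models)
  expect_length(p3$inputs, dim(scan$r_hq)[1])       # one pair per slice
  expect_identical(dim(p3$inputs[[1]])[3], 3L)
  expect_equal(p3$targets[[2]], scan$r_hq[2, , ])
})

test_that("training overfits the identity mapping on identical pairs", {
  set.seed(3)
  img <- matrix(runif(16 * 16), 16, 16)
  pairs <- list(inputs = rep(list(array(img, dim = c(16, 16, 1))), 4),
                targets = rep(list(img), 4), stage = 1L)
  cfg <- training_config(epochs = c(600L, 1L, 1L), learning_rate = 5e-3,
                         val_fraction = 0.25, seed = 2L)
  model <- train_stage(pairs, msd_spec(1L, 5L), cfg, stage = 1L)
  expect_lt(tail(model$history$train, 1), 1e-4)
})

test_that("early stopping halts within patience of the best epoch", {
  set.seed(4)
  pairs <- list(inputs = lapply(1:6, function(i)
                  array(runif(12 * 12), dim = c(12, 12, 1))),
                targets = lapply(1:6, function(i) matrix(runif(12 * 12), 12, 12)),
                stage = 1L)
  cfg <- training_config(epochs = c(300L, 1L, 1L), early_stop_patience = 5L,
                         seed = 9L)
  model <- train_stage(pairs, msd_spec(1L, 2L), cfg, stage = 1L)
  h <- model$history
  expect_lte(h$epochs_run, 300L)
  expect_lte(h$epochs_run - which.min(h$val), cfg$early_stop_patience)
  expect_equal(h$best_val, min(h$val))
})

test_that("training is deterministic given the seed", {
  set.seed(5)
  pairs <- list(inputs = lapply(1:4, function(i)
                  array(runif(10 * 10), dim = c(10, 10, 1))),
                targets = lapply(1:4, function(i) matrix(runif(100), 10, 10)),
                stage = 1L)
  cfg <- training_config(epochs = c(8L, 1L, 1L), seed = 17L)
  m1 <- train_stage(pairs, msd_spec(1L, 3L), cfg, stage = 1L)
  m2 <- train_stage(pairs, msd_spec(1L, 3L), cfg, stage = 1L)
  expect_identical(tail(m1$history$val, 1), tail(m2$history$val, 1))
  expect_identical(m1$params, m2$params)
})

test_that("degenerate training inputs raise errors", {
  pairs <- list(inputs = list(array(0, dim = c(8, 8, 1))),
                targets = list(matrix(0, 8, 8)), stage = 1L)
  expect_error(train_stage(pairs, msd_spec(1L, 2L)), "at least 2")
  expect_error(training_config(val_fraction = 1.2), "val_fraction")
  expect_error(training_config(learning_rate = 0), "learning_rate")
})

test_that("train_all runs stages strictly in order and freezes them", {
  scan <- tiny_scan()
  cfg <- training_config(epochs = c(2L, 2L, 2L), seed = 21L)
  specs <- lapply(c(1L, 2L, 3L), function(c) msd_spec(c, depth = 2L))
  models <- train_all(scan, specs, cfg)
  log <- attr(models, "log")
  expect_identical(log, c("build_pairs stage 1", "train stage 1",
                          "freeze stage 1", "build_pairs stage 2",
                          "train stage 2", "freeze stage 2",
                          "build_pairs stage 3", "train stage 3",
                          "freeze stage 3"))
  # returned parameter counts match the specs
  expect_identical(length(models$f_p$params), msd_count_params(specs[[1]]))
  expect_identical(length(models$f_s$params), msd_count_params(specs[[2]]))
  expect_identical(length(models$f_r$params), msd_count_params(specs[[3]]))
  # stage 1 is untouched by later training: training it alone with the
  # same seed gives identical parameters
  alone <- train_stage(build_pairs(scan, 1L), specs[[1]], cfg, stage = 1L)
  expect_identical(models$f_p$params, alone$params)
})
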