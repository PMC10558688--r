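sample_trials <- function(n, metric_fn, seed = 1) {
  set.seed(seed)
  space <- config_space()
  lapply(seq_len(n), function(i) {
    cfg <- sample_config(space)
    m <- metric_fn(cfg)
    structure(list(id = i, config = cfg,
                   meta_losses = c(task = 1 - m), total_meta_loss = 1 - m,
                   status = "ok", dev_metrics = c(task = m),
                   used_images = TRUE),
              class = "fiber_trial")
  })
}

test_that("the surrogate recovers a step function of one decision", {
  trials <- sample_trials(120, function(cfg) 0.6 + 0.3 * (cfg$capacity >= 4))
  sur <- fit_surrogate(trials, "task", seed = 1)
  expect_gt(sur$oob_r2, 0.9)
  # determinism given a seed
  sur2 <- fit_surrogate(trials, "task", seed = 1)
  expect_identical(predict(sur$forest, sur$data)$predictions,
                   predict(sur2$forest, sur2$data)$predictions)
  expect_error(fit_surrogate(trials[1:10], "task"), "at least")
})

test_that("constant performance yields near-zero attributions", {
  trials <- sample_trials(60, function(cfg) 0.75)
  sur <- fit_surrogate(trials, "task", seed = 2)
  att <- config_shapley(sur, explain_rows = 1:10, method = "permutation",
                        n_perm = 8, seed = 1)
  expect_lt(max(att$mean_abs), 1e-9)
})

test_that("Shapley values match exact enumeration on an additive surrogate", {
  set.seed(33)
  df <- data.frame(g1 = sample(1:4, 40, replace = TRUE),
                   g2 = runif(40))
  g1_fn <- function(v) c(0.1, 0.5, 0.2, 0.9)[v]
  g2_fn <- function(v) 2 * v
  sur <- surrogate_from_function(function(nd) g1_fn(nd$g1) + g2_fn(nd$g2), df)
  att <- config_shapley(sur, explain_rows = 1:10, background = df,
                        method = "exact")
  # closed form for an additive function under interventional Shapley:
  # phi_j(x) = g_j(x_j) - mean(g_j over the background)
  for (ri in 1:10) {
    expect_equal(unname(att$values[ri, "g1"]),
                 g1_fn(df$g1[ri]) - mean(g1_fn(df$g1)), tolerance = 1e-10)
    expect_equal(unname(att$values[ri, "g2"]),
                 g2_fn(df$g2[ri]) - mean(g2_fn(df$g2)), tolerance = 1e-10)
  }
  # additivity: values sum to prediction minus baseline
  expect_equal(rowSums(att$values),
               att$predictions - att$baseline, tolerance = 1e-10)
  # symmetry: duplicated dimensions share credit equally
  df2 <- data.frame(a = df$g2, b = df$g2)
  sur2 <- surrogate_from_function(function(nd) nd$a + nd$b, df2)
  att2 <- config_shapley(sur2, explain_rows = 1:10, background = df2,
                         method = "exact")
  expect_equal(att2$values[, "a"], att2$values[, "b"], tolerance = 1e-10)
  # permutation sampling agrees with enumeration up to Monte-Carlo error
  attp <- config_shapley(sur, explain_rows = 1:5, background = df,
                         method = "permutation", n_perm = 64, seed = 2)
  expect_lt(max(abs(attp$values[1:5, ] - att$values[1:5, ])), 0.05)
})

test_that("sample attribution is exact on a linear stub and zero at baseline", {
  model <- linear_stub()
  set.seed(34)
  x <- array(rnorm(16), c(4, 4, 1))
  p <- c(0.7, -0.3)
  sa <- sample_attribution(model, x, p, steps = 1)
  # output = 2 * mean(x) + 0.5 p1 - 1.5 p2; each voxel gets c * x / 16
  expect_equal(sa$image, 2 * x / 16, tolerance = 1e-10)
  expect_equal(unname(sa$priors), c(0.5, -1.5) * p, tolerance = 1e-10)
  expect_lt(abs(sa$additivity_gap), 1e-10)
  # baseline equal to the sample: all attributions vanish
  sa0 <- sample_attribution(model, x, p, baseline_x = x, baseline_priors = p)
  expect_equal(max(abs(sa0$image)), 0)
  expect_equal(max(abs(sa0$priors)), 0)
})

test_that("attribution is additive on a trained nonlinear model", {
  tc <- tiny_cohort()
  cfg <- trial_configuration(representation = "2.5D_1",
                             prior_integration = "Branches", capacity = 1,
                             optimizer = "adam", lr = 3e-3, batch_size = 8)
  data <- prepare_training_data(tc$cohort, tc$split, tc$priors, cfg,
                                tc$task_types)
  st <- train_trial(data, cfg, budget = 10, seed = 2)
  gap_ok <- 0
  for (i in which(data$sets == "dev")[1:4]) {
    sa <- sample_attribution(st$model, data$x[[i]], data$priors[i, ],
                             task_index = 1, steps = 64)
    rel <- abs(sa$additivity_gap) /
      max(abs(sa$output - sa$baseline_output), 1e-6)
    if (rel < 0.05) gap_ok <- gap_ok + 1
  }
  expect_gte(gap_ok, 3)
  # NoPriors model: empty prior attribution block
  cfg2 <- trial_configuration(representation = "2.5D_1", capacity = 1)
  data2 <- prepare_training_data(tc$cohort, tc$split, tc$priors, cfg2,
                                 tc$task_types)
  st2 <- train_trial(data2, cfg2, budget = 2, seed = 1)
  sa2 <- sample_attribution(st2$model, data2$x[[1]], data2$priors[1, ],
                            steps = 4)
  expect_equal(length(sa2$priors), 0)
})

test_that("attribution mass concentrates on a localized discriminative region", {
  # model whose first conv filter reads one small region only
  cfg <- trial_configuration(representation = "2.5D_1", capacity = 1)
  model <- build_model(cfg, 1, 5, input_shape = c(24, 20, 3), seed = 3)
  for (nm in names(model$params))
    model$params[[nm]] <- model$params[[nm]] * 0
  # a localized detector: positive weights feeding channel 1 from channel 1
  model$params$conv1_W[2, 2, 1, 1] <- 1
  model$params$conv2_W[2, 2, 1, 1] <- 1
  model$params$fc1_W[1, 1] <- 1
  model$params$out_W[1, 1] <- 1
  set.seed(35)
  x <- array(rnorm(24 * 20 * 3, 0, 0.05), c(24, 20, 3))
  x[9:11, 9:11, 1] <- 3  # the defect the model keys on
  sa <- sample_attribution(model, x, rep(0, 5), steps = 8)
  a <- abs(sa$image)
  top <- which(a >= 0.5 * max(a), arr.ind = TRUE)
  # the dominant attribution mass lies within a few voxels of the planted
  # region (5 um at this spacing)
  expect_true(all(top[, 1] >= 5 & top[, 1] <= 15))
  expect_true(all(top[, 2] >= 5 & top[, 2] <= 15))
  expect_gt(sum(a[5:15, 5:15, ]) / sum(a), 0.5)
})

test_that("random erasing hurts a task carried by one localized feature", {
  # cohort of images whose label is a single bright localized blob
  set.seed(36)
  n <- 32
  imgs <- vector("list", n)
  y <- rep(c(0, 1), length.out = n)
  for (i in seq_len(n)) {
    v <- array(rnorm(16 * 24 * 20, 0, 0.3), c(16, 24, 20))
    if (y[i] == 1) v[7:9, 11:14, 9:12] <- v[7:9, 11:14, 9:12] + 3
    imgs[[i]] <- fiber_image(v, rep(0.5, 3), sample_id = sprintf("S%03d", i),
                             mask = array(TRUE, c(16, 24, 20)))
  }
  man <- data.frame(sample_id = sprintf("S%03d", 1:n), image_path = NA,
                    group_id = sprintf("G%03d", 1:n), study_id = "A",
                    blob = y)
  coh <- structure(list(manifest = man, images = imgs), class = "fiber_cohort")
  split <- data.frame(sample_id = man$sample_id, group_id = man$group_id,
                      set = rep(c("train", "train", "dev", "train"),
                                length.out = n))
  ptab <- data.frame(sample_id = man$sample_id,
                     matrix(0, n, 5, dimnames = list(NULL, prior_names())))
  for (nm in prior_names()) ptab[[paste0(nm, "_available")]] <- FALSE
  tt <- c(blob = "binary")
  wins <- 0
  for (s in 1:5) {
    res <- lapply(c(FALSE, TRUE), function(erase) {
      cfg <- trial_configuration(representation = "2.5D_1", capacity = 1,
                                 optimizer = "adam", lr = 3e-3,
                                 batch_size = 8, random_erasing = erase)
      data <- prepare_training_data(coh, split, ptab, cfg, tt)
      st <- train_trial(data, cfg, budget = 12, seed = 400 + s)
      min(st$meta_history[, "blob"], na.rm = TRUE)
    })
    if (res[[2]] >= res[[1]]) wins <- wins + 1
  }
  expect_gte(wins, 3)
})
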