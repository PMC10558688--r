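test_that("slice representations use the stated offsets and 3D downsampling", {
  arr <- array(rnorm(100 * 20 * 16), c(100, 20, 16))
  img <- fiber_image(arr, rep(0.5, 3))
  r20 <- build_representation(img, trial_configuration(representation = "2.5D_20"),
                              clamp = FALSE)
  expect_equal(attr(r20, "slice_indices"), c(10, 50, 90))
  expect_equal(dim(r20), c(20, 16, 3))
  expect_equal(r20[, , 1], arr[10, , ])
  r1 <- build_representation(img, trial_configuration(representation = "2.5D_1"))
  expect_equal(attr(r1, "slice_indices"), c(48, 50, 52))
  thin <- fiber_image(array(0, c(30, 16, 16)), rep(0.5, 3))
  expect_error(build_representation(
    thin, trial_configuration(representation = "2.5D_20"), clamp = FALSE),
    "too thin")
  big <- fiber_image(array(rnorm(100^3), c(100, 100, 100)), rep(0.5, 3))
  r3d <- build_representation(big, trial_configuration(representation = "3D",
                                                       downsample = TRUE))
  expect_equal(dim(r3d), c(67, 67, 67, 1))
})

test_that("augmentation is seeded, bounded, and a no-op when disabled", {
  x <- array(1, c(24, 20, 3))
  off <- trial_configuration(augment = FALSE, random_erasing = FALSE)
  expect_identical(augment(x, off, seed = 1), x)
  on <- trial_configuration(augment = TRUE, random_erasing = TRUE)
  a1 <- augment(x, on, seed = 5)
  a2 <- augment(x, on, seed = 5)
  expect_identical(a1, a2)
  expect_false(identical(a1, augment(x, on, seed = 6)))
  # erased fraction: 1-3 boxes of 2-10% each -> within [0.02, 0.30]
  er <- trial_configuration(random_erasing = TRUE)
  for (s in 1:20) {
    fr <- mean(augment(x, er, seed = s) == 0)
    expect_gte(fr, 0.015); expect_lte(fr, 0.31)
  }
})

test_that("model heads follow the prior-integration level", {
  m0 <- build_model(trial_configuration(prior_integration = "NoPriors"),
                    n_tasks = 3, n_priors = 5, input_shape = c(16, 12, 3))
  expect_equal(m0$n_out, 3)
  expect_false(m0$use_branch)
  mb <- build_model(trial_configuration(prior_integration = "AuxLosses@Branches"),
                    n_tasks = 3, n_priors = 5, input_shape = c(16, 12, 3))
  expect_equal(mb$n_out, 8)
  expect_true(mb$use_branch)
  m_aux <- build_model(trial_configuration(prior_integration = "AuxLosses"),
                       n_tasks = 3, n_priors = 5, input_shape = c(16, 12, 3))
  # branch widening: final fully connected input gains n_priors columns
  expect_equal(nrow(mb$params$fc1_W), nrow(m_aux$params$fc1_W) + 5)
  expect_error(build_model(trial_configuration(prior_integration = "PriorsOnly"),
                           3, 5, c(16, 12, 3)), "PriorsOnly")
  # strict capacity ordering by parameter count
  np <- vapply(1:6, function(k)
    n_parameters(build_model(trial_configuration(capacity = k), 3, 5,
                             c(16, 12, 3))), 1)
  expect_true(all(diff(np) > 0))
})

test_that("compiled convolutions match the plain-R reference implementation", {
  set.seed(21)
  X <- array(rnorm(3 * 9 * 11 * 4), c(3, 9, 11, 4))
  W <- array(rnorm(3 * 3 * 4 * 6), c(3, 3, 4, 6)); b <- rnorm(6)
  expect_equal(fiberprior:::conv2_fw(X, W, b),
               fiberprior:::conv2_fw_ref(X, W, b), tolerance = 1e-12)
  dY <- array(rnorm(3 * 9 * 11 * 6), c(3, 9, 11, 6))
  bw <- fiberprior:::conv2_bw(X, W, dY)
  bw_ref <- fiberprior:::conv2_bw_ref(X, W, dY)
  expect_equal(bw$dX, bw_ref$dX, tolerance = 1e-12)
  expect_equal(bw$dW, bw_ref$dW, tolerance = 1e-12)
  X3 <- array(rnorm(2 * 5 * 7 * 6 * 3), c(2, 5, 7, 6, 3))
  W3 <- array(rnorm(27 * 3 * 4), c(3, 3, 3, 3, 4)); b3 <- rnorm(4)
  expect_equal(fiberprior:::conv3_fw(X3, W3, b3),
               fiberprior:::conv3_fw_ref(X3, W3, b3), tolerance = 1e-12)
  dY3 <- array(rnorm(2 * 5 * 7 * 6 * 4), c(2, 5, 7, 6, 4))
  bw3 <- fiberprior:::conv3_bw(X3, W3, dY3)
  bw3_ref <- fiberprior:::conv3_bw_ref(X3, W3, dY3)
  expect_equal(bw3$dX, bw3_ref$dX, tolerance = 1e-12)
  expect_equal(bw3$dW, bw3_ref$dW, tolerance = 1e-12)
})

test_that("the uncertainty-weighted loss honours its algebra and masking", {
  set.seed(22)
  pred <- matrix(rnorm(12), 4, 3)
  targ <- matrix(c(rbinom(4, 1, 0.5), rnorm(8)), 4, 3)
  mask <- matrix(TRUE, 4, 3)
  types <- c("binary", "continuous", "continuous")
  # sigma = 1 everywhere: the plain sum of base losses
  ls <- masked_uncertainty_loss(pred, targ, mask, rep(0, 3), types)
  expect_equal(ls$loss, sum(ls$base_losses), tolerance = 1e-12)
  # worked single-term value: L = 2 at sigma = sqrt(2)
  ls2 <- masked_uncertainty_loss(matrix(0), matrix(sqrt(2)), matrix(TRUE),
                                 log(sqrt(2)), "continuous")
  expect_equal(ls2$loss, 1 + log(sqrt(2)), tolerance = 1e-12)
  expect_equal(ls2$loss, 1.3466, tolerance = 1e-4)
  # masked entries contribute zero value and zero gradient
  mask3 <- mask; mask3[, 2] <- FALSE; mask3[1, 1] <- FALSE
  ls3 <- masked_uncertainty_loss(pred, targ, mask3, rep(0, 3), types)
  expect_true(all(ls3$dpred[!mask3] == 0))
  expect_equal(ls3$dlog_sigma[2], 0)
  expect_true(is.na(ls3$base_losses[2]))
  # and exactly zero parameter gradient for a fully masked head
  model <- build_model(trial_configuration(), 3, 5, c(12, 10, 3), seed = 1)
  X <- array(rnorm(4 * 12 * 10 * 3), c(4, 12, 10, 3))
  fw <- nn_forward(model, X, keep_cache = TRUE)
  lsm <- masked_uncertainty_loss(fw$out, targ, mask3,
                                 model$params$log_sigma, types)
  bw <- nn_backward(model, fw$cache, lsm$dpred)
  expect_true(all(bw$grads$out_W[, 2] == 0))
  expect_equal(bw$grads$out_b[2], 0)
})

test_that("the early-stopping rule matches an independent simulation", {
  # never-improving series: exactly warmup + patience epochs
  expect_equal(early_stop_epoch(rep(1, 500))$stop_epoch, 125)
  # strictly decreasing series never triggers
  expect_true(is.na(early_stop_epoch(seq(1, 0.5, length.out = 200))$stop_epoch))
  # oracle: direct scalar simulation of the MA-10 / patience-50 rule
  sim_rule <- function(series, warmup = 75, patience = 50, window = 10) {
    best <- Inf; best_at <- 0
    for (e in seq_along(series)) {
      sm <- mean(series[max(1, e - window + 1):e])
      if (sm < best) { best <- sm; best_at <- e }
      if (e - max(best_at, warmup) >= patience) return(e)
    }
    NA_integer_
  }
  set.seed(23)
  for (r in 1:20) {
    series <- c(seq(2, 1, length.out = sample(50:150, 1)),
                rep(1, 200)) + rnorm(1, 0, 0)  # decreasing then flat
    expect_equal(early_stop_epoch(series)$stop_epoch, sim_rule(series))
    noisy <- cumsum(rnorm(260, -0.01, 0.2))
    expect_equal(early_stop_epoch(noisy)$stop_epoch, sim_rule(noisy))
  }
})

test_that("metrics match pairwise counting and variance identities", {
  expect_equal(auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_true(is.na(auc_score(c(0.1, 0.2), c(1, 1))))
  expect_equal(r2_score(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r2_score(rep(2, 3), c(1, 2, 3)), 0)
  sc <- cbind(a = c(0.1, 0.4, 0.35, 0.8), b = rep(1, 4))
  lb <- cbind(a = c(0, 0, 1, 1), b = c(NA, NA, NA, 1))
  expect_warning(m <- evaluate_metrics(sc, lb, c(a = "binary", b = "continuous")))
  expect_equal(unname(m["a"]), 0.75)
  expect_true(is.na(m["b"]))
})

test_that("a small model overfits a clean prior-driven cohort", {
  tc <- tiny_cohort()
  cfg <- trial_configuration(representation = "2.5D_1",
                             prior_integration = "Branches", capacity = 1,
                             optimizer = "adam", lr = 3e-3, batch_size = 8)
  data <- prepare_training_data(tc$cohort, tc$split, tc$priors, cfg,
                                tc$task_types)
  st <- train_trial(data, cfg, budget = 40, seed = 1)
  tr <- which(data$sets == "train")
  m <- suppressWarnings(evaluate_metrics(
    predict_tasks(st, data, tr), data$labels[tr, , drop = FALSE],
    tc$task_types))
  expect_gt(m[["dystrophic"]], 0.9)
  expect_equal(st$epochs_run, 40)
  # determinism on CPU: identical loss trajectory for identical seeds
  st2 <- train_trial(data, cfg, budget = 5, seed = 9)
  st3 <- train_trial(data, cfg, budget = 5, seed = 9)
  expect_identical(st2$total_history, st3$total_history)
})

test_that("learned sigmas order themselves by task noise", {
  tc <- tiny_cohort()
  # two continuous tasks with identical structure but very different noise
  man <- tc$cohort$manifest
  truth <- tc$cohort$truth
  votes <- 0
  for (s in 1:5) {
    set.seed(300 + s)
    coh <- tc$cohort
    coh$manifest$clean <- truth$cas * 5 + rnorm(nrow(man), 0, 0.05)
    coh$manifest$noisy <- truth$cas * 5 + rnorm(nrow(man), 0, 2.5)
    tt <- c(clean = "continuous", noisy = "continuous")
    cfg <- trial_configuration(representation = "2.5D_1", capacity = 1,
                               optimizer = "adam", lr = 3e-3, batch_size = 8)
    data <- prepare_training_data(coh, tc$split, tc$priors, cfg, tt)
    st <- train_trial(data, cfg, budget = 15, seed = s)
    ls <- st$model$params$log_sigma
    if (ls[2] > ls[1]) votes <- votes + 1
  }
  expect_gte(votes, 3)
})
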