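# independent brute-force oracle for dominance fronts: peel off the set of
# points not dominated by any remaining point
brute_fronts <- function(obj) {
  n <- nrow(obj)
  front <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  f <- 1L
  while (length(remaining)) {
    nd <- vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        j != i && all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ])
      }, TRUE))
    }, TRUE)
    front[remaining[nd]] <- f
    remaining <- remaining[!nd]
    f <- f + 1L
  }
  front
}

test_that("non-dominated sorting matches the brute-force oracle", {
  obj <- rbind(c(1, 2), c(2, 1), c(3, 3))
  expect_equal(nondominated_sort(obj), c(1L, 1L, 2L))
  set.seed(31)
  for (r in 1:100) {
    o <- matrix(runif(50 * sample(2:3, 1)), nrow = 50)
    expect_identical(nondominated_sort(o), brute_fronts(o))
  }
})

test_that("crowding distances mark boundary solutions infinite", {
  o <- cbind(c(0, 0.3, 0.6, 1), c(1, 0.7, 0.2, 0))
  d <- crowding_distance(o)
  expect_true(is.infinite(d[1]) && is.infinite(d[4]))
  expect_true(all(is.finite(d[2:3])))
  expect_true(all(is.infinite(crowding_distance(o[1:2, ]))))
})

test_that("NSGA-II offspring are reproducible and valid configurations", {
  space <- config_space()
  set.seed(1)
  configs <- replicate(10, sample_config(space), simplify = FALSE)
  obj <- matrix(runif(20), 10, 2)
  off1 <- nsga2_step(configs, obj, space, 10, seed = 42)
  off2 <- nsga2_step(configs, obj, space, 10, seed = 42)
  expect_identical(off1, off2)
  off3 <- nsga2_step(configs, obj, space, 10, seed = 43)
  expect_false(identical(off1, off3))
  for (c in off1) expect_s3_class(c, "trial_configuration")
  # empty population: uniform sampling
  init <- nsga2_step(list(), NULL, space, 5, seed = 1)
  expect_equal(length(init), 5)
})

test_that("generational search improves a conflicting two-objective toy front", {
  space <- config_space()
  # two conflicting synthetic objectives over the genes: small capacity is
  # good for task 1 and bad for task 2, modulated by learning rate
  eval_cfg <- function(cfg)
    c(cfg$capacity / 6 + 0.1 * abs(log10(cfg$lr) + 3),
      (6 - cfg$capacity) / 6 + 0.1 * (cfg$batch_size == 4))
  set.seed(2)
  pop <- replicate(12, sample_config(space), simplify = FALSE)
  obj <- t(vapply(pop, eval_cfg, numeric(2)))
  hv1 <- hypervolume2d(obj, ref = c(2, 2))
  for (g in 1:10) {
    off <- nsga2_step(pop, obj, space, 12, seed = g)
    oobj <- t(vapply(off, eval_cfg, numeric(2)))
    all_obj <- rbind(obj, oobj)
    keep <- fiberprior:::surviving_population(all_obj, 12)
    pop <- c(pop, off)[keep]
    obj <- all_obj[keep, , drop = FALSE]
  }
  hv10 <- hypervolume2d(obj, ref = c(2, 2))
  expect_gte(hv10, hv1)
  # front soundness after evolution
  expect_identical(nondominated_sort(obj), brute_fronts(obj))
})

make_feature_data <- function(n = 60, seed = 1, permute = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, prior_names()))
  y <- as.numeric(X[, 1] > median(X[, 1]))
  if (permute) y <- sample(y)
  groups <- sprintf("g%02d", rep(seq_len(n / 2), each = 2))
  list(x = NULL, priors = X,
       labels = matrix(y, ncol = 1, dimnames = list(NULL, "t")),
       mask = matrix(TRUE, n, 1, dimnames = list(NULL, "t")),
       task_types = c(t = "binary"), task_names = "t",
       sets = rep(c("train", "dev"), length.out = n), groups = groups)
}

test_that("the feature-only pipeline separates a separable task", {
  po <- priors_only_trial(make_feature_data(seed = 3), seed = 1)
  expect_gt(po$metrics[["t"]], 0.95)
  # bundles never straddle CV folds
  d <- make_feature_data(seed = 3)
  expect_true(all(tapply(po$fold, d$groups[d$sets %in% c("train", "dev")],
                         function(f) length(unique(f))) == 1))
})

test_that("permuted labels give chance-level feature-only performance", {
  aucs <- vapply(1:20, function(r)
    priors_only_trial(make_feature_data(seed = 100 + r, permute = TRUE),
                      seed = r)$metrics[["t"]], 1)
  expect_gt(mean(aucs, na.rm = TRUE), 0.35)
  expect_lt(mean(aucs, na.rm = TRUE), 0.65)
})

fake_trial <- function(id, losses, total = sum(losses), status = "ok") {
  structure(list(id = id, config = trial_configuration(),
                 meta_losses = losses, total_meta_loss = total,
                 status = status, dev_metrics = 1 - losses,
                 used_images = TRUE),
            class = "fiber_trial")
}

test_that("model selection follows the scarce-data rule with stable ties", {
  t1 <- fake_trial(1, c(A = 0.2, B = 0.10), total = 0.40)
  t2 <- fake_trial(2, c(A = 0.1, B = 0.35), total = 0.30)
  t3 <- fake_trial(3, c(A = 0.1, B = 0.30), total = 0.55)
  sel <- select_models(list(t1, t2, t3), c(A = 150, B = 40))
  # plentiful task: per-task argmin with earliest-trial tie break
  expect_equal(unname(sel["A"]), 2L)
  # scarce task: best total meta-loss wins although t1 has the best B loss
  expect_equal(unname(sel["B"]), 2L)
  sel2 <- select_models(list(t1, t2, t3), c(A = 150, B = 400))
  expect_equal(unname(sel2["B"]), 1L)
})

test_that("trial dispatch respects the integration level end to end", {
  tc <- tiny_cohort()
  po_cfg <- trial_configuration(prior_integration = "PriorsOnly")
  tr_po <- run_trial(po_cfg, tc$cohort, tc$split, tc$priors, tc$task_types,
                     budget = 3, seed = 1)
  expect_false(tr_po$used_images)
  expect_equal(tr_po$status, "ok")
  expect_true(is.finite(tr_po$total_meta_loss))
  # PriorsOnly never builds an image tensor
  dat <- prepare_training_data(tc$cohort, tc$split, tc$priors, po_cfg,
                               tc$task_types)
  expect_null(dat$x)
  np_cfg <- trial_configuration(prior_integration = "NoPriors",
                                representation = "2.5D_1", capacity = 1)
  tr_np <- run_trial(np_cfg, tc$cohort, tc$split, tc$priors, tc$task_types,
                     budget = 3, seed = 1)
  expect_equal(tr_np$status, "ok")
  expect_false(tr_np$state$model$use_branch)
  expect_false(tr_np$state$model$use_aux)
  expect_true(all(is.finite(
    tr_np$meta_losses[!is.na(tr_np$meta_losses)])))
})

test_that("the self-enhancement loop logs every decision per trial", {
  tc <- tiny_cohort()
  lb <- tempfile(fileext = ".jsonl")
  se <- run_self_enhancement(tc$cohort, tc$split, tc$priors, tc$task_types,
                             n_trials = 6, population = 6, seed = 42,
                             budget = 2, labbook = lb)
  entries <- labbook_read(lb)
  expect_equal(length(entries), 6)
  decisions <- c("contrast_enhancement", "downsample", "augment",
                 "random_erasing", "representation", "prior_integration",
                 "capacity", "optimizer", "batch_size", "gradient_clipping",
                 "imbalance_sampling", "lr")
  for (e in entries) expect_true(all(decisions %in% names(e)))
  expect_equal(length(se$trials), 6)
  # rerun with the same seed: identical configuration sequence
  se2 <- run_self_enhancement(tc$cohort, tc$split, tc$priors, tc$task_types,
                              n_trials = 6, population = 6, seed = 42,
                              budget = 2)
  expect_identical(lapply(se$trials, `[[`, "config"),
                   lapply(se2$trials, `[[`, "config"))
  # Pareto soundness: front-1 trials are not dominated by any trial
  expect_identical(nondominated_sort(se$objectives),
                   brute_fronts(se$objectives))
  # fallback: with fewer than k trials the top-k summary averages them all
  ok <- vapply(se$trials, function(t) t$status == "ok" &&
                 !is.na(t$dev_metrics[["dystrophic"]]), TRUE)
  expect_equal(se$summary_topk[["dystrophic"]],
               mean(vapply(se$trials[ok], function(t)
                 t$dev_metrics[["dystrophic"]], 1)))
})
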