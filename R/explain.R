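# Two-level explanations: (i) model level - a random-forest surrogate maps
# configurations to dev performance and Shapley values attribute each
# configuration decision; (ii) sample level - expected-gradients attribution
# jointly over image voxels and the prior branch of a trained network.

encode_configs <- function(configs) {
  rep_levels <- c("3D", "2.5D_1", "2.5D_5", "2.5D_10", "2.5D_20")
  int_levels <- c("NoPriors", "AuxLosses", "Branches", "AuxLosses@Branches",
                  "PriorsOnly")
  df <- data.frame(
    contrast_enhancement = vapply(configs, function(c) as.numeric(c$contrast_enhancement), 1),
    downsample = vapply(configs, function(c) as.numeric(c$downsample), 1),
    augment = vapply(configs, function(c) as.numeric(c$augment), 1),
    random_erasing = vapply(configs, function(c) as.numeric(c$random_erasing), 1),
    representation = factor(vapply(configs, function(c) c$representation, ""),
                            levels = rep_levels),
    prior_integration = factor(vapply(configs, function(c) c$prior_integration, ""),
                               levels = int_levels),
    capacity = vapply(configs, function(c) as.numeric(c$capacity), 1),
    optimizer = factor(vapply(configs, function(c) c$optimizer, ""),
                       levels = c("sgd", "adam")),
    log_lr = vapply(configs, function(c) log10(c$lr), 1),
    batch_size = vapply(configs, function(c) as.numeric(c$batch_size), 1),
    gradient_clipping = vapply(configs, function(c) as.numeric(c$gradient_clipping), 1),
    imbalance_sampling = vapply(configs, function(c) as.numeric(c$imbalance_sampling), 1))
  df
}

#' Fit a performance surrogate over configurations
#'
#' Random-forest regressor (500 trees by default) from encoded
#' configurations to the dev metric of one task, with out-of-bag R squared
#' reported. Ordered genes (capacity, slice distance via the representation
#' factor order, learning rate, batch size) are encoded ordinally; unordered
#' genes as factors.
#'
#' @param trials list of `fiber_trial`s (or a `self_enhancement` result).
#' @param task task name.
#' @param num_trees forest size.
#' @param seed integer seed.
#' @param min_trials minimum completed trials required (default 30).
#' @return list of class `config_surrogate`: `forest`, `data`, `oob_r2`.
#' @export
fit_surrogate <- function(trials, task, num_trees = 500, seed = 1,
                          min_trials = 30) {
  if (inherits(trials, "self_enhancement")) trials <- trials$trials
  ok <- vapply(trials, function(t) t$status == "ok" &&
                 !is.null(t$dev_metrics) && !is.na(t$dev_metrics[[task]] %||% NA), TRUE)
  if (sum(ok) < min_trials)
    stop(sprintf("need at least %d completed trials (got %d)", min_trials, sum(ok)))
  use <- trials[ok]
  df <- encode_configs(lapply(use, `[[`, "config"))
  y <- vapply(use, function(t) t$dev_metrics[[task]], 1)
  df$.y <- y
  forest <- ranger::ranger(.y ~ ., data = df, num.trees = num_trees,
                           seed = seed, oob.error = TRUE)
  oob_r2 <- forest$r.squared
  structure(list(forest = forest, data = df[, setdiff(names(df), ".y")],
                 y = y, task = task, seed = seed, oob_r2 = oob_r2),
            class = "config_surrogate")
}

surrogate_predict <- function(surrogate, newdata) {
  if (is.function(surrogate$forest)) return(surrogate$forest(newdata))
  predict(surrogate$forest, newdata)$predictions
}

#' Wrap an arbitrary prediction function as a configuration surrogate
#'
#' Mainly for validating the Shapley attribution against closed forms on
#' known (e.g. additive) functions.
#'
#' @param fn function taking a data.frame of configuration dimensions and
#'   returning numeric predictions.
#' @param data data.frame of configuration rows (background population).
#' @return a `config_surrogate`.
#' @export
surrogate_from_function <- function(fn, data) {
  structure(list(forest = fn, data = data, y = fn(data), task = "synthetic",
                 seed = NA, oob_r2 = NA),
            class = "config_surrogate")
}

# interventional value function: v(S) for explained row x, averaging model
# predictions with off-coalition features replaced by background rows
coalition_value <- function(surrogate, x, background, S) {
  nd <- background
  for (nm in S) nd[[nm]] <- rep(x[[nm]], nrow(background))
  mean(surrogate_predict(surrogate, nd))
}

#' Shapley attribution of configuration decisions
#'
#' Interventional Shapley values per configuration dimension, in units of
#' the task's performance metric. `method = "exact"` enumerates all
#' coalitions (feasible for small spaces and used to validate against the
#' closed form for additive surrogates); `"permutation"` uses seeded
#' permutation sampling. Additivity (values summing to prediction minus
#' baseline) holds exactly for both. A stability check refits the surrogate
#' with different seeds/ensemble sizes and reports the rank agreement of the
#' top dimensions.
#'
#' @param surrogate a [fit_surrogate()] result.
#' @param explain_rows rows of `surrogate$data` to explain (default all).
#' @param background background rows for the interventional expectation
#'   (default: up to 30 rows of the trial data).
#' @param method `"auto"`, `"exact"`, or `"permutation"`.
#' @param n_perm permutations per explained row.
#' @param seed integer seed.
#' @return list of class `config_attribution`: `values` (rows x dimensions),
#'   `mean_abs`, `ranking`, `baseline`, `predictions`.
#' @export
config_shapley <- function(surrogate, explain_rows = NULL, background = NULL,
                           method = c("auto", "exact", "permutation"),
                           n_perm = 32, seed = 1) {
  method <- match.arg(method)
  df <- surrogate$data
  if (is.null(explain_rows)) explain_rows <- seq_len(nrow(df))
  if (is.null(background)) {
    bi <- seq_len(nrow(df))
    if (length(bi) > 30) {
      set.seed(seed); bi <- sample(bi, 30)
    }
    background <- df[bi, , drop = FALSE]
  }
  dims <- colnames(df)
  d <- length(dims)
  if (method == "auto") method <- if (d <= 8) "exact" else "permutation"
  baseline <- mean(surrogate_predict(surrogate, background))
  vals <- matrix(0, length(explain_rows), d,
                 dimnames = list(NULL, dims))
  preds <- numeric(length(explain_rows))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (method == "exact") {
    subsets <- lapply(0:(2^d - 1), function(m) dims[bitwAnd(m, 2^(0:(d - 1))) > 0])
    key <- function(S) paste0(".", paste(sort(S), collapse = "|"))
    for (ri in seq_along(explain_rows)) {
      x <- df[explain_rows[ri], , drop = FALSE]
      v <- vapply(subsets, function(S) coalition_value(surrogate, x, background, S), 1)
      names(v) <- vapply(subsets, key, "")
      for (j in seq_len(d)) {
        phi <- 0
        for (si in seq_along(subsets)) {
          S <- subsets[[si]]
          if (dims[j] %in% S) next
          s <- length(S)
          w <- factorial(s) * factorial(d - s - 1) / factorial(d)
          phi <- phi + w * (v[[key(c(S, dims[j]))]] - v[[key(S)]])
        }
        vals[ri, j] <- phi
      }
      preds[ri] <- v[[key(dims)]]
    }
  } else {
    for (ri in seq_along(explain_rows)) {
      x <- df[explain_rows[ri], , drop = FALSE]
      acc <- setNames(rep(0, d), dims)
      for (p in seq_len(n_perm)) {
        perm <- sample(dims)
        prev <- baseline
        S <- character(0)
        for (nm in perm) {
          S <- c(S, nm)
          cur <- coalition_value(surrogate, x, background, S)
          acc[nm] <- acc[nm] + (cur - prev)
          prev <- cur
        }
      }
      vals[ri, ] <- acc / n_perm
      preds[ri] <- coalition_value(surrogate, x, background, dims)
    }
  }
  mean_abs <- colMeans(abs(vals))
  structure(list(values = vals, mean_abs = mean_abs,
                 ranking = names(sort(mean_abs, decreasing = TRUE)),
                 baseline = baseline, predictions = preds,
                 method = method),
            class = "config_attribution")
}

#' Stability of the configuration ranking across surrogate refits
#'
#' Refits the surrogate with several seeds and ensemble sizes and reports
#' how often each of the reference top dimensions stays in the top set.
#'
#' @param trials trials (as for [fit_surrogate()]).
#' @param task task name.
#' @param seeds seeds to refit with.
#' @param num_trees ensemble sizes to refit with.
#' @param top how many top dimensions to compare.
#' @return list with `rankings` and `top_overlap` (mean Jaccard overlap).
#' @export
shapley_stability <- function(trials, task, seeds = 1:3,
                              num_trees = c(300, 500), top = 3) {
  rankings <- list()
  for (s in seeds) for (nt in num_trees) {
    sur <- fit_surrogate(trials, task, num_trees = nt, seed = s)
    att <- config_shapley(sur, method = "permutation", n_perm = 16, seed = s)
    rankings[[length(rankings) + 1]] <- att$ranking[seq_len(top)]
  }
  ref <- rankings[[1]]
  ov <- vapply(rankings[-1], function(r)
    length(intersect(r, ref)) / length(union(r, ref)), 1)
  list(rankings = rankings, top_overlap = mean(ov))
}

#' Sample-level attribution over image voxels and priors
#'
#' Expected-gradients attribution of one task output: gradients of the
#' model score are averaged along interpolation paths from reference inputs
#' to the sample, and multiplied by the input-minus-reference difference.
#' Image voxels and the prior branch are attributed jointly and on the same
#' scale. The attributions satisfy the additivity (completeness) axiom up
#' to path-discretization error; for a linear model they are exact with a
#' single step.
#'
#' @param model a `fiber_model` (e.g. `state$model` of a trained trial).
#' @param x input tensor of one sample.
#' @param priors prior vector of the sample (length `n_priors`).
#' @param task_index output column to attribute.
#' @param baseline_x,baseline_priors reference inputs (zeros, or a train-set
#'   average); defaults to zeros.
#' @param steps interpolation steps (default 32).
#' @return list of class `sample_attribution`: `image` (array like `x`),
#'   `priors` (named vector, empty for models without a prior branch),
#'   `output`, `baseline_output`, `additivity_gap`.
#' @export
sample_attribution <- function(model, x, priors = NULL, task_index = 1,
                               baseline_x = NULL, baseline_priors = NULL,
                               steps = 32) {
  d <- dim(x)
  if (is.null(baseline_x)) baseline_x <- array(0, d)
  np <- model$n_priors
  if (is.null(priors)) priors <- rep(0, np)
  if (is.null(baseline_priors)) baseline_priors <- rep(0, np)
  dx_total <- array(0, d)
  dp_total <- rep(0, np)
  one <- function(v) array(v, dim = c(1, dim(v)))
  for (s in seq_len(steps)) {
    alpha <- (s - 0.5) / steps
    xi <- baseline_x + alpha * (x - baseline_x)
    pi_ <- baseline_priors + alpha * (priors - baseline_priors)
    fw <- nn_forward(model, one(xi), priors = matrix(pi_, 1), keep_cache = TRUE)
    dOut <- matrix(0, 1, model$n_out)
    dOut[1, task_index] <- 1
    bw <- nn_backward(model, fw$cache, dOut, input_grad = TRUE)
    dx_total <- dx_total + array(bw$dX, d)
    if (!is.null(bw$dPriors)) dp_total <- dp_total + as.numeric(bw$dPriors)
  }
  attr_img <- (x - baseline_x) * dx_total / steps
  attr_pri <- if (model$use_branch)
    setNames((priors - baseline_priors) * dp_total / steps, prior_names()[seq_len(np)])
  else setNames(numeric(0), character(0))
  out_x <- nn_forward(model, one(x), priors = matrix(priors, 1))$out[1, task_index]
  out_b <- nn_forward(model, one(baseline_x),
                      priors = matrix(baseline_priors, 1))$out[1, task_index]
  gap <- (sum(attr_img) + sum(attr_pri)) - (out_x - out_b)
  structure(list(image = attr_img, priors = attr_pri, output = out_x,
                 baseline_output = out_b, additivity_gap = gap),
            class = "sample_attribution")
}
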