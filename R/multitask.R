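# Data representations, augmentation, the trial training loop with
# uncertainty-weighted masked loss, early stopping on the smoothed total
# meta-loss, and dev-set metrics.

#' One point of the configuration space
#'
#' The decisions optimized by the self-enhancement loop: data-representation
#' choices, the prior-integration level, and network settings.
#'
#' @param contrast_enhancement,downsample,augment,random_erasing,gradient_clipping,imbalance_sampling logicals.
#' @param representation `"3D"`, `"2.5D_1"`, `"2.5D_5"`, `"2.5D_10"` or
#'   `"2.5D_20"` (centre slice plus two slices at the stated micrometre
#'   offset).
#' @param prior_integration one of `"NoPriors"`, `"AuxLosses"`, `"Branches"`,
#'   `"AuxLosses@Branches"`, `"PriorsOnly"`.
#' @param capacity backbone capacity 1-6 (strictly increasing parameters).
#' @param optimizer `"sgd"` or `"adam"`.
#' @param lr learning rate; `momentum` used by SGD; `batch_size` in \{4,8,16\}.
#' @return list of class `trial_configuration`.
#' @export
trial_configuration <- function(contrast_enhancement = FALSE,
                                downsample = FALSE, augment = FALSE,
                                random_erasing = FALSE,
                                representation = "2.5D_5",
                                prior_integration = "NoPriors",
                                capacity = 1, optimizer = "adam",
                                lr = 1e-3, momentum = 0.9, batch_size = 8,
                                gradient_clipping = FALSE,
                                imbalance_sampling = FALSE) {
  stopifnot(representation %in% c("3D", "2.5D_1", "2.5D_5", "2.5D_10", "2.5D_20"),
            prior_integration %in% c("NoPriors", "AuxLosses", "Branches",
                                     "AuxLosses@Branches", "PriorsOnly"),
            capacity %in% 1:6, optimizer %in% c("sgd", "adam"),
            lr > 0, batch_size %in% c(4, 8, 16))
  structure(list(contrast_enhancement = contrast_enhancement,
                 downsample = downsample, augment = augment,
                 random_erasing = random_erasing,
                 representation = representation,
                 prior_integration = prior_integration,
                 capacity = as.integer(capacity), optimizer = optimizer,
                 lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 gradient_clipping = gradient_clipping,
                 imbalance_sampling = imbalance_sampling),
            class = "trial_configuration")
}

#' Build the model input tensor for one image
#'
#' 3D mode yields a single-channel volume `[Z, Y, X, 1]`, optionally
#' downsampled to 0.75 um; 2.5D_d yields three channels `[Y, X, 3]`: the
#' centre z-slice and the slices at +-d um (offset `round(d / spacing)`
#' slices, clamped to the volume when allowed).
#'
#' @param img standardized, cropped [fiber_image()].
#' @param config a [trial_configuration()].
#' @param clamp allow clamping of out-of-volume slice offsets; with
#'   `clamp = FALSE` a volume thinner than `2 d` is rejected.
#' @return numeric array.
#' @export
build_representation <- function(img, config, clamp = TRUE) {
  if (config$downsample) img <- resample_isotropic(img, 0.75)
  d <- dim(img$voxels)
  if (config$representation == "3D") {
    return(array(img$voxels, dim = c(d, 1)))
  }
  off_um <- as.numeric(sub("2.5D_", "", config$representation, fixed = TRUE))
  off <- as.integer(round(off_um / img$spacing[1]))
  ctr <- as.integer(ceiling(d[1] / 2))
  idx <- c(ctr - off, ctr, ctr + off)
  if (any(idx < 1 | idx > d[1])) {
    if (!clamp) stop("volume too thin for the requested slice offset")
    idx <- pmin(pmax(idx, 1L), d[1])
  }
  out <- array(0, dim = c(d[2], d[3], 3))
  for (k in 1:3) out[, , k] <- img$voxels[idx[k], , ]
  attr(out, "slice_indices") <- idx
  out
}

erase_fraction_bounds <- function() c(0.02, 0.10)

#' Randomized training augmentation
#'
#' Composition of random flips, in-plane rotation (+-10 degrees), a small
#' affine scale jitter, and additive Gaussian noise when `augment` is on;
#' random erasing zeroes 1-3 axis-aligned boxes each covering 2-10% of the
#' field when `random_erasing` is on. With both off the input is returned
#' unchanged. Deterministic for a fixed seed. Applied to train samples only.
#'
#' @param x input tensor from [build_representation()].
#' @param config a [trial_configuration()].
#' @param seed integer seed.
#' @return augmented tensor of the same shape.
#' @export
augment <- function(x, config, seed = 1) {
  if (!isTRUE(config$augment) && !isTRUE(config$random_erasing)) return(x)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  d <- dim(x)
  nd <- length(d) - 1
  if (isTRUE(config$augment)) {
    # flips over the two in-plane axes
    ax_hw <- if (nd == 2) c(1, 2) else c(2, 3)
    for (ax in ax_hw) {
      if (runif(1) < 0.5) {
        idx <- rev(seq_len(d[ax]))
        x <- if (nd == 2) {
          if (ax == 1) x[idx, , , drop = FALSE] else x[, idx, , drop = FALSE]
        } else {
          if (ax == 2) x[, idx, , , drop = FALSE] else x[, , idx, , drop = FALSE]
        }
      }
    }
    ang <- runif(1, -10, 10) * pi / 180
    sc <- runif(1, 0.95, 1.05)
    shear <- runif(1, -0.03, 0.03)
    rot_plane <- function(M) {
      dm <- dim(M)
      ctr <- (dm - 1) / 2
      rr <- rep(seq_len(dm[1]) - 1, times = dm[2]) - ctr[1]
      cc <- rep(seq_len(dm[2]) - 1, each = dm[1]) - ctr[2]
      a11 <- cos(ang) / sc; a12 <- -sin(ang) / sc + shear
      a21 <- sin(ang) / sc; a22 <- cos(ang) / sc
      matrix(interp_bilinear(M, a11 * rr + a12 * cc + ctr[1],
                             a21 * rr + a22 * cc + ctr[2]), dm[1], dm[2])
    }
    if (nd == 2) {
      for (k in seq_len(d[3])) x[, , k] <- rot_plane(x[, , k])
    } else {
      for (z in seq_len(d[1])) x[z, , , 1] <- rot_plane(x[z, , , 1])
    }
    x <- x + rnorm(length(x), sd = 0.05)
  }
  if (isTRUE(config$random_erasing)) {
    nrect <- sample(1:3, 1)
    sp <- d[seq_len(nd)]
    for (r in seq_len(nrect)) {
      frac <- runif(1, erase_fraction_bounds()[1], erase_fraction_bounds()[2])
      side <- pmax(1L, as.integer(round(sp * frac^(1 / nd))))
      start <- vapply(seq_len(nd), function(ax)
        sample.int(max(sp[ax] - side[ax] + 1L, 1L), 1L), 1L)
      if (nd == 2) {
        x[start[1]:(start[1] + side[1] - 1L),
          start[2]:(start[2] + side[2] - 1L), ] <- 0
      } else {
        x[start[1]:(start[1] + side[1] - 1L),
          start[2]:(start[2] + side[2] - 1L),
          start[3]:(start[3] + side[3] - 1L), ] <- 0
      }
    }
  }
  x
}

#' Area under the ROC curve by pairwise concordance
#'
#' @param scores predicted scores.
#' @param labels 0/1 labels.
#' @return AUC (ties count 0.5), or `NA` for a single-class input.
#' @export
auc_score <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' R squared on labeled samples
#' @param pred predictions; `obs` observed values.
#' @return `1 - SS_res / SS_tot`, or `NA` when undefined.
#' @export
r2_score <- function(pred, obs) {
  if (length(obs) < 2 || var(obs) == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Per-task predictive metrics
#'
#' AUC of the ROC for classification tasks, R squared for regression tasks,
#' computed on labeled samples only. Tasks with fewer than two labeled
#' samples (or one class) are excluded with a warning.
#'
#' @param scores `N x T` prediction matrix (task columns).
#' @param labels `N x T` label matrix with `NA` for missing.
#' @param types per-task `"binary"`/`"continuous"`.
#' @return named numeric vector of metrics (NA where undefined).
#' @export
evaluate_metrics <- function(scores, labels, types) {
  out <- rep(NA_real_, ncol(labels))
  names(out) <- colnames(labels)
  for (k in seq_len(ncol(labels))) {
    ok <- !is.na(labels[, k])
    if (sum(ok) < 2) { warning("task ", colnames(labels)[k],
                               " has < 2 labeled samples; excluded"); next }
    out[k] <- if (types[k] == "binary") {
      a <- auc_score(scores[ok, k], labels[ok, k])
      if (is.na(a)) warning("task ", colnames(labels)[k],
                            " is single-class; excluded")
      a
    } else r2_score(scores[ok, k], labels[ok, k])
  }
  out
}

#' Early-stopping rule on the smoothed total meta-loss
#'
#' The total meta-loss series is smoothed by a moving average over the last
#' `window` epochs (using the available history while shorter). Training
#' stops at the first epoch `e` with `e - max(b, warmup) >= patience`, where
#' `b` is the epoch of the last strict minimum of the smoothed series; with
#' a never-improving series this yields exactly `warmup + patience` epochs.
#'
#' @param series per-epoch total meta-loss values.
#' @param warmup epochs before the criterion becomes active (default 75).
#' @param patience epochs without improvement that trigger the stop (50).
#' @param window moving-average window (10).
#' @return list with `stop_epoch` (`NA` if the series ends first) and the
#'   `smoothed` series.
#' @export
early_stop_epoch <- function(series, warmup = 75, patience = 50, window = 10) {
  smoothed <- vapply(seq_along(series), function(e)
    mean(series[max(1, e - window + 1):e]), 1)
  best <- Inf; best_e <- 0
  for (e in seq_along(smoothed)) {
    if (smoothed[e] < best) { best <- smoothed[e]; best_e <- e }
    if (e - max(best_e, warmup) >= patience)
      return(list(stop_epoch = e, smoothed = smoothed[seq_len(e)]))
  }
  list(stop_epoch = NA_integer_, smoothed = smoothed)
}

#' Assemble training tensors for a cohort and configuration
#'
#' Builds per-sample representations, the normalized prior matrix
#' (unavailable priors imputed at the train mean, i.e. 0 after
#' normalization), the label matrix, and the output mask.
#'
#' @param cohort a [make_cohort()] result with in-memory images.
#' @param split data.frame from [stratified_group_split()].
#' @param priors data.frame from [priors_table()].
#' @param config a [trial_configuration()].
#' @param task_types named character per task.
#' @return list consumed by [train_trial()].
#' @export
prepare_training_data <- function(cohort, split, priors, config, task_types) {
  man <- cohort$manifest
  stopifnot(identical(man$sample_id, split$sample_id),
            identical(man$sample_id, priors$sample_id))
  tasks <- names(task_types)
  labels_raw <- man[, tasks, drop = FALSE]
  prior_vals <- priors[, prior_names(), drop = FALSE]
  # normalize continuous labels and priors by train statistics
  cont <- tasks[task_types[tasks] == "continuous"]
  norm_l <- fit_apply_normalization(labels_raw, split, columns = cont)
  norm_p <- fit_apply_normalization(prior_vals, split,
                                    columns = prior_names())
  pv <- as.matrix(norm_p$values)
  pv[is.na(pv)] <- 0
  mask <- build_masks(labels_raw, priors)
  x <- NULL
  if (config$prior_integration != "PriorsOnly")
    x <- lapply(cohort$images, build_representation, config = config)
  list(x = x, priors = pv, labels = as.matrix(norm_l$values), mask = mask,
       task_types = task_types, task_names = tasks,
       sets = split$set, groups = man$group_id,
       norm_stats = list(labels = norm_l$stats, priors = norm_p$stats))
}

stack_batch <- function(xs) {
  d <- dim(xs[[1]])
  out <- array(0, dim = c(length(xs), d))
  for (i in seq_along(xs)) {
    if (length(d) == 3) out[i, , , ] <- xs[[i]] else out[i, , , , ] <- xs[[i]]
  }
  out
}

#' Train one trial
#'
#' Epoch loop with the configured optimizer, optional global-norm gradient
#' clipping (max norm 1) and gradient accumulation to an effective batch of
#' at least 8 in 3D mode. After each epoch the dev meta-losses (1 - AUC /
#' 1 - R squared) and their weighted total are computed; the total is
#' smoothed by a 10-epoch moving average and training stops by
#' [early_stop_epoch()] (warmup 75, patience 50) or at `budget` epochs.
#' Snapshots of the best parameters are kept per task and for the total.
#'
#' @param data from [prepare_training_data()].
#' @param config a [trial_configuration()] (not `PriorsOnly`).
#' @param budget maximum number of epochs.
#' @param seed integer seed (initialization, shuffling, augmentation).
#' @param task_weights named weights of the total meta-loss (default 1).
#' @param warmup,patience early-stopping parameters.
#' @return list of class `train_state`: `model`, per-epoch `meta_history`
#'   (matrix), `total_history`, `smoothed`, `epochs_run`, `stopped_early`,
#'   `best` (per-task and total snapshots), `failed`.
#' @export
train_trial <- function(data, config, budget = 200, seed = 1,
                        task_weights = NULL, warmup = 75, patience = 50) {
  tasks <- data$task_names
  nT <- length(tasks)
  if (is.null(task_weights)) task_weights <- setNames(rep(1, nT), tasks)
  use_aux <- config$prior_integration %in% c("AuxLosses", "AuxLosses@Branches")
  nP <- if (use_aux) length(prior_names()) else 0L
  model <- build_model(config, nT, length(prior_names()),
                       input_shape = dim(data$x[[1]]), seed = seed)
  types <- c(unname(data$task_types[tasks]), rep("continuous", nP))
  tr <- which(data$sets == "train")
  dv <- which(data$sets == "dev")
  stopifnot(length(tr) > 0, length(dv) > 0)
  targets <- cbind(data$labels,
                   if (nP) data$priors[, seq_len(nP), drop = FALSE])
  mask <- data$mask[, c(tasks, if (nP) prior_names()), drop = FALSE]
  targets[is.na(targets)] <- 0  # masked anyway

  opt <- make_optimizer(config$optimizer, config$lr, config$momentum)
  clip <- if (isTRUE(config$gradient_clipping)) 1 else NULL
  bs <- config$batch_size
  accum <- if (config$representation == "3D" && bs < 8) ceiling(8 / bs) else 1L

  # imbalance sampling: inverse class frequency on the rarest-labeled
  # classification task
  samp_w <- rep(1, length(tr))
  if (isTRUE(config$imbalance_sampling)) {
    bin <- tasks[data$task_types[tasks] == "binary"]
    if (length(bin)) {
      nlab <- vapply(bin, function(t) sum(mask[tr, t]), 1)
      t0 <- bin[which.min(nlab)]
      lab <- data$labels[tr, t0]
      f1 <- mean(lab == 1, na.rm = TRUE)
      if (is.finite(f1) && f1 > 0 && f1 < 1)
        samp_w <- ifelse(is.na(lab), 1, ifelse(lab == 1, 1 / f1, 1 / (1 - f1)))
    }
  }

  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  dev_x <- stack_batch(data$x[dv])
  dev_p <- data$priors[dv, , drop = FALSE]

  meta_history <- NULL
  total_history <- numeric(0)
  best_task <- setNames(vector("list", nT), tasks)
  best_task_val <- setNames(rep(Inf, nT), tasks)
  best_total <- NULL; best_total_val <- Inf
  failed <- FALSE
  epoch <- 0L
  while (epoch < budget) {
    epoch <- epoch + 1L
    order_idx <- if (isTRUE(config$imbalance_sampling))
      sample(tr, length(tr), replace = TRUE, prob = samp_w)
    else sample(tr, length(tr))
    i <- 1L
    while (i <= length(order_idx)) {
      grads_sum <- NULL; n_micro <- 0L
      for (a in seq_len(accum)) {
        if (i > length(order_idx)) break
        take <- order_idx[i:min(i + bs - 1L, length(order_idx))]
        i <- i + bs
        xs <- data$x[take]
        if (isTRUE(config$augment) || isTRUE(config$random_erasing))
          xs <- lapply(seq_along(xs), function(q)
            augment(xs[[q]], config,
                    seed = (seed + 131L * epoch + 7L * take[q]) %% .Machine$integer.max))
        Xb <- stack_batch(xs)
        fw <- nn_forward(model, Xb, priors = data$priors[take, , drop = FALSE],
                         keep_cache = TRUE)
        ls <- masked_uncertainty_loss(fw$out, targets[take, , drop = FALSE],
                                      mask[take, , drop = FALSE],
                                      model$params$log_sigma, types)
        if (!is.finite(ls$loss)) { failed <- TRUE; break }
        if (ls$n_terms == 0) next
        bw <- nn_backward(model, fw$cache, ls$dpred)
        g <- bw$grads
        g$log_sigma <- ls$dlog_sigma
        grads_sum <- if (is.null(grads_sum)) g else
          Map(`+`, grads_sum[names(g)], g)
        n_micro <- n_micro + 1L
      }
      if (failed) break
      if (!is.null(grads_sum)) {
        grads_sum <- lapply(grads_sum, function(g) g / n_micro)
        model$params <- opt$step(model$params, grads_sum, clip = clip)
      }
    }
    if (failed) break
    # dev meta-losses
    out <- nn_forward(model, dev_x, priors = dev_p)$out
    sc <- out[, seq_len(nT), drop = FALSE]
    colnames(sc) <- tasks
    lb <- data$labels[dv, , drop = FALSE]
    metr <- suppressWarnings(evaluate_metrics(sc, lb, data$task_types[tasks]))
    ml <- 1 - metr
    meta_history <- rbind(meta_history, ml)
    wl <- task_weights[tasks]
    okt <- !is.na(ml)
    total <- if (any(okt)) sum(wl[okt] * ml[okt]) / 1 else Inf
    total_history <- c(total_history, total)
    for (t in tasks) {
      if (!is.na(ml[t]) && ml[t] < best_task_val[t]) {
        best_task_val[t] <- ml[t]
        best_task[[t]] <- list(epoch = epoch, params = model$params)
      }
    }
    if (is.finite(total) && total < best_total_val) {
      best_total_val <- total
      best_total <- list(epoch = epoch, params = model$params)
    }
    es <- early_stop_epoch(total_history, warmup = warmup, patience = patience)
    if (!is.na(es$stop_epoch)) break
  }
  es <- early_stop_epoch(total_history, warmup = warmup, patience = patience)
  structure(list(model = model, meta_history = meta_history,
                 total_history = total_history, smoothed = es$smoothed,
                 epochs_run = epoch, stopped_early = !is.na(es$stop_epoch),
                 best = list(task = best_task, task_val = best_task_val,
                             total = best_total, total_val = best_total_val),
                 failed = failed, config = config, seed = seed),
            class = "train_state")
}

#' Predict task scores with a trained model
#'
#' @param state a `train_state` from [train_trial()].
#' @param data from [prepare_training_data()].
#' @param idx sample indices to score.
#' @param params optional parameter snapshot (e.g. a `best` entry).
#' @return matrix `length(idx) x n_tasks` of raw scores.
#' @export
predict_tasks <- function(state, data, idx, params = NULL) {
  model <- state$model
  if (!is.null(params)) model$params <- params
  out <- nn_forward(model, stack_batch(data$x[idx]),
                    priors = data$priors[idx, , drop = FALSE])$out
  sc <- out[, seq_along(data$task_names), drop = FALSE]
  colnames(sc) <- data$task_names
  sc
}
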