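# Self-enhancement loop: NSGA-II search over trial configurations,
# per-task dev meta-losses, the weighted total meta-loss, model selection
# rules, and the feature-only (PriorsOnly) AutoML-lite path.

#' Configuration search space
#'
#' Genes and their admissible values; the learning rate is log-uniform on
#' the stated range. The `PriorsOnly` level participates as the fifth value
#' of the integration gene (its data-representation and network genes are
#' inert for such trials).
#'
#' @param representations,integrations,capacities,optimizers,batch_sizes
#'   admissible values per gene.
#' @param lr_range log-uniform learning-rate range.
#' @return list of class `config_space`.
#' @export
config_space <- function(representations = c("3D", "2.5D_1", "2.5D_5",
                                             "2.5D_10", "2.5D_20"),
                         integrations = c("NoPriors", "AuxLosses", "Branches",
                                          "AuxLosses@Branches", "PriorsOnly"),
                         capacities = 1:6,
                         optimizers = c("sgd", "adam"),
                         batch_sizes = c(4, 8, 16),
                         lr_range = c(1e-4, 1e-2)) {
  genes <- list(
    contrast_enhancement = c(FALSE, TRUE),
    downsample = c(FALSE, TRUE),
    augment = c(FALSE, TRUE),
    random_erasing = c(FALSE, TRUE),
    representation = representations,
    prior_integration = integrations,
    capacity = capacities,
    optimizer = optimizers,
    batch_size = batch_sizes,
    gradient_clipping = c(FALSE, TRUE),
    imbalance_sampling = c(FALSE, TRUE))
  structure(list(genes = genes, lr_range = lr_range), class = "config_space")
}

#' Sample one configuration uniformly from the space
#' @param space a [config_space()].
#' @return a [trial_configuration()].
#' @export
sample_config <- function(space) {
  args <- lapply(space$genes, function(vals) vals[sample.int(length(vals), 1)])
  args$lr <- exp(runif(1, log(space$lr_range[1]), log(space$lr_range[2])))
  do.call(trial_configuration, args)
}

config_genes <- function(config) {
  c(lapply(config[c("contrast_enhancement", "downsample", "augment",
                    "random_erasing", "representation", "prior_integration",
                    "capacity", "optimizer", "batch_size",
                    "gradient_clipping", "imbalance_sampling")], identity),
    list(lr = config$lr))
}

genes_to_config <- function(g) do.call(trial_configuration, g)

#' Fast non-dominated sorting
#'
#' @param obj matrix of objective values (rows = solutions, minimized).
#' @return integer vector of front numbers (1 = non-dominated).
#' @export
nondominated_sort <- function(obj) {
  n <- nrow(obj)
  dominates <- function(i, j)
    all(obj[i, ] <= obj[j, ]) && any(obj[i, ] < obj[j, ])
  dom_count <- integer(n)
  dominated_by <- vector("list", n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && dominates(i, j))
      dominated_by[[i]] <- c(dominated_by[[i]], j)
  }
  for (i in seq_len(n)) for (j in dominated_by[[i]])
    dom_count[j] <- dom_count[j] + 1L
  front <- integer(n)
  current <- which(dom_count == 0L)
  f <- 1L
  while (length(current)) {
    front[current] <- f
    nxt <- integer(0)
    for (i in current) for (j in dominated_by[[i]]) {
      dom_count[j] <- dom_count[j] - 1L
      if (dom_count[j] == 0L) nxt <- c(nxt, j)
    }
    current <- unique(nxt)
    f <- f + 1L
  }
  front
}

#' Crowding distance within a front
#'
#' @param obj objective matrix of one front's members.
#' @return numeric distances; boundary solutions get `Inf`.
#' @export
crowding_distance <- function(obj) {
  n <- nrow(obj)
  if (n <= 2) return(rep(Inf, n))
  d <- rep(0, n)
  for (m in seq_len(ncol(obj))) {
    o <- order(obj[, m])
    d[o[1]] <- d[o[n]] <- Inf
    rng <- obj[o[n], m] - obj[o[1], m]
    if (rng <= 0) next
    d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
      (obj[o[3:n], m] - obj[o[1:(n - 2)], m]) / rng
  }
  d
}

#' One NSGA-II generation
#'
#' Fast non-dominated sorting and crowding distances rank the evaluated
#' population; binary tournaments pick parents; uniform crossover is applied
#' with probability `pc` (each gene swapped with probability `pswap`);
#' mutation resamples a gene from the space with probability `pm` (0 by
#' default). Deterministic for a fixed seed. With an empty population,
#' configurations are sampled uniformly.
#'
#' @param configs list of evaluated [trial_configuration()]s.
#' @param obj objective matrix aligned with `configs` (minimized).
#' @param space a [config_space()].
#' @param n_offspring offspring count.
#' @param seed integer seed.
#' @param pc,pswap,pm crossover, per-gene swap, and mutation probabilities.
#' @return list of [trial_configuration()]s for the next generation.
#' @export
nsga2_step <- function(configs, obj, space, n_offspring, seed = 42,
                       pc = 0.9, pswap = 0.5, pm = 0) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (length(configs) == 0)
    return(replicate(n_offspring, sample_config(space), simplify = FALSE))
  obj <- as.matrix(obj)
  front <- nondominated_sort(obj)
  crowd <- rep(0, length(configs))
  for (f in unique(front)) {
    idx <- which(front == f)
    crowd[idx] <- crowding_distance(obj[idx, , drop = FALSE])
  }
  better <- function(i, j) {
    if (front[i] != front[j]) return(front[i] < front[j])
    if (crowd[i] != crowd[j]) return(crowd[i] > crowd[j])
    i < j
  }
  tournament <- function() {
    cand <- sample.int(length(configs), 2, replace = TRUE)
    if (better(cand[1], cand[2])) cand[1] else cand[2]
  }
  offspring <- vector("list", n_offspring)
  k <- 1L
  while (k <= n_offspring) {
    g1 <- config_genes(configs[[tournament()]])
    g2 <- config_genes(configs[[tournament()]])
    if (runif(1) < pc) {
      for (nm in names(g1)) {
        if (runif(1) < pswap) { tmp <- g1[[nm]]; g1[[nm]] <- g2[[nm]]; g2[[nm]] <- tmp }
      }
    }
    if (pm > 0) {
      for (nm in names(space$genes)) if (runif(1) < pm)
        g1[[nm]] <- space$genes[[nm]][sample.int(length(space$genes[[nm]]), 1)]
      if (runif(1) < pm)
        g1$lr <- exp(runif(1, log(space$lr_range[1]), log(space$lr_range[2])))
    }
    offspring[[k]] <- genes_to_config(g1)
    k <- k + 1L
    if (k <= n_offspring) { offspring[[k]] <- genes_to_config(g2); k <- k + 1L }
  }
  offspring
}

#' Feature-only AutoML-lite trial
#'
#' Small pipeline search over top-k univariate feature selection
#' (k = 1..5) crossed with three probabilistic estimator families
#' (L2 logistic/linear model, tree ensemble, k-nearest-neighbour), scored
#' by grouped two-fold cross-validation on the combined train and dev set.
#' Muscle bundles are never split across folds. The best CV metric per task
#' is reported as that task's meta-loss.
#'
#' @param data from [prepare_training_data()] (images unused).
#' @param seed integer seed.
#' @return list with `meta_losses` (named, 1 - AUC / 1 - R2), `metrics`,
#'   and `chosen` (winning pipeline per task).
#' @export
priors_only_trial <- function(data, seed = 1) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  idx <- which(data$sets %in% c("train", "dev"))
  X <- data$priors[idx, , drop = FALSE]
  groups <- data$groups[idx]
  ug <- unique(groups)
  fold_of_group <- setNames(sample(rep(1:2, length.out = length(ug))), ug)
  fold <- fold_of_group[groups]
  tasks <- data$task_names
  metrics <- setNames(rep(NA_real_, length(tasks)), tasks)
  chosen <- setNames(vector("list", length(tasks)), tasks)
  for (t in tasks) {
    y <- data$labels[idx, t]
    ok <- !is.na(y)
    if (sum(ok) < 8) next
    type <- data$task_types[[t]]
    if (type == "binary" && length(unique(y[ok])) < 2) next
    scr <- abs(apply(X[ok, , drop = FALSE], 2, function(col)
      suppressWarnings(cor(col, y[ok]))))
    scr[is.na(scr)] <- 0
    best_metric <- -Inf; best_pipe <- NULL
    for (k in seq_len(min(5, ncol(X)))) {
      feats <- order(scr, decreasing = TRUE)[seq_len(k)]
      for (est in c("linear", "forest", "knn")) {
        preds <- rep(NA_real_, length(y))
        for (f in 1:2) {
          trn <- which(ok & fold != f); tst <- which(ok & fold == f)
          if (length(trn) < 4 || length(tst) < 2) next
          Xtr <- X[trn, feats, drop = FALSE]; Xte <- X[tst, feats, drop = FALSE]
          preds[tst] <- fit_predict_simple(est, Xtr, y[trn], Xte, type, seed)
        }
        okp <- ok & !is.na(preds)
        if (sum(okp) < 4) next
        m <- if (type == "binary") auc_score(preds[okp], y[okp])
             else r2_score(preds[okp], y[okp])
        if (!is.na(m) && m > best_metric) {
          best_metric <- m
          best_pipe <- list(k = k, estimator = est)
        }
      }
    }
    if (is.finite(best_metric)) {
      metrics[t] <- best_metric
      chosen[[t]] <- best_pipe
    }
  }
  list(meta_losses = 1 - metrics, metrics = metrics, chosen = chosen,
       fold = fold)
}

fit_predict_simple <- function(est, Xtr, ytr, Xte, type, seed) {
  Xtr <- as.data.frame(Xtr); Xte <- as.data.frame(Xte)
  colnames(Xte) <- colnames(Xtr)
  if (est == "linear") {
    # ridge-stabilized closed form; logistic link applied post hoc for AUC
    A <- cbind(1, as.matrix(Xtr))
    B <- cbind(1, as.matrix(Xte))
    beta <- tryCatch(solve(crossprod(A) + 1e-3 * diag(ncol(A)),
                           crossprod(A, ytr)), error = function(e) NULL)
    if (is.null(beta)) return(rep(NA_real_, nrow(Xte)))
    return(as.numeric(B %*% beta))
  }
  if (est == "forest") {
    df <- Xtr; df$.y <- ytr
    fit <- ranger::ranger(.y ~ ., data = df, num.trees = 100, seed = seed,
                          probability = FALSE)
    return(predict(fit, Xte)$predictions)
  }
  # knn with probability output
  k <- min(5L, max(1L, nrow(Xtr) - 1L))
  sdv <- apply(Xtr, 2, sd); sdv[sdv == 0] <- 1
  Xtr_s <- scale(Xtr, scale = sdv); Xte_s <- scale(Xte, center = attr(Xtr_s, "scaled:center"), scale = sdv)
  if (type == "binary") {
    pr <- class::knn(Xtr_s, Xte_s, factor(ytr), k = k, prob = TRUE)
    p <- attr(pr, "prob")
    return(ifelse(pr == "1", p, 1 - p))
  }
  d2 <- as.matrix(dist(rbind(Xte_s, Xtr_s)))[seq_len(nrow(Xte_s)),
                                             -seq_len(nrow(Xte_s)), drop = FALSE]
  apply(d2, 1, function(row) mean(ytr[order(row)[seq_len(k)]]))
}

#' Run one trial of the self-enhancement loop
#'
#' Dispatches `PriorsOnly` configurations to the feature pipeline (no image
#' tensor is ever built); all other integrations train the network with
#' [train_trial()] and evaluate dev metrics with the best-total snapshot.
#'
#' @param config a [trial_configuration()].
#' @param cohort,split,priors_tbl cohort inputs.
#' @param task_types named task types.
#' @param budget epoch budget per trial.
#' @param seed integer seed.
#' @param task_weights weights of the total meta-loss.
#' @param warmup,patience early-stopping parameters.
#' @return list of class `fiber_trial`: `config`, `meta_losses`,
#'   `total_meta_loss`, `status`, `dev_metrics`, `state` (network trials),
#'   `used_images` flag.
#' @export
run_trial <- function(config, cohort, split, priors_tbl, task_types,
                      budget = 125, seed = 1, task_weights = NULL,
                      warmup = 75, patience = 50) {
  tasks <- names(task_types)
  if (is.null(task_weights)) task_weights <- setNames(rep(1, length(tasks)), tasks)
  if (config$prior_integration == "PriorsOnly") {
    data <- prepare_training_data(cohort, split, priors_tbl,
                                  trial_configuration(prior_integration = "PriorsOnly"),
                                  task_types)
    po <- priors_only_trial(data, seed = seed)
    ml <- po$meta_losses
    okt <- !is.na(ml)
    total <- if (any(okt)) sum(task_weights[tasks][okt] * ml[okt]) else Inf
    return(structure(list(config = config, meta_losses = ml,
                          total_meta_loss = total,
                          status = if (any(okt)) "ok" else "failed",
                          dev_metrics = po$metrics, state = po,
                          used_images = FALSE),
                     class = "fiber_trial"))
  }
  data <- prepare_training_data(cohort, split, priors_tbl, config, task_types)
  st <- train_trial(data, config, budget = budget, seed = seed,
                    task_weights = task_weights, warmup = warmup,
                    patience = patience)
  if (st$failed || is.null(st$best$total)) {
    return(structure(list(config = config,
                          meta_losses = setNames(rep(NA_real_, length(tasks)), tasks),
                          total_meta_loss = NA_real_, status = "failed",
                          dev_metrics = NULL, state = st, used_images = TRUE),
                     class = "fiber_trial"))
  }
  dv <- which(data$sets == "dev")
  sc <- predict_tasks(st, data, dv, params = st$best$total$params)
  metr <- suppressWarnings(evaluate_metrics(sc, data$labels[dv, , drop = FALSE],
                                            data$task_types[tasks]))
  ml <- 1 - metr
  okt <- !is.na(ml)
  total <- if (any(okt)) sum(task_weights[tasks][okt] * ml[okt]) else Inf
  structure(list(config = config, meta_losses = ml, total_meta_loss = total,
                 status = "ok", dev_metrics = metr, state = st,
                 used_images = TRUE),
            class = "fiber_trial")
}

#' Select the model for each task from evaluated trials
#'
#' Tasks with at least `scarce_threshold` labeled samples take the trial
#' with the minimal per-task dev meta-loss; scarcer tasks take the trial
#' with the minimal total meta-loss. Ties break toward the earlier trial.
#'
#' @param trials list of `fiber_trial`s.
#' @param task_sizes named labeled-sample counts.
#' @param scarce_threshold sample-count threshold (default 100).
#' @return named integer vector of selected trial indices per task.
#' @export
select_models <- function(trials, task_sizes, scarce_threshold = 100) {
  ok <- which(vapply(trials, function(t) t$status == "ok", TRUE))
  stopifnot(length(ok) >= 1)
  tasks <- names(task_sizes)
  sel <- setNames(rep(NA_integer_, length(tasks)), tasks)
  totals <- vapply(trials, function(t)
    if (is.na(t$total_meta_loss)) Inf else t$total_meta_loss, 1)
  best_total <- ok[which.min(totals[ok])]
  for (t in tasks) {
    if (task_sizes[[t]] < scarce_threshold) {
      sel[t] <- best_total
    } else {
      ml <- vapply(trials, function(tr) {
        v <- tr$meta_losses[[t]]
        if (is.null(v) || is.na(v)) Inf else v
      }, 1)
      ml[-ok] <- Inf
      sel[t] <- which.min(ml)  # which.min takes the earliest on ties
    }
  }
  sel
}

#' Run the self-enhancement loop
#'
#' Generational NSGA-II over the configuration space: an initial uniform
#' population is evaluated, then offspring generations are produced by
#' [nsga2_step()] and evaluated until `n_trials` trials are spent.
#' Environmental selection keeps the best `population` individuals (front,
#' then crowding). Every trial is appended to the JSONL labbook with its
#' full configuration and objectives. Failed trials receive
#' worst-observed + 10% objectives so the population stays full while the
#' Pareto fronts exclude them.
#'
#' @param cohort,split,priors_tbl,task_types cohort inputs.
#' @param space a [config_space()].
#' @param n_trials total trials (>= `population`).
#' @param population population size.
#' @param seed integer seed (default 42).
#' @param budget epoch budget per network trial.
#' @param task_weights total-meta-loss weights.
#' @param warmup,patience early-stopping parameters.
#' @param labbook optional JSONL path.
#' @param top_k size of the best-trials summary (default 50).
#' @return list of class `self_enhancement`: `trials`, `objectives`,
#'   `selected` (per-task trial index), `summary_topk` (mean dev metric of
#'   the `top_k` best trials per task), `task_sizes`.
#' @export
run_self_enhancement <- function(cohort, split, priors_tbl, task_types,
                                 space = config_space(), n_trials = 60,
                                 population = 10, seed = 42, budget = 40,
                                 task_weights = NULL, warmup = 75,
                                 patience = 50, labbook = NULL, top_k = 50) {
  stopifnot(n_trials >= population)
  tasks <- names(task_types)
  man <- cohort$manifest
  task_sizes <- vapply(tasks, function(t) sum(!is.na(man[[t]])), 1)
  trials <- list()
  configs <- list()
  objs <- NULL
  gen <- 0L
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  init_seed <- seed
  while (length(trials) < n_trials) {
    gen <- gen + 1L
    n_new <- min(population, n_trials - length(trials))
    pop_idx <- surviving_population(objs, population)
    cand <- nsga2_step(configs[pop_idx],
                       if (is.null(objs)) NULL else objs[pop_idx, , drop = FALSE],
                       space, n_new, seed = init_seed + gen)
    for (cfg in cand) {
      tid <- length(trials) + 1L
      tr <- run_trial(cfg, cohort, split, priors_tbl, task_types,
                      budget = budget, seed = init_seed + 1000L + tid,
                      task_weights = task_weights, warmup = warmup,
                      patience = patience)
      tr$id <- tid
      ml <- tr$meta_losses
      if (tr$status == "failed" || all(is.na(ml))) {
        worst <- if (is.null(objs) || !nrow(objs)) rep(1, length(tasks))
                 else apply(objs, 2, max)
        ml <- worst * 1.1
        tr$status <- "failed"
      }
      ml[is.na(ml)] <- if (!is.null(objs) && nrow(objs)) max(objs) * 1.1 else 1.1
      trials[[tid]] <- tr
      configs[[tid]] <- cfg
      objs <- rbind(objs, unname(ml))
      if (!is.null(labbook))
        labbook_append(labbook, c(list(trial = tid, generation = gen,
                                       status = tr$status,
                                       total_meta_loss = tr$total_meta_loss,
                                       meta_losses = as.list(tr$meta_losses)),
                                  config_genes(cfg)))
    }
  }
  colnames(objs) <- tasks
  selected <- select_models(trials, task_sizes)
  summary_topk <- summarize_top_trials(trials, tasks, top_k)
  structure(list(trials = trials, objectives = objs, selected = selected,
                 summary_topk = summary_topk, task_sizes = task_sizes,
                 space = space, seed = seed),
            class = "self_enhancement")
}

surviving_population <- function(objs, population) {
  if (is.null(objs) || nrow(objs) == 0) return(integer(0))
  n <- nrow(objs)
  if (n <= population) return(seq_len(n))
  front <- nondominated_sort(objs)
  crowd <- rep(0, n)
  for (f in unique(front)) {
    idx <- which(front == f)
    crowd[idx] <- crowding_distance(objs[idx, , drop = FALSE])
  }
  order(front, -crowd)[seq_len(population)]
}

summarize_top_trials <- function(trials, tasks, top_k) {
  out <- setNames(rep(NA_real_, length(tasks)), tasks)
  for (t in tasks) {
    vals <- vapply(trials, function(tr) {
      if (tr$status != "ok" || is.null(tr$dev_metrics)) return(NA_real_)
      v <- tr$dev_metrics[[t]]
      if (is.null(v)) NA_real_ else v
    }, 1)
    vals <- vals[!is.na(vals)]
    if (!length(vals)) next
    out[t] <- mean(sort(vals, decreasing = TRUE)[seq_len(min(top_k, length(vals)))])
  }
  out
}

#' Hypervolume of a 2-objective front (minimization)
#'
#' @param points matrix of 2D objective vectors.
#' @param ref reference point dominating nothing.
#' @return scalar dominated hypervolume.
#' @export
hypervolume2d <- function(points, ref) {
  stopifnot(ncol(points) == 2)
  keep <- nondominated_sort(points) == 1
  p <- points[keep, , drop = FALSE]
  p <- p[order(p[, 1]), , drop = FALSE]
  hv <- 0
  prev_y <- ref[2]
  for (i in seq_len(nrow(p))) {
    if (p[i, 1] >= ref[1] || p[i, 2] >= prev_y) next
    hv <- hv + (ref[1] - p[i, 1]) * (prev_y - p[i, 2])
    prev_y <- p[i, 2]
  }
  hv
}
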