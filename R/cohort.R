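# Cohort assembly: stratification keys, the grouped stratified 2/4-1/4-1/4
# split, train-statistics normalization, and label masks for sparse
# multi-task training.

#' Dichotomize continuous labels for stratification
#'
#' Continuous tasks are median-split into `"high"`/`"low"` (values equal to
#' the median go to `"low"`); binary tasks pass through as `"0"`/`"1"`;
#' missing values map to the `"NA"` stratum. The per-task keys are combined
#' into one stratum string per sample. Dichotomized keys are used for
#' stratification only, never as learning tasks.
#'
#' @param labels data.frame of task columns (rows = samples).
#' @param task_types named character, `"binary"` or `"continuous"` per task.
#' @return character vector of stratum keys, one per sample.
#' @export
dichotomize_for_stratification <- function(labels, task_types) {
  keys <- matrix("NA", nrow(labels), ncol(labels))
  for (j in seq_along(labels)) {
    v <- labels[[j]]
    nm <- colnames(labels)[j]
    ok <- !is.na(v)
    if (task_types[[nm]] == "continuous") {
      if (sum(ok) >= 2) {
        med <- median(v[ok])
        keys[ok, j] <- ifelse(v[ok] <= med, "low", "high")
      }
    } else {
      keys[ok, j] <- as.character(v[ok])
    }
  }
  apply(keys, 1, paste, collapse = "|")
}

#' Stratified grouped train/dev/test split
#'
#' Whole muscle bundles (groups) are allocated greedily to the three sets,
#' stratum by stratum (strata in decreasing size order, groups shuffled by
#' the seed), always assigning the next group to the set furthest below its
#' target fraction. A group is never split across sets; a group's stratum is
#' the modal stratum of its samples. Deterministic for a fixed seed.
#'
#' @param manifest data.frame with `sample_id` and `group_id` columns.
#' @param strata character stratum key per sample (e.g. from
#'   [dichotomize_for_stratification()]).
#' @param fractions target group fractions for train/dev/test.
#' @param seed integer seed.
#' @return data.frame `sample_id`, `group_id`, `set`.
#' @export
stratified_group_split <- function(manifest, strata = NULL,
                                   fractions = c(2, 1, 1) / 4, seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3)
  groups <- unique(manifest$group_id)
  if (length(groups) < 4) stop("need at least 4 groups to split")
  if (is.null(strata)) strata <- rep("all", nrow(manifest))
  g_stratum <- vapply(groups, function(g) {
    s <- strata[manifest$group_id == g]
    names(sort(table(s), decreasing = TRUE))[1]
  }, "")
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sets <- c("train", "dev", "test")
  assigned <- setNames(rep(NA_character_, length(groups)), groups)
  counts <- c(train = 0, dev = 0, test = 0)
  strata_order <- names(sort(table(g_stratum), decreasing = TRUE))
  for (st in strata_order) {
    gs <- groups[g_stratum == st]
    gs <- gs[sample.int(length(gs))]
    if (length(gs) < 3)
      warning(sprintf("stratum '%s' has fewer than 3 groups; best-effort allocation", st))
    local_counts <- c(train = 0, dev = 0, test = 0)
    for (g in gs) {
      # deficit relative to target, stratum-local first then global tiebreak
      def_local <- fractions - local_counts / max(sum(local_counts), 1)
      def_global <- fractions - counts / max(sum(counts), 1)
      pick <- sets[order(-def_local, -def_global)][1]
      assigned[g] <- pick
      local_counts[pick] <- local_counts[pick] + 1
      counts[pick] <- counts[pick] + 1
    }
  }
  data.frame(sample_id = manifest$sample_id, group_id = manifest$group_id,
             set = unname(assigned[manifest$group_id]))
}

#' Fit and apply train-set standard-score normalization
#'
#' Means and standard deviations (population convention, ddof = 0) are
#' computed on the train set only and applied to all sets; missing values
#' stay missing. Quantities with zero train standard deviation are left
#' unnormalized with a warning.
#'
#' @param values data.frame of numeric columns (labels and/or priors).
#' @param split data.frame from [stratified_group_split()] aligned by row.
#' @param columns columns to normalize (default: all numeric).
#' @return list with `values` (normalized data.frame) and `stats`
#'   (data.frame of per-column train mean/sd and whether it was applied).
#' @export
fit_apply_normalization <- function(values, split, columns = NULL) {
  stopifnot(nrow(values) == nrow(split))
  if (is.null(columns))
    columns <- colnames(values)[vapply(values, is.numeric, TRUE)]
  tr <- split$set == "train"
  stats_rows <- list()
  for (cn in columns) {
    v <- values[[cn]]
    vt <- v[tr & !is.na(v)]
    if (length(vt) == 0) {
      warning("no train values for ", cn, "; left unnormalized")
      stats_rows[[cn]] <- data.frame(column = cn, mean = NA, sd = NA,
                                     applied = FALSE)
      next
    }
    mu <- mean(vt)
    s <- sqrt(mean((vt - mu)^2))
    if (!is.finite(s) || s <= 0) {
      warning("zero train sd for ", cn, "; left unnormalized")
      stats_rows[[cn]] <- data.frame(column = cn, mean = mu, sd = s,
                                     applied = FALSE)
      next
    }
    values[[cn]] <- (v - mu) / s
    stats_rows[[cn]] <- data.frame(column = cn, mean = mu, sd = s,
                                   applied = TRUE)
  }
  list(values = values, stats = do.call(rbind, stats_rows))
}

#' Build per-sample output presence masks
#'
#' One boolean row per sample aligned with the model outputs: the task heads
#' first, then the auxiliary prior heads. Missing labels and unavailable
#' priors are masked (FALSE); masked outputs receive no backpropagation.
#'
#' @param labels data.frame of task columns (NA = missing).
#' @param priors optional data.frame with `<prior>_available` flags from
#'   [priors_table()].
#' @return logical matrix, `n x (n_tasks + n_priors)`.
#' @export
build_masks <- function(labels, priors = NULL) {
  m_task <- !is.na(as.matrix(labels))
  colnames(m_task) <- colnames(labels)
  if (is.null(priors)) return(m_task)
  av <- as.matrix(priors[, paste0(prior_names(), "_available"), drop = FALSE])
  colnames(av) <- prior_names()
  cbind(m_task, av)
}
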