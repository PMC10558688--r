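# Shared fixtures, generated in code and memoized for the test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# clean, perfectly parallel fiber with near-noiseless banding
clean_fiber <- function() fixture("clean_fiber", function()
  generate_fiber(fiber_spec(sarcomere_length = 2.5, semi_axes = c(10, 6),
                            dispersion_kappa = Inf, n_verniers = 0, snr = 1e6),
                 spacing = c(0.5, 0.5, 0.5), shape = c(32, 96, 48), seed = 7))

# moderately noisy fiber used by the standardization tests
noisy_fiber <- function() fixture("noisy_fiber", function()
  generate_fiber(fiber_spec(semi_axes = c(10, 6), snr = 10),
                 shape = c(32, 96, 48), seed = 2))

# a tiny multi-study cohort with priors and split, reused by the learning
# tests (images 16 x 32 x 24 voxels at 0.5 um)
tiny_cohort <- function() fixture("tiny_cohort", function() {
  design <- demo_design()
  coh <- make_cohort(64, design, seed = 5)
  ptab <- priors_table(coh)
  tt <- design$task_types
  strata <- dichotomize_for_stratification(coh$manifest[, names(tt)], tt)
  split <- suppressWarnings(
    stratified_group_split(coh$manifest, strata, seed = 7))
  list(cohort = coh, priors = ptab, split = split, task_types = tt)
})

# synthetic manifest without images, for split/normalization properties
synthetic_manifest <- function(n_groups, samples_per_group = 1,
                               strata_levels = 1, seed = 1) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = samples_per_group)
  data.frame(sample_id = sprintf("s%04d", seq_along(g)),
             group_id = sprintf("g%04d", g),
             stratum = sample(letters[seq_len(strata_levels)],
                              length(g), replace = TRUE))
}

# a hand-built model that is exactly linear on the attribution path:
# global average pooling, an identity hidden layer held in the positive
# relu region, and known output weights over features and priors
linear_stub <- function(c_feat = 2, c_priors = c(0.5, -1.5)) {
  hid <- 1 + length(c_priors)
  M <- 50
  structure(list(
    arch = list(list(type = "gap")),
    params = list(fc1_W = diag(hid), fc1_b = rep(M, hid),
                  out_W = matrix(c(c_feat, c_priors), ncol = 1),
                  out_b = -M * sum(c(c_feat, c_priors)),
                  log_sigma = 0),
    nd = 2, n_tasks = 1, n_priors = length(c_priors),
    use_branch = TRUE, use_aux = FALSE, n_out = 1L,
    config = NULL, input_shape = c(4, 4, 1)),
    class = "fiber_model")
}

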