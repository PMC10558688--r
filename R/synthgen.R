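# Synthetic SHG-like fiber generator. A fiber is an elliptical cylinder along
# the y axis carrying quasi-periodic sarcomere banding
#   I = envelope * (1 + m * cos(2*pi*s/SL + phi)),  m = 0.6,
# where the local band normal is tilted away from the axis by von-Mises(kappa)
# angles (spatially correlated, 5 um correlation length) and phi carries
# planted vernier phase dislocations. Ground truth (SL, orientation field,
# defect coordinates, cross-section) is returned alongside the image so every
# downstream detector can be validated without real data.

BAND_MODULATION <- 0.6

#' Specification of one synthetic muscle fiber
#'
#' @param sarcomere_length banding period in micrometre (> 0; physiological
#'   range is roughly 2-3).
#' @param semi_axes length-2, elliptical cross-section semi-axes `(a, b)` in
#'   micrometre; `a` lies along x, `b` along z.
#' @param dispersion_kappa von Mises concentration of myofibril orientations
#'   about the fiber main axis; `Inf` means perfectly parallel.
#' @param n_verniers number of planted Y-shaped phase-dislocation defects.
#' @param snr linear signal-to-noise ratio, defined as banding amplitude over
#'   additive Gaussian noise standard deviation; `Inf` disables noise.
#' @param pose rigid pose: list with `rotation` (degrees about z, y, x) and
#'   `translation` (micrometre, `(z, y, x)`).
#' @param intensity_scale arbitrary intensity units of the envelope.
#' @return an object of class `fiber_spec`.
#' @export
fiber_spec <- function(sarcomere_length = 2.5, semi_axes = c(20, 10),
                       dispersion_kappa = Inf, n_verniers = 0, snr = 10,
                       pose = list(rotation = c(0, 0, 0),
                                   translation = c(0, 0, 0)),
                       intensity_scale = 1) {
  stopifnot(sarcomere_length > 0, length(semi_axes) == 2, all(semi_axes > 0),
            dispersion_kappa >= 0, n_verniers >= 0, snr > 0,
            intensity_scale > 0)
  structure(list(sarcomere_length = sarcomere_length,
                 semi_axes = as.numeric(semi_axes),
                 dispersion_kappa = dispersion_kappa,
                 n_verniers = as.integer(n_verniers), snr = snr,
                 pose = pose, intensity_scale = intensity_scale),
            class = "fiber_spec")
}

#' Generate one synthetic fiber volume with ground truth
#'
#' Deterministic for a fixed `(spec, seed)` pair. The returned truth record
#' carries everything the biomarker detectors estimate: the banding period,
#' the per-voxel orientation tilts actually sampled (summarised as the mean
#' cosine over the foreground), the planted vernier coordinates, and the
#' analytic cross-section.
#'
#' @param spec a [fiber_spec()].
#' @param spacing voxel spacing in micrometre, `(z, y, x)`.
#' @param shape voxel counts `(z, y, x)`; each must be at least 32.
#' @param seed integer seed.
#' @return list of class `fiber_sim` with elements `image` ([fiber_image()])
#'   and `truth` (named list).
#' @export
generate_fiber <- function(spec, spacing = c(0.5, 0.5, 0.5),
                           shape = c(64, 192, 96), seed = 1) {
  stopifnot(inherits(spec, "fiber_spec"), all(spacing > 0))
  shape <- as.integer(shape)
  if (any(shape < 16)) stop("shape must be at least 16 voxels per axis")
  if (spec$sarcomere_length < 2 * spacing[2])
    stop("sarcomere period below the Nyquist limit of the axial spacing")
  half_ext <- (shape - 1) * spacing / 2
  rot <- euler_matrix(spec$pose$rotation)
  # bounding half-extents of the rotated cross-section axes must fit
  ax_x <- abs(rot %*% c(0, 0, spec$semi_axes[1]))
  ax_z <- abs(rot %*% c(spec$semi_axes[2], 0, 0))
  need <- pmax(ax_x, ax_z)[c(1, 3)] + abs(spec$pose$translation[c(1, 3)])
  if (any(need > half_ext[c(1, 3)]))
    stop("elliptical cross-section does not fit inside the volume after pose")

  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  co <- voxel_coords(shape, spacing)
  # world -> fiber frame: undo translation then rotation
  inv <- t(rot)
  wz <- as.vector(co$z) - spec$pose$translation[1]
  wy <- as.vector(co$y) - spec$pose$translation[2]
  wx <- as.vector(co$x) - spec$pose$translation[3]
  fz <- inv[1, 1] * wz + inv[1, 2] * wy + inv[1, 3] * wx
  fy <- inv[2, 1] * wz + inv[2, 2] * wy + inv[2, 3] * wx
  fx <- inv[3, 1] * wz + inv[3, 2] * wy + inv[3, 3] * wx
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]
  r2 <- (fx / a)^2 + (fz / b)^2
  fg <- r2 <= 1

  k0 <- 2 * pi / spec$sarcomere_length
  kappa <- spec$dispersion_kappa
  if (is.finite(kappa)) {
    g1 <- correlated_field(shape, spacing, corr_um = 5)
    g2 <- correlated_field(shape, spacing, corr_um = 5)
    theta <- rvonmises(0, kappa, p = stats::pnorm(as.vector(g1)))
    alpha <- 2 * pi * stats::pnorm(as.vector(g2))
    tilt <- pmin(abs(theta), 75 * pi / 180) * sign(theta + (theta == 0))
    tt <- tan(tilt)
    phi_disp <- k0 * (fx * tt * cos(alpha) + fz * tt * sin(alpha))
    cos_true <- cos(theta)
  } else {
    theta <- rep(0, length(fz))
    phi_disp <- 0
    cos_true <- rep(1, length(fz))
  }

  # vernier defects: full 2*pi phase dislocations (one extra band terminating
  # at the core -> a Y-shaped split), running through the fiber depth as
  # line defects; cores rejection-sampled with a minimum in-plane separation
  # so each defect is individually resolvable
  phi_vern <- 0
  vern <- NULL
  if (spec$n_verniers > 0) {
    y0s <- x0s <- numeric(0)
    attempts <- 0L
    while (length(y0s) < spec$n_verniers && attempts < 500L) {
      attempts <- attempts + 1L
      y0 <- (runif(1) - 0.5) * 1.6 * half_ext[2]
      x0 <- (runif(1) - 0.5) * 1.1 * a
      if (length(y0s)) {
        sep <- pmax(abs(y0 - y0s) / 8, abs(x0 - x0s) / 6)
        if (min(sep) < 1) next
      }
      y0s <- c(y0s, y0); x0s <- c(x0s, x0)
    }
    if (length(y0s) < spec$n_verniers)
      stop("could not place the requested number of verniers with minimum separation")
    phi_vern <- rep(0, length(fz))
    # alternate winding signs (a Y split can open either way); same-signed
    # windings would accumulate a far-field phase gradient that biases the
    # apparent banding period
    sgn_k <- rep(c(1, -1), length.out = spec$n_verniers)
    for (k in seq_len(spec$n_verniers)) {
      phi_vern <- phi_vern + sgn_k[k] * atan2(fy - y0s[k], fx - x0s[k])
    }
    vern <- cbind(z = rep(0, spec$n_verniers), y = y0s, x = x0s,
                  winding = sgn_k)
  }

  band <- 1 + BAND_MODULATION * cos(k0 * fy + phi_disp + phi_vern)
  vox <- spec$intensity_scale * as.numeric(fg) * band
  noise_sd <- 0
  if (is.finite(spec$snr)) {
    noise_sd <- BAND_MODULATION * spec$intensity_scale / spec$snr
    vox <- vox + rnorm(length(vox), sd = noise_sd)
  }
  vox <- array(vox, dim = shape)
  img <- fiber_image(vox, spacing, sample_id = sprintf("fiber_seed%d", seed),
                     mask = array(fg, dim = shape))
  img <- fi_record(img, "generate_fiber",
                   list(seed = seed, sl = spec$sarcomere_length,
                        kappa = kappa, snr = spec$snr))

  n_slices <- sum(abs((seq_len(shape[1]) - 1 - (shape[1] - 1) / 2) *
                        spacing[1]) < b)
  truth <- list(
    sl = spec$sarcomere_length,
    semi_axes = spec$semi_axes,
    csa = pi * a * b,
    kappa = kappa,
    cas = mean(cos_true[fg]),
    mean_cos_theory = vonmises_mean_cos(kappa),
    n_verniers = spec$n_verniers,
    vernier_coords = vern,
    vd = spec$n_verniers / mean_slice_area(fg, shape, spacing),
    snr = spec$snr,
    noise_sd = noise_sd,
    intensity_scale = spec$intensity_scale,
    sampled_cos = cos_true[fg][seq(1, sum(fg), length.out = min(4000, sum(fg)))]
  )
  structure(list(image = img, truth = truth), class = "fiber_sim")
}

# mean foreground area (um^2) of z-slices that intersect the fiber
mean_slice_area <- function(fg, shape, spacing) {
  fga <- array(fg, dim = shape)
  per_slice <- apply(fga, 1, sum) * spacing[2] * spacing[3]
  mean(per_slice[per_slice > 0])
}

#' Link model tying simulated labels to ground-truth structure
#'
#' Each task is a generalized linear function of the ground-truth parameters
#' of a [generate_fiber()] run (`sl`, `cas`, `csa`, `vd`, `snr`). Binary
#' tasks draw Bernoulli(sigmoid(linear predictor)); continuous tasks add
#' Gaussian noise. The `availability` fraction makes labels sparse, emulating
#' a multi-study design where some tasks are labeled for few samples only.
#'
#' @param tasks named list; each element is a list with `type`
#'   (`"binary"`/`"continuous"`), `coef` (named numeric over truth
#'   parameters), `intercept`, and `noise_sd` (continuous only).
#' @param availability named numeric in (0, 1], labeled fraction per task.
#' @return an object of class `label_link_model`.
#' @export
label_link_model <- function(tasks, availability = NULL) {
  stopifnot(is.list(tasks), length(names(tasks)) == length(tasks))
  allowed <- c("sl", "cas", "csa", "vd", "snr")
  for (nm in names(tasks)) {
    t <- tasks[[nm]]
    stopifnot(t$type %in% c("binary", "continuous"))
    if (length(t$coef) && !all(names(t$coef) %in% allowed))
      stop("link coefficients must reference ground-truth parameters: ",
           paste(allowed, collapse = ", "))
  }
  if (is.null(availability)) availability <- setNames(rep(1, length(tasks)),
                                                      names(tasks))
  stopifnot(all(availability > 0), all(availability <= 1),
            all(names(tasks) %in% names(availability)))
  structure(list(tasks = tasks, availability = availability),
            class = "label_link_model")
}

truth_features <- function(truth) {
  c(sl = truth$sl, cas = truth$cas, csa = truth$csa, vd = truth$vd,
    snr = if (is.finite(truth$snr)) truth$snr else 1e3)
}

#' Simulate sparse task labels from ground truth
#'
#' @param truth a truth record from [generate_fiber()].
#' @param link a [label_link_model()].
#' @param seed integer seed.
#' @return named list of label values; unlabeled tasks are `NA`.
#' @export
simulate_labels <- function(truth, link, seed = 1) {
  stopifnot(inherits(link, "label_link_model"))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  feats <- truth_features(truth)
  out <- list()
  for (nm in names(link$tasks)) {
    t <- link$tasks[[nm]]
    lp <- t$intercept
    if (length(t$coef)) lp <- lp + sum(t$coef * feats[names(t$coef)])
    val <- if (t$type == "binary") {
      rbinom(1, 1, plogis(lp))
    } else {
      lp + rnorm(1, sd = t$noise_sd %||% 0)
    }
    labeled <- runif(1) <= link$availability[[nm]]
    out[[nm]] <- if (labeled) val else NA_real_
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a multi-study cohort of synthetic fibers
#'
#' Samples are grouped into muscle bundles of 1-3 fibers, assigned to
#' studies with study-specific fiber-parameter distributions and noise
#' regimes, and given sparse labels through the study design's link model.
#' Ground truth is retained for testing. Deterministic for a fixed seed.
#'
#' @param n number of fibers (>= 8).
#' @param design list with elements `studies` (named list; each study has
#'   `weight`, a `spec_fn(i)` returning a [fiber_spec()] or a list of fixed
#'   spec arguments, and optionally `snr`), `link` (a [label_link_model()]),
#'   `shape`, `spacing`, and `fibers_per_bundle` (max bundle size, 1-3).
#' @param seed integer seed.
#' @param dir optional output directory; when given, images are written as
#'   multi-page TIFF and the manifest/truth tables as CSV.
#' @param keep_images keep generated volumes in memory (default `TRUE`).
#' @return list of class `fiber_cohort`: `manifest` (data.frame), `truth`
#'   (data.frame), `images` (list or `NULL`), `link`, `design`.
#' @export
make_cohort <- function(n, design, seed = 1, dir = NULL, keep_images = TRUE) {
  stopifnot(n >= 8)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  studies <- design$studies
  stopifnot(length(studies) >= 1)
  shape <- design$shape %||% c(64, 192, 96)
  spacing <- design$spacing %||% c(0.5, 0.5, 0.5)
  fpb <- design$fibers_per_bundle %||% 3
  stopifnot(fpb >= 1, fpb <= 3)
  wts <- vapply(studies, function(s) s$weight %||% 1, 1)
  study_of <- sample(names(studies), n, replace = TRUE, prob = wts / sum(wts))

  # bundles of 1..fpb fibers, never spanning studies
  group_of <- integer(n)
  gid <- 0L
  for (st in names(studies)) {
    idx <- which(study_of == st)
    i <- 1L
    while (i <= length(idx)) {
      gid <- gid + 1L
      sz <- if (fpb == 1) 1L else sample(seq_len(fpb), 1L)
      take <- idx[i:min(i + sz - 1L, length(idx))]
      group_of[take] <- gid
      i <- i + length(take)
    }
  }

  sample_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  images <- if (keep_images) vector("list", n) else NULL
  truth_rows <- vector("list", n)
  label_rows <- vector("list", n)
  paths <- rep(NA_character_, n)
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  for (i in seq_len(n)) {
    st <- studies[[study_of[i]]]
    spec <- if (!is.null(st$spec_fn)) st$spec_fn(i) else do.call(fiber_spec, st$spec %||% list())
    sim <- generate_fiber(spec, spacing = spacing, shape = shape,
                          seed = sample_seeds[i])
    labs <- simulate_labels(sim$truth, design$link, seed = sample_seeds[n + i])
    sid <- sprintf("S%03d", i)
    sim$image$meta$sample_id <- sid
    sim$image$meta$study_id <- study_of[i]
    if (!is.null(dir)) {
      paths[i] <- file.path(dir, paste0(sid, ".tif"))
      write_fiber_image(sim$image, paths[i])
    }
    if (keep_images) images[[i]] <- sim$image
    truth_rows[[i]] <- data.frame(sample_id = sid, sl = sim$truth$sl,
                                  cas = sim$truth$cas, csa = sim$truth$csa,
                                  vd = sim$truth$vd, kappa = sim$truth$kappa,
                                  snr = sim$truth$snr,
                                  n_verniers = sim$truth$n_verniers)
    label_rows[[i]] <- data.frame(sample_id = sid, image_path = paths[i],
                                  group_id = sprintf("G%03d", group_of[i]),
                                  study_id = study_of[i],
                                  as.data.frame(labs))
  }
  manifest <- do.call(rbind, label_rows)
  truth <- do.call(rbind, truth_rows)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  structure(list(manifest = manifest, truth = truth, images = images,
                 link = design$link, design = design, seed = seed),
            class = "fiber_cohort")
}

#' Two-study demonstration design with prior-driven labels
#'
#' A ready-made [make_cohort()] design emulating a small multi-study
#' collection: two studies with different noise regimes (SNR 8 vs 3) and
#' per-fiber variation in sarcomere length (uniform 2.2-3.0 um), myofibril
#' dispersion (kappa drawn from \{16, 4, 2, 1\}) and cross-section. Three
#' tasks are linked to ground-truth structure: a binary dystrophy-like
#' phenotype driven by low fiber alignment (CAS), a continuous force-like
#' task driven by CAS, and a scarce continuous task driven by CSA labeled
#' for only 8% of samples (a Table-2-like sparse design).
#'
#' @param shape voxel counts `(z, y, x)` for the generated volumes.
#' @param spacing voxel spacing in micrometre.
#' @return a design list for [make_cohort()].
#' @export
demo_design <- function(shape = c(16, 32, 24), spacing = c(0.5, 0.5, 0.5)) {
  half <- (shape - 1) * spacing / 2
  ax <- 0.62 * half[3]; az <- 0.62 * half[1]
  mk_spec <- function(snr, scale) {
    force(snr); force(scale)
    function(i) fiber_spec(sarcomere_length = runif(1, 2.2, 3.0),
                           semi_axes = c(ax, az) * scale,
                           dispersion_kappa = sample(c(16, 4, 2, 1), 1),
                           n_verniers = 0, snr = snr)
  }
  link <- label_link_model(
    tasks = list(
      dystrophic = list(type = "binary", coef = c(cas = -12), intercept = 10.2),
      force = list(type = "continuous", coef = c(cas = 5), intercept = 0,
                   noise_sd = 0.3),
      scarce = list(type = "continuous", coef = c(csa = 0.02), intercept = 0,
                    noise_sd = 0.2)),
    availability = c(dystrophic = 1, force = 0.8, scarce = 0.08))
  list(studies = list(A = list(weight = 1, spec_fn = mk_spec(8, 1)),
                      B = list(weight = 1, spec_fn = mk_spec(3, 1.1))),
       link = link, shape = shape, spacing = spacing, fibers_per_bundle = 2,
       task_types = c(dystrophic = "binary", force = "continuous",
                      scarce = "continuous"))
}

#' @export
print.fiber_cohort <- function(x, ...) {
  cat(sprintf("<fiber_cohort> %d samples, %d bundles, studies: %s\n",
              nrow(x$manifest), length(unique(x$manifest$group_id)),
              paste(unique(x$manifest$study_id), collapse = ", ")))
  invisible(x)
}

cohort_task_names <- function(cohort) {
  setdiff(colnames(cohort$manifest),
          c("sample_id", "image_path", "group_id", "study_id"))
}
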