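# Cross-study image standardization. Fixed pipeline order:
# resample -> median denoise -> Otsu background zeroing -> (CLAHE-enhanced
# copy used to estimate a rigid transform against a canonical reference) ->
# transform applied to the non-enhanced image -> probability-atlas crop ->
# sample-wise standard score. Every step appends to the image history and,
# when a labbook path is supplied, to a JSONL labbook.

#' Standardization configuration
#'
#' @param target_spacing isotropic voxel size in micrometre (default 0.5).
#' @param median_size median-filter window in micrometre (default 1).
#' @param atlas_threshold presence probability for the crop box (default 0.85).
#' @param enhancement logical, apply CLAHE before registration.
#' @param register_method `"mi"` (multi-resolution mutual information) or
#'   `"pca"` (principal-axes alignment, fast).
#' @param levels,iterations multi-resolution levels and per-level iteration
#'   cap for MI registration.
#' @return a named list of class `standardization_config`.
#' @export
standardization_config <- function(target_spacing = 0.5, median_size = 1,
                                   atlas_threshold = 0.85, enhancement = TRUE,
                                   register_method = "mi", levels = 6,
                                   iterations = 600) {
  stopifnot(target_spacing > 0, atlas_threshold > 0, atlas_threshold < 1)
  structure(list(target_spacing = target_spacing, median_size = median_size,
                 atlas_threshold = atlas_threshold, enhancement = enhancement,
                 register_method = register_method, levels = levels,
                 iterations = iterations),
            class = "standardization_config")
}

#' Resample a volume to isotropic voxel size
#'
#' Trilinear interpolation onto a grid of `round(n * spacing / target)`
#' voxels per axis, which preserves the physical extent to within one voxel.
#' When the input grid already coincides with the target grid the voxel
#' array is returned unchanged.
#'
#' @param img a [fiber_image()].
#' @param target isotropic spacing in micrometre.
#' @return resampled [fiber_image()].
#' @export
resample_isotropic <- function(img, target) {
  stopifnot(target > 0)
  d <- dim(img$voxels)
  if (any(d <= 1)) stop("degenerate axis: volume must have > 1 voxel per axis")
  nd <- pmax(2L, as.integer(round(d * img$spacing / target)))
  # sample positions j*target expressed in input voxel units i = pos/spacing
  zi <- (seq_len(nd[1]) - 1) * target / img$spacing[1]
  yi <- (seq_len(nd[2]) - 1) * target / img$spacing[2]
  xi <- (seq_len(nd[3]) - 1) * target / img$spacing[3]
  cz <- rep(zi, times = nd[2] * nd[3])
  cy <- rep(rep(yi, each = nd[1]), times = nd[3])
  cx <- rep(xi, each = nd[1] * nd[2])
  # clamp the sub-voxel overhang so the last sample stays on the input grid
  cz <- pmin(cz, d[1] - 1); cy <- pmin(cy, d[2] - 1); cx <- pmin(cx, d[3] - 1)
  vox <- array(interp_trilinear(img$voxels, cz, cy, cx), dim = nd)
  out <- img
  out$voxels <- vox
  out$spacing <- rep(target, 3)
  if (!is.null(img$mask)) {
    m <- array(interp_trilinear(array(as.numeric(img$mask), dim = d),
                                cz, cy, cx), dim = nd)
    out$mask <- m > 0.5
  }
  fi_record(out, "resample_isotropic", list(target = target))
}

#' Median denoising
#'
#' Window per axis is `round(size / spacing)` voxels, forced odd with a
#' minimum of 3 whenever `size >= spacing` (a symmetric window matching a
#' "slight" denoise); axes with `size < spacing` are left untouched.
#'
#' @param img a [fiber_image()].
#' @param size physical window size in micrometre.
#' @return denoised [fiber_image()].
#' @export
denoise_median <- function(img, size = 1) {
  w <- integer(3)
  for (ax in 1:3) {
    if (size >= img$spacing[ax]) {
      k <- max(3L, as.integer(round(size / img$spacing[ax])))
      if (k %% 2L == 0L) k <- k + 1L
      w[ax] <- k
    } else w[ax] <- 1L
  }
  r <- (w - 1L) %/% 2L
  out <- img
  if (any(r > 0))
    out$voxels <- .median3d_cpp(img$voxels, dim(img$voxels), r[1], r[2], r[3])
  fi_record(out, "denoise_median", list(size = size, window = w))
}

#' Zero the image background by Otsu thresholding
#'
#' @param img a [fiber_image()] with nonzero dynamic range.
#' @return [fiber_image()] with background voxels set to zero and the
#'   foreground mask stored in the `mask` slot.
#' @export
zero_background_otsu <- function(img) {
  thr <- otsu_threshold(as.vector(img$voxels))
  mask <- img$voxels > thr
  out <- img
  out$voxels[!mask] <- 0
  out$mask <- mask
  fi_record(out, "zero_background_otsu", list(threshold = thr))
}

#' 3D contrast-limited adaptive histogram equalization
#'
#' CLAHE in 3D tiles with trilinear blending of per-tile mappings. Each
#' tile's histogram is computed over its own min-max range (the adaptive
#' range), clipped at `clip_limit` of the tile mass with uniform
#' redistribution, and turned into a CDF mapping to `[0, 1]`. Background
#' zeros are preserved as zeros.
#'
#' @param img a [fiber_image()] with nonempty foreground.
#' @param tile_um tile size in micrometre (default 16).
#' @param clip_limit clip fraction of the tile histogram mass (default 0.01).
#' @param nbins histogram bins per tile.
#' @return enhanced [fiber_image()] with values in `[0, 1]`.
#' @export
enhance_contrast_clahe3d <- function(img, tile_um = 16, clip_limit = 0.01,
                                     nbins = 64) {
  mask <- fi_mask(img)
  if (!any(mask)) stop("empty foreground")
  d <- dim(img$voxels)
  nt <- pmax(1L, as.integer(round(d * img$spacing / tile_um)))
  # tile centres along each axis, in voxel units
  centers <- lapply(1:3, function(ax) (seq_len(nt[ax]) - 0.5) * d[ax] / nt[ax] - 0.5)
  tile_of <- lapply(1:3, function(ax)
    pmin(nt[ax], pmax(1L, ceiling(seq_len(d[ax]) / (d[ax] / nt[ax])))))
  v <- as.vector(img$voxels)
  tz <- tile_of[[1]][slice.index(img$voxels, 1)]
  ty <- tile_of[[2]][slice.index(img$voxels, 2)]
  tx <- tile_of[[3]][slice.index(img$voxels, 3)]
  tid <- as.vector(tz + nt[1] * ((ty - 1) + nt[2] * (tx - 1)))
  ntiles <- prod(nt)
  tmin <- rep(0, ntiles); tmax <- rep(0, ntiles)
  maps <- matrix(0.5, ntiles, nbins)
  for (t in seq_len(ntiles)) {
    vals <- v[tid == t]
    rng <- range(vals)
    tmin[t] <- rng[1]; tmax[t] <- rng[2]
    if (diff(rng) <= 1e-12) next
    b <- pmin(pmax(floor((vals - rng[1]) / diff(rng) * nbins) + 1L, 1L), nbins)
    h <- tabulate(b, nbins)
    cl <- max(1, clip_limit * length(vals))
    excess <- sum(pmax(h - cl, 0))
    h <- pmin(h, cl) + excess / nbins
    cdf <- cumsum(h)
    maps[t, ] <- (cdf - cdf[1]) / max(cdf[nbins] - cdf[1], 1e-12)
  }
  # trilinear blend of the 8 surrounding tile mappings
  gz <- as.vector(slice.index(img$voxels, 1)) - 1
  gy <- as.vector(slice.index(img$voxels, 2)) - 1
  gx <- as.vector(slice.index(img$voxels, 3)) - 1
  fpos <- function(g, ax) {
    if (nt[ax] == 1) return(list(i0 = rep(1L, length(g)), f = rep(0, length(g))))
    step <- d[ax] / nt[ax]
    t <- (g - centers[[ax]][1]) / step
    i0 <- pmin(pmax(floor(t), 0), nt[ax] - 2)
    list(i0 = as.integer(i0) + 1L, f = pmin(pmax(t - i0, 0), 1))
  }
  pz <- fpos(gz, 1); py <- fpos(gy, 2); px <- fpos(gx, 3)
  out_v <- rep(0, length(v))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dz) pz$f else 1 - pz$f) * (if (dy) py$f else 1 - py$f) *
      (if (dx) px$f else 1 - px$f)
    if (all(w == 0)) next
    iz <- pmin(pz$i0 + dz, nt[1]); iy <- pmin(py$i0 + dy, nt[2])
    ix <- pmin(px$i0 + dx, nt[3])
    ct <- iz + nt[1] * ((iy - 1L) + nt[2] * (ix - 1L))
    rngw <- pmax(tmax[ct] - tmin[ct], 1e-12)
    bin <- pmin(pmax(floor((v - tmin[ct]) / rngw * nbins) + 1L, 1L), nbins)
    out_v <- out_v + w * maps[cbind(ct, bin)]
  }
  out <- img
  out$voxels <- array(out_v, dim = d)
  out$voxels[!mask] <- 0
  out$mask <- mask
  fi_record(out, "enhance_contrast_clahe3d",
            list(tile_um = tile_um, clip_limit = clip_limit))
}

#' Rigid transform
#'
#' Pull-back convention: resampling an image with transform `T` evaluates the
#' input at `R (p - center) + center + translation` for every output
#' physical position `p` (micrometre, `(z, y, x)`).
#'
#' @param rotation Euler angles in degrees about the z, y, x axes.
#' @param translation micrometre offsets `(z, y, x)`.
#' @param center rotation centre in micrometre (volume centre by default).
#' @param converged logical flag set by [register_rigid()].
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0), converged = TRUE) {
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center), converged = converged),
            class = "rigid_transform")
}

#' Apply a rigid transform by resampling
#'
#' @param img moving [fiber_image()].
#' @param tf a [rigid_transform()].
#' @param like optional reference image whose grid the output should use.
#' @return resampled [fiber_image()].
#' @export
apply_rigid <- function(img, tf, like = NULL) {
  grid <- if (is.null(like)) img else like
  d <- dim(grid$voxels)
  co <- voxel_coords(d, grid$spacing)
  R <- euler_matrix(tf$rotation)
  pz <- as.vector(co$z) - tf$center[1]
  py <- as.vector(co$y) - tf$center[2]
  px <- as.vector(co$x) - tf$center[3]
  qz <- R[1, 1] * pz + R[1, 2] * py + R[1, 3] * px + tf$center[1] + tf$translation[1]
  qy <- R[2, 1] * pz + R[2, 2] * py + R[2, 3] * px + tf$center[2] + tf$translation[2]
  qx <- R[3, 1] * pz + R[3, 2] * py + R[3, 3] * px + tf$center[3] + tf$translation[3]
  ds <- dim(img$voxels)
  half <- (ds - 1) * img$spacing / 2
  vz <- (qz + half[1]) / img$spacing[1]
  vy <- (qy + half[2]) / img$spacing[2]
  vx <- (qx + half[3]) / img$spacing[3]
  out <- img
  out$voxels <- array(interp_trilinear(img$voxels, vz, vy, vx), dim = d)
  out$spacing <- grid$spacing
  if (!is.null(img$mask)) {
    m <- interp_trilinear(array(as.numeric(img$mask), dim = ds), vz, vy, vx)
    out$mask <- array(m > 0.5, dim = d)
  }
  fi_record(out, "apply_rigid",
            list(rotation = tf$rotation, translation = tf$translation))
}

mutual_information <- function(a, b, bins = 32) {
  ra <- range(a); rb <- range(b)
  if (diff(ra) <= 0 || diff(rb) <= 0) return(0)
  ia <- pmin(pmax(floor((a - ra[1]) / diff(ra) * bins) + 1L, 1L), bins)
  ib <- pmin(pmax(floor((b - rb[1]) / diff(rb) * bins) + 1L, 1L), bins)
  p <- matrix(tabulate(ia + bins * (ib - 1L), bins * bins), bins) / length(a)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  sum(p[nz] * log(p[nz] / (pa[nz[, 1]] * pb[nz[, 2]])))
}

#' Registration similarity metric
#'
#' Mutual information (32 bins by default) between a reference image and a
#' transformed moving image on the reference grid.
#'
#' @param reference,moving [fiber_image()]s on a common grid.
#' @param tf optional [rigid_transform()] applied to `moving` first.
#' @param bins histogram bins.
#' @return scalar mutual information (nats).
#' @export
registration_similarity <- function(reference, moving, tf = NULL, bins = 32) {
  if (!is.null(tf)) moving <- apply_rigid(moving, tf, like = reference)
  mutual_information(as.vector(reference$voxels), as.vector(moving$voxels),
                     bins = bins)
}

cog_um <- function(img) {
  m <- pmax(img$voxels, 0)
  tot <- sum(m)
  if (tot <= 0) return(c(0, 0, 0))
  co <- voxel_coords(dim(img$voxels), img$spacing)
  c(sum(co$z * m), sum(co$y * m), sum(co$x * m)) / tot
}

#' Rigid registration to a canonical reference
#'
#' Default method maximizes a 32-bin mutual-information metric over a
#' multi-resolution schedule (coarse-to-fine, up to `levels` levels, at most
#' `iterations` optimizer iterations per level) after centre-of-gravity
#' initialization. The `"pca"` method aligns foreground principal axes and
#' centroids in a single step and is provided as a fast alternative. If the
#' optimized transform does not improve the similarity over the identity the
#' identity is returned with a warning and `converged = FALSE`.
#'
#' @param moving,reference [fiber_image()]s standardized to a common spacing.
#' @param method `"mi"` or `"pca"`.
#' @param levels,iterations,bins see [standardization_config()].
#' @return a [rigid_transform()].
#' @export
register_rigid <- function(moving, reference, method = c("mi", "pca"),
                           levels = 6, iterations = 600, bins = 32) {
  method <- match.arg(method)
  stopifnot(max(abs(moving$spacing - reference$spacing)) < 1e-9)
  if (method == "pca") return(register_pca(moving, reference))
  init_t <- cog_um(moving) - cog_um(reference)
  par <- c(0, 0, 0, init_t)
  d <- dim(reference$voxels)
  max_f <- max(1, floor(min(d) / 16))
  factors <- sort(unique(pmin(2^((levels - 1):0), max_f)), decreasing = TRUE)
  score <- function(par, ref_l, mov_l) {
    tf <- rigid_transform(par[1:3], par[4:6])
    -registration_similarity(ref_l, mov_l, tf, bins = bins)
  }
  first <- TRUE
  for (f in factors) {
    if (f > 1) {
      ref_l <- resample_isotropic(reference, reference$spacing[1] * f)
      mov_l <- resample_isotropic(moving, moving$spacing[1] * f)
    } else {
      ref_l <- reference; mov_l <- moving
    }
    if (first) {
      # coarse exhaustive sweep over rotations (fibers arrive roughly
      # pre-aligned; +-15 degrees covers the residual misorientation)
      grid <- seq(-15, 15, by = 5)
      best <- score(par, ref_l, mov_l)
      for (rz in grid) for (ry in grid) for (rx in grid) {
        cand <- c(rz, ry, rx, par[4:6])
        v <- score(cand, ref_l, mov_l)
        if (v < best) { best <- v; par <- cand }
      }
      first <- FALSE
    }
    opt <- optim(par, score, ref_l = ref_l, mov_l = mov_l,
                 method = "Nelder-Mead",
                 control = list(maxit = iterations,
                                parscale = c(5, 5, 5, 2, 2, 2)))
    par <- opt$par
  }
  tf <- rigid_transform(par[1:3], par[4:6])
  base <- registration_similarity(reference, moving, NULL, bins = bins)
  fit <- registration_similarity(reference, moving, tf, bins = bins)
  if (!is.finite(fit) || fit < base) {
    warning("rigid registration did not improve similarity; returning identity")
    return(rigid_transform(converged = FALSE))
  }
  tf
}

register_pca <- function(moving, reference) {
  axes <- function(img) {
    m <- fi_mask(img)
    co <- voxel_coords(dim(img$voxels), img$spacing)
    P <- cbind(co$z[m], co$y[m], co$x[m])
    mu <- colMeans(P)
    e <- eigen(stats::cov(P), symmetric = TRUE)
    V <- e$vectors
    for (j in 1:3) if (V[j, j] < 0) V[, j] <- -V[, j]
    if (det(V) < 0) V[, 3] <- -V[, 3]
    list(mu = mu, V = V)
  }
  am <- axes(moving); ar <- axes(reference)
  # the principal frame is defined up to proper sign flips; take the
  # candidate rotation nearest the identity (fibers arrive roughly aligned)
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  R <- NULL; best_tr <- -Inf
  for (s in signs) {
    Rc <- (am$V %*% diag(s)) %*% t(ar$V)
    if (sum(diag(Rc)) > best_tr) { best_tr <- sum(diag(Rc)); R <- Rc }
  }
  # Euler angles matching euler_matrix (Rz %*% Ry %*% Rx on (z,y,x) triples)
  ry <- asin(max(-1, min(1, R[1, 3])))
  rz <- atan2(-R[2, 3], R[3, 3])
  rx <- atan2(-R[1, 2], R[1, 1])
  rigid_transform(c(rz, ry, rx) * 180 / pi, am$mu - ar$mu)
}

#' Build a presence-probability atlas from registered masks
#'
#' Voxelwise mean of binarized foreground masks; the value at a voxel is the
#' fraction of cohort fibers present there.
#'
#' @param masks list of >= 2 logical arrays on a common grid.
#' @return numeric array with values in `[0, 1]`.
#' @export
build_presence_atlas <- function(masks) {
  stopifnot(length(masks) >= 2)
  d <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), d)) stop("grid mismatch between masks")
  Reduce(`+`, lapply(masks, function(m) array(as.numeric(m > 0), dim = d))) /
    length(masks)
}

#' Bounding box of high-presence voxels
#'
#' @param atlas probability array from [build_presence_atlas()].
#' @param threshold presence probability (strictly exceeded).
#' @return list of per-axis index ranges (`zlim`, `ylim`, `xlim`).
#' @export
probability_box <- function(atlas, threshold = 0.85) {
  w <- which(atlas > threshold, arr.ind = TRUE)
  if (nrow(w) == 0)
    stop("no voxel exceeds the atlas threshold; lower the threshold")
  list(zlim = range(w[, 1]), ylim = range(w[, 2]), xlim = range(w[, 3]))
}

#' Crop an image to the probability bounding box
#'
#' @param img a [fiber_image()].
#' @param atlas probability atlas on the same grid (or a precomputed box via
#'   `box`).
#' @param threshold presence threshold.
#' @param box optional list from [probability_box()], applied identically to
#'   all cohort images.
#' @return cropped [fiber_image()].
#' @export
crop_to_probability_box <- function(img, atlas = NULL, threshold = 0.85,
                                    box = NULL) {
  if (is.null(box)) box <- probability_box(atlas, threshold)
  out <- img
  out$voxels <- img$voxels[box$zlim[1]:box$zlim[2], box$ylim[1]:box$ylim[2],
                           box$xlim[1]:box$xlim[2], drop = FALSE]
  if (!is.null(img$mask))
    out$mask <- img$mask[box$zlim[1]:box$zlim[2], box$ylim[1]:box$ylim[2],
                         box$xlim[1]:box$xlim[2], drop = FALSE]
  fi_record(out, "crop_to_probability_box", list(box = box))
}

#' Sample-wise standard score
#'
#' Normalizes the image to zero mean and unit standard deviation. The
#' statistics are computed over foreground voxels only (the background is an
#' exact zero by construction after Otsu zeroing, and would otherwise
#' dominate the score); background voxels are left at zero.
#'
#' @param img a [fiber_image()] with nonzero variance.
#' @param foreground_only compute statistics over the foreground mask.
#' @return standardized [fiber_image()].
#' @export
standard_score <- function(img, foreground_only = TRUE) {
  mask <- if (foreground_only) fi_mask(img) else array(TRUE, dim(img$voxels))
  v <- img$voxels[mask]
  s <- sd(v) * sqrt((length(v) - 1) / length(v))  # population sd
  if (!is.finite(s) || s <= 0) stop("zero variance: standard score undefined")
  out <- img
  out$voxels[mask] <- (v - mean(v)) / s
  out$voxels[!mask] <- 0
  fi_record(out, "standard_score", list(foreground_only = foreground_only))
}

#' Standardize a cohort of fiber images
#'
#' Runs the full pipeline against a canonical reference fiber: the
#' CLAHE-enhanced copies of reference and moving image are used to estimate
#' the rigid transform, which is then applied to the non-enhanced image. The
#' presence atlas and crop box are built from all registered masks and
#' applied identically to every image.
#'
#' @param images list of [fiber_image()]s.
#' @param reference canonical reference [fiber_image()] (e.g. a clean
#'   synthetic fiber generated axis-aligned).
#' @param config a [standardization_config()].
#' @param labbook optional path of a JSONL labbook to append to.
#' @return list with `images` (standardized), `atlas`, `box`, `transforms`.
#' @export
standardize_cohort <- function(images, reference,
                               config = standardization_config(),
                               labbook = NULL) {
  prep <- function(im) {
    im <- resample_isotropic(im, config$target_spacing)
    im <- denoise_median(im, config$median_size)
    zero_background_otsu(im)
  }
  ref <- prep(reference)
  ref_enh <- if (config$enhancement) enhance_contrast_clahe3d(ref) else ref
  regs <- vector("list", length(images))
  tfs <- vector("list", length(images))
  for (i in seq_along(images)) {
    im <- prep(images[[i]])
    est_src <- if (config$enhancement) enhance_contrast_clahe3d(im) else im
    tf <- register_rigid(est_src, ref_enh, method = config$register_method,
                         levels = config$levels,
                         iterations = config$iterations)
    reg <- apply_rigid(im, tf, like = ref)
    reg$meta$history[[length(reg$meta$history)]]$params$estimated_on <-
      if (config$enhancement) "enhanced" else "non-enhanced"
    regs[[i]] <- reg
    tfs[[i]] <- tf
    if (!is.null(labbook))
      labbook_append(labbook, list(
        stage = "standardize", sample_id = im$meta$sample_id,
        steps = fi_steps(reg), rotation = tf$rotation,
        translation = tf$translation, converged = tf$converged,
        checksum = array_checksum(reg$voxels)))
  }
  atlas <- build_presence_atlas(lapply(regs, fi_mask))
  box <- probability_box(atlas, config$atlas_threshold)
  out <- lapply(regs, function(im)
    standard_score(crop_to_probability_box(im, box = box)))
  list(images = out, atlas = atlas, box = box, transforms = tfs)
}
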