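# Handcrafted muscle-fiber biomarkers used as priors: cosine angle sum (CAS,
# 2D and 3D), sarcomere length (SL), vernier density (VD), and a robust
# "smart" cross-sectional area (CSA) combining three estimators.

#' Prior vector of handcrafted biomarkers
#'
#' @param cas2d,cas3d cosine angle sums (dimensionless, 1 = parallel).
#' @param vd vernier density in defects per square micrometre.
#' @param sl sarcomere length in micrometre.
#' @param csa cross-sectional area in square micrometre.
#' @param diagnostics optional list (e.g. from [csa_smart()]).
#' @return object of class `prior_vector`; unavailable priors are `NA` with
#'   the corresponding `available` flag `FALSE`.
#' @export
prior_vector <- function(cas2d = NA_real_, cas3d = NA_real_, vd = NA_real_,
                         sl = NA_real_, csa = NA_real_, diagnostics = NULL) {
  vals <- c(cas2d = cas2d, cas3d = cas3d, vd = vd, sl = sl, csa = csa)
  structure(list(values = vals, available = !is.na(vals),
                 diagnostics = diagnostics),
            class = "prior_vector")
}

#' @export
print.prior_vector <- function(x, ...) {
  cat("<prior_vector>\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Names of the prior biomarkers
#' @return character vector.
#' @export
prior_names <- function() c("cas2d", "cas3d", "vd", "sl", "csa")

#' Per-voxel orientation field from structure-tensor analysis
#'
#' Gradients are taken at a fixed derivative scale of 0.5 um; the tensor is
#' averaged at the Gaussian integration scale `scale`. The per-voxel
#' orientation is the dominant eigenvector (the banding normal, canonicalized
#' to a nonnegative component along the fiber main axis y) obtained by
#' vectorized power iteration; coherence measures the eigenvalue gap,
#' `(lambda1 - mean(lambda2, lambda3)) / trace`, scaled to `[0, 1]`.
#'
#' @param img a [fiber_image()].
#' @param scale integration scale in micrometre (default 1).
#' @param mask optional foreground mask; defaults to the image mask. The
#'   mask is eroded before sampling so the fiber surface gradient does not
#'   contaminate the interior banding orientation.
#' @return object of class `orientation_field` with matrix `vectors`
#'   (rows = voxels, columns z/y/x), `coherence`, and voxel indices.
#' @export
estimate_orientations <- function(img, scale = 1, mask = NULL) {
  if (is.null(mask)) mask <- fi_mask(img)
  if (!any(mask)) stop("empty foreground")
  sp <- img$spacing
  sig_d <- 0.5 / sp
  sig_i <- scale / sp
  sm <- blur_gaussian3(img$voxels, sig_d)
  gz <- diff_axis3(sm, 1) / sp[1]
  gy <- diff_axis3(sm, 2) / sp[2]
  gx <- diff_axis3(sm, 3) / sp[3]
  J <- list(zz = blur_gaussian3(gz * gz, sig_i),
            yy = blur_gaussian3(gy * gy, sig_i),
            xx = blur_gaussian3(gx * gx, sig_i),
            zy = blur_gaussian3(gz * gy, sig_i),
            zx = blur_gaussian3(gz * gx, sig_i),
            yx = blur_gaussian3(gy * gx, sig_i))
  # erode the mask so boundary gradients are excluded
  er <- blur_gaussian3(array(as.numeric(mask), dim(mask)), 2 / sp) > 0.97
  if (sum(er) < 20) er <- mask
  idx <- which(er)
  jzz <- J$zz[idx]; jyy <- J$yy[idx]; jxx <- J$xx[idx]
  jzy <- J$zy[idx]; jzx <- J$zx[idx]; jyx <- J$yx[idx]
  vz <- rep(0.3, length(idx)); vy <- rep(1, length(idx)); vx <- rep(0.5, length(idx))
  for (it in 1:30) {
    wz <- jzz * vz + jzy * vy + jzx * vx
    wy <- jzy * vz + jyy * vy + jyx * vx
    wx <- jzx * vz + jyx * vy + jxx * vx
    nrm <- sqrt(wz^2 + wy^2 + wx^2) + 1e-30
    vz <- wz / nrm; vy <- wy / nrm; vx <- wx / nrm
  }
  lam1 <- jzz * vz^2 + jyy * vy^2 + jxx * vx^2 +
    2 * (jzy * vz * vy + jzx * vz * vx + jyx * vy * vx)
  tr <- jzz + jyy + jxx
  coh <- pmin(pmax((lam1 - (tr - lam1) / 2) / (tr + 1e-30), 0), 1)
  sgn <- ifelse(vy < 0, -1, 1)
  orientation_field(cbind(z = vz * sgn, y = vy * sgn, x = vx * sgn),
                    coherence = coh, voxels = idx, dim = dim(img$voxels),
                    spacing = sp)
}

#' Construct an orientation field directly
#'
#' Used both by [estimate_orientations()] and to build fields from known
#' orientation draws when validating alignment statistics against closed
#' forms.
#'
#' @param vectors numeric matrix, one unit orientation vector per row in
#'   `(z, y, x)` component order.
#' @param coherence per-vector coherence in `[0, 1]`.
#' @param voxels,dim,spacing optional provenance of the sampled voxels.
#' @return object of class `orientation_field`.
#' @export
orientation_field <- function(vectors, coherence = rep(1, nrow(vectors)),
                              voxels = NULL, dim = NULL, spacing = NULL) {
  vectors <- as.matrix(vectors)
  stopifnot(ncol(vectors) == 3, all(coherence >= 0), all(coherence <= 1.0001))
  nrm <- sqrt(rowSums(vectors^2))
  vectors <- vectors / pmax(nrm, 1e-12)
  structure(list(vectors = vectors, coherence = pmin(coherence, 1),
                 voxels = voxels, dim = dim, spacing = spacing,
                 axis = c(0, 1, 0)),
            class = "orientation_field")
}

#' Cosine angle sum
#'
#' Mean cosine of the angle between the local orientation and the fiber main
#' axis, over the foreground voxels of the volume (3D) or of one z-plane
#' (2D). 1 means perfect alignment. For a field whose angles are von Mises
#' distributed with concentration `kappa` the expectation is the Bessel
#' ratio `I1(kappa)/I0(kappa)` ([vonmises_mean_cos()]).
#'
#' @param field an [orientation_field()].
#' @param mode `"3D"` or `"2D"`.
#' @param plane z index for 2D mode.
#' @param min_voxels below this count the statistic is marked unavailable.
#' @return scalar CAS in `[-1, 1]`, or `NA` when unavailable.
#' @export
cosine_angle_sum <- function(field, mode = c("3D", "2D"), plane = NULL,
                             min_voxels = 100) {
  mode <- match.arg(mode)
  stopifnot(inherits(field, "orientation_field"))
  keep <- seq_len(nrow(field$vectors))
  if (mode == "2D") {
    if (is.null(field$voxels) || is.null(field$dim))
      stop("2D mode requires a field with voxel provenance")
    stopifnot(plane >= 1, plane <= field$dim[1])
    zidx <- ((field$voxels - 1) %% field$dim[1]) + 1
    keep <- which(zidx == plane)
  }
  if (length(keep) < min_voxels) return(NA_real_)
  mean(field$vectors[keep, ] %*% field$axis)
}

#' Sarcomere length from the average axial power spectrum
#'
#' Axial intensity profiles through the fiber foreground are Hann-windowed,
#' zero-padded and Fourier transformed; their average power spectrum is
#' searched for a dominant peak in the physiological band, with sub-bin
#' refinement by parabolic interpolation of the log power. The peak must
#' exceed `peak_factor` times the in-band median power, otherwise the value
#' is unavailable.
#'
#' @param img a [fiber_image()].
#' @param mask optional foreground mask.
#' @param range_um admissible period band in micrometre (default 1.5-4).
#' @param peak_factor detection threshold over the noise floor (default 2;
#'   isotropic noise yields ratios near 1, dispersed fibers 2.5 and above).
#' @return sarcomere length in micrometre, or `NA` when no credible peak.
#' @export
sarcomere_length <- function(img, mask = NULL, range_um = c(1.5, 4),
                             peak_factor = 2) {
  if (is.null(mask)) mask <- fi_mask(img)
  d <- dim(img$voxels)
  frac <- apply(mask, c(1, 3), mean)
  cols <- which(frac >= 0.9, arr.ind = TRUE)
  if (nrow(cols) == 0) cols <- which(frac >= 0.5, arr.ind = TRUE)
  if (nrow(cols) == 0) return(NA_real_)
  if (nrow(cols) > 400) cols <- cols[seq(1, nrow(cols), length.out = 400), , drop = FALSE]
  lines <- matrix(0, d[2], nrow(cols))
  for (j in seq_len(nrow(cols)))
    lines[, j] <- img$voxels[cols[j, 1], , cols[j, 2]]
  lines <- sweep(lines, 2, colMeans(lines))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(d[2]) / (d[2] + 1))
  lines <- lines * win
  nfft <- 2^ceiling(log2(2 * d[2]))
  lines <- rbind(lines, matrix(0, nfft - d[2], ncol(lines)))
  pw <- rowMeans(Mod(mvfft(lines))^2)
  freq <- (seq_len(nfft) - 1) / (nfft * img$spacing[2])
  band <- which(freq >= 1 / range_um[2] & freq <= 1 / range_um[1])
  if (length(band) < 3) return(NA_real_)
  pk <- band[which.max(pw[band])]
  floor_p <- median(pw[band])
  if (pw[pk] < peak_factor * floor_p) return(NA_real_)
  # parabolic sub-bin refinement on log power
  if (pk > 1 && pk < nfft) {
    lp <- log(pw[(pk - 1):(pk + 1)] + 1e-300)
    denom <- lp[1] - 2 * lp[2] + lp[3]
    delta <- if (abs(denom) > 1e-12) 0.5 * (lp[1] - lp[3]) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
  } else delta <- 0
  f_star <- (pk - 1 + delta) / (nfft * img$spacing[2])
  1 / f_star
}

shift2 <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# branch points of a 2D skeleton: skeleton pixels with >= 3 skeleton
# neighbours in 8-connectivity
branch_points <- function(skel) {
  nb <- Reduce(`+`, lapply(list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                                c(0, 1), c(1, -1), c(1, 0), c(1, 1)),
                           function(o) shift2(skel, o[1], o[2])))
  which(skel == 1L & nb >= 3, arr.ind = TRUE)
}

#' Vernier density
#'
#' Verniers are Y-shaped phase dislocations in the sarcomere banding. Each
#' z-slice with substantial foreground is band-pass filtered at the banding
#' frequency `1/SL`, the positive-phase crests are skeletonized, and
#' skeleton branch points away from the fiber surface are collected. Since a
#' vernier is a dislocation line through the fiber depth, detections are
#' projected to the `(y, x)` plane and merged within one banding period; a
#' defect must be detected in at least two slices. The count is normalized
#' by the mean foreground slice area.
#'
#' @param img a [fiber_image()].
#' @param sl sarcomere length in micrometre (from [sarcomere_length()]).
#' @param mask optional foreground mask.
#' @param max_slices cap on the number of analyzed slices (evenly strided).
#' @return density in defects per square micrometre, or `NA` when `sl` is
#'   unavailable. The defect count is attached as attribute `count`.
#' @export
vernier_density <- function(img, sl, mask = NULL, max_slices = 24) {
  if (is.na(sl)) return(NA_real_)
  if (is.null(mask)) mask <- fi_mask(img)
  d <- dim(img$voxels)
  sp <- img$spacing
  areas <- apply(mask, 1, sum)
  sel <- which(areas >= 0.3 * max(areas))
  if (length(sel) > max_slices)
    sel <- sel[unique(as.integer(seq(1, length(sel), length.out = max_slices)))]
  f0 <- 1 / sl
  ny <- d[2]
  freq <- (seq_len(ny) - 1) / (ny * sp[2])
  freq_sym <- pmin(freq, 1 / sp[2] - freq)
  bandw <- exp(-((freq_sym - f0) / (0.25 * f0))^2)
  brush <- EBImage::makeBrush(5, shape = "disc")
  pts <- NULL
  for (z in sel) {
    M <- matrix(img$voxels[z, , ], d[2], d[3])
    fg <- matrix(as.numeric(mask[z, , ]), d[2], d[3])
    filt <- Re(mvfft(mvfft(M) * bandw, inverse = TRUE)) / ny
    interior <- EBImage::erode(fg, brush)
    crest <- (filt > 0) & (interior > 0.5)
    skel <- .thin2d_cpp(matrix(as.integer(crest), d[2], d[3]))
    bp <- branch_points(skel)
    if (nrow(bp) > 0)
      pts <- rbind(pts, cbind(z * sp[1], (bp[, 1] - 1) * sp[2],
                              (bp[, 2] - 1) * sp[3]))
  }
  mean_area <- mean(areas[sel]) * sp[2] * sp[3]
  if (is.null(pts) || nrow(pts) == 0) {
    out <- 0
    attr(out, "count") <- 0L
    return(out)
  }
  # defects are through-depth line dislocations: project detections to the
  # (y, x) plane and merge within one banding period
  sc <- cbind(pts[, 2] / sl, pts[, 3] / sl)
  cl <- if (nrow(sc) == 1) 1L else
    cutree(hclust(dist(sc, method = "maximum"), method = "single"), h = 1)
  sizes <- table(cl)
  count <- sum(sizes >= 2)
  out <- count / mean_area
  attr(out, "count") <- as.integer(count)
  out
}

retained_slices <- function(mask, exclude = 10) {
  ny <- dim(mask)[2]
  keep <- seq_len(ny)
  keep <- keep[keep > exclude & keep <= ny - exclude]
  keep
}

#' Cross-sectional area, algorithm 1: exact pixel counting
#'
#' The fiber is assumed vertically oriented (main axis y, as guaranteed by
#' registration). The top and bottom 10 slices along the axis are excluded;
#' each remaining slice is cleaned by 2D morphological opening then closing
#' with a disk of 1 um radius, and the foreground pixel count times the
#' pixel area is averaged over slices.
#'
#' @param mask logical 3D foreground array `(z, y, x)`.
#' @param spacing voxel spacing in micrometre.
#' @param exclude slices dropped at each end of the axis (default 10).
#' @return area in square micrometre, `NA` if fewer than 3 slices remain.
#' @export
csa_exact_counting <- function(mask, spacing = c(0.5, 0.5, 0.5), exclude = 10) {
  keep <- retained_slices(mask, exclude)
  if (length(keep) < 3) return(NA_real_)
  r <- max(1L, round(1 / spacing[1]))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  px_area <- spacing[1] * spacing[3]
  vals <- vapply(keep, function(j) {
    sl <- matrix(as.numeric(mask[, j, ]), dim(mask)[1], dim(mask)[3])
    sl <- EBImage::closing(EBImage::opening(sl, brush), brush)
    sum(sl > 0.5) * px_area
  }, 1)
  mean(vals)
}

slice_points_um <- function(mask, j, spacing) {
  w <- which(mask[, j, ], arr.ind = TRUE)
  cbind(w[, 1] * spacing[1], w[, 2] * spacing[3])
}

#' Cross-sectional area, algorithm 2: principal-component ellipse
#'
#' Per retained slice, the 2D PCA radii of the foreground pixel cloud give
#' an ellipse area `pi * r_max * r_min` with the uniform-ellipse
#' second-moment convention `radius = 2 * sqrt(eigenvalue)`, which is
#' unbiased for solid ellipses. Degenerate slices are skipped.
#'
#' @inheritParams csa_exact_counting
#' @return area in square micrometre, `NA` if unavailable.
#' @export
csa_pca_ellipse <- function(mask, spacing = c(0.5, 0.5, 0.5), exclude = 10) {
  keep <- retained_slices(mask, exclude)
  if (length(keep) < 3) return(NA_real_)
  vals <- vapply(keep, function(j) {
    P <- slice_points_um(mask, j, spacing)
    if (nrow(P) < 10) return(NA_real_)
    ev <- eigen(stats::cov(P), symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 1e-9)) return(NA_real_)
    pi * prod(2 * sqrt(ev))
  }, 1)
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Cross-sectional area, algorithm 3: robust elliptic envelope
#'
#' Per retained slice, an iteratively trimmed covariance ellipse covering
#' the `1 - contamination` most central foreground pixels is fitted
#' (Mahalanobis trimming, 5 rounds). For a uniform solid ellipse the
#' trimmed-eigenvalue area must be rescaled by the coverage fraction `q`:
#' the central `q` mass of a uniform ellipse has covariance `q` times the
#' full one, so `area = 4 * pi * sqrt(lambda1 * lambda2) / q`, making the
#' clean-input estimate unbiased while gross outliers below the breakdown
#' fraction are trimmed away.
#'
#' @inheritParams csa_exact_counting
#' @param contamination trimmed fraction (default 0.2).
#' @return area in square micrometre, `NA` if unavailable.
#' @export
csa_elliptic_envelope <- function(mask, spacing = c(0.5, 0.5, 0.5),
                                  exclude = 10, contamination = 0.2) {
  keep <- retained_slices(mask, exclude)
  if (length(keep) < 3) return(NA_real_)
  q <- 1 - contamination
  vals <- vapply(keep, function(j) {
    P <- slice_points_um(mask, j, spacing)
    if (nrow(P) < 20) return(NA_real_)
    if (nrow(P) > 3000) P <- P[seq(1, nrow(P), length.out = 3000), ]
    sel <- seq_len(nrow(P))
    for (it in 1:5) {
      mu <- colMeans(P[sel, , drop = FALSE])
      S <- stats::cov(P[sel, , drop = FALSE])
      if (any(!is.finite(S)) || det(S) <= 1e-12) return(NA_real_)
      dd <- stats::mahalanobis(P, mu, S)
      sel <- order(dd)[seq_len(ceiling(q * nrow(P)))]
    }
    S_trim <- stats::cov(P[sel, , drop = FALSE])
    ev <- eigen(S_trim, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 1e-9)) return(NA_real_)
    # coverage self-calibration: the trimmed set is the central q fraction
    # of ALL points; when gross outliers were trimmed the effective inlier
    # coverage exceeds q. Count points inside the implied ellipse boundary
    # (Mahalanobis 4/q_eff for a uniform ellipse, 10% margin) and solve for
    # the coverage by fixed-point iteration, so clean and contaminated
    # slices are both estimated without bias.
    dd <- stats::mahalanobis(P, colMeans(P[sel, , drop = FALSE]), S_trim)
    q_eff <- q
    for (it in 1:10) {
      n_in <- sum(dd <= 1.1 * 4 / q_eff)
      q_eff <- min(1, q * nrow(P) / max(n_in, 1))
    }
    4 * pi * sqrt(prod(ev)) / q_eff
  }, 1)
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Smart cross-sectional area: concordance of three estimators
#'
#' Computes all three CSA algorithms and returns the mean of the pair with
#' the smallest absolute difference, discarding the outlier. With only one
#' successful algorithm that value is returned with a low-confidence flag;
#' with none, the result is unavailable.
#'
#' @inheritParams csa_exact_counting
#' @return list with `value`, `low_confidence`, and `diagnostics` (all three
#'   estimates, the pair used, the discarded one).
#' @export
csa_smart <- function(mask, spacing = c(0.5, 0.5, 0.5), exclude = 10) {
  est <- c(exact = csa_exact_counting(mask, spacing, exclude),
           pca = csa_pca_ellipse(mask, spacing, exclude),
           envelope = csa_elliptic_envelope(mask, spacing, exclude))
  ok <- which(!is.na(est))
  if (length(ok) == 0)
    return(list(value = NA_real_, low_confidence = TRUE,
                diagnostics = list(estimates = est)))
  if (length(ok) == 1)
    return(list(value = unname(est[ok]), low_confidence = TRUE,
                diagnostics = list(estimates = est, used = names(est)[ok])))
  best <- smart_pair(est)
  list(value = mean(est[best]), low_confidence = FALSE,
       diagnostics = list(estimates = est, used = names(est)[best],
                          discarded = setdiff(names(est)[ok], names(est)[best])))
}

# indices of the concordant pair: minimum absolute difference, first pair on
# ties (pairs enumerated in index order)
smart_pair <- function(est) {
  ok <- which(!is.na(est))
  pairs <- utils::combn(ok, 2)
  diffs <- abs(est[pairs[1, ]] - est[pairs[2, ]])
  pairs[, which.min(diffs)]
}

#' Compute the full prior vector for one fiber image
#'
#' Assembles CAS (2D on the centre z-plane, and 3D), SL, VD and smart CSA
#' with per-prior availability flags; unavailability of one prior never
#' aborts the others (VD depends on SL by construction).
#'
#' @param img a [fiber_image()], standardized or freshly generated (the
#'   foreground mask is taken from the image, falling back to Otsu).
#' @param scale structure-tensor integration scale in micrometre.
#' @return a [prior_vector()].
#' @export
compute_priors <- function(img, scale = 1) {
  mask <- fi_mask(img)
  cas2d <- cas3d <- NA_real_
  if (sum(mask) >= 100) {
    field <- estimate_orientations(img, scale = scale, mask = mask)
    cas3d <- cosine_angle_sum(field, "3D")
    zcounts <- tabulate(((field$voxels - 1) %% field$dim[1]) + 1,
                        nbins = field$dim[1])
    center <- round(dim(img$voxels)[1] / 2)
    if (zcounts[center] < 100 && any(zcounts >= 100))
      center <- which.max(zcounts)
    cas2d <- cosine_angle_sum(field, "2D", plane = center)
  }
  sl <- sarcomere_length(img, mask = mask)
  vd <- vernier_density(img, sl, mask = mask)
  smart <- csa_smart(mask, spacing = img$spacing)
  prior_vector(cas2d = cas2d, cas3d = cas3d, vd = as.numeric(vd), sl = sl,
               csa = smart$value,
               diagnostics = list(csa = smart$diagnostics,
                                  vernier_count = attr(vd, "count")))
}

#' Priors table for a cohort
#'
#' @param cohort a [make_cohort()] result with in-memory images, or a list
#'   of [fiber_image()]s.
#' @param scale structure-tensor scale in micrometre.
#' @return data.frame with `sample_id`, the five priors, and availability
#'   flags (`<prior>_available`).
#' @export
priors_table <- function(cohort, scale = 1) {
  images <- if (inherits(cohort, "fiber_cohort")) cohort$images else cohort
  stopifnot(!is.null(images))
  rows <- lapply(seq_along(images), function(i) {
    pv <- compute_priors(images[[i]], scale = scale)
    id <- images[[i]]$meta$sample_id
    if (is.na(id)) id <- sprintf("S%03d", i)
    out <- data.frame(sample_id = id, t(pv$values))
    for (nm in prior_names()) out[[paste0(nm, "_available")]] <- pv$available[[nm]]
    out
  })
  do.call(rbind, rows)
}
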