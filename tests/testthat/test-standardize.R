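test_that("isotropic resampling follows extent arithmetic and preserves content", {
  img <- fiber_image(array(rnorm(100 * 250 * 250), c(100, 250, 250)),
                     c(0.5, 0.2, 0.2))
  out <- resample_isotropic(img, 0.5)
  expect_equal(dim(out$voxels), c(100, 100, 100))
  expect_equal(out$spacing, rep(0.5, 3))
  # physical extent preserved within one voxel per axis
  expect_true(all(abs(dim(out$voxels) * 0.5 - dim(img$voxels) * img$spacing) <= 0.5))
  # aligned grid: exact identity
  img2 <- fiber_image(array(rnorm(20 * 30 * 30), c(20, 30, 30)), rep(0.5, 3))
  expect_equal(max(abs(resample_isotropic(img2, 0.5)$voxels - img2$voxels)), 0)
  # constant image stays constant
  img3 <- fiber_image(array(3.7, c(20, 20, 20)), c(0.4, 0.4, 0.4))
  expect_lt(max(abs(resample_isotropic(img3, 0.5)$voxels - 3.7)), 1e-12)
  expect_error(resample_isotropic(
    fiber_image(array(0, c(1, 10, 10)), rep(0.5, 3)), 0.5), "degenerate")
})

test_that("median denoising removes impulses, keeps constants, rounds to odd windows", {
  arr <- array(1, c(20, 20, 20)); arr[10, 10, 10] <- 100
  img <- fiber_image(arr, rep(0.5, 3))
  out <- denoise_median(img, 1)
  expect_equal(out$voxels[10, 10, 10], 1)
  expect_true(all(out$voxels == 1))
  # window rule: 1 um at 0.5 um spacing -> odd 3-voxel window
  h <- out$meta$history[[length(out$meta$history)]]
  expect_equal(h$params$window, c(3L, 3L, 3L))
  # size below spacing leaves the axis untouched
  out2 <- denoise_median(fiber_image(arr, c(2, 0.5, 0.5)), 1)
  h2 <- out2$meta$history[[length(out2$meta$history)]]
  expect_equal(h2$params$window[1], 1L)
})

test_that("Otsu zeroing recovers a bimodal foreground and is scale invariant", {
  set.seed(3)
  truth_mask <- array(FALSE, c(24, 40, 24)); truth_mask[8:16, 10:30, 8:16] <- TRUE
  vox <- array(rnorm(prod(dim(truth_mask)), 0, 1), dim(truth_mask))
  vox[truth_mask] <- rnorm(sum(truth_mask), 10, 1)
  img <- fiber_image(vox, rep(0.5, 3))
  zb <- zero_background_otsu(img)
  dice <- 2 * sum(zb$mask & truth_mask) / (sum(zb$mask) + sum(truth_mask))
  expect_gt(dice, 0.95)
  expect_true(all(zb$voxels[!zb$mask] == 0))
  # bright ellipse on exact-zero background: foreground untouched
  vox2 <- array(0, c(16, 20, 16)); vox2[4:12, 5:15, 4:12] <- 5
  zb2 <- zero_background_otsu(fiber_image(vox2, rep(0.5, 3)))
  expect_equal(zb2$voxels, vox2)
  # threshold scales with a positive intensity scaling: identical mask
  zb3 <- zero_background_otsu(fiber_image(2 * vox, rep(0.5, 3)))
  expect_identical(zb3$mask, zb$mask)
  expect_error(zero_background_otsu(fiber_image(array(1, c(16, 16, 16)),
                                                rep(0.5, 3))), "constant")
})

test_that("3D CLAHE increases banding contrast within [0,1] and keeps zeros", {
  sim <- fixture("lowcontrast_fiber", function() {
    s <- generate_fiber(fiber_spec(semi_axes = c(7, 4.5), snr = 1e5),
                        shape = c(24, 64, 32), seed = 4)
    # squash the banding to modulation ~0.1 around a bright plateau
    v <- s$image$voxels
    v[s$image$mask] <- 1 + (v[s$image$mask] - 1) / 6
    s$image$voxels <- v
    s$image
  })
  enh <- enhance_contrast_clahe3d(sim)
  expect_gte(min(enh$voxels), 0)
  expect_lte(max(enh$voxels), 1)
  expect_true(all(enh$voxels[!sim$mask] == 0))
  gap <- function(img) {
    ctr <- dim(img$voxels) %/% 2
    p <- img$voxels[ctr[1], , ctr[3]]
    diff(range(p[p > 0]))
  }
  expect_gt(gap(enh) / max(enh$voxels), gap(sim) / max(sim$voxels))
  # constant foreground: no spurious contrast
  vox <- array(0, c(16, 24, 16)); vox[4:12, 4:20, 4:12] <- 2
  cimg <- fiber_image(vox, rep(0.5, 3), mask = vox > 0)
  cenh <- enhance_contrast_clahe3d(cimg)
  expect_lt(diff(range(cenh$voxels[vox > 0])), 1e-9)
})

test_that("rigid registration recovers identity and a known rotation", {
  sim <- generate_fiber(fiber_spec(semi_axes = c(6, 4), snr = 10),
                        shape = c(24, 64, 32), seed = 2)
  ref <- zero_background_otsu(sim$image)
  tfi <- register_rigid(ref, ref, method = "mi", levels = 3, iterations = 120)
  expect_lt(max(abs(tfi$rotation)), 0.5)
  expect_lt(max(abs(tfi$translation)), 0.25)  # half a 0.5 um voxel
  mov <- apply_rigid(ref, rigid_transform(rotation = c(10, 0, 0)))
  tf <- register_rigid(mov, ref, method = "mi", levels = 3, iterations = 200)
  expect_lt(abs(tf$rotation[1] - (-10)), 1)
  # optimization contract: similarity never degraded
  expect_gte(registration_similarity(ref, mov, tf),
             registration_similarity(ref, mov))
  # fast principal-axes fallback finds the same rotation coarsely
  tfp <- register_rigid(mov, ref, method = "pca")
  expect_lt(abs(tfp$rotation[1] - (-10)), 2.5)
})

test_that("presence atlas counts masks and the crop box honours the threshold", {
  m <- array(FALSE, c(8, 10, 8)); m[3:6, 3:8, 3:6] <- TRUE
  atlas3 <- build_presence_atlas(list(m, m, m))
  expect_true(all(atlas3 %in% c(0, 1)))
  box <- probability_box(atlas3, 0.85)
  expect_equal(box$zlim, c(3, 6)); expect_equal(box$ylim, c(3, 8))
  # a 5-of-6 fringe voxel (0.833) is excluded at 0.85
  m2 <- m; m2[2, 3, 3] <- TRUE
  atlas6 <- build_presence_atlas(c(rep(list(m2), 5), list(m)))
  expect_equal(atlas6[2, 3, 3], 5 / 6)
  expect_equal(probability_box(atlas6, 0.85)$zlim, c(3, 6))
  # linearity of atlas mass
  expect_equal(sum(atlas6) * 6, 5 * sum(m2) + sum(m))
  # cropping twice is idempotent
  img <- fiber_image(array(rnorm(8 * 10 * 8), c(8, 10, 8)), rep(0.5, 3))
  c1 <- crop_to_probability_box(img, atlas3, 0.85)
  c2 <- crop_to_probability_box(c1, box = list(zlim = c(1, dim(c1$voxels)[1]),
                                               ylim = c(1, dim(c1$voxels)[2]),
                                               xlim = c(1, dim(c1$voxels)[3])))
  expect_equal(c2$voxels, c1$voxels)
  m_shift <- array(FALSE, dim(m)); m_shift[1:2, 1:2, 1:2] <- TRUE
  expect_error(probability_box(build_presence_atlas(list(m, m_shift)), 0.9),
               "threshold")
  expect_error(build_presence_atlas(list(m, m[1:4, , ])), "mismatch")
})

test_that("standard score is exact, affine invariant, and foreground based", {
  set.seed(5)
  vox <- array(rnorm(30^3, 5, 2), c(30, 30, 30))
  img <- fiber_image(vox, rep(0.5, 3), mask = array(TRUE, c(30, 30, 30)))
  out <- standard_score(img)
  expect_lt(abs(mean(out$voxels)), 1e-6)
  expect_lt(abs(sqrt(mean(out$voxels^2)) - 1), 1e-6)
  img2 <- img; img2$voxels <- 3 * vox + 11
  expect_equal(standard_score(img2)$voxels, out$voxels, tolerance = 1e-9)
  expect_error(standard_score(fiber_image(array(2, c(16, 16, 16)), rep(0.5, 3),
                                          mask = array(TRUE, c(16, 16, 16)))),
               "variance")
})

test_that("the pipeline keeps its order and registers on the enhanced copy only", {
  imgs <- lapply(1:3, function(s)
    generate_fiber(fiber_spec(semi_axes = c(6, 4), snr = 8),
                   shape = c(24, 48, 32), seed = s)$image)
  ref <- generate_fiber(fiber_spec(semi_axes = c(6, 4), snr = 30),
                        shape = c(24, 48, 32), seed = 99)$image
  lb <- tempfile(fileext = ".jsonl")
  std <- standardize_cohort(imgs, ref,
                            standardization_config(register_method = "pca"),
                            labbook = lb)
  steps <- fi_steps(std$images[[1]])
  expect_equal(steps[steps != "generate_fiber"],
               c("resample_isotropic", "denoise_median", "zero_background_otsu",
                 "apply_rigid", "crop_to_probability_box", "standard_score"))
  # the enhanced image never enters the output chain
  expect_false("enhance_contrast_clahe3d" %in% steps)
  reg_entry <- Filter(function(h) h$step == "apply_rigid",
                      std$images[[1]]$meta$history)[[1]]
  expect_equal(reg_entry$params$estimated_on, "enhanced")
  # labbook has one entry per image with checksums
  entries <- labbook_read(lb)
  expect_equal(length(entries), 3)
  expect_true(all(vapply(entries, function(e) nzchar(e$checksum), TRUE)))
  # identical crop grid across the cohort
  dims <- vapply(std$images, function(im) dim(im$voxels), integer(3))
  expect_true(all(dims == dims[, 1]))
  # end-to-end determinism
  std2 <- standardize_cohort(imgs, ref,
                             standardization_config(register_method = "pca"))
  expect_equal(std$images[[2]]$voxels, std2$images[[2]]$voxels)
})
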