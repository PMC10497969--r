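test_that("isotropic resampling follows the shape contract", {
  arr <- array(runif(16 * 20 * 20), c(16, 20, 20))
  st <- image_stack(arr, c(1, 0.1099, 0.1099))
  iso <- resample_isotropic(st)
  expect_equal(dim(iso$data)[1], round(16 * 1 / 0.1099))
  expect_equal(iso$voxel_size, rep(0.1099, 3))
  # physical extent preserved within one voxel per axis
  expect_lt(abs(dim(iso$data)[1] * 0.1099 - 16), 0.1099)

  same <- image_stack(array(runif(5^3), c(5, 5, 5)), c(1, 1, 1))
  expect_identical(resample_isotropic(same), same)

  single <- image_stack(array(runif(25), c(1, 5, 5)), c(1, 0.5, 0.5))
  expect_error(resample_isotropic(single), "single-slice")
})

test_that("resampling preserves integrated intensity of a smooth blob", {
  rs <- render_stack(one_ellipsoid(), voxel_size = c(2, 0.5, 0.5),
                     noise = noise_preset("clean"), box = c(24, 24, 24))
  sm <- image_stack(chondrosim:::cpp_gauss_blur(rs$stack$data * 1.0, dim(rs$stack$data),
                                   c(1, 2, 2)),
                    rs$stack$voxel_size, 16L)
  iso <- resample_isotropic(sm)
  tot_in <- sum(sm$data) * prod(sm$voxel_size)
  tot_out <- sum(iso$data) * prod(iso$voxel_size)
  expect_lt(abs(tot_out / tot_in - 1), 0.01)
})

test_that("preprocessing flattens illumination gradients", {
  const <- image_stack(array(500, c(8, 8, 8)), c(1, 1, 1))
  out <- preprocess(const, segmentation_config(stretch = FALSE))
  expect_true(all(abs(out$data) < 1e-6))

  nm <- noise_model(background_level = 0.3, gaussian_sd = 0,
                    illumination_gradient = c(0.8, 0, 0), seed = 5)
  rs <- render_stack(ellipsoid_set(data.frame()), voxel_size = 1, noise = nm,
                     box = rep(48, 3))
  pre <- preprocess(rs$stack, segmentation_config(stretch = FALSE))
  slice_means_in <- apply(rs$stack$data, 1, mean)
  slice_means_out <- apply(pre$data, 1, mean)
  expect_gt(sd(slice_means_in) / max(sd(slice_means_out), 1e-12), 5)
})

test_that("auto-threshold separates the modes and honours polarity", {
  x <- array(10, c(6, 6, 6))
  x[3:4, 3:4, 3:4] <- 200
  st <- image_stack(x, c(1, 1, 1))
  m <- auto_threshold(st)
  expect_equal(m$labels == 1, x == 200)
  inv <- auto_threshold(image_stack(210 - x, c(1, 1, 1)), invert = TRUE)
  expect_equal(inv$labels, m$labels)
  expect_error(auto_threshold(image_stack(array(7, c(4, 4, 4)), c(1, 1, 1))),
               "no threshold")
})

test_that("thresholding a clean rendered stack recovers the cells", {
  fx <- clean_stack(n = 4, box = 56, voxel = 1, seed = 21)
  mask <- auto_threshold(fx$stack)
  inter <- sum(mask$labels > 0 & fx$labels$labels > 0)
  uni <- sum(mask$labels > 0 | fx$labels$labels > 0)
  expect_gt(inter / uni, 0.9)
})

test_that("artifact filters implement the area and volume rules", {
  vs <- c(1, 1, 1)
  # a blob of ~150 um^3 (< 200): removed by the volume filter
  mk <- function(r, center, dims = c(24, 24, 24)) {
    rs <- render_stack(ellipsoid_set(data.frame(label = 1, cx = center[1],
                                                cy = center[2], cz = center[3],
                                                a = r, b = r, c = r)),
                       voxel_size = vs, noise = noise_preset("clean"),
                       box = dims)
    labeled_volume(array(as.integer(rs$labels$labels > 0),
                         dim(rs$labels$labels)), vs)
  }
  small <- mk(3.3, c(12, 12, 12))           # ~150 um^3
  expect_equal(sum(ellipsoid_volumes(ellipsoid_set(data.frame(
    label = 1, cx = 0, cy = 0, cz = 0, a = 3.3, b = 3.3, c = 3.3)))) < 200,
    TRUE)
  out <- filter_artifacts(small)
  expect_equal(sum(out$labels), 0L)

  # one gigantic flat slab: slice area 400 um^2 -> removed slice-wise
  slab <- array(0L, c(10, 30, 30))
  slab[5, 6:25, 6:25] <- 1L                  # 400 voxels = 400 um^2
  out2 <- filter_artifacts(labeled_volume(slab, vs))
  expect_equal(sum(out2$labels), 0L)

  # a 250 um^3 blob whose largest slice is ~80 um^2: retained
  keep <- mk(3.9, c(12, 12, 12))             # ~248 um^3, max slice ~ 48 um^2
  vol_in <- sum(keep$labels)
  out3 <- filter_artifacts(keep)
  expect_equal(sum(out3$labels), vol_in)

  # idempotence
  fx <- clean_stack(n = 3, box = 56, voxel = 1, seed = 13)
  m1 <- filter_artifacts(auto_threshold(fx$stack))
  m2 <- filter_artifacts(m1)
  expect_identical(m1$labels, m2$labels)
})

test_that("distance-transform watershed separates touching cells", {
  two <- ellipsoid_set(data.frame(label = 1:2, cx = c(14, 26), cy = 20,
                                  cz = 20, a = 8, b = 8, c = 8))
  rs <- render_stack(two, voxel_size = 0.5, noise = noise_preset("clean"),
                     box = rep(40, 3))
  mask <- labeled_volume(array(as.integer(rs$labels$labels > 0),
                               dim(rs$labels$labels)), rep(0.5, 3))
  sp <- split_cells(mask)
  expect_equal(max(sp$labels), 2L)
  for (k in 1:2) {
    idx <- which(sp$labels == k, arr.ind = TRUE)
    com_x <- (mean(idx[, 3]) - 0.5) * 0.5
    expect_lt(min(abs(com_x - c(14, 26))), 2)
  }
  # labels never leave the filled mask
  filled <- chondrosim:::cpp_fill_holes(array(as.integer(mask$labels), dim(mask$labels)),
                           dim(mask$labels))
  expect_true(all(sp$labels[filled == 0] == 0))

  one <- split_cells(labeled_volume(
    render_stack(one_ellipsoid(8, 7, 6, c(12, 12, 12)), 1,
                 noise_preset("clean"), box = c(24, 24, 24))$labels$labels,
    c(1, 1, 1)))
  expect_equal(max(one$labels), 1L)

  none <- split_cells(labeled_volume(array(0L, c(6, 6, 6)), c(1, 1, 1)))
  expect_equal(max(none$labels), 0L)
})

test_that("moment-based ellipsoid fitting recovers shape and orientation", {
  rs <- render_stack(one_ellipsoid(), voxel_size = 0.5,
                     noise = noise_preset("clean"), box = c(24, 24, 24))
  fit <- fit_ellipsoids(rs$labels)
  expect_equal(nrow(fit), 1L)
  expect_lt(abs(fit$a / 10 - 1), 0.05)
  expect_lt(abs(fit$b / 8 - 1), 0.05)
  expect_lt(abs(fit$c / 6 - 1), 0.05)
  vol_vox <- sum(rs$labels$labels > 0) * 0.5^3
  expect_lt(abs(ellipsoid_volumes(fit) / vol_vox - 1), 1e-10)

  # sphere: all three semi-axes equal within 3%
  sph <- render_stack(one_ellipsoid(8, 8, 8), voxel_size = 0.5,
                      noise = noise_preset("clean"), box = c(24, 24, 24))
  fs <- fit_ellipsoids(sph$labels)
  expect_lt(fs$a / fs$c - 1, 0.03)

  # rotated ellipsoid: principal axis recovered within 5 degrees
  rot <- ellipsoid_set(data.frame(label = 1, cx = 14, cy = 14, cz = 14,
                                  a = 10, b = 6, c = 6,
                                  phi = 0.6, theta = 0.4, psi = 0.2))
  rr <- render_stack(rot, voxel_size = 0.5, noise = noise_preset("clean"),
                     box = c(28, 28, 28))
  fr <- fit_ellipsoids(rr$labels)
  axis_true <- euler_rotation(0.6, 0.4, 0.2)[, 1]
  axis_fit <- euler_rotation(fr$phi, fr$theta, fr$psi)[, 1]
  ang <- acos(min(abs(sum(axis_true * axis_fit)), 1)) * 180 / pi
  expect_lt(ang, 5)

  # volume identity across several labels
  fx <- clean_stack(n = 4, box = 56, voxel = 1, seed = 17)
  fits <- fit_ellipsoids(fx$labels)
  expect_equal(sum(ellipsoid_volumes(fits)),
               sum(fx$labels$labels > 0) * 1, tolerance = 1e-10)
})

test_that("degenerate labels are skipped with a warning", {
  lab <- array(0L, c(6, 6, 6))
  lab[3, 3, 3] <- 1L                 # 1 voxel
  lab[1:5, 1, 1] <- 2L               # collinear support
  expect_warning(fit <- fit_ellipsoids(labeled_volume(lab, c(1, 1, 1))),
                 "skipped")
  expect_false(1L %in% fit$label)
})

test_that("threshold and distance transform agree with independent 2D oracles", {
  # EBImage works slice-wise in 2D and serves as the independent reference
  set.seed(99)
  img <- matrix(runif(64 * 64, 0, 0.3), 64, 64)
  img[20:40, 25:45] <- img[20:40, 25:45] + 0.6
  st <- image_stack(array(img * 65535, c(1, 64, 64)), c(1, 1, 1))
  thr_pkg <- chondrosim:::otsu_threshold(as.vector(st$data)) / 65535
  thr_ref <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  # any threshold inside the empty inter-mode gap is a valid Otsu optimum;
  # the resulting masks must agree
  expect_identical(img > thr_pkg, img > thr_ref)

  mask2d <- matrix(0L, 32, 32)
  mask2d[8:24, 10:20] <- 1L
  edt_pkg <- chondrosim:::cpp_edt(array(mask2d, c(1, 32, 32)),
                                  c(1L, 32L, 32L), c(1e6, 1, 1))
  edt_ref <- EBImage::distmap(EBImage::Image(mask2d), metric = "euclidean")
  expect_lt(max(abs(edt_pkg[1, , ] - edt_ref@.Data)), 1e-6)
})
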