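test_that("iso-surface of a voxelised sphere matches analytic measures", {
  rs <- render_stack(one_ellipsoid(10, 10, 10, c(13, 13, 13)),
                     voxel_size = 0.5, noise = noise_preset("clean"),
                     box = rep(26, 3))
  m <- extract_surface_mesh(rs$labels)[[1]]
  expect_true(is_watertight(m))
  expect_equal(mesh_components(m), 1L)
  expect_lt(abs(mesh_volume(m) / (4 / 3 * pi * 1000) - 1), 0.02)
  expect_lt(abs(mesh_area(m) / (4 * pi * 100) - 1), 0.05)
})

test_that("degenerate and multi-label cases stay closed", {
  lab <- array(0L, c(6, 6, 6))
  lab[3, 3, 3] <- 1L
  m <- extract_surface_mesh(labeled_volume(lab, c(1, 1, 1)),
                            smooth_sigma = 0)[[1]]
  expect_true(is_watertight(m))
  expect_gt(mesh_volume(m), 0)
  expect_lt(mesh_volume(m), 2)   # about one voxel volume

  lab2 <- array(0L, c(10, 10, 18))
  lab2[4:6, 4:6, 3:5] <- 1L
  lab2[4:6, 4:6, 12:14] <- 2L
  ms <- extract_surface_mesh(labeled_volume(lab2, c(1, 1, 1)),
                             smooth_sigma = 0)
  expect_equal(length(ms), 2L)
  expect_true(all(vapply(ms, is_watertight, TRUE)))
  # a label touching the volume border still closes (padding)
  lab3 <- array(0L, c(6, 6, 6))
  lab3[1:3, 1:3, 1:3] <- 1L
  mb <- extract_surface_mesh(labeled_volume(lab3, c(1, 1, 1)),
                             smooth_sigma = 0)[[1]]
  expect_true(is_watertight(mb))
})

test_that("marching the raw binary field reproduces the voxel volume", {
  rs <- render_stack(one_ellipsoid(), voxel_size = 0.5,
                     noise = noise_preset("clean"), box = rep(24, 3))
  m <- extract_surface_mesh(rs$labels, smooth_sigma = 0)[[1]]
  vol_vox <- sum(rs$labels$labels > 0) * 0.5^3
  expect_lt(abs(mesh_volume(m) / vol_vox - 1), 0.02)
})

test_that("Taubin smoothing preserves volume better than pure Laplacian", {
  rs <- render_stack(one_ellipsoid(10, 10, 10, c(13, 13, 13)),
                     voxel_size = 0.5, noise = noise_preset("clean"),
                     box = rep(26, 3))
  m <- extract_surface_mesh(rs$labels, smooth_sigma = 0)[[1]]
  expect_identical(taubin_smooth(m, iterations = 0), m)
  expect_identical(taubin_smooth(m, lambda = 0), m)
  v0 <- mesh_volume(m)
  taub <- taubin_smooth(m, 0.5, -0.53, 10)
  lapl <- taubin_smooth(m, 0.5, 0, 10)
  expect_lt(abs(mesh_volume(taub) - v0), abs(mesh_volume(lapl) - v0))
  expect_identical(taub$faces, m$faces)
  expect_equal(mesh_components(taub), mesh_components(m))
})

test_that("quadric decimation respects the face budget and fidelity envelope", {
  rs <- render_stack(one_ellipsoid(10, 10, 10, c(13, 13, 13)),
                     voxel_size = 0.5, noise = noise_preset("clean"),
                     box = rep(26, 3))
  m <- taubin_smooth(extract_surface_mesh(rs$labels)[[1]], 0.5, -0.53, 5)
  expect_gt(nrow(m$faces), 20000)
  expect_identical(decimate(m, nrow(m$faces)), m)
  dm <- decimate(m, 2000)
  expect_lte(nrow(dm$faces), 2000)
  expect_true(is_watertight(dm))
  expect_equal(mesh_components(dm), 1L)
  expect_lt(abs(mesh_volume(dm) / mesh_volume(m) - 1), 0.05)
  expect_lt(abs(mesh_area(dm) / mesh_area(m) - 1), 0.15)
})

test_that("fidelity report returns signed percentage errors", {
  rs <- render_stack(one_ellipsoid(6, 6, 6, c(8, 8, 8)), voxel_size = 0.5,
                     noise = noise_preset("clean"), box = rep(16, 3))
  m <- extract_surface_mesh(rs$labels)[[1]]
  r0 <- mesh_fidelity_report(m, mesh_volume(m), mesh_area(m))
  expect_equal(r0$volume_error_pct, 0)
  expect_equal(r0$area_error_pct, 0)
  ms <- m; ms$vertices <- ms$vertices * 1.01
  r1 <- mesh_fidelity_report(ms, mesh_volume(m), mesh_area(m))
  expect_equal(r1$volume_error_pct, 100 * (1.01^3 - 1), tolerance = 1e-8)
  expect_equal(r1$area_error_pct, 100 * (1.01^2 - 1), tolerance = 1e-8)
})

test_that("STL round-trips watertight meshes", {
  rs <- render_stack(one_ellipsoid(6, 5, 4, c(8, 8, 8)), voxel_size = 0.5,
                     noise = noise_preset("clean"), box = rep(16, 3))
  m <- extract_surface_mesh(rs$labels)[[1]]
  path <- tempfile(fileext = ".stl")
  write_stl(m, path)
  back <- read_stl(path)
  expect_equal(nrow(back$faces), nrow(m$faces))
  expect_true(is_watertight(back))
  expect_equal(mesh_volume(back), mesh_volume(m), tolerance = 1e-6)
  unlink(path)
})
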