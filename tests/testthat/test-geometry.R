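test_that("intersection graph counts all logical pair checks", {
  one <- one_ellipsoid()
  g1 <- build_intersection_graph(one)
  expect_equal(g1$n_checks, 0)
  expect_equal(nrow(g1$edges), 0L)

  cells <- sample_population(20, rep(80, 3), seed = 5)
  expect_equal(build_intersection_graph(cells)$n_checks, 190)
})

test_that("unit spheres touch at centre distance below the radius sum", {
  near <- ellipsoid_set(data.frame(label = 1:2, cx = c(0, 1.5), cy = 0,
                                   cz = 0, a = 1, b = 1, c = 1))
  expect_equal(nrow(build_intersection_graph(near)$edges), 1L)
  far <- ellipsoid_set(data.frame(label = 1:2, cx = c(0, 3), cy = 0,
                                  cz = 0, a = 1, b = 1, c = 1))
  expect_equal(nrow(build_intersection_graph(far)$edges), 0L)
  # containment also counts as intersection
  inside <- ellipsoid_set(data.frame(label = 1:2, cx = 0, cy = 0, cz = 0,
                                     a = c(3, 1), b = c(3, 1), c = c(3, 1)))
  expect_equal(nrow(build_intersection_graph(inside)$edges), 1L)
})

test_that("a three-sphere ring yields exactly one filler sphere", {
  ang <- 2 * pi * (0:2) / 3
  ring <- ellipsoid_set(data.frame(label = 1:3,
                                   cx = 10 + 5.5 * cos(ang),
                                   cy = 10 + 5.5 * sin(ang),
                                   cz = 10, a = 5, b = 5, c = 5))
  g <- build_intersection_graph(ring)
  expect_equal(nrow(g$edges), 3L)
  fill <- detect_and_fill_voids(g, ring)
  expect_equal(nrow(fill), 1L)
  expect_false(fill$needs_review)
  # the filler covers the central gap: the ring centre was uncovered before
  ctr <- c(10, 10, 10)
  expect_true(all(ellipsoid_coordinate(ring[1, ], rbind(ctr)) > 1))
  expect_lt(sqrt(sum((c(fill$cx, fill$cy, fill$cz) - ctr)^2)), 2)
  expect_gt(fill$r, 5.5 - 5)   # at least the in-plane gap radius

  # after filling, background flood fill reaches every non-cell voxel
  withfill <- voxelize_geometry(cells = ring, box = rep(22, 3),
                                voxel_size = 0.5, fillers = fill)
  mask <- withfill$materials
  filled <- chondrosim:::cpp_fill_holes(mask, dim(mask))
  expect_identical(as.vector(filled), as.vector(mask))
})

test_that("chains and disjoint cells produce no fillers", {
  chain <- ellipsoid_set(data.frame(label = 1:2, cx = c(10, 16), cy = 10,
                                    cz = 10, a = 5, b = 5, c = 5))
  expect_equal(nrow(detect_and_fill_voids(build_intersection_graph(chain),
                                          chain)), 0L)
  disj <- ellipsoid_set(data.frame(label = 1:3, cx = c(0, 20, 40), cy = 0,
                                   cz = 0, a = 5, b = 5, c = 5))
  expect_equal(nrow(detect_and_fill_voids(build_intersection_graph(disj),
                                          disj)), 0L)
})

test_that("voxelised geometry fuses intersecting cells without inner walls", {
  none <- voxelize_geometry(cells = ellipsoid_set(data.frame()),
                            box = rep(10, 3), voxel_size = 1)
  expect_equal(sum(none$materials), 0L)
  expect_equal(nrow(none$faces), 0L)

  # single centred sphere: corrected membrane area approaches 4 pi R^2
  geom <- sphere_geometry(R = 8, L = 40, n = 40)  # 20 voxels per diameter
  expect_lt(abs(membrane_area(geom) / (4 * pi * 64) - 1), 0.15)
  # the raw staircase area is far above the corrected one (documented bias)
  expect_gt(membrane_area(geom, corrected = FALSE), membrane_area(geom))

  pair <- ellipsoid_set(data.frame(label = 1:2, cx = c(16, 24), cy = 20,
                                   cz = 20, a = 6, b = 6, c = 6))
  gp <- voxelize_geometry(cells = pair, box = rep(40, 3), voxel_size = 1)
  # all faces separate cytoplasm from buffer; the shared wall is gone
  d <- dim(gp$materials)
  for (r in seq_len(nrow(gp$faces))) {
    f <- gp$faces[r, ]
    lo <- c(f$iz, f$iy, f$ix)
    hi <- lo; hi[f$axis] <- hi[f$axis] + 1
    expect_equal(gp$materials[matrix(lo, 1)] + gp$materials[matrix(hi, 1)], 1L)
  }
})

test_that("cells outside the box are clipped with a warning", {
  big <- ellipsoid_set(data.frame(label = 1, cx = 2, cy = 10, cz = 10,
                                  a = 5, b = 5, c = 5))
  expect_warning(g <- voxelize_geometry(cells = big, box = rep(22, 3),
                                        voxel_size = 1), "clipped")
  expect_gt(sum(g$materials), 0)
})

test_that("refinement preserves the discrete shape and membrane measures", {
  geom <- sphere_geometry(R = 8, L = 40, n = 16)
  fine <- refine_geometry(geom, 2)
  expect_equal(dim(fine$materials), c(32L, 32L, 32L))
  expect_equal(volume_fraction(fine), volume_fraction(geom))
  expect_equal(membrane_area(fine), membrane_area(geom), tolerance = 1e-12)
  expect_equal(membrane_area(fine, corrected = FALSE),
               membrane_area(geom, corrected = FALSE), tolerance = 1e-12)
})

test_that("voxelised volume ratio converges to the analytic ratio", {
  va <- 4 / 3 * pi * 8^3 / 40^3
  errs <- sapply(c(20, 40), function(n)
    abs(volume_fraction(sphere_geometry(R = 8, L = 40, n = n)) / va - 1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.02)
})
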