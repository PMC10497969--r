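test_that("population sampling honours the volume distribution and seed", {
  expect_equal(nrow(sample_population(0, c(10, 10, 10))), 0L)

  cells <- sample_population(500, rep(400, 3), seed = 42)
  v <- ellipsoid_volumes(cells)
  # mean within 3 standard errors of the 2157 +/- 957 population values
  expect_lt(abs(mean(v) - 2157), 3 * 957 / sqrt(500))
  expect_equal(cells$label, 1:500)
  expect_true(all(cells$a >= cells$b & cells$b >= cells$c))
  expect_true(all(cells$a / cells$c >= 1 & cells$a / cells$c <= 2 + 1e-9))

  again <- sample_population(500, rep(400, 3), seed = 42)
  expect_identical(cells, again)
  other <- sample_population(500, rep(400, 3), seed = 43)
  expect_false(identical(cells, other))
})

test_that("placement fails loudly when the box cannot host the cells", {
  expect_error(sample_population(4, c(18, 18, 18), allow_touching = FALSE,
                                 seed = 1),
               "placement failure|too small")
})

test_that("rendering produces exact ground truth labels", {
  empty <- render_stack(ellipsoid_set(data.frame()), voxel_size = 1,
                        noise = noise_preset("clean"), box = c(8, 8, 8))
  expect_true(all(empty$labels$labels == 0))
  expect_equal(length(unique(as.vector(empty$stack$data))), 1L)

  rs <- render_stack(one_ellipsoid(), voxel_size = 0.5,
                     noise = noise_preset("clean"), box = c(24, 24, 24))
  vol <- sum(rs$labels$labels > 0) * 0.5^3
  expect_lt(abs(vol / (4 / 3 * pi * 480) - 1), 0.02)

  aniso <- render_stack(one_ellipsoid(), voxel_size = c(1, 0.1099, 0.1099),
                        noise = noise_preset("clean"), box = c(24, 24, 24))
  vola <- sum(aniso$labels$labels > 0) * prod(aniso$labels$voxel_size)
  expect_lt(abs(vola / (4 / 3 * pi * 480) - 1), 0.05)
})

test_that("every labelled voxel centre lies inside its generating ellipsoid", {
  cells <- sample_population(4, rep(48, 3), seed = 3)
  rs <- render_stack(cells, voxel_size = 1, noise = noise_preset("clean"),
                     box = rep(48, 3))
  lab <- rs$labels$labels
  d <- dim(lab)
  idx <- which(lab > 0)
  iz <- (idx - 1) %% d[1]
  iy <- ((idx - 1) %/% d[1]) %% d[2]
  ix <- (idx - 1) %/% (d[1] * d[2])
  pts <- cbind((ix + 0.5), (iy + 0.5), (iz + 0.5))  # voxel = 1 um
  for (k in unique(lab[idx])) {
    sel <- lab[idx] == k
    m <- ellipsoid_coordinate(cells[cells$label == k, ],
                              pts[sel, , drop = FALSE])
    expect_true(all(m <= 1 + 1e-12))
  }
})

test_that("ground-truth volume converges to the analytic volume", {
  va <- 4 / 3 * pi * 480
  errs <- sapply(c(1, 0.5), function(h) {
    rs <- render_stack(one_ellipsoid(), voxel_size = h,
                       noise = noise_preset("clean"), box = c(24, 24, 24))
    abs(sum(rs$labels$labels > 0) * h^3 - va) / va
  })
  expect_lt(errs[2], errs[1] / 2 + 1e-4)
})

test_that("rendering is deterministic and refuses oversized stacks", {
  nm <- noise_preset("very-noisy", seed = 9)
  a <- render_stack(one_ellipsoid(), 1, nm, box = c(24, 24, 24))
  b <- render_stack(one_ellipsoid(), 1, nm, box = c(24, 24, 24))
  expect_identical(a$stack$data, b$stack$data)
  expect_error(render_stack(one_ellipsoid(), 0.01,
                            noise_preset("clean"), box = c(24, 24, 24)),
               "refusing")
})

test_that("population summary reports counts, volumes and ratio", {
  cells <- one_ellipsoid(a = 5, b = 5, c = 5)
  s <- population_summary(cells, box = c(20, 20, 20))
  expect_equal(s$count, 1L)
  expect_equal(s$volume_ratio, 100 * (4 / 3 * pi * 125) / 8000)
  e <- population_summary(ellipsoid_set(data.frame()), box = c(10, 10, 10))
  expect_equal(e$count, 0L)
  expect_equal(e$volume_ratio, 0)
  expect_error(population_summary(cells, box = c(0, 0, 0)), "box volume")

  # box constructed for a 4% target ratio recovers that ratio
  pop <- sample_population(500, rep(400, 3), seed = 7)
  target_box <- rep((sum(ellipsoid_volumes(pop)) / 0.04)^(1 / 3), 3)
  s2 <- population_summary(pop, box = target_box)
  expect_lt(abs(s2$volume_ratio - 4), 0.5)
})
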