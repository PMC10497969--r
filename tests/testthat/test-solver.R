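props <- material_props()

test_that("homogeneous buffer reduces to the parallel-plate closed form", {
  geom <- voxelize_geometry(cells = ellipsoid_set(data.frame()),
                            box = rep(100, 3), voxel_size = 100 / 8,
                            electrode_axis = "x")
  for (f in c(0, 1e3, 1e8)) {
    sys <- assemble_system(geom, props, 2 * pi * f)
    fld <- solve_potential(sys)
    z <- compute_impedance(fld, sys)
    zth <- (100e-6) / ((props$sigma_buf +
                          2i * pi * f * 8.854e-12 * props$eps_rbuf) *
                         (100e-6)^2)
    expect_lt(Mod(z - zth) / Mod(zth), 1e-3)
    # potential varies linearly between the plates
    phi <- Re(fld$phi)
    prof <- apply(phi, 3, mean)
    lin <- (seq_len(8) - 0.5) / 8
    expect_lt(max(abs(prof - lin)), 1e-8)
  }
})

test_that("the assembled operator is complex-symmetric", {
  geom <- sphere_geometry(R = 3, L = 10, n = 8)
  sys <- assemble_system(geom, props, 2 * pi * 1e6)
  A <- system_matrix(sys)
  expect_lt(max(Mod(A - t(A))), 1e-18)
  expect_false(isTRUE(all.equal(A, Conj(t(A)))))  # not Hermitian
})

test_that("an insulating membrane at DC blocks current into the cell", {
  geom <- sphere_geometry(R = 3, L = 10, n = 10)
  pr0 <- material_props(sigma_m = 0)
  sys <- assemble_system(geom, pr0, 0)
  # every membrane-face branch admittance is exactly zero
  d <- dim(geom$materials)
  cyt <- geom$materials > 0
  for (ax in 1:3) {
    n <- d[ax]
    m1 <- chondrosim:::slice_index(cyt, ax, seq_len(n - 1))
    m2 <- chondrosim:::slice_index(cyt, ax, seq(2, n))
    b <- list(sys$bz, sys$by, sys$bx)[[ax]]
    expect_true(all(Mod(b[m1 != m2]) == 0))
  }
})

test_that("plate currents balance and scale linearly with voltage", {
  geom <- sphere_geometry(R = 8, L = 40, n = 24)
  sys <- assemble_system(geom, props, 2 * pi * 1e5)
  fld <- solve_potential(sys)
  z1 <- compute_impedance(fld, sys)
  expect_lt(attr(z1, "current_mismatch"), 1e-6)
  sys2 <- assemble_system(geom, props, 2 * pi * 1e5, v_applied = 2)
  fld2 <- solve_potential(sys2)
  z2 <- compute_impedance(fld2, sys2)
  expect_equal(as.complex(z1), as.complex(z2), tolerance = 1e-8)
  expect_equal(Mod(fld2$phi[5, 5, 5]), 2 * Mod(fld$phi[5, 5, 5]),
               tolerance = 1e-6)
})

test_that("interior node currents are conserved", {
  geom <- sphere_geometry(R = 3, L = 10, n = 10)
  sys <- assemble_system(geom, props, 2 * pi * 1e6)
  fld <- solve_potential(sys)
  resid <- chondrosim:::cpp_grid_matvec(sys$dim, sys$bz, sys$by, sys$bx,
                                        as.vector(sys$diagextra),
                                        as.vector(fld$phi)) -
    as.vector(sys$rhs)
  ymax <- max(Mod(sys$diagextra) + 1e-30, Mod(sys$bz), Mod(sys$by),
              Mod(sys$bx))
  expect_lt(max(Mod(resid)) / ymax, 1e-8)
})

test_that("the default frequency grid spans 1 kHz to 1 THz at 91 points", {
  f <- frequency_grid()
  expect_equal(length(f), 91L)
  expect_equal(f[1], 1e3)
  expect_equal(f[91], 1e12)
  expect_equal(diff(log10(f)), rep(0.1, 90), tolerance = 1e-12)
})

test_that("Re(Z) decreases with frequency for the shelled-cell geometry", {
  geom <- sphere_geometry(R = 8, L = 40, n = 24)
  sp <- frequency_sweep(geom, props, frequencies = 10^seq(3, 9, by = 1),
                        tol = 1e-9)
  expect_true(all(diff(Re(sp$Z)) <= 1e-8 * Re(sp$Z[1])))
  # symmetric geometry: potential antisymmetric about the mid-plane
  sys <- assemble_system(geom, props, 2 * pi * 1e3)
  fld <- solve_potential(sys)
  phi <- fld$phi - 0.5
  flipped <- phi[, , rev(seq_len(dim(phi)[3]))]
  expect_lt(max(Mod(phi + flipped)), 1e-6)
})

test_that("transmembrane potential follows the Schwan low-frequency limit", {
  R <- 8; L <- 40
  geom <- sphere_geometry(R = R, L = L, n = 64)
  sys <- assemble_system(geom, props, 2 * pi * 1e3)
  fld <- solve_potential(sys)
  tmp <- transmembrane_potential(fld, geom)
  E <- 1 / (L * 1e-6)
  expect_lt(abs(max(abs(tmp$re_tmp_v)) / (1.5 * E * R * 1e-6) - 1), 0.1)
  # antisymmetric across the equatorial plane normal to the field
  pole_hi <- tmp$re_tmp_v[which.max(tmp$x_um)]
  pole_lo <- tmp$re_tmp_v[which.min(tmp$x_um)]
  expect_lt(abs(pole_hi + pole_lo) / max(abs(tmp$re_tmp_v)), 0.05)

  none <- voxelize_geometry(cells = ellipsoid_set(data.frame()),
                            box = rep(10, 3), voxel_size = 1)
  sn <- assemble_system(none, props, 0)
  expect_equal(nrow(transmembrane_potential(solve_potential(sn), none)), 0L)
})

test_that("refining the discretisation shrinks the impedance change", {
  base <- sphere_geometry(R = 8, L = 40, n = 8)
  zs <- vapply(c(1, 2, 4), function(f) {
    g <- refine_geometry(base, f)
    sys <- assemble_system(g, props, 2 * pi * 1e6)
    Mod(compute_impedance(solve_potential(sys, tol = 1e-10), sys))
  }, 0)
  expect_lt(abs(zs[3] - zs[2]), abs(zs[2] - zs[1]))
})
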