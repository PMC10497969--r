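#' Dielectric material properties of the tissue components
#'
#' Default values describe a chondrocyte suspension in culture medium: a
#' nearly insulating plasma membrane (sigma_m = 8.7e-6 S/m, eps_rm = 5.8,
#' 7 nm thick, treated as a thin interfacial layer), conductive cytoplasm
#' (0.48 S/m, eps 60) and buffer (1 S/m, eps 80).
#'
#' @param sigma_m,sigma_cyt,sigma_buf conductivities, S/m.
#' @param eps_rm,eps_rcyt,eps_rbuf relative permittivities.
#' @param d_m membrane thickness, m.
#' @return a `material_props` list.
#' @export
material_props <- function(sigma_m = 8.7e-6, sigma_cyt = 0.48,
                           sigma_buf = 1, eps_rm = 5.8, eps_rcyt = 60,
                           eps_rbuf = 80, d_m = 7e-9) {
  stopifnot(sigma_m >= 0, sigma_cyt >= 0, sigma_buf >= 0,
            eps_rm >= 1, eps_rcyt >= 1, eps_rbuf >= 1, d_m > 0)
  structure(list(sigma_m = sigma_m, sigma_cyt = sigma_cyt,
                 sigma_buf = sigma_buf, eps_rm = eps_rm,
                 eps_rcyt = eps_rcyt, eps_rbuf = eps_rbuf, d_m = d_m),
            class = "material_props")
}

# complex admittivity kappa = sigma + j omega eps0 eps_r
kappa <- function(sigma, eps_r, omega) complex(real = sigma,
                                               imaginary = omega * EPS0 * eps_r)

#' Assemble the electro-quasistatic admittance network
#'
#' Finite-volume discretisation of `div((sigma + j omega eps) grad phi) = 0`
#' on the voxel grid: one node per voxel centre, a branch admittance
#' `y = kappa A / d` between adjacent voxels (series combination of the two
#' half-voxel admittances), and on every membrane face an additional series
#' thin-layer element `y_m = kappa_m A_face corr / d_m` representing the
#' 7 nm membrane, which is far below any resolvable voxel size. Dirichlet
#' plates (potential 0 and `v_applied`) sit on the two box faces normal to
#' the electrode axis and couple to the adjacent voxel layer through
#' half-voxel branches.
#'
#' @param geom a `tissue_geometry`.
#' @param props a [material_props()].
#' @param omega angular frequency, rad/s (`omega = 0` is pure conduction).
#' @param v_applied plate voltage, V.
#' @return an `eqs_system` (branch arrays, Dirichlet data, right-hand side).
#' @export
assemble_system <- function(geom, props, omega, v_applied = 1) {
  stopifnot(omega >= 0)
  d <- dim(geom$materials)
  h <- geom$voxel_size * UM            # (z, y, x), m
  cyt <- geom$materials > 0
  km <- kappa(props$sigma_m, props$eps_rm, omega)
  kv <- array(ifelse(cyt, kappa(props$sigma_cyt, props$eps_rcyt, omega),
                     kappa(props$sigma_buf, props$eps_rbuf, omega)), d)
  areas <- c(h[2] * h[3], h[1] * h[3], h[1] * h[2])
  branch <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2) { branch[[ax]] <- complex(0); next }
    k1 <- slice_index(kv, ax, seq_len(n - 1))
    k2 <- slice_index(kv, ax, seq(2, n))
    base <- h[ax] / (2 * areas[ax])
    imp <- base / k1 + base / k2
    m1 <- slice_index(cyt, ax, seq_len(n - 1))
    m2 <- slice_index(cyt, ax, seq(2, n))
    dif <- m1 != m2
    if (any(dif)) {
      corr <- array(1, dim(k1))
      fx <- geom$faces[geom$faces$axis == ax, , drop = FALSE]
      if (nrow(fx)) {
        dd <- dim(k1)
        lin <- (fx$ix - 1) * dd[1] * dd[2] + (fx$iy - 1) * dd[1] + fx$iz
        corr[lin] <- pmax(fx$corr, 1e-6)
      }
      if (Mod(km) > 0) {
        imp[dif] <- imp[dif] + props$d_m / (km * areas[ax] * corr[dif])
      } else {
        imp[dif] <- Inf   # perfectly insulating membrane limit
      }
    }
    y <- 1 / imp
    y[!is.finite(Re(y)) | !is.finite(Im(y))] <- 0
    branch[[ax]] <- array(y, dim(k1))
  }
  axid <- match(geom$electrode_axis, c("z", "y", "x"))
  n_ax <- d[axid]
  diagextra <- array(complex(real = 0), d)
  rhs <- array(complex(real = 0), d)
  k_lo <- slice_index(kv, axid, 1L)
  k_hi <- slice_index(kv, axid, n_ax)
  y_lo <- 2 * k_lo * areas[axid] / h[axid]
  y_hi <- 2 * k_hi * areas[axid] / h[axid]
  idx_lo <- slice_assign_index(d, axid, 1L)
  idx_hi <- slice_assign_index(d, axid, n_ax)
  diagextra[idx_lo] <- diagextra[idx_lo] + as.vector(y_lo)
  diagextra[idx_hi] <- diagextra[idx_hi] + as.vector(y_hi)
  rhs[idx_hi] <- rhs[idx_hi] + as.vector(y_hi) * v_applied
  structure(list(dim = d, bz = branch[[1]], by = branch[[2]],
                 bx = branch[[3]], diagextra = diagextra, rhs = rhs,
                 plate0 = list(idx = idx_lo, y = as.vector(y_lo)),
                 plateV = list(idx = idx_hi, y = as.vector(y_hi)),
                 v_applied = v_applied, omega = omega,
                 electrode_axis = geom$electrode_axis,
                 voxel_size = geom$voxel_size, box = geom$box),
            class = "eqs_system")
}

# linear indices of a full slice at position i along one axis
slice_assign_index <- function(d, axis, i) {
  grid <- switch(axis,
                 expand.grid(iz = i, iy = seq_len(d[2]), ix = seq_len(d[3])),
                 expand.grid(iz = seq_len(d[1]), iy = i, ix = seq_len(d[3])),
                 expand.grid(iz = seq_len(d[1]), iy = seq_len(d[2]), ix = i))
  (grid$ix - 1) * d[1] * d[2] + (grid$iy - 1) * d[1] + grid$iz
}

#' Dense matrix of a small assembled system
#'
#' Builds the full complex system matrix column by column through the
#' operator; intended for structural checks on tiny grids only.
#'
#' @param system an `eqs_system`.
#' @return complex matrix.
#' @export
system_matrix <- function(system) {
  n <- prod(system$dim)
  stopifnot(n <= 4096)
  A <- matrix(complex(real = 0), n, n)
  for (j in seq_len(n)) {
    e <- complex(real = numeric(n))
    e[j] <- 1
    A[, j] <- cpp_grid_matvec(system$dim, system$bz, system$by, system$bx,
                              as.vector(system$diagextra), e)
  }
  A
}

#' Solve the assembled system for the potential field
#'
#' Conjugate Orthogonal Conjugate Gradient (COCG) iteration with a Jacobi
#' preconditioner, zero initial guess and deterministic ordering, run to a
#' relative residual of `tol`.
#'
#' @param system an `eqs_system`.
#' @param tol relative residual tolerance.
#' @param maxit iteration cap.
#' @return a `potential_field`: complex `phi` array (V), `omega`,
#'   `residual_norm`, `iterations`.
#' @export
solve_potential <- function(system, tol = 1e-10, maxit = 50000L) {
  res <- cpp_cocg(system$dim, system$bz, system$by, system$bx,
                  as.vector(system$diagextra), as.vector(system$rhs),
                  tol, as.integer(maxit))
  if (!res$converged && res$relres > tol)
    stop("COCG did not converge: relative residual ", signif(res$relres, 3),
         " after ", res$iter, " iterations")
  structure(list(phi = array(res$phi, system$dim), omega = system$omega,
                 residual_norm = res$relres, iterations = res$iter),
            class = "potential_field")
}

#' Impedance from a solved potential field
#'
#' `Z = V / I` with the total current summed over the plate-adjacent
#' branches; current conservation makes any cross-section equivalent, and
#' the mismatch between the two plate currents is reported as a
#' consistency diagnostic.
#'
#' @param field a `potential_field`.
#' @param system the `eqs_system` it solves.
#' @return complex impedance (Ohm) with attribute `current_mismatch`.
#' @export
compute_impedance <- function(field, system) {
  phi <- as.vector(field$phi)
  iV <- sum(system$plateV$y * (system$v_applied - phi[system$plateV$idx]))
  i0 <- sum(system$plate0$y * phi[system$plate0$idx])
  if (Mod(iV) == 0) stop("zero current through the electrodes")
  z <- system$v_applied / iV
  attr(z, "current_mismatch") <- Mod(iV - i0) / Mod(iV)
  z
}

#' Logarithmic frequency grid
#'
#' `10^linspace(log10(f_min), log10(f_max), decades * ppd + 1)`: both
#' endpoints included, `ppd` points per decade (the 1 kHz - 1 THz default
#' gives 91 frequencies).
#'
#' @param f_min,f_max endpoints, Hz.
#' @param points_per_decade grid density.
#' @return numeric vector of frequencies.
#' @export
frequency_grid <- function(f_min = 1e3, f_max = 1e12,
                           points_per_decade = 10) {
  stopifnot(f_min < f_max)
  n <- round(log10(f_max / f_min) * points_per_decade) + 1
  10^seq(log10(f_min), log10(f_max), length.out = n)
}

#' Impedance spectrum over a frequency sweep
#'
#' One independent solve per frequency (zero initial guess each time, so
#' results are frequency-order independent).
#'
#' @param geom a `tissue_geometry`.
#' @param props a [material_props()].
#' @param f_min,f_max,points_per_decade frequency grid (see
#'   [frequency_grid()]).
#' @param frequencies explicit frequency vector overriding the grid.
#' @param v_applied plate voltage, V.
#' @param tol solver tolerance.
#' @param verbose print per-frequency progress.
#' @return an `impedance_spectrum` data frame (`frequency`, `Z`) with the
#'   plate geometry attached as attributes.
#' @export
frequency_sweep <- function(geom, props, f_min = 1e3, f_max = 1e12,
                            points_per_decade = 10, frequencies = NULL,
                            v_applied = 1, tol = 1e-10, verbose = FALSE) {
  f <- if (is.null(frequencies))
    frequency_grid(f_min, f_max, points_per_decade) else sort(frequencies)
  Z <- complex(length(f))
  for (i in seq_along(f)) {
    sys <- assemble_system(geom, props, 2 * pi * f[i], v_applied)
    fld <- solve_potential(sys, tol = tol)
    Z[i] <- compute_impedance(fld, sys)
    if (verbose) message(sprintf("f = %.3g Hz: %d iters", f[i],
                                 fld$iterations))
  }
  axid <- match(geom$electrode_axis, c("z", "y", "x"))
  sep <- geom$box[axid] * UM
  area <- prod(geom$box[-axid]) * UM^2
  structure(data.frame(frequency = f, Z = Z),
            plate_separation = sep, plate_area = area,
            v_applied = v_applied,
            class = c("impedance_spectrum", "data.frame"))
}

#' Transmembrane potential map
#'
#' Potential jump across every membrane face, `phi(cytoplasm side) -
#' phi(buffer side)`, with the face centroid coordinates. At low
#' frequencies the thin-layer element carries almost the whole local drop,
#' so this node difference is the induced transmembrane potential.
#'
#' @param field a `potential_field`.
#' @param geom the `tissue_geometry` the system was assembled from.
#' @return data frame `x_um`, `y_um`, `z_um`, `re_tmp_v`, `im_tmp_v`.
#' @export
transmembrane_potential <- function(field, geom) {
  fx <- geom$faces
  if (nrow(fx) == 0)
    return(data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      re_tmp_v = numeric(), im_tmp_v = numeric()))
  d <- dim(field$phi)
  low <- cbind(fx$iz, fx$iy, fx$ix)
  high <- low
  high[fx$axis == 1, 1] <- high[fx$axis == 1, 1] + 1L
  high[fx$axis == 2, 2] <- high[fx$axis == 2, 2] + 1L
  high[fx$axis == 3, 3] <- high[fx$axis == 3, 3] + 1L
  phi_low <- field$phi[low]
  phi_high <- field$phi[high]
  tmp <- ifelse(fx$cyt_low, phi_low - phi_high, phi_high - phi_low)
  data.frame(x_um = fx$x, y_um = fx$y, z_um = fx$z,
             re_tmp_v = Re(tmp), im_tmp_v = Im(tmp))
}
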