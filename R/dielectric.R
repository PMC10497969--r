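#' Effective dielectric properties from an impedance spectrum
#'
#' For a parallel-plate configuration with cell constant
#' `k = separation / area` (1/m):
#' `sigma_eff = Re(1/Z) k` and `eps_r_eff = Im(1/Z) k / (omega eps0)`.
#'
#' @param spec an `impedance_spectrum` (from [frequency_sweep()]) or a data
#'   frame with `frequency` (Hz) and complex `Z` (Ohm).
#' @param plate_separation plate distance, m (default: spectrum attribute).
#' @param plate_area plate area, m² (default: spectrum attribute).
#' @return a `dielectric_spectrum` data frame (`frequency`, `sigma_eff`,
#'   `eps_r_eff`) with the cell constant as attribute. Rows with
#'   `frequency == 0` report `eps_r_eff = NA`.
#' @export
extract_dielectric <- function(spec, plate_separation = NULL,
                               plate_area = NULL) {
  if (is.null(plate_separation)) plate_separation <- attr(spec, "plate_separation")
  if (is.null(plate_area)) plate_area <- attr(spec, "plate_area")
  stopifnot(plate_separation > 0, plate_area > 0)
  if (any(Mod(spec$Z) == 0)) stop("zero impedance in spectrum")
  k <- plate_separation / plate_area
  Y <- 1 / spec$Z
  omega <- 2 * pi * spec$frequency
  eps <- ifelse(omega > 0, Im(Y) * k / (omega * EPS0), NA_real_)
  structure(data.frame(frequency = spec$frequency,
                       sigma_eff = Re(Y) * k, eps_r_eff = eps),
            cell_constant = k,
            class = c("dielectric_spectrum", "data.frame"))
}

# complex relative permittivity eps_hat = eps_r - j sigma / (omega eps0)
eps_hat <- function(sigma, eps_r, omega) {
  complex(real = eps_r, imaginary = -sigma / (omega * EPS0))
}

#' Maxwell two-phase dilute mixture
#'
#' Maxwell-Wagner dilute mixture of spherical particles (complex
#' permittivity `ep`) in a medium (`eb`) at volume fraction `p`.
#'
#' @param eb,ep complex relative permittivities of medium and particle.
#' @param p volume fraction.
#' @return complex effective relative permittivity.
#' @export
maxwell_mixture <- function(eb, ep, p) {
  beta <- (ep - eb) / (ep + 2 * eb)
  eb * (1 + 2 * p * beta) / (1 - p * beta)
}

#' Analytic single-shell suspension spectrum
#'
#' Dielectric spectrum of a dilute suspension of shelled spheres
#' (cytoplasm core of radius `cell_radius - d_m` wrapped in a membrane
#' shell of thickness `d_m`) in buffer: the shelled particle is first
#' reduced to an equivalent homogeneous sphere,
#' `ep = em (2(1-v) em + (1+2v) ec) / ((2+v) em + (1-v) ec)` with
#' `v = (1 - d_m/R)^3`, then combined with the buffer by the dilute
#' Maxwell-Wagner mixture formula. This is the standard interfacial
#' (beta-dispersion) model for cell suspensions and serves as the
#' independent oracle for the voxel solver.
#'
#' @param props a [material_props()].
#' @param cell_radius outer cell radius, m.
#' @param volume_fraction cell volume fraction (dilute, < 0.1).
#' @param frequencies frequency vector, Hz (> 0).
#' @return a `dielectric_spectrum` data frame.
#' @export
single_shell_suspension <- function(props, cell_radius, volume_fraction,
                                    frequencies) {
  stopifnot(cell_radius > 0, volume_fraction >= 0, all(frequencies > 0))
  if (volume_fraction >= 0.1)
    warning("volume fraction ", volume_fraction,
            " is outside the dilute regime; result is extrapolated")
  stopifnot(props$d_m < cell_radius)
  omega <- 2 * pi * frequencies
  eb <- eps_hat(props$sigma_buf, props$eps_rbuf, omega)
  ec <- eps_hat(props$sigma_cyt, props$eps_rcyt, omega)
  em <- eps_hat(props$sigma_m, props$eps_rm, omega)
  v <- (1 - props$d_m / cell_radius)^3
  ep <- em * (2 * (1 - v) * em + (1 + 2 * v) * ec) /
    ((2 + v) * em + (1 - v) * ec)
  ee <- maxwell_mixture(eb, ep, volume_fraction)
  structure(data.frame(frequency = frequencies,
                       sigma_eff = -Im(ee) * omega * EPS0,
                       eps_r_eff = Re(ee)),
            class = c("dielectric_spectrum", "data.frame"))
}
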