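#' Write an image stack or label volume as multi-page TIFF
#'
#' 16-bit (or 8-bit) multi-page TIFF, one page per z-slice, with a JSON
#' sidecar recording the voxel size and any extra metadata.
#'
#' @param x an [image_stack()] or [labeled_volume()].
#' @param path output `.tif` path.
#' @param meta extra metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, meta = list()) {
  if (inherits(x, "labeled_volume")) {
    arr <- x$labels; bits <- 16L; kind <- "labels"
  } else {
    arr <- x$data; bits <- x$bit_depth; kind <- "intensity"
  }
  maxint <- 2^bits - 1
  if (max(arr) > maxint) stop("values exceed ", bits, "-bit range")
  pages <- lapply(seq_len(dim(arr)[1]), function(iz)
    matrix(arr[iz, , ] / maxint, dim(arr)[2], dim(arr)[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  sidecar <- c(list(kind = kind, voxel_size_um = x$voxel_size,
                    dim = dim(arr), bits = bits), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack()]
#'
#' @param path `.tif` path (sidecar `.json` expected next to it, else
#'   `voxel_size` must be given).
#' @param voxel_size fallback voxel size (z, y, x), µm.
#' @return an [image_stack()] or [labeled_volume()] depending on the
#'   sidecar `kind`.
#' @export
read_stack <- function(path, voxel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- NULL
  if (file.exists(paste0(path, ".json")))
    side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  bits <- if (!is.null(side)) side$bits else 16L
  vs <- if (!is.null(voxel_size)) voxel_size else side$voxel_size_um
  if (is.null(vs)) stop("voxel size unknown: no sidecar and none given")
  arr <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (iz in seq_along(pages)) arr[iz, , ] <- pages[[iz]]
  arr <- round(arr * (2^bits - 1))
  if (!is.null(side) && identical(side$kind, "labels"))
    labeled_volume(array(as.integer(arr), dim(arr)), vs)
  else image_stack(arr, vs, as.integer(bits))
}

#' Write the geometric input file (ellipsoid table)
#'
#' Plain CSV with columns `label, cx, cy, cz, a, b, c, phi_deg, theta_deg,
#' psi_deg` (centres and semi-axes in µm, intrinsic z-y-x angles in
#' degrees).
#'
#' @param cells an [ellipsoid_set()].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_ellipsoids <- function(cells, path) {
  df <- as.data.frame(cells)
  out <- data.frame(label = df$label, cx = df$cx, cy = df$cy, cz = df$cz,
                    a = df$a, b = df$b, c = df$c,
                    phi_deg = df$phi * 180 / pi,
                    theta_deg = df$theta * 180 / pi,
                    psi_deg = df$psi * 180 / pi)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a geometric input file
#'
#' @param path `.csv` written by [write_ellipsoids()].
#' @return an [ellipsoid_set()].
#' @export
read_ellipsoids <- function(path) {
  df <- read.csv(path)
  ellipsoid_set(data.frame(label = df$label, cx = df$cx, cy = df$cy,
                           cz = df$cz, a = df$a, b = df$b, c = df$c,
                           phi = df$phi_deg * pi / 180,
                           theta = df$theta_deg * pi / 180,
                           psi = df$psi_deg * pi / 180))
}

#' Write an impedance spectrum as CSV
#'
#' Columns `frequency_Hz`, `ReZ_Ohm`, `ImZ_Ohm`.
#'
#' @param spec an `impedance_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  write.csv(data.frame(frequency_Hz = spec$frequency,
                       ReZ_Ohm = Re(spec$Z), ImZ_Ohm = Im(spec$Z)),
            path, row.names = FALSE)
  invisible(path)
}

#' Read an impedance spectrum CSV
#'
#' @param path CSV written by [write_spectrum()].
#' @param plate_separation,plate_area electrode geometry attributes (m, m²).
#' @return an `impedance_spectrum`.
#' @export
read_spectrum <- function(path, plate_separation = NULL, plate_area = NULL) {
  df <- read.csv(path)
  structure(data.frame(frequency = df$frequency_Hz,
                       Z = complex(real = df$ReZ_Ohm,
                                   imaginary = df$ImZ_Ohm)),
            plate_separation = plate_separation, plate_area = plate_area,
            class = c("impedance_spectrum", "data.frame"))
}

#' Write a dielectric spectrum as CSV
#'
#' @param diel a `dielectric_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dielectric <- function(diel, path) {
  write.csv(data.frame(frequency_Hz = diel$frequency,
                       sigma_eff_S_per_m = diel$sigma_eff,
                       eps_r_eff = diel$eps_r_eff),
            path, row.names = FALSE)
  invisible(path)
}
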