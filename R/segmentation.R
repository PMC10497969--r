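#' Segmentation configuration
#'
#' Parameters of the classical instance-segmentation chain. All sizes are in
#' physical units so the filters behave identically across resolutions:
#' slice components larger than `slice_area_max` µm² are treated as gigantic
#' artifacts and removed slice-wise; 3D components smaller than `volume_min`
#' µm³ are removed as tiny noise.
#'
#' @param slice_area_max per-slice area cutoff, µm² (default 300).
#' @param volume_min 3D volume cutoff, µm³ (default 200).
#' @param threshold_method automatic global threshold method.
#' @param watershed_h h-maxima dynamic (µm of distance-map height) used to
#'   suppress spurious watershed seeds.
#' @param smoothing_sigma Gaussian denoising sigma, µm.
#' @param background_sigma large-kernel background estimation sigma, µm.
#' @param stretch_quantiles lower/upper percentile for contrast stretch.
#' @param denoise,flatten,stretch logical toggles for the three
#'   pre-processing stages.
#' @param conn3d,conn2d connectivity used for 3D (6/26) and slice (4/8)
#'   components.
#' @return a `segmentation_config`.
#' @export
segmentation_config <- function(slice_area_max = 300, volume_min = 200,
                                threshold_method = c("otsu", "mean"),
                                watershed_h = 2, smoothing_sigma = 0.5,
                                background_sigma = 10,
                                stretch_quantiles = c(0.01, 0.999),
                                denoise = TRUE, flatten = TRUE,
                                stretch = TRUE,
                                conn3d = 26L, conn2d = 8L) {
  stopifnot(slice_area_max > 0, volume_min > 0, watershed_h >= 0)
  structure(list(slice_area_max = slice_area_max, volume_min = volume_min,
                 threshold_method = match.arg(threshold_method),
                 watershed_h = watershed_h,
                 smoothing_sigma = smoothing_sigma,
                 background_sigma = background_sigma,
                 stretch_quantiles = stretch_quantiles,
                 denoise = denoise, flatten = flatten, stretch = stretch,
                 conn3d = as.integer(conn3d), conn2d = as.integer(conn2d)),
            class = "segmentation_config")
}

# linear interpolation of a 3D array along one axis to n_new samples, with
# voxel centres at (i + 0.5) * h; clamped at the ends
interp_axis <- function(arr, axis, n_new, order = 1L) {
  n_old <- dim(arr)[axis]
  if (n_new == n_old) return(arr)
  # target centres in source index units (0-based voxel index space)
  pos <- ((seq_len(n_new) - 0.5) * n_old / n_new) - 0.5
  if (order == 0L) {
    i0 <- pmin(pmax(round(pos), 0), n_old - 1) + 1
    return(slice_index(arr, axis, i0))
  }
  lo <- floor(pos)
  w <- pos - lo
  i0 <- pmin(pmax(lo, 0), n_old - 1) + 1
  i1 <- pmin(pmax(lo + 1, 0), n_old - 1) + 1
  a0 <- slice_index(arr, axis, i0)
  a1 <- slice_index(arr, axis, i1)
  wr <- array(rep(w, times = if (axis == 1) prod(dim(arr)[-1]) else 1,
                  each = if (axis == 1) 1 else prod(dim(arr)[seq_len(axis - 1)])),
              dim = dim(a0))
  a0 * (1 - wr) + a1 * wr
}

# index a 3D array along one axis with an integer vector
slice_index <- function(arr, axis, idx) {
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

#' Resample a stack to isotropic voxels
#'
#' Linear (or nearest-neighbour) resampling of every axis to the smallest
#' voxel dimension, preserving the physical extent to within one voxel per
#' axis. Confocal stacks are strongly anisotropic in z, which hampers the
#' separation of adjacent cells; this puts them on an isotropic grid first.
#'
#' @param stack an [image_stack()].
#' @param order interpolation order: 0 (nearest) or 1 (linear).
#' @return an [image_stack()] with isotropic `voxel_size`.
#' @export
resample_isotropic <- function(stack, order = 1L) {
  vs <- stack$voxel_size
  stopifnot(all(vs > 0))
  if (dim(stack$data)[1] < 2)
    stop("degenerate single-slice stack cannot be resampled")
  h <- min(vs)
  if (all(vs == h)) return(stack)
  d <- dim(stack$data)
  arr <- stack$data
  for (ax in 1:3) {
    n_new <- as.integer(round(d[ax] * vs[ax] / h))
    arr <- interp_axis(arr, ax, n_new, order = order)
  }
  image_stack(arr, c(h, h, h), stack$bit_depth)
}

#' Pre-process a stack: denoise, flatten background, stretch contrast
#'
#' Gaussian denoising, large-kernel background subtraction (removing uneven
#' illumination) and percentile contrast normalisation, each individually
#' toggleable through the configuration. The output is rescaled to the
#' stack's bit-depth range.
#'
#' @param stack an [image_stack()].
#' @param cfg a [segmentation_config()].
#' @return an [image_stack()].
#' @export
preprocess <- function(stack, cfg = segmentation_config()) {
  arr <- stack$data * 1.0
  vs <- stack$voxel_size
  maxint <- 2^stack$bit_depth - 1
  if (cfg$denoise && cfg$smoothing_sigma > 0)
    arr <- cpp_gauss_blur(arr, dim(arr), cfg$smoothing_sigma / vs)
  if (cfg$flatten && cfg$background_sigma > 0) {
    bg <- cpp_gauss_blur(arr, dim(arr), cfg$background_sigma / vs)
    arr <- pmax(arr - bg, 0)
  }
  if (cfg$stretch) {
    q <- quantile(arr, cfg$stretch_quantiles, names = FALSE)
    if (q[2] > q[1]) {
      arr <- (arr - q[1]) / (q[2] - q[1])
      arr <- pmin(pmax(arr, 0), 1) * maxint
    }
  }
  image_stack(array(arr, dim(stack$data)), vs, stack$bit_depth)
}

# Otsu threshold on a 256-bin histogram
otsu_threshold <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) stop("no threshold found: constant image")
  nb <- 256L
  h <- tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * nb) + 1, 1), nb), nb)
  p <- h / sum(h)
  w0 <- cumsum(p)
  mu <- cumsum(p * seq_len(nb))
  mut <- mu[nb]
  bc <- (mut * w0 - mu)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- -Inf
  k <- which.max(bc)
  rng[1] + k / nb * diff(rng)
}

#' Automatic global threshold
#'
#' Splits the stack into cell interior and exterior with an automatically
#' chosen global threshold (Otsu by default) so that no manual tweaking is
#' involved.
#'
#' @param stack an [image_stack()].
#' @param method `"otsu"` (between-class variance) or `"mean"`.
#' @param invert if `TRUE`, dark objects on a bright background are
#'   segmented (complementary mask).
#' @return a binary [labeled_volume()] (values 0/1).
#' @export
auto_threshold <- function(stack, method = c("otsu", "mean"), invert = FALSE) {
  method <- match.arg(method)
  x <- stack$data
  if (max(x) == min(x)) stop("no threshold found: constant image")
  thr <- switch(method, otsu = otsu_threshold(as.vector(x)),
                mean = mean(x))
  m <- if (invert) (x <= thr) else (x > thr)
  labeled_volume(array(as.integer(m), dim(x)), stack$voxel_size)
}

#' Remove gigantic slice artifacts and tiny volume noise
#'
#' Two physically parameterised filters: per-slice 2D components with area
#' above `slice_area_max` (default 300 µm²) are removed (gigantic imaging
#' artifacts), then 3D components with volume below `volume_min` (default
#' 200 µm³) are removed (tiny noise). The operation is idempotent.
#'
#' @param mask a binary [labeled_volume()].
#' @param cfg a [segmentation_config()].
#' @return a binary [labeled_volume()].
#' @export
filter_artifacts <- function(mask, cfg = segmentation_config()) {
  m <- mask$labels > 0
  vs <- mask$voxel_size
  d <- dim(m)
  area_vox <- vs[2] * vs[3]
  for (iz in seq_len(d[1])) {
    sl <- matrix(as.integer(m[iz, , ]), d[2], d[3])
    lab <- cpp_label2d(sl, cfg$conn2d)
    if (max(lab) == 0) next
    areas <- tabulate(lab[lab > 0]) * area_vox
    kill <- which(areas > cfg$slice_area_max)
    if (length(kill)) {
      sl[lab %in% kill] <- 0L
      m[iz, , ] <- sl > 0
    }
  }
  lab3 <- cpp_label3d(array(as.integer(m), d), d, cfg$conn3d)
  if (max(lab3) > 0) {
    vols <- tabulate(lab3[lab3 > 0]) * prod(vs)
    kill <- which(vols < cfg$volume_min)
    if (length(kill)) m[array(lab3, d) %in% kill] <- FALSE
  }
  labeled_volume(array(as.integer(m), d), vs)
}

#' Split touching cells by the distance-transform watershed
#'
#' Fills holes, computes the Euclidean distance transform of the mask (in
#' physical units), finds internal maxima with h-maxima suppression
#' (dynamic `watershed_h`), and floods the distance map from those seeds
#' restricted to the mask. Each separated cell receives its own label.
#'
#' @param mask a binary [labeled_volume()].
#' @param cfg a [segmentation_config()].
#' @return a [labeled_volume()] with one label per cell.
#' @export
split_cells <- function(mask, cfg = segmentation_config()) {
  d <- dim(mask$labels)
  vs <- mask$voxel_size
  m <- cpp_fill_holes(array(as.integer(mask$labels > 0), d), d)
  if (!any(m > 0)) return(labeled_volume(array(0L, d), vs))
  dist <- cpp_edt(m, d, vs)
  seeds <- hmaxima_seeds(dist, h = cfg$watershed_h, conn = cfg$conn3d)
  if (max(seeds) == 0) {
    # mask present but flat distance map: a single label
    return(labeled_volume(array(as.integer(m), d), vs))
  }
  lab <- cpp_watershed(dist, seeds, m, d, cfg$conn3d)
  labeled_volume(lab, vs)
}

# extended-maxima seeds of a height map: regional maxima of the h-maxima
# transform (reconstruction of f - h under f)
hmaxima_seeds <- function(f, h, conn = 26L) {
  d <- dim(f)
  hm <- if (h > 0) cpp_reconstruct(f - h, f, d, conn) else f
  delta <- 1e-4 * max(hm)
  if (delta <= 0) return(array(0L, d))
  rec <- cpp_reconstruct(hm - delta, hm, d, conn)
  cpp_label3d(array(as.integer(hm - rec > delta / 2), d), d, conn)
}

#' Fit 3D ellipsoids to labelled cells
#'
#' For each label the centre is the voxel centroid and the semi-axes and
#' orientation come from the eigen-decomposition of the voxel covariance
#' matrix (with the within-voxel variance term), using the uniform solid
#' ellipsoid relation `semi_axis = sqrt(5 * eigenvalue)` and a final
#' rescaling so every fitted ellipsoid has exactly the volume of its voxel
#' support. Labels with fewer than 4 voxels or degenerate (coplanar)
#' support are skipped with a warning.
#'
#' @param labels a [labeled_volume()].
#' @return an [ellipsoid_set()] with the surviving labels.
#' @export
fit_ellipsoids <- function(labels) {
  lab <- labels$labels
  vs <- labels$voxel_size
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) return(ellipsoid_set(data.frame()))
  idx <- which(lab > 0)
  d <- dim(lab)
  iz <- (idx - 1) %% d[1]
  iy <- ((idx - 1) %/% d[1]) %% d[2]
  ix <- (idx - 1) %/% (d[1] * d[2])
  # physical voxel-centre coordinates, (x, y, z) µm
  px <- (ix + 0.5) * vs[3]; py <- (iy + 0.5) * vs[2]; pz <- (iz + 0.5) * vs[1]
  lv <- lab[idx]
  voxvol <- prod(vs)
  rows <- lapply(ids, function(k) {
    sel <- lv == k
    n <- sum(sel)
    if (n < 4) {
      warning("label ", k, " has fewer than 4 voxels; skipped")
      return(NULL)
    }
    P <- cbind(px[sel], py[sel], pz[sel])
    ctr <- colMeans(P)
    CV <- crossprod(sweep(P, 2, ctr)) / n + diag(c(vs[3], vs[2], vs[1])^2) / 12
    eg <- eigen(CV, symmetric = TRUE)
    if (any(eg$values <= 0)) {
      warning("label ", k, " has degenerate (coplanar) support; skipped")
      return(NULL)
    }
    ax <- sqrt(5 * eg$values)               # solid-ellipsoid moments
    scale <- (n * voxvol / (4 / 3 * pi * prod(ax)))^(1 / 3)
    ax <- ax * scale                        # exact voxel-volume identity
    R <- eg$vectors
    if (det(R) < 0) R[, 3] <- -R[, 3]
    # recover intrinsic z-y-x Euler angles from R = Rz Ry Rx
    theta <- asin(pmin(pmax(-R[3, 1], -1), 1))
    if (abs(cos(theta)) > 1e-9) {
      phi <- atan2(R[2, 1], R[1, 1])
      psi <- atan2(R[3, 2], R[3, 3])
    } else {
      phi <- atan2(-R[1, 2], R[2, 2]); psi <- 0
    }
    data.frame(label = k, cx = ctr[1], cy = ctr[2], cz = ctr[3],
               a = ax[1], b = ax[2], c = ax[3],
               phi = phi, theta = theta, psi = psi)
  })
  ellipsoid_set(do.call(rbind, rows[!vapply(rows, is.null, TRUE)]))
}

#' Full classical segmentation chain
#'
#' Convenience wrapper running resample -> preprocess -> auto-threshold ->
#' artifact filters -> distance-transform watershed -> ellipsoid fitting.
#'
#' @param stack an [image_stack()].
#' @param cfg a [segmentation_config()].
#' @return list with `labels` (a [labeled_volume()]) and `cells`
#'   (an [ellipsoid_set()]).
#' @export
segment_stack <- function(stack, cfg = segmentation_config()) {
  iso <- if (length(unique(stack$voxel_size)) > 1)
    resample_isotropic(stack) else stack
  pre <- preprocess(iso, cfg)
  mask <- auto_threshold(pre, cfg$threshold_method)
  mask <- filter_artifacts(mask, cfg)
  lab <- split_cells(mask, cfg)
  list(labels = lab, cells = fit_ellipsoids(lab))
}
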