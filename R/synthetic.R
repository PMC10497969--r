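#' Noise model for synthetic image stacks
#'
#' Describes the intensity corruption applied when rendering a synthetic
#' confocal-style stack: a constant background offset, additive Gaussian
#' read noise, a multiplicative linear illumination gradient per axis,
#' optional Poisson shot noise, and bright non-cell artifacts.
#'
#' @param background_level background intensity (fraction of full scale).
#' @param gaussian_sd additive Gaussian noise sd (fraction of full scale).
#' @param illumination_gradient length-3 fractional amplitude per axis
#'   (z, y, x); intensity is scaled by `1 + g * (pos/extent - 1/2)`.
#' @param artifact_rate expected number of small bright artifacts per stack.
#' @param poisson logical; add Poisson shot noise.
#' @param seed integer seed; identical seeds give identical stacks.
#' @return a `noise_model` list.
#' @export
noise_model <- function(background_level = 0.05, gaussian_sd = 0.02,
                        illumination_gradient = c(0, 0, 0),
                        artifact_rate = 0, poisson = FALSE, seed = 1L) {
  illumination_gradient <- rep_len(illumination_gradient, 3)
  stopifnot(background_level >= 0, gaussian_sd >= 0, artifact_rate >= 0)
  structure(list(background_level = background_level,
                 gaussian_sd = gaussian_sd,
                 illumination_gradient = illumination_gradient,
                 artifact_rate = artifact_rate,
                 poisson = poisson, seed = as.integer(seed)),
            class = "noise_model")
}

#' Preset noise models
#'
#' `"clean"` renders noise-free stacks, `"noisy"` adds moderate background,
#' read noise and a mild illumination gradient, `"very-noisy"` additionally
#' enables shot noise and frequent bright artifacts.
#'
#' @param preset one of `"clean"`, `"noisy"`, `"very-noisy"`.
#' @param seed integer seed.
#' @return a `noise_model`.
#' @export
noise_preset <- function(preset = c("clean", "noisy", "very-noisy"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    "clean" = noise_model(0, 0, c(0, 0, 0), 0, FALSE, seed),
    "noisy" = noise_model(0.08, 0.04, c(0.2, 0.1, 0.1), 3, FALSE, seed),
    "very-noisy" = noise_model(0.12, 0.08, c(0.4, 0.2, 0.2), 10, TRUE, seed))
}

# truncated-normal (> 0) volumes by rejection; deterministic under the
# caller's RNG state
rtrunc_volumes <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    v <- rnorm(n, mean, sd)
    out <- c(out, v[v > 0])
  }
  out[seq_len(n)]
}

#' Sample a synthetic chondrocyte population
#'
#' Draws `n_cells` ellipsoidal cells inside a rectangular tissue box. Cell
#' volumes follow a truncated normal distribution (default 2157 +/- 957 µm³,
#' the population statistics of healthy bovine chondrocytes this generator
#' emulates); semi-axis ratios a:c are uniform in `[1, 2]`; orientations are
#' uniform Euler angles.
#'
#' @param n_cells number of cells (>= 0).
#' @param box length-3 box extents (z, y, x), µm.
#' @param volume_mean,volume_sd volume distribution parameters, µm³.
#' @param allow_touching if `TRUE` cells are placed independently and may
#'   touch or intersect each other and the box boundary; if `FALSE`
#'   placement enforces disjoint bounding spheres fully inside the box.
#' @param min_gap minimal surface gap (µm) enforced when
#'   `allow_touching = FALSE`.
#' @param seed integer seed.
#' @param max_retries bounded placement retries per cell before failing.
#' @return an [ellipsoid_set()] with labels `1..n_cells`.
#' @export
sample_population <- function(n_cells, box, volume_mean = 2157,
                              volume_sd = 957, allow_touching = TRUE,
                              min_gap = 0, seed = 1L, max_retries = 200L) {
  stopifnot(n_cells >= 0, length(box) == 3, all(box > 0))
  if (n_cells == 0) return(ellipsoid_set(data.frame()))
  with_seed(seed, {
    vols <- rtrunc_volumes(n_cells, volume_mean, volume_sd)
    s1 <- runif(n_cells, 1, 2)              # a : c
    s2 <- runif(n_cells, 1, s1)             # b : c
    cc <- (3 * vols / (4 * pi * s1 * s2))^(1 / 3)
    a <- s1 * cc; b <- s2 * cc
    phi <- runif(n_cells, 0, 2 * pi)
    theta <- runif(n_cells, 0, pi)
    psi <- runif(n_cells, 0, 2 * pi)
    bx <- box[3]; by <- box[2]; bz <- box[1]  # box given as (z, y, x)
    centers <- matrix(0, n_cells, 3)
    for (i in seq_len(n_cells)) {
      rmax <- a[i]
      placed <- FALSE
      for (k in seq_len(max_retries)) {
        if (allow_touching) {
          cand <- c(runif(1, 0, bx), runif(1, 0, by), runif(1, 0, bz))
        } else {
          if (2 * rmax >= min(bx, by, bz))
            stop("box too small to place cell ", i, " without touching")
          cand <- c(runif(1, rmax, bx - rmax), runif(1, rmax, by - rmax),
                    runif(1, rmax, bz - rmax))
        }
        ok <- TRUE
        if (!allow_touching && i > 1) {
          prev <- centers[seq_len(i - 1), , drop = FALSE]
          d <- sqrt(rowSums(sweep(prev, 2, cand, `-`)^2))
          ok <- all(d > rmax + a[seq_len(i - 1)] + min_gap)
        }
        if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) stop("placement failure: could not place cell ", i,
                        " after ", max_retries, " retries")
    }
    ellipsoid_set(data.frame(label = seq_len(n_cells),
                             cx = centers[, 1], cy = centers[, 2],
                             cz = centers[, 3], a = a, b = b, c = cc,
                             phi = phi, theta = theta, psi = psi))
  })
}

#' Construct an image stack container
#'
#' @param data 3D non-negative intensity array, dim `(nz, ny, nx)`.
#' @param voxel_size length-3 physical voxel size (z, y, x), µm.
#' @param bit_depth 8 or 16.
#' @return an `image_stack`.
#' @export
image_stack <- function(data, voxel_size, bit_depth = 16L) {
  stopifnot(length(dim(data)) == 3, all(voxel_size > 0),
            bit_depth %in% c(8L, 16L))
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 bit_depth = as.integer(bit_depth)),
            class = "image_stack")
}

#' Construct a labelled volume container
#'
#' @param labels 3D integer array (0 = background), dim `(nz, ny, nx)`.
#' @param voxel_size length-3 physical voxel size (z, y, x), µm.
#' @return a `labeled_volume`.
#' @export
labeled_volume <- function(labels, voxel_size) {
  stopifnot(length(dim(labels)) == 3, all(voxel_size > 0), all(labels >= 0))
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size)),
            class = "labeled_volume")
}

#' Render a cell population into a synthetic image stack
#'
#' Rasterises the cells into an intensity stack (bright cells over a noisy
#' background with per-cell intensity jitter and optional artifacts) plus
#' the exact ground-truth label volume obtained from the analytic ellipsoid
#' membership test at voxel centres. Voxel centres sit at
#' `(i + 0.5) * voxel_size` with 0-based indices.
#'
#' @param cells an [ellipsoid_set()].
#' @param voxel_size scalar or length-3 voxel size (z, y, x), µm; default
#'   the confocal acquisition geometry `(1, 0.1099, 0.1099)`.
#' @param noise a [noise_model()].
#' @param box length-3 stack extent (z, y, x) in µm; default the tight
#'   bounding box of the population (plus one voxel).
#' @param bit_depth 8 or 16.
#' @param max_voxels refusal cap on the stack size.
#' @return list with elements `stack` ([image_stack()]) and `labels`
#'   ([labeled_volume()]).
#' @export
render_stack <- function(cells, voxel_size = c(1, 0.1099, 0.1099),
                         noise = noise_model(), box = NULL,
                         bit_depth = 16L, max_voxels = 2.5e8) {
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  stopifnot(all(voxel_size > 0))
  if (is.null(box)) {
    if (nrow(cells) == 0) box <- voxel_size * 8
    else {
      rmax <- cells$a
      box <- c(max(cells$cz + rmax), max(cells$cy + rmax),
               max(cells$cx + rmax)) + voxel_size
    }
  }
  dims <- pmax(1L, as.integer(round(box / voxel_size)))
  if (prod(dims) > max_voxels)
    stop("refusing to allocate ", prod(dims), " voxels (cap ", max_voxels, ")")
  maxint <- 2^bit_depth - 1
  lab <- array(0L, dims)
  if (nrow(cells) > 0) {
    lab <- cpp_render_labels(as.matrix(cells[, c("cx", "cy", "cz")]),
                             as.matrix(cells[, c("a", "b", "c")]),
                             cell_rotations(cells),
                             as.integer(cells$label),
                             dims, voxel_size)
  }
  img <- with_seed(noise$seed, {
    base <- array(noise$background_level, dims)
    if (nrow(cells) > 0) {
      jitter <- runif(nrow(cells), 0.8, 1.2)
      lv <- as.vector(lab)
      fg <- lv > 0
      amp <- numeric(length(lv))
      amp[fg] <- 0.6 * jitter[match(lv[fg], cells$label)]
      base <- base + array(amp, dims)
    }
    # bright non-cell artifacts: small spheres below the volume-filter cutoff
    n_art <- if (noise$artifact_rate > 0) rpois(1, noise$artifact_rate) else 0L
    if (n_art > 0) {
      ar <- runif(n_art, 0.4, 1.5)
      acx <- runif(n_art, 0, dims[3] * voxel_size[3])
      acy <- runif(n_art, 0, dims[2] * voxel_size[2])
      acz <- runif(n_art, 0, dims[1] * voxel_size[1])
      art <- cpp_render_labels(cbind(acx, acy, acz), cbind(ar, ar, ar),
                               rep(list(diag(3)), n_art),
                               seq_len(n_art), dims, voxel_size)
      base[art > 0] <- pmax(base[art > 0], 0.9)
    }
    g <- noise$illumination_gradient
    if (any(g != 0)) {
      zf <- 1 + g[1] * ((seq_len(dims[1]) - 0.5) / dims[1] - 0.5)
      yf <- 1 + g[2] * ((seq_len(dims[2]) - 0.5) / dims[2] - 0.5)
      xf <- 1 + g[3] * ((seq_len(dims[3]) - 0.5) / dims[3] - 0.5)
      base <- base * (zf %o% yf %o% xf)
    }
    if (noise$poisson) {
      # shot noise at a nominal full-well of 1000 counts
      base <- array(rpois(length(base), pmax(base, 0) * 1000) / 1000, dims)
    }
    if (noise$gaussian_sd > 0)
      base <- base + array(rnorm(length(base), 0, noise$gaussian_sd), dims)
    base
  })
  img <- round(pmin(pmax(img, 0), 1) * maxint)
  list(stack = image_stack(array(img, dims), voxel_size, bit_depth),
       labels = labeled_volume(lab, voxel_size))
}

#' Count/volume/ratio summary of a cell population
#'
#' @param cells an [ellipsoid_set()].
#' @param box optional length-3 box (z, y, x), µm, for the volume ratio.
#' @return list with `count`, `mean_volume`, `sd_volume` (µm³) and, when a
#'   box is given, `volume_ratio` in percent.
#' @export
population_summary <- function(cells, box = NULL) {
  v <- ellipsoid_volumes(cells)
  out <- list(count = nrow(cells),
              mean_volume = if (length(v)) mean(v) else 0,
              sd_volume = if (length(v) > 1) sd(v) else 0)
  if (!is.null(box)) {
    bv <- prod(box)
    if (bv <= 0) stop("box volume must be > 0")
    out$volume_ratio <- 100 * sum(v) / bv
  }
  out
}
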