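# shared fixture builders (everything generated in code; no stored data)

# a single axis-aligned ellipsoid population
one_ellipsoid <- function(a = 10, b = 8, c = 6, center = c(12, 12, 12)) {
  ellipsoid_set(data.frame(label = 1L, cx = center[1], cy = center[2],
                           cz = center[3], a = a, b = b, c = c))
}

# render a clean stack of n non-touching cells in a cubic box
clean_stack <- function(n = 5, box = 64, voxel = 0.8, seed = 11) {
  cells <- sample_population(n, rep(box, 3), allow_touching = FALSE,
                             min_gap = 2, seed = seed)
  rs <- render_stack(cells, voxel_size = voxel,
                     noise = noise_preset("clean", seed = seed + 1),
                     box = rep(box, 3))
  list(cells = cells, stack = rs$stack, labels = rs$labels)
}

# centred shelled-sphere geometry (radius R um in an L um cube)
sphere_geometry <- function(R = 8, L = 40, n = 32, axis = "x") {
  cells <- ellipsoid_set(data.frame(label = 1L, cx = L / 2, cy = L / 2,
                                    cz = L / 2, a = R, b = R, c = R))
  voxelize_geometry(cells = cells, box = rep(L, 3), voxel_size = L / n,
                    electrode_axis = axis)
}

# brute-force maximum-total-IoU one-to-one assignment via permutations;
# returns tp at the given tau
brute_force_match <- function(pred, gt, tau) {
  pl <- sort(unique(pred[pred > 0]))
  gl <- sort(unique(gt[gt > 0]))
  if (!length(pl) || !length(gl))
    return(list(tp = 0, total = 0))
  iou <- matrix(0, length(pl), length(gl))
  for (i in seq_along(pl))
    for (j in seq_along(gl)) {
      inter <- sum(pred == pl[i] & gt == gl[j])
      if (inter > 0)
        iou[i, j] <- inter / sum(pred == pl[i] | gt == gl[j])
    }
  n <- max(dim(iou))
  M <- matrix(0, n, n)
  M[seq_len(nrow(iou)), seq_len(ncol(iou))] <- iou
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- -1; best_p <- NULL
  for (p in perms(seq_len(n))) {
    w <- sum(M[cbind(seq_len(n), p)])
    if (w > best + 1e-12) { best <- w; best_p <- p }
  }
  sel <- M[cbind(seq_len(n), best_p)]
  list(tp = sum(sel >= tau & sel > 0), total = best)
}

# analytic ellipsoid implicit field sampled at voxel centres (iso level 0)
ellipsoid_field <- function(a, b, c, center, h, dims) {
  iz <- (seq_len(dims[1]) - 0.5) * h
  iy <- (seq_len(dims[2]) - 0.5) * h
  ix <- (seq_len(dims[3]) - 0.5) * h
  f <- array(0, dims)
  for (k in seq_len(dims[3]))
    f[, , k] <- 1 - sqrt(outer(((iz - center[3]) / c)^2,
                               ((iy - center[2]) / b)^2, `+`) +
                           ((ix[k] - center[1]) / a)^2)
  f
}
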