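#' Uncertain parameter with a uniform distribution
#'
#' @param name parameter name.
#' @param low,high range bounds in native units (`low < high`).
#' @return an `uncertain_parameter`.
#' @export
uncertain_parameter <- function(name, low, high) {
  stopifnot(low < high)
  structure(list(name = name, low = low, high = high),
            class = "uncertain_parameter")
}

#' Collocation-node budget of the point-collocation PCE
#'
#' With a total-degree basis of dimension `M = C(d + p, p)` the point
#' collocation uses `2 M + 2` model evaluations: order 4 with 5 uncertain
#' parameters gives 254, with 7 parameters 662.
#'
#' @param d number of uncertain parameters (>= 1).
#' @param p polynomial order (>= 0).
#' @return node count `2 * choose(d + p, p) + 2`.
#' @export
pce_node_count <- function(d, p) {
  stopifnot(d >= 1, p >= 0)
  2 * choose(d + p, p) + 2
}

# orthonormal Legendre polynomials on U(-1, 1): psi_k = sqrt(2k+1) P_k
legendre_matrix <- function(u, kmax) {
  n <- length(u)
  P <- matrix(0, n, kmax + 1)
  P[, 1] <- 1
  if (kmax >= 1) P[, 2] <- u
  if (kmax >= 2) for (k in 2:kmax)
    P[, k + 1] <- ((2 * k - 1) * u * P[, k] - (k - 1) * P[, k - 1]) / k
  sweep(P, 2, sqrt(2 * seq(0, kmax) + 1), `*`)
}

# all multi-indices of dimension d with total degree <= p (constant first)
total_degree_indices <- function(d, p) {
  grids <- replicate(d, 0:p, simplify = FALSE)
  idx <- as.matrix(do.call(expand.grid, grids))
  idx <- idx[rowSums(idx) <= p, , drop = FALSE]
  idx <- idx[order(rowSums(idx), apply(idx, 1, paste, collapse = ",")), ,
             drop = FALSE]
  dimnames(idx) <- NULL
  idx
}

# design matrix of the orthonormal tensor basis at points u (n x d in [-1,1])
pce_design <- function(u, indices) {
  d <- ncol(u)
  kmax <- max(indices)
  legs <- lapply(seq_len(d), function(j) legendre_matrix(u[, j], kmax))
  M <- nrow(indices)
  out <- matrix(1, nrow(u), M)
  for (m in seq_len(M))
    for (j in seq_len(d))
      if (indices[m, j] > 0) out[, m] <- out[, m] * legs[[j]][, indices[m, j] + 1]
  out
}

#' Build a polynomial-chaos surrogate by point collocation
#'
#' Expands the model output in polynomials orthonormal with respect to the
#' (uniform) parameter distributions, with coefficients estimated by least
#' squares on a seeded random collocation design of `2 M + 2` nodes
#' (oversampling factor two as is standard for point collocation).
#'
#' @param model function taking a named numeric vector of parameters (native
#'   units) and returning a numeric output vector (constant length).
#' @param params list of [uncertain_parameter()]s.
#' @param order total polynomial degree (default 4).
#' @param seed integer seed for the node draw.
#' @param validate optional function taking the parameter vector and
#'   returning `TRUE` for admissible nodes; rejected nodes are redrawn so
#'   the design size stays fixed.
#' @return a `pce_surrogate`.
#' @export
build_surrogate <- function(model, params, order = 4, seed = 1L,
                            validate = NULL) {
  d <- length(params)
  indices <- total_degree_indices(d, order)
  M <- nrow(indices)
  n_nodes <- pce_node_count(d, order)
  lows <- vapply(params, `[[`, 0, "low")
  highs <- vapply(params, `[[`, 0, "high")
  nm <- vapply(params, `[[`, "", "name")
  u <- with_seed(seed, {
    U <- matrix(runif(n_nodes * d, -1, 1), n_nodes, d)
    if (!is.null(validate)) {
      for (i in seq_len(n_nodes)) {
        tries <- 0
        repeat {
          x <- lows + (U[i, ] + 1) / 2 * (highs - lows)
          names(x) <- nm
          if (validate(x)) break
          U[i, ] <- runif(d, -1, 1)
          tries <- tries + 1
          if (tries > 1000) stop("could not draw an admissible node")
        }
      }
    }
    U
  })
  X <- sweep(sweep(u, 2, (highs - lows) / 2, `*`), 2,
             (lows + highs) / 2, `+`)
  Y <- NULL
  for (i in seq_len(n_nodes)) {
    x <- X[i, ]; names(x) <- nm
    yi <- model(x)
    if (is.null(Y)) Y <- matrix(0, n_nodes, length(yi),
                                dimnames = list(NULL, names(yi)))
    Y[i, ] <- yi
  }
  Psi <- pce_design(u, indices)
  qrP <- qr(Psi)
  if (qrP$rank < M)
    stop("rank-deficient collocation matrix (rank ", qrP$rank, " < ", M,
         "); increase the node count or lower the order")
  coef <- qr.coef(qrP, Y)
  structure(list(params = params, names = nm, order = order,
                 indices = indices, M = M, coef = coef,
                 nodes = X, node_outputs = Y,
                 lows = lows, highs = highs, seed = seed),
            class = "pce_surrogate")
}

#' Evaluate a PCE surrogate
#'
#' @param object a `pce_surrogate`.
#' @param newdata matrix of parameter points (native units), one row per
#'   point.
#' @param ... unused.
#' @return matrix of surrogate outputs (points x outputs).
#' @export
predict.pce_surrogate <- function(object, newdata, ...) {
  newdata <- matrix(newdata, ncol = length(object$params))
  u <- sweep(sweep(newdata, 2, (object$lows + object$highs) / 2, `-`),
             2, (object$highs - object$lows) / 2, `/`)
  pce_design(u, object$indices) %*% object$coef
}

#' First-order Sobol indices of a PCE surrogate
#'
#' From the orthonormal expansion, `S_i` is the coefficient power of basis
#' terms depending on parameter `i` alone, divided by the total variance.
#' Outputs with zero variance report all indices as 0.
#'
#' @param s a `pce_surrogate`.
#' @return matrix (parameters x outputs) of first-order indices.
#' @export
sobol_first_order <- function(s) {
  nonconst <- rowSums(s$indices) > 0
  totvar <- colSums(s$coef[nonconst, , drop = FALSE]^2)
  # a constant model leaves only round-off in the non-constant coefficients;
  # declare zero variance relative to the output scale
  scale <- s$coef[1, ]^2 + totvar
  live <- totvar > 1e-20 * pmax(scale, 1e-300)
  d <- length(s$params)
  out <- matrix(0, d, ncol(s$coef),
                dimnames = list(s$names, colnames(s$coef)))
  for (i in seq_len(d)) {
    only_i <- s$indices[, i] > 0 &
      rowSums(s$indices[, -i, drop = FALSE]) == 0
    vi <- colSums(s$coef[only_i, , drop = FALSE]^2)
    out[i, ] <- ifelse(live, vi / totvar, 0)
  }
  out
}

#' Surrogate-sampled prediction interval
#'
#' Empirical 5th and 95th percentiles (and mean) of the surrogate evaluated
#' at `n_samples` independent parameter draws.
#'
#' @param s a `pce_surrogate`.
#' @param n_samples Monte-Carlo sample count (default 10^4).
#' @param seed integer seed.
#' @param probs percentile pair.
#' @return list with `p5`, `p95`, `mean` (vectors over outputs).
#' @export
prediction_interval <- function(s, n_samples = 1e4, seed = 1L,
                                probs = c(0.05, 0.95)) {
  stopifnot(n_samples >= 100)
  d <- length(s$params)
  X <- with_seed(seed, {
    U <- matrix(runif(n_samples * d, -1, 1), n_samples, d)
    sweep(sweep(U, 2, (s$highs - s$lows) / 2, `*`), 2,
          (s$lows + s$highs) / 2, `+`)
  })
  Yh <- predict(s, X)
  q <- apply(Yh, 2, quantile, probs = probs, names = FALSE)
  list(p5 = q[1, ], p95 = q[2, ], mean = colMeans(Yh))
}

# shared output layout: named vector over quantity x frequency
spectrum_outputs <- function(diel) {
  out <- c(diel$sigma_eff, diel$eps_r_eff)
  names(out) <- c(paste0("sigma_eff@", signif(diel$frequency, 6)),
                  paste0("eps_r_eff@", signif(diel$frequency, 6)))
  out
}

# aggregate a fitted surrogate into the tidy UQ result
uq_aggregate <- function(s, frequencies, n_samples = 1e4, seed = 1L) {
  pi_ <- prediction_interval(s, n_samples, seed)
  sob <- sobol_first_order(s)
  nonconst <- rowSums(s$indices) > 0
  vars <- colSums(s$coef[nonconst, , drop = FALSE]^2)
  nf <- length(frequencies)
  qty <- rep(c("sigma_eff", "eps_r_eff"), each = nf)
  df <- data.frame(frequency = rep(frequencies, 2), quantity = qty,
                   mean = s$coef[1, ], variance = vars,
                   p5 = pi_$p5, p95 = pi_$p95, row.names = NULL)
  for (p in rownames(sob)) df[[paste0("S_", p)]] <- sob[p, ]
  structure(list(table = df, surrogate = s, sobol = sob,
                 frequencies = frequencies),
            class = "uq_result")
}

#' @export
print.uq_result <- function(x, ...) {
  cat("uq_result over", length(x$frequencies), "frequencies;",
      length(x$surrogate$params), "uncertain parameters\n")
  print(head(x$table))
  invisible(x)
}

#' Geometric-uncertainty UQ (case 1)
#'
#' Two-cell unit geometry: one cell at the box centre whose x/y/z position,
#' volume and orientation angle are uncertain, and a fixed copy towards the
#' top-right corner. The position range is constructed so the
#' surface-to-surface distance between the cells spans
#' `distance_span` (default 4.5-22.5 µm); nodes where the two cells would
#' intersect are redrawn. Every collocation node rebuilds the geometry,
#' runs the frequency sweep and extracts the dielectric spectrum.
#'
#' @param props a [material_props()].
#' @param box cubic box edge, µm.
#' @param n_vox voxels per axis.
#' @param base_volume nominal cell volume, µm³.
#' @param axis_ratio prolate a:c ratio of the cell shape.
#' @param volume_rel relative half-width of the volume range (default 0.25).
#' @param angle_range orientation angle range, radians (rotation about y).
#' @param distance_span surface-to-surface distance span to realise, µm.
#' @param frequencies sweep frequencies, Hz.
#' @param order PCE order.
#' @param seed integer seed.
#' @param tol solver tolerance.
#' @return a `uq_result`.
#' @export
run_case1 <- function(props = material_props(), box = 48, n_vox = 32L,
                      base_volume = 524, axis_ratio = 1.5,
                      volume_rel = 0.25, angle_range = c(0, pi / 2),
                      distance_span = c(4.5, 22.5),
                      frequencies = 10^seq(4, 9, length.out = 6),
                      order = 4, seed = 1L, tol = 1e-8) {
  r_eff <- (3 * base_volume / (4 * pi))^(1 / 3)
  dmin <- distance_span[1] + 2 * r_eff
  dmax <- distance_span[2] + 2 * r_eff
  d0 <- (dmin + dmax) / 2
  delta <- (dmax - dmin) / (2 * sqrt(3))
  ctr <- box / 2
  fixed_ctr <- ctr + d0 / sqrt(3)
  make_cell <- function(volume, offset, angle, label, center) {
    # prolate shape a : b = a : c = axis_ratio at the requested volume
    cc <- (3 * volume / (4 * pi) / axis_ratio)^(1 / 3)
    a <- axis_ratio * cc
    data.frame(label = label, cx = center[1] + offset[1],
               cy = center[2] + offset[2], cz = center[3] + offset[3],
               a = a, b = cc, c = cc, phi = 0, theta = angle, psi = 0)
  }
  fixed <- make_cell(base_volume, c(0, 0, 0), 0, 2L,
                     rep(fixed_ctr, 3))
  params <- list(
    uncertain_parameter("x", -delta, delta),
    uncertain_parameter("y", -delta, delta),
    uncertain_parameter("z", -delta, delta),
    uncertain_parameter("volume", base_volume * (1 - volume_rel),
                        base_volume * (1 + volume_rel)),
    uncertain_parameter("angle", angle_range[1], angle_range[2]))
  build_cells <- function(x) {
    mov <- make_cell(x[["volume"]], x[c("x", "y", "z")], x[["angle"]], 1L,
                     rep(ctr, 3))
    ellipsoid_set(rbind(mov, fixed))
  }
  validate <- function(x) {
    cells <- build_cells(x)
    nrow(build_intersection_graph(cells)$edges) == 0
  }
  model <- function(x) {
    cells <- build_cells(x)
    geom <- voxelize_geometry(cells = cells, box = rep(box, 3),
                              voxel_size = box / n_vox,
                              electrode_axis = "x")
    sp <- frequency_sweep(geom, props, frequencies = frequencies, tol = tol)
    spectrum_outputs(extract_dielectric(sp))
  }
  s <- build_surrogate(model, params, order = order, seed = seed,
                       validate = validate)
  uq_aggregate(s, frequencies, seed = seed)
}

#' Material-property UQ on a fixed geometry (case 2)
#'
#' Probes an uncertain membrane thickness and uncertain dielectric
#' properties on a fixed tissue geometry. With `fix_extracellular = TRUE`
#' (the buffer is measurable separately and would otherwise overshadow the
#' cellular parameters) the active set is `d_m`, `sigma_m`, `sigma_cyt`,
#' `eps_rm`, `eps_rcyt`; otherwise `sigma_buf` and `eps_rbuf` are also
#' uncertain (7 parameters).
#'
#' @param geom a `tissue_geometry`.
#' @param nominal nominal [material_props()].
#' @param rel_range relative half-width of every parameter range.
#' @param fix_extracellular keep the buffer properties fixed.
#' @param frequencies sweep frequencies, Hz.
#' @param order PCE order.
#' @param seed integer seed.
#' @param tol solver tolerance.
#' @return a `uq_result`.
#' @export
run_case2 <- function(geom, nominal = material_props(), rel_range = 0.25,
                      fix_extracellular = TRUE,
                      frequencies = 10^seq(4, 9, length.out = 6),
                      order = 4, seed = 1L, tol = 1e-8) {
  active <- c("d_m", "sigma_m", "sigma_cyt", "eps_rm", "eps_rcyt")
  if (!fix_extracellular) active <- c(active, "sigma_buf", "eps_rbuf")
  params <- lapply(active, function(p)
    uncertain_parameter(p, nominal[[p]] * (1 - rel_range),
                        nominal[[p]] * (1 + rel_range)))
  model <- function(x) {
    pr <- nominal
    for (p in names(x)) pr[[p]] <- x[[p]]
    sp <- frequency_sweep(geom, pr, frequencies = frequencies, tol = tol)
    spectrum_outputs(extract_dielectric(sp))
  }
  s <- build_surrogate(model, params, order = order, seed = seed)
  uq_aggregate(s, frequencies, seed = seed)
}
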