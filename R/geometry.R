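#' Pairwise cell intersection graph
#'
#' Tests every unordered pair of cells for geometric intersection or touch
#' and records the touching pairs as graph edges. All n(n-1)/2 logical pair
#' checks are counted (a bounding-sphere prefilter only short-circuits the
#' expensive surface test). Two ellipsoids intersect when a deterministic
#' sample of surface points of one lies inside the other (within
#' tolerance), or vice versa, or when one contains the other's centre.
#'
#' @param cells an [ellipsoid_set()].
#' @param tol touch tolerance, µm.
#' @param n_surface surface sample points per ellipsoid.
#' @return an `intersection_graph`: list with `nodes`, `edges` (2-column
#'   matrix of label pairs), `n_checks` and `graph` (igraph object).
#' @export
build_intersection_graph <- function(cells, tol = 0.01, n_surface = 1000) {
  n <- nrow(cells)
  n_checks <- n * (n - 1) / 2
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    pts <- lapply(seq_len(n), function(i)
      ellipsoid_surface_points(cells[i, ], n_surface))
    ctr <- as.matrix(cells[, c("cx", "cy", "cz")])
    amax <- cells$a
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d <- sqrt(sum((ctr[i, ] - ctr[j, ])^2))
        if (d > amax[i] + amax[j] + tol) next   # bounding-sphere reject
        # scale tolerance into normalised coordinates of the containing cell
        ti <- 1 + tol / cells$c[i]
        tj <- 1 + tol / cells$c[j]
        hit <- any(ellipsoid_coordinate(cells[i, ], pts[[j]]) <= ti) ||
          any(ellipsoid_coordinate(cells[j, ], pts[[i]]) <= tj) ||
          ellipsoid_coordinate(cells[i, ], ctr[j, , drop = FALSE]) <= ti ||
          ellipsoid_coordinate(cells[j, ], ctr[i, , drop = FALSE]) <= tj
        if (hit) edges <- rbind(edges, c(cells$label[i], cells$label[j]))
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (n > 0) igraph::V(g)$name <- as.character(cells$label)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, as.character(t(edges)))
  structure(list(nodes = cells$label, edges = edges,
                 n_checks = n_checks, graph = g),
            class = "intersection_graph")
}

# fundamental cycles of each connected component from a BFS spanning tree
fundamental_cycles <- function(g) {
  if (igraph::ecount(g) == 0) return(list())
  mst <- igraph::mst(g)
  in_tree <- igraph::get_edge_ids(mst, t(igraph::ends(g, igraph::E(g)))) > 0
  extra <- igraph::E(g)[!in_tree]
  lapply(seq_along(extra), function(k) {
    ep <- igraph::ends(g, extra[k])[1, ]
    path <- igraph::shortest_paths(mst, from = ep[1], to = ep[2])$vpath[[1]]
    as.integer(igraph::V(g)$name[path])
  })
}

#' Detect voids enclosed by cell cycles and fill them with spheres
#'
#' Intersecting cells form cycles in the intersection graph; the fused
#' pairwise common volumes of a cycle can enclose a small void that breaks
#' downstream meshing. For each fundamental cycle the member cells are
#' voxelised at fine resolution; when the fused common volumes form more
#' than one connected piece or the union of the cells encloses a background
#' cavity, the cavity is filled with a sphere centred at the cavity
#' centroid with a margin-scaled covering radius.
#'
#' @param g an `intersection_graph` built from `cells`.
#' @param cells the same [ellipsoid_set()].
#' @param margin filler radius margin factor over the cavity bounding
#'   radius.
#' @param rel_resolution local voxel size as a fraction of the smallest
#'   semi-axis in the cycle.
#' @param max_cavity_frac cavities larger than this fraction of the cycle
#'   union volume are flagged for manual review instead of auto-filled.
#' @return data frame of filler spheres (`cx`, `cy`, `cz`, `r`,
#'   `needs_review`); zero rows when no cycles or no voids exist.
#' @export
detect_and_fill_voids <- function(g, cells, margin = 1.1,
                                  rel_resolution = 0.15,
                                  max_cavity_frac = 0.5) {
  cycles <- fundamental_cycles(g$graph)
  out <- data.frame(cx = numeric(), cy = numeric(), cz = numeric(),
                    r = numeric(), needs_review = logical())
  for (cyc in cycles) {
    sub <- cells[cells$label %in% cyc, , drop = FALSE]
    h <- rel_resolution * min(sub$c)
    lo <- c(min(sub$cx - sub$a), min(sub$cy - sub$a), min(sub$cz - sub$a)) - 2 * h
    hi <- c(max(sub$cx + sub$a), max(sub$cy + sub$a), max(sub$cz + sub$a)) + 2 * h
    dims <- as.integer(ceiling((hi - lo) / h))[c(3, 2, 1)]  # (z, y, x)
    shifted <- sub
    shifted$cx <- sub$cx - lo[1]; shifted$cy <- sub$cy - lo[2]
    shifted$cz <- sub$cz - lo[3]
    lab <- cpp_render_labels(as.matrix(shifted[, c("cx", "cy", "cz")]),
                             as.matrix(shifted[, c("a", "b", "c")]),
                             cell_rotations(shifted),
                             as.integer(shifted$label), dims, rep(h, 3))
    union_mask <- array(as.integer(lab > 0), dims)
    # fused pairwise common volumes
    memb <- lapply(seq_len(nrow(shifted)), function(i) {
      one <- cpp_render_labels(as.matrix(shifted[i, c("cx", "cy", "cz")]),
                               as.matrix(shifted[i, c("a", "b", "c")]),
                               cell_rotations(shifted[i, ]), 1L,
                               dims, rep(h, 3))
      one > 0
    })
    fused <- array(FALSE, dims)
    for (i in seq_len(length(memb) - 1))
      for (j in seq(i + 1, length(memb)))
        fused <- fused | (memb[[i]] & memb[[j]])
    n_fused <- max(cpp_label3d(array(as.integer(fused), dims), dims, 26L))
    filled <- cpp_fill_holes(union_mask, dims)
    cavity <- filled > 0 & union_mask == 0
    if (!any(cavity) && n_fused > 1) {
      # fused common volumes fragment without a closed cavity: the void is
      # the gap spanned between the fused pieces (an open channel through
      # the cycle); take the uncovered voxels within their bounding sphere
      fidx <- which(fused)
      fz <- (fidx - 1) %% dims[1]
      fy <- ((fidx - 1) %/% dims[1]) %% dims[2]
      fx <- (fidx - 1) %/% (dims[1] * dims[2])
      fp <- cbind((fx + 0.5) * h, (fy + 0.5) * h, (fz + 0.5) * h)
      v0 <- colMeans(fp)
      rad0 <- max(sqrt(rowSums(sweep(fp, 2, v0)^2)))
      aidx <- which(union_mask == 0)
      az <- (aidx - 1) %% dims[1]
      ay <- ((aidx - 1) %/% dims[1]) %% dims[2]
      ax2 <- (aidx - 1) %/% (dims[1] * dims[2])
      ap <- cbind((ax2 + 0.5) * h, (ay + 0.5) * h, (az + 0.5) * h)
      near <- sqrt(rowSums(sweep(ap, 2, v0)^2)) <= rad0
      cavity[aidx[near]] <- TRUE
    }
    if (!any(cavity)) next
    idx <- which(cavity)
    iz <- (idx - 1) %% dims[1]
    iy <- ((idx - 1) %/% dims[1]) %% dims[2]
    ix <- (idx - 1) %/% (dims[1] * dims[2])
    pc <- cbind((ix + 0.5) * h + lo[1], (iy + 0.5) * h + lo[2],
                (iz + 0.5) * h + lo[3])
    ctr <- colMeans(pc)
    rad <- max(sqrt(rowSums(sweep(pc, 2, ctr)^2))) + h / 2
    frac <- length(idx) / max(sum(union_mask), 1)
    out <- rbind(out, data.frame(cx = ctr[1], cy = ctr[2], cz = ctr[3],
                                 r = margin * rad,
                                 needs_review = frac > max_cavity_frac))
  }
  out
}
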