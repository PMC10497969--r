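#' Triangle mesh container
#'
#' @param vertices V x 3 matrix of (x, y, z) coordinates, µm.
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @param label optional cell label the mesh belongs to.
#' @return a `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, label = NULL) {
  structure(list(vertices = vertices, faces = faces, label = label),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("tri_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces",
      if (!is.null(x$label)) paste0("(label ", x$label, ")"), "\n")
  invisible(x)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem; positive for outward-oriented
#' closed surfaces.
#'
#' @param mesh a `tri_mesh`.
#' @return volume, µm³.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Surface area of a mesh
#'
#' @param mesh a `tri_mesh`.
#' @return total triangle area, µm².
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  nx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  ny <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  nz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sum(sqrt(nx^2 + ny^2 + nz^2)) / 2
}

#' Watertightness (edge-manifold) check
#'
#' A closed manifold surface has every undirected edge shared by exactly
#' two triangles.
#'
#' @param mesh a `tri_mesh`.
#' @return `TRUE` if every edge is used by exactly 2 faces.
#' @export
is_watertight <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0) return(FALSE)
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' Number of connected components of a mesh
#'
#' @param mesh a `tri_mesh`.
#' @return component count (over vertices used by faces).
#' @export
mesh_components <- function(mesh) {
  F <- mesh$faces
  g <- igraph::make_graph(edges = as.vector(t(rbind(F[, 1:2], F[, 2:3]))),
                          n = nrow(mesh$vertices), directed = FALSE)
  comp <- igraph::components(g)
  length(unique(comp$membership[unique(as.vector(F))]))
}

#' Extract an iso-surface mesh from a scalar field
#'
#' Marches the Freudenthal tetrahedral decomposition of the voxel grid
#' (a tessellation-consistent variant of marching cubes) over the field and
#' returns a closed, outward-oriented triangle mesh of the region
#' `field > iso`. Field values live on voxel centres.
#'
#' @param field 3D numeric array, dim `(nz, ny, nx)`.
#' @param voxel_size scalar or length-3 voxel size (z, y, x), µm.
#' @param iso iso level.
#' @param origin physical position of voxel centre `(0, 0, 0)`, (x, y, z) µm.
#' @return a `tri_mesh`.
#' @export
mesh_from_field <- function(field, voxel_size, iso = 0.5,
                            origin = NULL) {
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (is.null(origin))
    origin <- c(voxel_size[3], voxel_size[2], voxel_size[1]) / 2
  # cpp origin order is (z, y, x)
  res <- cpp_marching_tets(field, dim(field),
                           voxel_size, c(origin[3], origin[2], origin[1]), iso)
  tri_mesh(res$vertices, res$faces)
}

#' Extract per-cell surface meshes from a labelled volume
#'
#' For each label the binary occupancy is padded by one background voxel
#' (so surfaces of border-touching cells close), optionally smoothed with a
#' small Gaussian to relax the voxel staircase, and triangulated at the 0.5
#' iso level. Mesh coordinates are in physical µm.
#'
#' @param labels a [labeled_volume()] (or integer array plus `voxel_size`).
#' @param level iso level on the (possibly smoothed) occupancy.
#' @param smooth_sigma Gaussian pre-smoothing sigma in voxels (0 disables).
#' @param voxel_size used when `labels` is a bare array.
#' @return named list of `tri_mesh` objects, one per label.
#' @export
extract_surface_mesh <- function(labels, level = 0.5, smooth_sigma = 1,
                                 voxel_size = NULL) {
  if (inherits(labels, "labeled_volume")) {
    lab <- labels$labels; vs <- labels$voxel_size
  } else {
    lab <- labels; vs <- rep_len(voxel_size, 3)
  }
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) stop("no labels to mesh")
  out <- list()
  d <- dim(lab)
  for (k in ids) {
    idx <- which(lab == k, arr.ind = TRUE)
    pad <- 2L
    lo <- pmax(apply(idx, 2, min) - pad, 1L)
    hi <- pmin(apply(idx, 2, max) + pad, d)
    sub <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == k
    # guarantee one background layer even at the volume border
    f <- array(0, dim(sub) + 2L)
    f[2:(dim(sub)[1] + 1), 2:(dim(sub)[2] + 1), 2:(dim(sub)[3] + 1)] <-
      as.numeric(sub)
    if (smooth_sigma > 0)
      f <- cpp_gauss_blur(f, dim(f), rep(smooth_sigma, 3))
    # first padded voxel has 0-based index lo - 2, centre at (lo - 1.5) * h
    origin_xyz <- c((lo[3] - 1.5) * vs[3], (lo[2] - 1.5) * vs[2],
                    (lo[1] - 1.5) * vs[1])
    m <- mesh_from_field(f, vs, iso = level, origin = origin_xyz)
    m$label <- k
    out[[as.character(k)]] <- m
  }
  out
}

#' Taubin lambda/mu mesh smoothing
#'
#' Alternating shrink (`lambda > 0`) and inflate (`mu < 0`) uniform-weight
#' Laplacian steps. With `|mu| > lambda` the pass-band filter smooths the
#' staircase without the systematic shrinkage of plain Laplacian smoothing,
#' which is why it is the volume-preserving choice for cell surfaces.
#' Connectivity is unchanged.
#'
#' @param mesh a `tri_mesh`.
#' @param lambda positive smoothing factor.
#' @param mu negative inflation factor (`|mu| > lambda` recommended).
#' @param iterations number of lambda/mu passes.
#' @return the smoothed `tri_mesh`.
#' @export
taubin_smooth <- function(mesh, lambda = 0.5, mu = -0.53, iterations = 10) {
  stopifnot(lambda >= 0, mu <= 0, iterations >= 0)
  if (iterations == 0 || lambda == 0) return(mesh)
  V <- mesh$vertices; F <- mesh$faces
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                            dims = c(nrow(V), nrow(V)))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  lap <- function(X) as.matrix(A %*% X) / deg - X
  for (it in seq_len(iterations)) {
    V <- V + lambda * lap(V)
    if (mu != 0) V <- V + mu * lap(V)
  }
  tri_mesh(V, F, mesh$label)
}

#' Quadric edge-collapse decimation
#'
#' Collapses edges in order of quadric error until the face count drops to
#' `target_faces`, preserving edge-manifoldness (collapses violating the
#' link condition or flipping triangle normals are rejected). Stops early
#' with a warning when the target cannot be reached without breaking the
#' mesh.
#'
#' @param mesh a `tri_mesh`.
#' @param target_faces requested face budget (>= 4).
#' @return the simplified `tri_mesh`.
#' @export
decimate <- function(mesh, target_faces) {
  stopifnot(target_faces >= 4)
  if (nrow(mesh$faces) <= target_faces) return(mesh)
  res <- cpp_decimate(mesh$vertices, mesh$faces, as.integer(target_faces))
  if (!res$reached_target)
    warning("decimation stopped early at ", nrow(res$faces),
            " faces to preserve manifoldness")
  tri_mesh(res$vertices, res$faces, mesh$label)
}

#' Mesh fidelity report
#'
#' Signed relative differences (in percent) of the mesh volume and area
#' against analytic reference values.
#'
#' @param mesh a `tri_mesh`.
#' @param reference_volume analytic volume, µm³ (> 0).
#' @param reference_area analytic area, µm² (> 0).
#' @return list with `volume_error_pct` and `area_error_pct`.
#' @export
mesh_fidelity_report <- function(mesh, reference_volume, reference_area) {
  stopifnot(reference_volume > 0, reference_area > 0)
  list(volume_error_pct = 100 * (mesh_volume(mesh) - reference_volume) /
         reference_volume,
       area_error_pct = 100 * (mesh_area(mesh) - reference_area) /
         reference_area)
}

#' Write a binary STL file
#'
#' Little-endian binary STL, coordinates in µm.
#'
#' @param mesh a `tri_mesh` (or list of them, concatenated).
#' @param path output file.
#' @export
write_stl <- function(mesh, path) {
  if (inherits(mesh, "tri_mesh")) mesh <- list(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0, 80)), con)
  ntri <- sum(vapply(mesh, function(m) nrow(m$faces), 1L))
  writeBin(as.integer(ntri), con, size = 4, endian = "little")
  for (m in mesh) {
    V <- m$vertices; F <- m$faces
    u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
    w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
    n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
    len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
    n <- n / len
    for (f in seq_len(nrow(F))) {
      writeBin(as.numeric(c(n[f, ], V[F[f, 1], ], V[F[f, 2], ], V[F[f, 3], ])),
               con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a binary STL file
#'
#' Vertices are welded by exact coordinate match so that closed surfaces
#' round-trip watertight.
#'
#' @param path STL file.
#' @return a `tri_mesh`.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  dat <- matrix(0, ntri, 9)
  for (f in seq_len(ntri)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
    dat[f, ] <- rec[4:12]
  }
  pts <- rbind(dat[, 1:3], dat[, 4:6], dat[, 7:9])
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  V <- pts[uk, , drop = FALSE]
  F <- matrix(vid, ntri, 3)
  tri_mesh(V, F)
}
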