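#' Default pipeline configuration
#'
#' A small, fully specified configuration for the end-to-end pipeline:
#' synthetic stack generation, segmentation, voxelisation, impedance sweep,
#' dielectric extraction and (optionally) uncertainty quantification.
#'
#' @param seed master seed; stage seeds are derived deterministically.
#' @return nested configuration list.
#' @export
pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synth = list(n_cells = 2, box = c(32, 32, 32), voxel_size = 1,
                 volume_mean = 500, volume_sd = 100,
                 noise_preset = "clean", allow_touching = FALSE,
                 min_gap = 2),
    segment = list(watershed_h = 2),
    solve = list(frequencies = c(1e4, 1e6, 1e8), electrode_axis = "x",
                 tol = 1e-9),
    uq = list(case = NULL, frequencies = 10^seq(4, 8, length.out = 3),
              order = 2)
  )
}

#' Run the full pipeline
#'
#' Executes synth -> segment -> evaluate -> voxelize -> solve ->
#' dielectric -> (optional) uq, writing every stage artifact to `out_dir`
#' (TIFF stacks, CSV tables and spectra) plus a JSON run manifest with the
#' configuration snapshot, content hashes, per-stage timings and status.
#' A stage failure is recorded and downstream stages are skipped.
#'
#' @param config configuration list (see [pipeline_config()]) or path to a
#'   JSON file with the same structure.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = paste0("chondrosim ",
                                 as.character(utils::packageVersion("chondrosim"))),
                   config = config, files = list(), timings = list(),
                   status = list())
  seed <- as.integer(config$seed)
  state <- new.env()
  reg <- function(name, path) manifest$files[[name]] <<- path
  stage <- function(name, fun) {
    if (any(unlist(manifest$status) == "failed")) {
      manifest$status[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) {
                     manifest$status[[name]] <<- "failed"
                     manifest$error <<- conditionMessage(e)
                     FALSE
                   })
    if (ok) manifest$status[[name]] <<- "ok"
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  stage("synth", function() {
    cf <- config$synth
    cells <- sample_population(cf$n_cells, cf$box,
                               volume_mean = cf$volume_mean,
                               volume_sd = cf$volume_sd,
                               allow_touching = isTRUE(cf$allow_touching),
                               min_gap = if (is.null(cf$min_gap)) 0 else cf$min_gap,
                               seed = seed)
    nm <- noise_preset(cf$noise_preset, seed = seed + 1L)
    rs <- render_stack(cells, voxel_size = cf$voxel_size, noise = nm,
                       box = cf$box)
    state$cells_gt <- cells
    state$stack <- rs$stack
    state$labels_gt <- rs$labels
    write_stack(rs$stack, file.path(out_dir, "stack.tif"),
                meta = list(seed = seed))
    write_stack(rs$labels, file.path(out_dir, "labels_gt.tif"))
    write_ellipsoids(cells, file.path(out_dir, "cells_gt.csv"))
    reg("stack", file.path(out_dir, "stack.tif"))
    reg("labels_gt", file.path(out_dir, "labels_gt.tif"))
    reg("cells_gt", file.path(out_dir, "cells_gt.csv"))
  })

  stage("segment", function() {
    cfg <- do.call(segmentation_config, config$segment)
    res <- segment_stack(state$stack, cfg)
    state$labels_pred <- res$labels
    state$cells_pred <- res$cells
    write_stack(res$labels, file.path(out_dir, "labels_pred.tif"))
    write_ellipsoids(res$cells, file.path(out_dir, "cells_pred.csv"))
    m <- match_instances(res$labels, state$labels_gt, tau = 0.5)
    met <- c(list(tp = m$tp, fp = m$fp, fn = m$fn, tau = m$tau,
                  accuracy = accuracy(m)), precision_recall_f1(m))
    jsonlite::write_json(met, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    reg("labels_pred", file.path(out_dir, "labels_pred.tif"))
    reg("cells_pred", file.path(out_dir, "cells_pred.csv"))
    reg("metrics", file.path(out_dir, "metrics.json"))
  })

  stage("voxelize", function() {
    cf <- config$synth
    state$geom <- voxelize_geometry(cells = state$cells_pred, box = cf$box,
                                    voxel_size = cf$voxel_size,
                                    electrode_axis = config$solve$electrode_axis)
    jsonlite::write_json(list(box_um = cf$box, voxel_um = cf$voxel_size,
                              n_membrane_faces = nrow(state$geom$faces),
                              volume_fraction = volume_fraction(state$geom)),
                         file.path(out_dir, "geometry.json"),
                         auto_unbox = TRUE, digits = NA)
    reg("geometry", file.path(out_dir, "geometry.json"))
  })

  stage("solve", function() {
    cf <- config$solve
    state$spec <- frequency_sweep(state$geom, material_props(),
                                  frequencies = cf$frequencies,
                                  tol = cf$tol)
    write_spectrum(state$spec, file.path(out_dir, "spectrum.csv"))
    reg("spectrum", file.path(out_dir, "spectrum.csv"))
  })

  stage("dielectric", function() {
    diel <- extract_dielectric(state$spec)
    write_dielectric(diel, file.path(out_dir, "dielectric.csv"))
    reg("dielectric", file.path(out_dir, "dielectric.csv"))
  })

  if (!is.null(config$uq$case)) {
    stage("uq", function() {
      cf <- config$uq
      res <- if (cf$case == 1)
        run_case1(frequencies = cf$frequencies, order = cf$order,
                  seed = seed + 2L)
      else run_case2(state$geom, frequencies = cf$frequencies,
                     order = cf$order, seed = seed + 2L)
      write.csv(res$table, file.path(out_dir, sprintf("uq_case%d.csv", cf$case)),
                row.names = FALSE)
      reg("uq", file.path(out_dir, sprintf("uq_case%d.csv", cf$case)))
    })
  }

  hashes <- lapply(manifest$files, function(p)
    unname(tools::md5sum(p)))
  manifest$hashes <- hashes
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
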