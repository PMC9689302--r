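# File export: legacy-ASCII VTK fields for inspection, tidy CSV metrics,
# leaflet trajectories and a JSON run manifest.

#' Write cell-centred fields as a legacy VTK image file
#'
#' STRUCTURED_POINTS, ASCII, with one scalar dataset per field.  Intended
#' for inspection in ParaView or similar.
#'
#' @param path output file path (`.vtk`).
#' @param grid a [flow_grid()].
#' @param fields named list of `nx x ny` matrices.
#' @return `path`, invisibly.
#' @export
write_vtk_image <- function(path, grid, fields) {
  stopifnot(length(fields) > 0, !is.null(names(fields)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "ijvflow field export", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", grid$nx, grid$ny),
               sprintf("ORIGIN %.9g %.9g 0", grid$hx / 2, grid$hy / 2),
               sprintf("SPACING %.9g %.9g 1", grid$hx, grid$hy),
               sprintf("POINT_DATA %d", grid$nx * grid$ny)), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    stopifnot(identical(dim(f), c(grid$nx, grid$ny)))
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    # VTK expects x fastest: our matrices are [i (x), j (y)], so column
    # by column is already the right order
    writeLines(formatC(as.vector(f), format = "g", digits = 9), con)
  }
  invisible(path)
}

# cell-centred fields of a snapshot for export
snapshot_fields <- function(solver, snap) {
  cv <- center_velocity(solver, snap)
  f <- list(u = cv$u, v = cv$v, speed = sqrt(cv$u^2 + cv$v^2),
            p = snap$p, solid = matrix(as.numeric(solver$mask),
                                       solver$grid$nx, solver$grid$ny))
  if (!is.null(snap$k)) { f$k <- snap$k; f$omega <- snap$omega }
  f
}

#' Export a run's outputs to a directory
#'
#' Writes `metrics.csv`, `profile_final.csv` (maximum-velocity profile at
#' the last snapshot), one VTK file per snapshot, leaflet node
#' trajectories (`leaflets.csv`) and `manifest.json` (provenance: config,
#' hash, seed, package version, file list).
#'
#' @param result a [run_result][run_case()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
export_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  mpath <- file.path(out_dir, "metrics.csv")
  write.csv(result$metrics, mpath, row.names = FALSE)
  files <- c(files, mpath)

  snap <- result$snapshots[[length(result$snapshots)]]
  prof <- max_velocity_vs_x(result$solver, snap)
  ppath <- file.path(out_dir, "profile_final.csv")
  write.csv(data.frame(x = prof$x, vmax = prof$vmax), ppath,
            row.names = FALSE)
  files <- c(files, ppath)

  for (nm in names(result$snapshots)) {
    sn <- result$snapshots[[nm]]
    vpath <- file.path(out_dir,
                       sprintf("fields_%s.vtk", gsub("[^0-9a-zA-Z.]", "_", nm)))
    write_vtk_image(vpath, result$solver$grid,
                    snapshot_fields(result$solver, sn))
    files <- c(files, vpath)
  }

  if (!is.null(result$valve)) {
    rows <- do.call(rbind, lapply(names(result$snapshots), function(nm) {
      sn <- result$snapshots[[nm]]
      if (is.null(sn$valve)) return(NULL)
      do.call(rbind, lapply(c("lower", "upper"), function(side) {
        lf <- sn$valve[[side]]
        data.frame(time = sn$t, leaflet = side,
                   node = seq_along(lf$x), x = lf$x, y = lf$y)
      }))
    }))
    lpath <- file.path(out_dir, "leaflets.csv")
    write.csv(rows, lpath, row.names = FALSE)
    files <- c(files, lpath)
  }

  manifest <- list(case = result$label,
                   config = config_as_list(result$config),
                   provenance = result$provenance,
                   log = result$log,
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
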