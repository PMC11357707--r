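# Legacy-ASCII VTK structured-points export for visual inspection of
# label grids, SAR fields and temperature snapshots (ParaView-compatible).

.write_vtk_points <- function(path, grid, data_list) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "dmwasim field export",
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", grid$dim[1], grid$dim[2],
                       grid$dim[3]),
               sprintf("ORIGIN %g %g %g",
                       grid$origin[1] + grid$spacing / 2,
                       grid$origin[2] + grid$spacing / 2,
                       grid$origin[3] + grid$spacing / 2),
               sprintf("SPACING %g %g %g", grid$spacing, grid$spacing,
                       grid$spacing),
               sprintf("POINT_DATA %d", prod(grid$dim))), con)
  for (nm in names(data_list)) {
    v <- data_list[[nm]]
    writeLines(c(sprintf("SCALARS %s float 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(v), trim = TRUE, digits = 7), con)
  }
  invisible(path)
}

#' Export a label grid as a VTK structured-points file
#'
#' @param grid A `label_grid`.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_labels <- function(grid, path) {
  .write_vtk_points(path, grid,
                    list(tissue_label = array(as.numeric(grid$labels),
                                              dim = grid$dim)))
}

#' Export a SAR field as a VTK structured-points file
#'
#' @param sar A `sar_field`.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_sar <- function(sar, path) {
  .write_vtk_points(path, sar$grid, list(SAR_W_per_kg = sar$values))
}

#' Export a temperature snapshot as a VTK structured-points file
#'
#' @param field A `temperature_field`.
#' @param path Output `.vtk` path.
#' @param time_index Snapshot index, default the final one.
#' @return `path`, invisibly.
#' @export
write_vtk_temperature <- function(field, path,
                                  time_index = length(field$values)) {
  .write_vtk_points(path, field$grid,
                    list(temperature_C = field$values[[time_index]]))
}
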