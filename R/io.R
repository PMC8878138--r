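#' Write a mesh and element fields as legacy VTK
#'
#' Writes an ASCII legacy-VTK unstructured grid of the axisymmetric (r, z)
#' section, with any number of per-element (CELL_DATA) or per-node
#' (POINT_DATA) scalar fields.
#'
#' @param mesh A [build_mesh()] mesh.
#' @param path Output file path.
#' @param cell_data Named list of per-element numeric vectors.
#' @param point_data Named list of per-node numeric vectors.
#' @return \code{path}, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list(), point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- mesh$n_node; ne <- mesh$n_elem
  writeLines(c("# vtk DataFile Version 2.0",
               "osteoremod axisymmetric section",
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  coords <- expand.grid(r = mesh$r_nodes, z = mesh$z_nodes)
  writeLines(sprintf("%.9g %.9g 0", coords$r, coords$z), con)
  writeLines(sprintf("CELLS %d %d", ne, 5L * ne), con)
  conn <- t(vapply(seq_len(ne), function(e) elem_nodes(mesh, e) - 1L,
                   integer(4)))
  writeLines(sprintf("4 %d %d %d %d", conn[, 1], conn[, 2], conn[, 3],
                     conn[, 4]), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("9", ne), con)  # VTK_QUAD
  scalar_block <- function(fields, n, what) {
    if (length(fields) == 0) return()
    writeLines(sprintf("%s %d", what, n), con)
    for (nm in names(fields)) {
      stopifnot(length(fields[[nm]]) == n)
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default",
                   sprintf("%.9g", fields[[nm]])), con)
    }
  }
  scalar_block(cell_data, ne, "CELL_DATA")
  scalar_block(point_data, nn, "POINT_DATA")
  invisible(path)
}

#' Export a remodeling run
#'
#' Writes the snapshot time series as CSV, initial/final fields as legacy
#' VTK, and a JSON manifest of all resolved parameter values.
#'
#' @param result A [run_scenario()] result.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
export_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$snapshots, file.path(dir, "timeseries.csv"),
                   row.names = FALSE, quote = FALSE)
  write_vtk(result$mesh, file.path(dir, "fields.vtk"),
            cell_data = list(density_initial = result$initial_density,
                             density_final = result$final_density,
                             sed_final = result$final_solution$sed),
            point_data = list(ur = result$final_solution$ur,
                              uz = result$final_solution$uz))
  cfg <- result$config
  manifest <- list(
    scenario = cfg$name, scenario_energy_mJ = cfg$scenario_energy,
    duration_days = cfg$duration, dt_days = cfg$dt,
    coupling_interval_days = cfg$coupling_interval,
    energy_mode = cfg$energy_mode,
    delay = list(mode = cfg$delay$mode, coefficient = cfg$delay$coefficient,
                 rate_per_day = cfg$delay$rate_per_day),
    mesh_size_mm = cfg$mesh_size, density_floor = cfg$density_floor,
    activity = cfg$act[c("k1", "k2", "A1", "A2", "W0", "W1", "W2", "W3")],
    modulation = unclass(cfg$mod),
    material = unclass(cfg$material),
    mass_ledger_mg = list(formed = result$formed_mass,
                          resorbed = result$resorbed_mass,
                          net = result$net_mass))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
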