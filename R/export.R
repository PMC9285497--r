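## Plain-text exports: tidy CSV time series, VTU (VTK XML unstructured
## grid) field snapshots and a human-readable run report. Units are stated
## in the column headers.

#' Write the time-series CSV of a run
#'
#' One row per output sample: time, applied r.m.s. voltage, tip and
#' maximum temperature, and the perpendicular/parallel cell-death radii.
#' Deterministic: identical configurations produce byte-identical files.
#'
#' @param result An [run_simulation()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_result_csv <- function(result, path) {
  df <- data.frame(
    time_s = result$times,
    voltage_V = result$voltage,
    tip_temp_C = result$tip_T,
    max_temp_C = result$max_T,
    r_perp_mm = result$r_perp,
    r_par_mm = result$r_par)
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a mesh (with optional fields) as a VTK XML unstructured grid
#'
#' ASCII VTU export readable by ParaView/VTK and meshio: the (r, z) nodes
#' as 3-D points with y = 0, triangles as VTK cells, the region label as
#' cell data, and any supplied nodal (point) or per-element (cell) fields.
#'
#' @param mesh An `oo_mesh`.
#' @param path Output file path (conventionally `.vtu`).
#' @param point_data Named list of nodal fields.
#' @param cell_data Named list of per-element fields.
#' @return The path, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- mesh$n_nodes; m <- mesh$n_tris
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  num <- function(x) paste(format(x, digits = 9, trim = TRUE), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(as.vector(t(cbind(mesh$nodes[, 1], 0, mesh$nodes[, 2])))))
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(as.vector(t(mesh$tris)) - 1L, collapse = " "))
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(seq_len(m) * 3L, collapse = " "))
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(5L, m), collapse = " "))  # VTK_TRIANGLE
  w('</DataArray></Cells>')
  cell_data <- c(list(region_id = as.integer(factor(mesh$region))), cell_data)
  w('<CellData>')
  for (nm in names(cell_data)) {
    w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
    w(num(as.numeric(cell_data[[nm]])))
    w('</DataArray>')
  }
  w('</CellData>')
  if (length(point_data)) {
    w('<PointData>')
    for (nm in names(point_data)) {
      w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
      w(num(as.numeric(point_data[[nm]])))
      w('</DataArray>')
    }
    w('</PointData>')
  }
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}

#' Write a plain-text run report
#'
#' Configuration echo, mesh statistics, and the headline outcomes
#' (final radii, maximum temperature, final voltage), sufficient to re-run
#' the simulation exactly.
#'
#' @param result An [run_simulation()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_run_report <- function(result, path) {
  cfg <- result$config
  lines <- c(
    "ooablate run report",
    "===================",
    sprintf("package version : %s", result$provenance$package_version),
    sprintf("scenario        : %s", cfg$scenario),
    sprintf("control temp    : %g C", cfg$control_temp),
    sprintf("heating         : %g s (dt %g s)", cfg$heat_time, cfg$dt_heat),
    sprintf("cooldown        : %g s (dt %g s)", cfg$cool_time, cfg$dt_cool),
    sprintf("resolution      : %s (%d nodes, %d triangles, h_near %.3g mm)",
            cfg$resolution, result$provenance$n_nodes,
            result$provenance$n_tris, result$provenance$h_near_electrode_mm),
    sprintf("body temp       : %g C", cfg$body_temp),
    sprintf("gains           : Kp %g V/K, Ki %g V/K/s", cfg$Kp, cfg$Ki),
    sprintf("seed            : %d", cfg$seed),
    if (length(cfg$overrides)) sprintf(
      "overrides       : %s", paste(utils::capture.output(
        utils::str(cfg$overrides, give.head = FALSE)), collapse = " ")) else
      "overrides       : none",
    "",
    sprintf("final cell-death radius perpendicular : %.3f mm", result$final_r_perp),
    sprintf("final cell-death radius parallel      : %.3f mm", result$final_r_par),
    sprintf("maximum temperature anywhere          : %.2f C", result$max_T_overall),
    sprintf("final applied voltage                 : %.3f V",
            result$step_trace$voltage_V[nrow(result$step_trace)]))
  writeLines(lines, path)
  invisible(path)
}

#' Export the final fields of a run as VTU
#'
#' Final temperature, damage and death probability (point data) plus the
#' last Joule source and alive mask (cell data).
#'
#' @param result An [run_simulation()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fields_vtu <- function(result, path) {
  write_vtu(result$mesh, path,
            point_data = list(
              temperature_C = result$final_T,
              omega = result$final_omega,
              death_probability = death_probability(result$final_omega)),
            cell_data = list(
              Q_RF_W_m3 = result$snapshots$end_heat$Q_RF,
              alive = as.numeric(result$final_alive)))
}
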