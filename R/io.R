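#' Write cell fields as a legacy-ASCII VTK structured-points file
#'
#' Writes one or more cell-centered scalar fields of a common grid as
#' CELL_DATA of a legacy VTK STRUCTURED_POINTS dataset (readable by
#' ParaView and meshio).
#'
#' @param file Output path.
#' @param fields Named list of (nx, ny) matrices.
#' @param dx Cell size, m.
#' @return The file path, invisibly.
#' @export
write_vtk_fields <- function(file, fields, dx) {
  stopifnot(is.list(fields), length(fields) >= 1, !is.null(names(fields)))
  dims <- dim(fields[[1]])
  nx <- dims[1]; ny <- dims[2]
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "coilflow field export", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx + 1, ny + 1),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.10g %.10g %.10g", dx, dx, dx),
               sprintf("CELL_DATA %d", nx * ny)), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    stopifnot(all(dim(f) == dims))
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    # VTK cell order: x fastest, then y
    writeLines(formatC(as.vector(f), format = "g", digits = 10), con)
  }
  invisible(file)
}

#' Export a geometry as VTK (level function and masks)
#'
#' @param geometry An [build_geometry()] result.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_vtk_geometry <- function(geometry, file) {
  write_vtk_fields(file, list(sdf = geometry$sdf,
                              lumen = geometry$lumen_mask * 1,
                              sac = geometry$sac_mask * 1,
                              coil = geometry$coil_mask * 1),
                   geometry$dx)
}

write_vtk_snapshot <- function(snapshot, geometry, file) {
  write_vtk_fields(file, list(u = snapshot$uc, v = snapshot$vc,
                              p = snapshot$p, mu = snapshot$mu,
                              lumen = geometry$lumen_mask * 1,
                              coil = geometry$coil_mask * 1),
                   geometry$dx)
}

#' Write an index report as JSON
#'
#' @param report An [phase_metrics()] report.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_index_report <- function(report, file) {
  stopifnot(inherits(report, "index_report"))
  x <- unclass(report)
  x$phase_times <- as.list(x$phase_times)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(file)
}

#' Read an index report written by [write_index_report()]
#'
#' @param file JSON path.
#' @return An \code{index_report} object.
#' @export
read_index_report <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  for (nm in c("max_wss", "wall_pressure_max", "neck_avg_velocity",
               "max_osi_phase", "phase_times"))
    x[[nm]] <- unlist(x[[nm]])
  x$porosity <- x$porosity %||% NA_real_
  if (is.null(x$porosity) || length(x$porosity) == 0) x$porosity <- NA_real_
  structure(x, class = "index_report")
}

#' Read a study configuration from a YAML file
#'
#' The file mirrors [study_config()]: optional sections \code{geometry},
#' \code{waveform}, \code{rheology}, \code{solver}, \code{study}
#' (\code{conditions}: list of \code{label / H / porosity} entries;
#' \code{resolutions}: grid_ny levels). Missing entries fall back to the
#' package defaults; \code{rheology: newtonian: true} forces the
#' yield-free Newtonian fluid.
#'
#' @param file YAML path.
#' @return A [study_config()] object.
#' @export
read_study_config <- function(file) {
  y <- yaml::read_yaml(file)
  geom_args <- y$geometry %||% list()
  wf_args <- y$waveform %||% list()
  rh_args <- y$rheology %||% list()
  sv_args <- y$solver %||% list()
  conds <- NULL
  if (!is.null(y$study$conditions))
    conds <- lapply(y$study$conditions, function(cn)
      list(label = cn$label, H = cn$H, porosity = cn$porosity))
  study_config(geometry = do.call(geometry_params, geom_args),
               waveform = do.call(synth_waveform, wf_args),
               rheology_base = do.call(rheology_params, rh_args),
               solver = do.call(solver_config, sv_args),
               conditions = conds %||% default_conditions(),
               resolutions = unlist(y$study$resolutions) %||%
                 c(54L, 72L, 96L, 128L))
}
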