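#' The default hematocrit-by-porosity condition set
#'
#' Two hematocrits (0.35, 0.45) crossed with uncoiled and two coil
#' porosities (0.89, 0.79): six conditions on the shared geometry and
#' waveform.
#'
#' @return List of condition descriptors \code{list(label, H, porosity)}
#'   (\code{porosity = NULL} for uncoiled).
#' @export
default_conditions <- function() {
  conds <- list()
  for (H in c(0.35, 0.45))
    for (phi in list(NULL, 0.89, 0.79)) {
      lab <- sprintf("H%.2f_%s", H,
                     if (is.null(phi)) "uncoiled" else sprintf("phi%.2f", phi))
      conds[[lab]] <- list(label = lab, H = H, porosity = phi)
    }
  unname(conds)
}

#' Configuration of a full comparison study
#'
#' @param geometry A [geometry_params()] object (shared by all
#'   conditions).
#' @param waveform An [synth_waveform()] object.
#' @param rheology_base An [rheology_params()] carrying the shared
#'   \code{eta}, \code{m}, \code{rho}; the hematocrit is overridden per
#'   condition.
#' @param solver A [solver_config()].
#' @param conditions List of \code{list(label, H, porosity)} descriptors;
#'   see [default_conditions()].
#' @param resolutions Grid levels (cell counts \code{grid_nx} along the
#'   channel) for the convergence harness, coarse to fine, each refining
#'   the spacing by about 1.33x.
#' @param wire_diameter Coil wire diameter, m.
#' @param coil_fill Sac fill fraction for coiled conditions.
#' @return An object of class \code{"study_config"}.
#' @export
study_config <- function(geometry = geometry_params(),
                         waveform = synth_waveform(),
                         rheology_base = rheology_params(),
                         solver = solver_config(),
                         conditions = default_conditions(),
                         resolutions = c(120L, 168L, 216L, 312L),
                         wire_diameter = 2.5e-4,
                         coil_fill = 1) {
  stopifnot(inherits(geometry, "geometry_params"),
            inherits(waveform, "inlet_waveform"),
            inherits(rheology_base, "rheology_params"),
            inherits(solver, "solver_config"))
  labels <- vapply(conditions, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("condition labels must be unique: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  structure(list(geometry = geometry, waveform = waveform,
                 rheology_base = rheology_base, solver = solver,
                 conditions = conditions,
                 resolutions = sort(as.integer(resolutions)),
                 wire_diameter = wire_diameter, coil_fill = coil_fill),
            class = "study_config")
}

condition_rheology <- function(config, cond) {
  rb <- config$rheology_base
  rheology_params(H = cond$H, eta = rb$eta, m = rb$m, rho = rb$rho,
                  newtonian = rb$newtonian)
}

#' Run the full hematocrit-by-porosity study
#'
#' Integrates [run_cycles()] for every condition on the shared geometry
#' and waveform, computes an [phase_metrics()] report per condition and
#' all pairwise porosity / hematocrit comparisons, and assembles the
#' summary table (rows = cardiac phases, columns = conditions, one block
#' per metric). Fully deterministic: repeated runs of the same
#' configuration give identical numbers.
#'
#' @param config A [study_config()].
#' @param keep_runs Keep the full \code{flow_run} objects in the result
#'   (needed by [write_bundle()] for field snapshots).
#' @param verbose Print progress per condition.
#' @return An object of class \code{"coil_study"}: list with
#'   \code{reports}, \code{comparison} (NULL if a single condition),
#'   \code{summary} (data frame), \code{runs} (if kept), \code{config}.
#' @export
run_study <- function(config = study_config(), keep_runs = TRUE,
                      verbose = interactive()) {
  stopifnot(inherits(config, "study_config"))
  geom0 <- build_geometry(config$geometry)
  reports <- list(); runs <- list()
  for (cond in config$conditions) {
    if (verbose) message("condition ", cond$label)
    geom <- geom0
    coil <- NULL
    if (!is.null(cond$porosity)) {
      geom <- set_coil(geom0, config$coil_fill)
      coil <- coil_model(cond$porosity, config$wire_diameter)
    }
    run <- run_cycles(geom, config$waveform,
                      condition_rheology(config, cond),
                      coil = coil, config = config$solver)
    reports[[cond$label]] <- phase_metrics(run, label = cond$label)
    if (keep_runs) runs[[cond$label]] <- run
  }
  comparison <- if (length(reports) >= 2) compare_conditions(reports) else NULL
  structure(list(reports = reports, comparison = comparison,
                 summary = study_summary(reports),
                 runs = if (keep_runs) runs else NULL,
                 config = config), class = "coil_study")
}

# rows = phases, one block of columns per metric x condition
study_summary <- function(reports) {
  phases <- c("max_accel", "peak_sys", "max_decel", "early_dia")
  metrics <- c("max_wss", "max_osi_phase", "wall_pressure_max",
               "neck_avg_velocity")
  if (length(reports) == 0)
    return(data.frame(metric = character(), phase = character()))
  out <- data.frame()
  for (mt in metrics) {
    block <- data.frame(metric = mt, phase = phases)
    for (rp in reports) block[[rp$label]] <- unname(rp[[mt]][phases])
    out <- rbind(out, block)
  }
  out
}

#' @export
print.coil_study <- function(x, ...) {
  cat(sprintf("Aneurysm coiling study: %d condition(s)\n", length(x$reports)))
  for (rp in x$reports)
    cat(sprintf("  %-18s max WSS@peak %.4f Pa | max OSI %.4f | sac KE %.3g\n",
                rp$label, rp$max_wss[["peak_sys"]], rp$max_osi,
                rp$ke_sac_mean))
  if (!is.null(x$comparison)) {
    cat("\nKey contrasts (peak systole max WSS):\n")
    cc <- x$comparison
    sel <- cc$metric == "max_wss" & cc$phase == "peak_sys"
    print.data.frame(within(cc[sel, c("ref", "alt", "reduction_pct")],
                            reduction_pct <- round(reduction_pct, 2)),
                     row.names = FALSE)
  }
  invisible(x)
}

#' Grid-convergence harness for the neck-inflow metric
#'
#' Re-solves frozen-inflow steady states at the maximum-acceleration and
#' peak-systolic inflow levels of the waveform on a ladder of grids, and
#' reports the neck-plane average velocity per grid — the acceptance
#' logic of a mesh-independence table. The coarsest level within 1% of
#' the finest on both metrics is flagged as the economical choice.
#'
#' @param config A [study_config()].
#' @param resolutions Grid levels (\code{grid_nx}); >= 3 required.
#' @param t_end Steady settling time per solve, s.
#' @param verbose Print progress.
#' @return A \code{convergence_table}: data frame with columns
#'   \code{label, nx, ny, cells, v_neck_max_accel, v_neck_peak_sys},
#'   attribute \code{recommended} (flagged row label).
#' @export
grid_convergence <- function(config = study_config(),
                             resolutions = config$resolutions,
                             t_end = 0.6, verbose = interactive()) {
  if (length(resolutions) < 3)
    stop("at least 3 grid levels are required")
  resolutions <- as.integer(resolutions)
  gp <- config$geometry
  wf <- config$waveform
  rh <- config$rheology_base
  u_levels <- c(max_accel = unname(wf$u_fun(wf$phases[["t_max_accel"]])),
                peak_sys = unname(wf$u_fun(wf$phases[["t_peak_sys"]])))
  labels <- if (length(resolutions) == 4)
    c("coarse", "medium", "fine", "very fine")
  else paste0("level", seq_along(resolutions))
  rows <- list()
  for (k in seq_along(resolutions)) {
    nxk <- resolutions[k]
    nyk <- as.integer(round(nxk * gp$grid_ny / gp$grid_nx))
    gpk <- geometry_params(channel_width = gp$channel_width,
                           channel_length = gp$channel_length,
                           neck_width = gp$neck_width,
                           dome1_radius = gp$dome1_radius,
                           dome2_radius = gp$dome2_radius,
                           dome_offset = gp$dome_offset,
                           sac_tilt = gp$sac_tilt,
                           grid_nx = nxk, grid_ny = nyk,
                           neck_x_frac = gp$neck_x_frac,
                           wall_margin = gp$wall_margin)
    geom <- build_geometry(gpk)
    if (verbose) message("grid ", labels[k], ": ", nxk, " x ", nyk)
    vk <- vapply(u_levels, function(uu) {
      st <- run_steady(geom, uu, rh, config = config$solver, t_end = t_end)
      neck_average_velocity(st$snapshot, geom)
    }, numeric(1))
    rows[[k]] <- data.frame(label = labels[k], nx = nxk, ny = nyk,
                            cells = nxk * nyk,
                            v_neck_max_accel = vk[["max_accel"]],
                            v_neck_peak_sys = vk[["peak_sys"]])
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cells), ]
  rownames(out) <- NULL
  nfin <- nrow(out)
  rel <- pmax(abs(out$v_neck_max_accel - out$v_neck_max_accel[nfin]) /
                out$v_neck_max_accel[nfin],
              abs(out$v_neck_peak_sys - out$v_neck_peak_sys[nfin]) /
                out$v_neck_peak_sys[nfin])
  if (any(diff(sign(diff(out$v_neck_peak_sys))) != 0) && nfin >= 4)
    warning("neck-velocity sequence is not monotone across grids")
  ok <- which(rel < 0.01)
  attr(out, "recommended") <- out$label[if (length(ok)) min(ok) else nfin]
  attr(out, "rel_to_finest") <- rel
  class(out) <- c("convergence_table", class(out))
  out
}

#' @export
print.convergence_table <- function(x, ...) {
  cat("Grid-convergence table (neck-plane average velocity, m/s)\n")
  y <- x; class(y) <- "data.frame"
  y$v_neck_max_accel <- signif(y$v_neck_max_accel, 4)
  y$v_neck_peak_sys <- signif(y$v_neck_peak_sys, 4)
  print(y, row.names = FALSE)
  cat("recommended grid:", attr(x, "recommended"), "\n")
  invisible(x)
}

#' Write a study bundle to disk
#'
#' Writes, per condition: the index report (JSON), the wall profile
#' (CSV: arc length, TAWSS, OSI), the per-phase wall loads (CSV) and the
#' four phase-snapshot fields (legacy VTK). Plus the comparison table,
#' a single \code{study_summary.csv} (rows = phases, columns =
#' conditions, stacked per metric), the geometry VTK, the waveform CSV
#' and a run log echoing the configuration.
#'
#' @param study A [run_study()] result (with runs kept, for the VTK
#'   snapshots).
#' @param outdir Output directory.
#' @param force Overwrite an existing directory.
#' @return \code{outdir}, invisibly.
#' @export
write_bundle <- function(study, outdir, force = FALSE) {
  stopifnot(inherits(study, "coil_study"))
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !force)
    stop("output directory ", outdir, " exists and is not empty; ",
         "use force = TRUE to overwrite")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$summary, file.path(outdir, "study_summary.csv"),
                   row.names = FALSE)
  if (!is.null(study$comparison)) {
    cc <- study$comparison; class(cc) <- "data.frame"
    utils::write.csv(cc, file.path(outdir, "comparison.csv"),
                     row.names = FALSE)
  }
  for (rp in study$reports) {
    write_index_report(rp, file.path(outdir, paste0("report_", rp$label, ".json")))
    prof <- data.frame(s = rp$s, tawss = rp$tawss, osi = rp$osi,
                       in_view = rp$in_view, valid = rp$wall_valid)
    utils::write.csv(prof, file.path(outdir, paste0("wall_profile_", rp$label, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(study$runs)) {
    for (lab in names(study$runs)) {
      run <- study$runs[[lab]]
      export_wall_loads(run, file.path(outdir, paste0("wall_loads_", lab, ".csv")))
      for (ph in names(run$phase_snapshots))
        write_vtk_snapshot(run$phase_snapshots[[ph]], run$geometry,
                           file.path(outdir, sprintf("fields_%s_%s.vtk", lab, ph)))
    }
    geom <- study$runs[[1]]$geometry
    write_vtk_geometry(geom, file.path(outdir, "geometry.vtk"))
  }
  write_waveform_csv(study$config$waveform, file.path(outdir, "waveform.csv"))
  log <- c("coilflow study bundle",
           paste("package version:", as.character(utils::packageVersion("coilflow"))),
           paste("conditions:", paste(names(study$reports), collapse = ", ")),
           "configuration:",
           utils::capture.output(utils::str(config_echo(study$config))))
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

config_echo <- function(config) {
  list(geometry = unclass(config$geometry),
       waveform = list(period = config$waveform$period,
                       u_dia = config$waveform$u_dia,
                       u_peak = config$waveform$u_peak,
                       systole_fraction = config$waveform$systole_fraction),
       rheology = unclass(config$rheology_base)[c("eta", "m", "rho", "newtonian")],
       solver = unclass(config$solver),
       wire_diameter = config$wire_diameter,
       resolutions = config$resolutions)
}

#' Re-read the index reports of a written bundle
#'
#' @param outdir Directory written by [write_bundle()].
#' @return List with \code{reports} (named list of \code{index_report}s)
#'   and \code{summary} (data frame).
#' @export
read_bundle <- function(outdir) {
  files <- list.files(outdir, pattern = "^report_.*\\.json$",
                      full.names = TRUE)
  reports <- lapply(files, read_index_report)
  names(reports) <- vapply(reports, `[[`, character(1), "label")
  summary <- utils::read.csv(file.path(outdir, "study_summary.csv"),
                             check.names = FALSE)
  list(reports = reports, summary = summary)
}
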