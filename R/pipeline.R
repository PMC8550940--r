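#' Run the end-to-end pipeline
#'
#' Orchestrates simulate -> align -> resolution -> measure -> report from a
#' single configuration, writing stage outputs and a run manifest under
#' `out_dir`. Re-running with the same configuration and seed reproduces
#' all outputs.
#'
#' Configuration fields (all optional except `out_dir`): `seed` (default 1),
#' `preset` (see [npc_preset()]) or `phantom` (a list of [phantom_params()]
#' arguments), `shape`, `voxel_size`, `n_particles`, `snr`, `stages`
#' (subset of `c("simulate", "align", "resolution", "measure", "report")`),
#' `align` (list of [align_config()] arguments).
#'
#' @param config a named list or path to a JSON file of the same structure.
#' @return the run manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(
    list(seed = 1L, preset = "wildtype", phantom = list(), shape = 96,
         voxel_size = 13.6, n_particles = 16, snr = 0.5,
         stages = c("simulate", "align", "resolution", "measure", "report"),
         align = list(), out_dir = NULL),
    config)
  if (is.null(cfg$out_dir)) stop("config must name an out_dir", call. = FALSE)
  known <- c("simulate", "align", "resolution", "measure", "report")
  if (!all(cfg$stages %in% known))
    stop("unknown stages: ", paste(setdiff(cfg$stages, known),
                                   collapse = ", "), call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, stages = cfg$stages,
                   outputs = list(), timing_s = list())
  paths <- list(
    phantom = file.path(cfg$out_dir, "phantom.mrc"),
    table = file.path(cfg$out_dir, "particles.tsv"),
    merged = file.path(cfg$out_dir, "merged.mrc"),
    half_a = file.path(cfg$out_dir, "half_A.mrc"),
    half_b = file.path(cfg$out_dir, "half_B.mrc"),
    refined = file.path(cfg$out_dir, "particles_refined.tsv"),
    fsc = file.path(cfg$out_dir, "fsc.tsv"),
    meas = file.path(cfg$out_dir, "measurements.json"),
    report = file.path(cfg$out_dir, "report.json"))
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$timing_s[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }
  env <- new.env()
  if ("simulate" %in% cfg$stages) {
    stage("simulate", function() {
      params <- do.call(npc_preset, c(list(name = cfg$preset), cfg$phantom))
      phantom <- build_phantom(params, cfg$shape, cfg$voxel_size)
      sim <- sim_params(n_particles = cfg$n_particles, snr = cfg$snr,
                        seed = cfg$seed)
      out <- simulate_particles(phantom, sim,
                                params$membrane_pore_diameter)
      write_volume(phantom, paths$phantom)
      write_particle_table(out$table, paths$table)
      for (i in seq_along(out$particles))
        write_volume(out$particles[[i]],
                     file.path(cfg$out_dir, sprintf("particle_%03d.mrc", i)))
      env$params <- params; env$sim <- out
      manifest$outputs$simulate <<- c(paths$phantom, paths$table)
    })
  }
  if ("align" %in% cfg$stages) {
    stage("align", function() {
      if (is.null(env$sim)) stop("align needs the simulate stage outputs")
      acfg <- do.call(align_config, cfg$align)
      init <- env$sim$table
      init$rot <- 0; init$tilt <- 0; init$psi <- 0
      init$x <- 0; init$y <- 0; init$z <- 0
      res <- iterative_align(env$sim$particles, init, acfg)
      write_volume(res$merged, paths$merged)
      if (!is.null(res$half_A)) write_volume(res$half_A, paths$half_a)
      if (!is.null(res$half_B)) write_volume(res$half_B, paths$half_b)
      write_particle_table(res$table, paths$refined)
      env$avg <- res
      manifest$outputs$align <<- c(paths$merged, paths$refined)
    })
  }
  if ("resolution" %in% cfg$stages) {
    stage("resolution", function() {
      if (is.null(env$avg)) stop("resolution needs the align stage outputs")
      curve <- fsc(env$avg$half_A, env$avg$half_B,
                   mask_spec("soft_sphere",
                             radius = 0.45 * cfg$shape[1] * cfg$voxel_size,
                             soft_edge = 3))
      res_A <- resolution_at(curve, 0.5)
      write.table(curve, paths$fsc, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      env$resolution_A <- as.numeric(res_A)
      manifest$outputs$resolution <<- paths$fsc
      manifest$resolution_A <<- as.numeric(res_A)
    })
  }
  if ("measure" %in% cfg$stages) {
    stage("measure", function() {
      if (is.null(env$avg)) stop("measure needs the align stage outputs")
      m <- measure_npc(env$avg$merged)
      jsonlite::write_json(m, paths$meas, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      env$meas <- m
      manifest$outputs$measure <<- paths$meas
    })
  }
  if ("report" %in% cfg$stages) {
    stage("report", function() {
      if (is.null(env$meas)) stop("report needs the measure stage outputs")
      shells <- ring_shell_specs(env$params)
      pres <- ring_presence(env$avg$merged, shells)
      rep <- list(measurements = env$meas, ring_presence = pres,
                  mean_cc = if (!is.null(env$avg$log))
                    tail(env$avg$log$mean_cc, 1) else NA)
      jsonlite::write_json(rep, paths$report, auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      manifest$outputs$report <<- paths$report
    })
  }
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' All geometric measurements of an NPC map
#'
#' Convenience wrapper running the pore-diameter, channel-diameter, axial
#' geometry and membrane-angle measurements.
#'
#' @param v a [density_volume].
#' @return named list of measurements in nm / degrees.
#' @export
measure_npc <- function(v) {
  pd <- measure_pore_diameter(v)
  ax <- measure_axial_geometry(v, pore_diameter_nm = as.numeric(pd))
  cd <- measure_channel_diameter(v, z_ir_nm = ax$z_ir_nm)
  an <- measure_membrane_angles(v, pore_diameter_nm = as.numeric(pd))
  list(pore_diameter_nm = as.numeric(pd),
       channel_diameter_nm = as.numeric(cd),
       ir_cr_nm = ax$ir_cr_nm, ir_nr_nm = ax$ir_nr_nm,
       height_nm = ax$height_nm,
       angle_cyto_deg = as.numeric(an["cyto"]),
       angle_nucleo_deg = as.numeric(an["nucleo"]))
}
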