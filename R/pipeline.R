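#' Run the full probabilistic fatigue pipeline
#'
#' Executes the stages in order: mesh the configured geometry, solve the
#' elastic problem at the mean inputs, locate the critical point in the
#' implant, propagate the random inputs to stress/strain statistics at that
#' point (FOSM), convert to fatigue-life moments through Neuber and
#' Coffin-Basquin-Manson, calibrate the Markov damage chain by moment
#' matching, and evaluate the failure-probability curve over the configured
#' cycle grid. Writes the failure curve and stress field as CSV and a
#' structured key-value report; the run is deterministic for a fixed config.
#'
#' @param config A `study_config` object or the path to a YAML config
#'   written by [write_study_config()].
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing files.
#' @param quiet Suppress stage progress messages.
#' @return A `pipeline_report` (invisibly when files are written).
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_study_config(config)
  validate_study_config(config)
  say <- function(...) if (!quiet) message("[implantfatigue] ", ...)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", what, conditionMessage(e)),
           call. = FALSE)
    })
  }

  say("meshing (", config$geometry$connection, ")")
  mesh <- stage("mesh", build_mesh(config$geometry, seed = config$seed))

  say("solving elastic problem at mean inputs")
  E_rv <- config$rvs$titanium_E
  L_rv <- config$rvs$load_magnitude
  mats <- config$materials
  mats$titanium <- elastic_material(E_rv$mean,
                                    mats$titanium$poisson_ratio)
  model <- stage("fe_solve",
                 implant_surrogate(mesh, mats, config$load,
                                   load_magnitude = L_rv$mean))
  say(sprintf("critical element %d, von Mises %.4g MPa",
              model$critical$element, model$critical$value))

  say("propagating input randomness (FOSM)")
  stats <- stage("pfem", pfem_stats(model, config$rvs))

  say("fatigue life moments (Neuber + Coffin-Basquin-Manson)")
  surrogate <- function(E, load) {
    surrogate_response(model, E, load, "von_mises_stress")
  }
  # the 2D surrogate concentrates less stress than a thread-resolved 3D
  # model, so admit longer lives than the default inversion bracket
  life <- stage("fatigue_life",
                life_moments(surrogate, E_rv, L_rv, config$fatigue,
                             delta_eps_factor = config$delta_eps_factor,
                             log2n_range = c(0, 16)))

  say("calibrating damage chain and failure curve")
  chain <- stage("damage_chain", calibrate_chain(life))
  grid_m <- seq(config$cycle_grid$start, config$cycle_grid$stop,
                length.out = config$cycle_grid$count)
  curve <- stage("failure_curve", failure_curve(chain, grid_m * 1e6))
  curve_m <- data.frame(cycles_millions = grid_m,
                        probability = curve$probability)

  report <- structure(list(
    config = config,
    critical_point = list(element = model$critical$element,
                          mean_stress = stats$mean_stress),
    stress_stats = stats,
    life = life,
    life_millions = list(mean_life = life$mean_life / 1e6,
                         var_life = life$var_life / 1e12),
    chain = list(b_levels = chain$b_levels, r = chain$r),
    curve = curve_m,
    provenance = list(seed = config$seed,
                      version = as.character(
                        utils::packageVersion("implantfatigue")),
                      timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(curve_m, file.path(out_dir, "failure_curve.csv"),
                     row.names = FALSE)
    field <- assemble_and_solve(mesh, mats, config$load)
    export_stress_csv(field, file.path(out_dir, "stress_field.csv"))
    export_mesh_csv(mesh, file.path(out_dir, "mesh_nodes.csv"),
                    file.path(out_dir, "mesh_elements.csv"))
    writeLines(format_report(report), file.path(out_dir, "report.txt"))
    say("outputs written to ", out_dir)
    return(invisible(report))
  }
  report
}

# key-value report body; the timestamp is the last line so consumers can
# compare report bodies net of it
format_report <- function(report) {
  cfg <- report$config
  c(sprintf("connection: %s", cfg$geometry$connection),
    sprintf("mesh_density_mm: %g", cfg$geometry$mesh_density),
    sprintf("load_resultant_N: %.6g", cfg$load$resultant),
    sprintf("critical_element: %d", report$critical_point$element),
    sprintf("mean_stress_MPa: %.8g", report$stress_stats$mean_stress),
    sprintf("var_stress_MPa2: %.8g", report$stress_stats$var_stress),
    sprintf("mean_strain: %.8g", report$stress_stats$mean_strain),
    sprintf("var_strain: %.8g", report$stress_stats$var_strain),
    sprintf("mean_life_cycles: %.8g", report$life$mean_life),
    sprintf("var_life_cycles2: %.8g", report$life$var_life),
    sprintf("mean_life_Mcycles: %.8g", report$life_millions$mean_life),
    sprintf("var_life_Mcycles2: %.8g", report$life_millions$var_life),
    sprintf("chain_b_levels: %d", report$chain$b_levels),
    sprintf("chain_r: %.8g", report$chain$r),
    sprintf("seed: %d", report$provenance$seed),
    sprintf("version: %s", report$provenance$version),
    sprintf("timestamp: %s", report$provenance$timestamp))
}

#' @export
print.pipeline_report <- function(x, ...) {
  body <- format_report(x)
  cat(body[-length(body)], sep = "\n")
  cat("\n")
  p <- x$curve$probability
  cat(sprintf("failure curve: %d points, P from %.3g to %.3g over %g-%g Mcycles\n",
              nrow(x$curve), p[1], p[length(p)],
              x$curve$cycles_millions[1],
              x$curve$cycles_millions[nrow(x$curve)]))
  invisible(x)
}

#' Failure curve straight from life moments
#'
#' Thin composition of [calibrate_chain()] and [failure_curve()] for running
#' the damage-chain stage standalone from externally computed life
#' statistics.
#'
#' @param mean_life Mean life, cycles.
#' @param var_life Life variance, cycles^2.
#' @param x_grid Sorted cycle grid (cycles).
#' @return A `failure_curve` with the calibrated chain attached as
#'   attribute `chain`.
#' @export
run_chain_only <- function(mean_life, var_life, x_grid) {
  chain <- calibrate_chain(life_statistics(mean_life, var_life))
  curve <- failure_curve(chain, x_grid)
  attr(curve, "chain") <- chain
  curve
}
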