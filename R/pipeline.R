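#' Pipeline configuration
#'
#' A flat, JSON-serialisable list of every tunable in the pipeline, each
#' default traceable to the material table, the loading protocol or a
#' documented design choice. Round-trips losslessly through
#' [write_config()] / [read_config()].
#'
#' @param n_cases cohort size.
#' @param seed master seed; all randomness in a run derives from it.
#' @param use_reconstruction run the voxel-phantom reconstruction path
#'   instead of feeding synthetic surfaces directly to the mesher.
#' @param voxel_size_mm,noise_sd phantom sampling and noise level.
#' @param threshold_lo segmentation lower threshold (intensity units;
#'   contrast is 0 outside / 1 inside).
#' @param connectivity mask connectivity, 6 or 26.
#' @param smooth_iterations,taubin_lambda,taubin_mu surface smoothing.
#' @param clip_margin_mm axial margin cut from reconstructed closed surfaces
#'   to re-open inlet/outlet.
#' @param n_circumferential,n_axial surface sampling of synthetic lumens.
#' @param n_layers element layers through the wall.
#' @param young_modulus_mpa,poisson_ratio,density material parameters.
#' @param p_dias_low,p_sys_low,p_dias_high,p_sys_high,delta_p_first,delta_p_final,n_steps
#'   loading protocol, mmHg.
#' @param write_vtu also export VTU fields from the solve stage.
#' @param output_dir artifact directory.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_cases = 12, seed = 1L,
                            use_reconstruction = FALSE,
                            voxel_size_mm = 1, noise_sd = 0.1,
                            threshold_lo = 0.5, connectivity = 26,
                            smooth_iterations = 20, taubin_lambda = 0.5,
                            taubin_mu = -0.53, clip_margin_mm = 3,
                            n_circumferential = 48, n_axial = 72,
                            n_layers = 2,
                            young_modulus_mpa = 0.7, poisson_ratio = 0.45,
                            density = 1095,
                            p_dias_low = 80, p_sys_low = 130,
                            p_dias_high = 123, p_sys_high = 230,
                            delta_p_first = 50, delta_p_final = 77,
                            n_steps = 10,
                            write_vtu = FALSE, output_dir = "aortafem_run") {
  cfg <- as.list(environment())
  ints <- c("n_cases", "seed", "connectivity", "smooth_iterations",
            "n_circumferential", "n_axial", "n_layers", "n_steps")
  for (nm in ints) cfg[[nm]] <- as.integer(cfg[[nm]])
  dbls <- c("voxel_size_mm", "noise_sd", "threshold_lo", "taubin_lambda",
            "taubin_mu", "clip_margin_mm", "young_modulus_mpa",
            "poisson_ratio", "density", "p_dias_low", "p_sys_low",
            "p_dias_high", "p_sys_high", "delta_p_first", "delta_p_final")
  for (nm in dbls) cfg[[nm]] <- as.numeric(cfg[[nm]])
  cfg$use_reconstruction <- isTRUE(cfg$use_reconstruction)
  cfg$write_vtu <- isTRUE(cfg$write_vtu)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("pipeline_config: %d cases, seed %d, output '%s'%s\n",
              x$n_cases, x$seed, x$output_dir,
              if (x$use_reconstruction) " (reconstruction path)" else ""))
  invisible(x)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

# FNV-1a over the canonical JSON of the config (minus the output location):
# a stable content address for the run
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = I(17))
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) # keep in int range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

artifact_path <- function(config, name, ext) {
  file.path(config$output_dir,
            sprintf("%s_%s.%s", name, config_hash(config), ext))
}

require_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop(sprintf("missing upstream artifact '%s': run stage '%s' first",
                 path, producer), call. = FALSE)
  path
}

write_manifest <- function(config, stage, inputs, outputs) {
  man <- list(stage = stage, config = unclass(config),
              config_hash = config_hash(config), seed = config$seed,
              package = "aortafem",
              package_version = as.character(utils::packageVersion("aortafem")),
              inputs = inputs, outputs = outputs)
  jsonlite::write_json(man, artifact_path(config, paste0("manifest_", stage), "json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
}

log_stage <- function(fmt, ...) {
  message(sprintf("[aortafem] %s", sprintf(fmt, ...)))
}

clip_surface_z <- function(mesh, zmin, zmax) {
  v <- mesh$vertices; t <- mesh$triangles
  keep <- v[t[, 1], 3] >= zmin & v[t[, 1], 3] <= zmax &
    v[t[, 2], 3] >= zmin & v[t[, 2], 3] <= zmax &
    v[t[, 3], 3] >= zmin & v[t[, 3], 3] <= zmax
  t <- t[keep, , drop = FALSE]
  used <- sort(unique(as.vector(t)))
  remap <- integer(nrow(v)); remap[used] <- seq_along(used)
  surface_mesh(v[used, , drop = FALSE],
               matrix(remap[t], ncol = 3),
               provenance = paste0(mesh$provenance, " +clipped"))
}

reconstruct_case <- function(spec, config) {
  phantom <- generate_phantom_volume(spec, voxel_size = config$voxel_size_mm,
                                     noise_sd = config$noise_sd)
  mask <- threshold_segment(phantom, lo = config$threshold_lo)
  mask <- largest_component(mask, connectivity = config$connectivity)
  surf <- extract_surface(mask)
  smooth_surface(surf, iterations = config$smooth_iterations,
                 lambda = config$taubin_lambda, mu = config$taubin_mu)
}

load_cohort_specs <- function(config) {
  path <- require_artifact(artifact_path(config, "cohort", "json"), "synth")
  read_cohort_json(path)
}

config_material <- function(config) {
  material_model(config$young_modulus_mpa, config$poisson_ratio, config$density)
}

config_load_case <- function(config) {
  load_case(config$p_dias_low, config$p_sys_low, config$p_dias_high,
            config$p_sys_high, config$delta_p_first, config$delta_p_final,
            config$n_steps)
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `synth` (cohort specs + lumen surfaces), `reconstruct`
#' (phantom to segmented, smoothed surface), `mesh` (tetrahedral wall),
#' `solve` (incremental static FEM), `post` (field maxima and case records),
#' `risk` (pressure-strain modulus and calibrated rupture risk), `all`.
#' Every stage writes its artifacts plus a machine-readable manifest
#' (config, content hash, seed, package version) into `config$output_dir`;
#' reruns with an identical config and seed are byte-identical. Timing goes
#' to stderr.
#'
#' @param stage one of `"synth"`, `"reconstruct"`, `"mesh"`, `"solve"`,
#'   `"post"`, `"risk"`, `"all"`.
#' @param config a [pipeline_config()].
#' @return invisibly, a named list of the stage's main outputs.
#' @export
run_stage <- function(stage = c("synth", "reconstruct", "mesh", "solve",
                                "post", "risk", "all"),
                      config = pipeline_config()) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  out <- switch(stage,
    all = {
      res <- list()
      stages <- c("synth", if (config$use_reconstruction) "reconstruct",
                  "mesh", "solve", "post", "risk")
      for (s in stages) res[[s]] <- run_stage(s, config)
      res
    },
    synth = {
      cohort <- sample_cohort(config$n_cases, seed = config$seed)
      cpath <- artifact_path(config, "cohort", "json")
      write_cohort_json(cohort, cpath)
      surfs <- character(0)
      for (nm in names(cohort)) {
        surf <- generate_lumen_surface(cohort[[nm]],
                                       n_circumferential = config$n_circumferential,
                                       n_axial = config$n_axial)
        sp <- artifact_path(config, paste0(nm, "_surface"), "stl")
        write_stl(surf, sp)
        surfs <- c(surfs, sp)
      }
      write_manifest(config, "synth", inputs = list(),
                     outputs = c(cpath, surfs))
      list(cohort = cpath, surfaces = surfs)
    },
    reconstruct = {
      cohort <- load_cohort_specs(config)
      outs <- character(0)
      for (nm in names(cohort)) {
        surf <- reconstruct_case(cohort[[nm]], config)
        sp <- artifact_path(config, paste0(nm, "_recon_surface"), "stl")
        write_stl(surf, sp)
        outs <- c(outs, sp)
      }
      write_manifest(config, "reconstruct",
                     inputs = artifact_path(config, "cohort", "json"),
                     outputs = outs)
      list(surfaces = outs)
    },
    mesh = {
      cohort <- load_cohort_specs(config)
      outs <- character(0)
      for (nm in names(cohort)) {
        spec <- cohort[[nm]]
        if (config$use_reconstruction) {
          sp <- require_artifact(
            artifact_path(config, paste0(nm, "_recon_surface"), "stl"),
            "reconstruct")
          surf <- clip_surface_z(read_stl(sp), config$clip_margin_mm,
                                 spec$total_length - config$clip_margin_mm)
        } else {
          sp <- require_artifact(
            artifact_path(config, paste0(nm, "_surface"), "stl"), "synth")
          surf <- read_stl(sp)
        }
        mesh <- extrude_wall(surf, thickness = spec$wall_thickness,
                             n_layers = config$n_layers)
        mesh <- tag_boundaries(mesh, surf)
        mp <- artifact_path(config, paste0(nm, "_mesh"), "txt")
        write_mesh_text(mesh, mp)
        outs <- c(outs, mp)
      }
      write_manifest(config, "mesh",
                     inputs = artifact_path(config, "cohort", "json"),
                     outputs = outs)
      list(meshes = outs)
    },
    solve = {
      cohort <- load_cohort_specs(config)
      mat <- config_material(config)
      lc <- config_load_case(config)
      outs <- character(0)
      for (nm in names(cohort)) {
        mp <- require_artifact(artifact_path(config, paste0(nm, "_mesh"), "txt"),
                               "mesh")
        mesh <- read_mesh_text(mp)
        sol <- solve_static(mesh, mat, lc)
        up <- artifact_path(config, paste0(nm, "_displacement"), "txt")
        ufin <- sol$displacements_mm[, , dim(sol$displacements_mm)[3]]
        writeLines(c(sprintf("aortafem-displacement 1 %d", nrow(ufin)),
                     apply(format(ufin, digits = 17, trim = TRUE), 1, paste,
                           collapse = " ")), up)
        if (isTRUE(config$write_vtu)) {
          res <- field_result(mesh, mat, sol)
          write_vtu(mesh, artifact_path(config, paste0(nm, "_fields"), "vtu"),
                    point_data = list(displacement = res$node_displacement),
                    cell_data = list(von_mises = von_mises(res$element_stress),
                                     equivalent_strain = equivalent_strain(res$element_strain)))
        }
        outs <- c(outs, up)
      }
      write_manifest(config, "solve",
                     inputs = artifact_path(config, "cohort", "json"),
                     outputs = outs)
      list(displacements = outs)
    },
    post = {
      cohort <- load_cohort_specs(config)
      mat <- config_material(config)
      lc <- config_load_case(config)
      records <- list()
      for (nm in names(cohort)) {
        mp <- require_artifact(artifact_path(config, paste0(nm, "_mesh"), "txt"),
                               "mesh")
        up <- require_artifact(
          artifact_path(config, paste0(nm, "_displacement"), "txt"), "solve")
        mesh <- read_mesh_text(mp)
        lines <- readLines(up, warn = FALSE)
        u <- matrix(as.numeric(unlist(strsplit(trimws(lines[-1]), "\\s+"))),
                    ncol = 3, byrow = TRUE)
        sol <- structure(list(displacements_mm = array(u, c(nrow(u), 3, 1)),
                              delta_p_mmhg = lc$delta_p_final),
                         class = "fem_solution")
        res <- field_result(mesh, mat, sol, step = 1)
        records[[nm]] <- case_summary(res, 2 * cohort[[nm]]$max_radius,
                                      case_id = nm, mesh = mesh)
      }
      df <- do.call(rbind, lapply(records, as.data.frame))
      rp <- artifact_path(config, "case_records", "csv")
      utils::write.csv(df, rp, row.names = FALSE)
      write_manifest(config, "post",
                     inputs = artifact_path(config, "cohort", "json"),
                     outputs = rp)
      list(records = rp, table = df)
    },
    risk = {
      calib <- risk_calibration_table()
      curve <- calibrate_risk_curve(
        data.frame(ppsm_kpa = calib$ppsm_kpa, risk = calib$risk_percent / 100))
      rp <- artifact_path(config, "case_records", "csv")
      lc <- config_load_case(config)
      if (file.exists(rp)) {
        df <- utils::read.csv(rp, stringsAsFactors = FALSE)
        records <- lapply(seq_len(nrow(df)), function(i) {
          list(case_id = df$case_id[i],
               diagnostic_diameter = df$diagnostic_diameter_mm[i],
               systolic_diameter = df$systolic_diameter_mm[i])
        })
        report <- risk_report(records, lc, curve)
      } else {
        # standalone path: report straight from the packaged calibration table
        report <- data.frame(case_id = calib$case_id,
                             systolic_diameter_mm = calib$systolic_diameter_mm,
                             ppsm_kpa = calib$ppsm_kpa,
                             risk_percent = 100 * rupture_risk(curve, calib$ppsm_kpa),
                             stringsAsFactors = FALSE)
      }
      op <- artifact_path(config, "risk_report", "csv")
      utils::write.csv(report, op, row.names = FALSE)
      write_manifest(config, "risk", inputs = if (file.exists(rp)) rp else list(),
                     outputs = op)
      list(report = op, table = report, curve = curve)
    })
  log_stage("stage '%s' done in %.1f s", stage, proc.time()[["elapsed"]] - t0)
  invisible(out)
}
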