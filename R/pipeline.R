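#' Configuration of an end-to-end pipeline run
#'
#' Bundles every stage's parameters into one serializable record with a
#' global seed. The resolution tier controls voxel spacing: `"standard"`
#' keeps the phantom's 0.5 mm default; `"coarse"` resamples to 1 mm for
#' quick multi-subject smoke runs.
#'
#' @param n_subjects cohort size.
#' @param seed global seed.
#' @param tier `"standard"` or `"coarse"`.
#' @param coupling a `coupling_params`.
#' @param params_base baseline `phantom_params`.
#' @param h_m mucosal heat-transfer coefficient (W/m^2 K).
#' @param extension_mm outlet extension (mm).
#' @param hu_window segmentation window (HU).
#' @param out_dir optional artifact directory; `NULL` disables file output.
#' @return a `run_config`.
#' @export
run_config <- function(n_subjects = 25, seed = 1L,
                       tier = c("standard", "coarse"),
                       coupling = coupling_params(),
                       params_base = phantom_params(),
                       h_m = 50, extension_mm = 50,
                       hu_window = c(-1000, -430),
                       out_dir = NULL) {
  tier <- match.arg(tier)
  if (tier == "coarse") params_base$spacing <- 1.0
  cfg <- list(n_subjects = n_subjects, seed = as.integer(seed), tier = tier,
              coupling = coupling, params_base = params_base, h_m = h_m,
              extension_mm = extension_mm, hu_window = hu_window,
              out_dir = out_dir)
  cfg$hash <- str_hash(jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                                     auto_unbox = TRUE, digits = NA,
                                     force = TRUE))
  class(cfg) <- "run_config"
  cfg
}

# segmentation + domain construction for one phantom
segment_phantom <- function(phantom, cfg) {
  lm <- phantom$truth$landmarks
  mask <- threshold_airway(phantom$volume, cfg$hu_window[1], cfg$hu_window[2])
  mask <- remove_isolated_regions(mask, lm$nostril_plane, lm$nasopharynx_plane)
  mask <- crop_domain(mask, lm$nostril_plane, lm$nasopharynx_plane,
                      cfg$extension_mm)
  build_domain(mask)
}

#' Run the full pipeline for one subject and timepoint
#'
#' Generates the subject's phantom at the requested timepoint, segments the
#' airway, solves flow and temperature at the subject's doubled
#' patient-specific flow rate (identical pre and post), and integrates the
#' surface metrics.
#'
#' @param cohort a `nasal_cohort`.
#' @param subject subject index (1-based) or id string.
#' @param timepoint `"pre"` or `"post"`.
#' @param cfg a `run_config`.
#' @param verbose print solver progress.
#' @return one-row data frame: id, timepoint, ROI/outside wall shear force
#'   (N) and heat transfer (W), ROI airway volume (cm^3), rhinometry proxy
#'   (cm^3), pressure loss (Pa), outcomes and provenance fields.
#' @export
run_subject <- function(cohort, subject, timepoint = c("pre", "post"),
                        cfg = run_config(), verbose = FALSE) {
  timepoint <- match.arg(timepoint)
  if (is.character(subject))
    subject <- match(subject, unique(cohort$subjects$id))
  geo <- cohort$geometry[[subject]]
  params <- geo$params
  params$spacing <- cfg$params_base$spacing
  r <- if (timepoint == "post") geo$reduction else 0
  phantom <- generate_phantom(params, reduction = r)

  row0 <- cohort$subjects[cohort$subjects$id ==
                            unique(cohort$subjects$id)[subject] &
                            cohort$subjects$timepoint == timepoint, ]
  Q <- simulation_flow_rate(patient_flow_rate(row0$sex, row0$weight))
  bc <- boundary_conditions(Q = Q, h_m = cfg$h_m)
  props <- fluid_properties()

  domain <- segment_phantom(phantom, cfg)
  flow <- solve_flow(domain, props, bc, verbose = verbose)
  temp <- solve_temperature(domain, flow, props, bc)
  wf <- wall_field(domain, flow, temp, props, bc)

  lm <- phantom$truth$landmarks
  roi <- define_roi(wf, lm$anterior_peak$left["y"],
                    lm$middle_turbinate_z, lm$septum_x)
  airway <- wf$region == "airway"
  mask_cm3 <- measure_volume(
    airway_mask(phantom$truth$airway, params$spacing),
    y_range = lm$anterior_peak$left["y"] + phantom$truth$roi_band,
    z_range = c(0, lm$middle_turbinate_z))

  out <- data.frame(
    id = row0$id, timepoint = timepoint,
    roi_force = integrate_wall_force(wf, roi),
    out_force = integrate_wall_force(wf, airway & !roi),
    roi_heat = integrate_heat_transfer(wf, roi),
    out_heat = integrate_heat_transfer(wf, airway & !roi),
    roi_volume = mask_cm3,
    v25 = row0$v25,
    pressure_loss = pressure_loss(domain, flow),
    vas = row0$vas, ghsi = row0$ghsi,
    Q_m3s = Q,
    iterations = length(flow$residuals$momentum),
    config_hash = cfg$hash,
    stringsAsFactors = FALSE)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    stem <- file.path(cfg$out_dir, sprintf("%s_%s", row0$id, timepoint))
    write_volume(phantom$volume, paste0(stem, ".nii.gz"))
    write_wall_vtk(wf, paste0(stem, "_wall.vtk"))
    write.csv(out, paste0(stem, "_metrics.csv"), row.names = FALSE)
    prov <- list(config_hash = cfg$hash, subject = row0$id,
                 timepoint = timepoint, Q_m3s = Q,
                 h_m = cfg$h_m,
                 iterations = length(flow$residuals$momentum),
                 final_residuals = list(
                   momentum = tail_(flow$residuals$momentum),
                   continuity = tail_(flow$residuals$continuity)))
    jsonlite::write_json(prov, paste0(stem, "_provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Run the whole cohort and build the statistics report
#'
#' Loops subjects and timepoints through [run_subject()], assembles the long
#' cohort metrics table and the Tables 1-4 style statistics report. A
#' partially completed output directory is resumed: subjects with an existing
#' metrics CSV are skipped and their rows reloaded.
#'
#' @param cfg a `run_config`.
#' @param cohort optional pre-generated `nasal_cohort` (defaults to
#'   `generate_cohort(cfg$n_subjects, cfg$coupling, seed = cfg$seed)`).
#' @param verbose print progress.
#' @return list with `table` (cohort metrics data frame), `report`
#'   (a `stats_report`) and `cohort`.
#' @export
run_cohort <- function(cfg = run_config(), cohort = NULL, verbose = FALSE) {
  cohort <- cohort %||% generate_cohort(cfg$n_subjects, cfg$coupling,
                                        params_base = cfg$params_base,
                                        seed = cfg$seed)
  ids <- unique(cohort$subjects$id)
  rows <- list()
  for (i in seq_along(ids)) {
    for (tp in c("pre", "post")) {
      cached <- if (!is.null(cfg$out_dir))
        file.path(cfg$out_dir, sprintf("%s_%s_metrics.csv", ids[i], tp))
      else ""
      if (nzchar(cached) && file.exists(cached)) {
        rows[[paste(i, tp)]] <- utils::read.csv(cached,
                                                stringsAsFactors = FALSE)
        next
      }
      if (verbose) message(sprintf("subject %s %s", ids[i], tp))
      rows[[paste(i, tp)]] <- run_subject(cohort, i, tp, cfg)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  rep <- build_report(tab)
  if (!is.null(cfg$out_dir)) {
    write.csv(tab, file.path(cfg$out_dir, "cohort_metrics.csv"),
              row.names = FALSE)
    report_markdown(rep, file.path(cfg$out_dir, "report.md"))
    jsonlite::write_json(unclass(rep), file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(table = tab, report = rep, cohort = cohort)
}
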