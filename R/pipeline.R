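# Per-subject pipeline orchestration and the cohort study wrapper. The CLI
# dispatcher at inst/cli/laflow.R is a thin wrapper over these functions.

#' Run the full per-subject analysis
#'
#' Executes mask -> PC-MRA -> hemodynamic indices -> flow rates and wave
#' features -> volumetrics (-> pathlines) and writes curves (CSV), features
#' (JSON), optional derived fields (.vti) and a stage log into
#' `config$output_dir`. Deterministic given identical inputs.
#'
#' @param config named list (or path to a JSON file) with entries:
#'   `data_dir` (directory written by [save_flowdataset()]/[write_phantom()]),
#'   `mask_path` (NIfTI label volume), `seeds_path` (JSON),
#'   `output_dir`; optional `velocity_units` (default "m/s"), `gamma` (0.4),
#'   `rho` (1060), `mu` (0.0035), `q_threshold` (500), `median_filter` (TRUE),
#'   `write_fields` (FALSE), `pathlines` (FALSE), `trail` (6),
#'   `subject` (id), `group`, `age`, `weight_kg`, `height_cm`.
#' @return (invisibly) the feature list written to `features.json`.
#' @export
run_subject <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  cfg <- function(key, default = NULL) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  out_dir <- config$output_dir
  check(!is.null(out_dir), "config$output_dir is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    log_lines <<- c(log_lines, sprintf("%s: %.2f s", name,
                                       as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  loaded <- stage("load", {
    dd <- config$data_dir
    check(!is.null(dd) && dir.exists(dd), "data_dir missing or not found")
    ds <- load_flowdataset(file.path(dd, c("flow_velx.nii.gz", "flow_vely.nii.gz",
                                           "flow_velz.nii.gz")),
                           file.path(dd, "flow_mag.nii.gz"),
                           units = cfg("velocity_units", "m/s"),
                           meta_path = file.path(dd, "flow_meta.json"))
    mp <- cfg("mask_path", file.path(dd, "mask.nii.gz"))
    check(file.exists(mp), "mask file not found: %s", mp)
    lab <- aperm(array(RNifti::readNifti(mp), dim(ds$velocity)[4:2]), c(3, 2, 1))
    mask <- mask3d(array(as.integer(round(lab)), dim(lab)), c(LA = 1L),
                   ds$spacing, ds$origin)
    list(ds = ds, mask = mask)
  })
  ds <- loaded$ds; mask <- loaded$mask
  ds <- stage("mask", apply_mask(ds, mask, "LA"))
  pc <- stage("pcmra", compute_pcmra(ds, gamma = cfg("gamma", 0.4)))
  params <- hemo_params(rho = cfg("rho", 1060), mu = cfg("mu", 0.0035),
                        q_threshold = cfg("q_threshold", 500))

  quant <- stage("quantify", {
    ke <- kinetic_energy(ds, mask, "LA", params)
    vel <- viscous_energy_loss(ds, mask, "LA", params)
    vo <- vorticity(ds, mask, "LA")
    qc <- q_criterion(ds, mask, "LA", params)
    list(ke = ke, vel = vel, vo = vo, qc = qc,
         ratio = ke_vel_ratio(ke$ke, vel$vel))
  })

  flows <- stage("flowrate", {
    sp <- cfg("seeds_path", file.path(config$data_dir, "seeds.json"))
    check(file.exists(sp), "seeds file not found: %s", sp)
    seeds <- read_seeds(sp)
    check("MV" %in% names(seeds), "seeds must include the MV sphere")
    curves <- lapply(seeds, function(s) {
      n <- plane_normal_from_flow(ds, s)
      cs <- extract_cross_section(mask, "LA", s, n)
      flow_rate(ds, cs)
    })
    mvq <- curves$MV
    waves <- list()
    for (nm in names(curves))
      waves[[nm]] <- if (nm == "MV") detect_mv_waves(mvq)
                     else detect_pv_waves(curves[[nm]], mvq)
    list(curves = curves, waves = waves)
  })

  vols <- stage("volume", {
    v_ml <- mask_volume(mask, "LA")
    lavi <- if (!is.null(config$weight_kg) && !is.null(config$height_cm))
      lav_indexed(v_ml, config$weight_kg, config$height_cm) else NA_real_
    list(la_volume_ml = v_ml, lavi_ml_m2 = lavi)
  })

  if (isTRUE(cfg("pathlines", FALSE))) {
    stage("trace", {
      seeds <- read_seeds(cfg("seeds_path", file.path(config$data_dir, "seeds.json")))
      pv <- seeds[setdiff(names(seeds), "MV")]
      em <- do.call(rbind, lapply(pv, function(s) {
        n <- plane_normal_from_flow(ds, s)
        cs <- extract_cross_section(mask, "LA", s, n)
        cs$points[seq(1, nrow(cs$points), length.out = min(25, nrow(cs$points))), ,
                  drop = FALSE]
      }))
      pl <- advect(ds, em, mask, "LA", trail = cfg("trail", 6))
      write_pathlines_vtk(pl, file.path(out_dir, "pathlines.vtk"))
    })
  }

  stage("write", {
    for (nm in names(flows$curves))
      write.csv(as.data.frame(flows$curves[[nm]]),
                file.path(out_dir, sprintf("curve_%s.csv", nm)), row.names = FALSE)
    for (ts in list(quant$ke$ke, quant$ke$ke_per_volume, quant$vel$vel,
                    quant$vel$vel_per_volume, quant$vo$series, quant$qc$series))
      write.csv(as.data.frame(ts),
                file.path(out_dir, sprintf("curve_%s.csv", ts$name)), row.names = FALSE)
    if (isTRUE(cfg("write_fields", FALSE))) {
      qmed <- median_filter3(quant$qc$field[which.max(quant$qc$series$values), , , ])
      write_vti(list(pcmra = pc, qcrit_median = qmed), ds$spacing, ds$origin,
                file.path(out_dir, "fields.vti"))
    }
    TRUE
  })

  summarize <- function(ts) {
    i <- which.max(ts$values)
    list(peak = ts$values[i], peak_time_s = ts$times[i], units = ts$units)
  }
  features <- list(
    subject = cfg("subject", "unknown"), group = cfg("group", NA),
    age = cfg("age", NA),
    la_volume_ml = vols$la_volume_ml, lavi_ml_m2 = vols$lavi_ml_m2,
    ke = summarize(quant$ke$ke), vel = summarize(quant$vel$vel),
    omega_la = summarize(quant$vo$series), qcrit_ratio = summarize(quant$qc$series),
    waves = flows$waves)
  jsonlite::write_json(features, file.path(out_dir, "features.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  writeLines(log_lines, file.path(out_dir, "stages.log"))
  invisible(features)
}

#' Run the cohort statistics over per-subject features
#'
#' Aggregates a feature table across subjects and runs the age-adjusted
#' ANCOVA (with gated Tukey/BH post hoc) per feature. Features for which some
#' group falls below the minimum size are skipped with a warning; subjects
#' missing a feature are excluded from that feature only.
#'
#' @param table a [cohort_table()] covering all features, or a list of
#'   `features.json` paths together with `features` selecting scalar entries
#'   (dot-paths such as `"ke.peak"` or `"waves.MV.EA_peak"`).
#' @param features character vector of feature names to test (default: all in
#'   the table).
#' @param alpha post-hoc gate.
#' @return named list of `ancova_result` (or `NULL` where skipped).
#' @export
run_cohort <- function(table, features = NULL, alpha = 0.05) {
  if (!inherits(table, "cohort_table") && is.character(table))
    table <- features_to_table(table, features)
  if (is.null(features)) features <- unique(table$feature)
  out <- list()
  for (f in features) {
    out[[f]] <- tryCatch(ancova(table, f, alpha = alpha),
                         error = function(e) {
                           warning(sprintf("feature '%s' skipped: %s", f,
                                           conditionMessage(e)))
                           NULL
                         })
  }
  out
}

# Build a cohort_table from per-subject features.json paths; `features` are
# dot-paths into the JSON structure.
features_to_table <- function(paths, features) {
  rows <- list()
  for (p in paths) {
    fj <- jsonlite::fromJSON(p)
    for (f in features) {
      val <- fj
      for (k in strsplit(f, ".", fixed = TRUE)[[1]]) val <- val[[k]]
      if (is.null(val) || !is.finite(as.numeric(val))) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject = fj$subject, group = fj$group, age = as.numeric(fj$age),
        feature = f, value = as.numeric(val), stringsAsFactors = FALSE)
    }
  }
  check(length(rows) > 0, "no usable feature rows found")
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_table", "data.frame")
  out
}
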