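#' Default pipeline configuration
#'
#' Every protocol constant is explicit and echoed into the run outputs so it
#' can be audited: cone half-angle 20 degrees, Poisson ratio 0.5, 1.8 nN force
#' cap, ROUT Q = 1%, picrosirius hue bands, k = 20 grouped folds, and all
#' stage seeds.
#'
#' @param out_dir Output directory for the run.
#' @param seed Master seed; stage seeds derive from it.
#' @return A nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(out_dir = tempfile("nanomech_run_"),
                                    seed = 1L) {
  seed <- as.integer(seed)
  structure(list(
    out_dir = out_dir,
    stages = list(simulate = TRUE, fit = TRUE, spectra = TRUE,
                  collagen = TRUE, stats = TRUE, classify = TRUE,
                  report = TRUE),
    simulate = list(
      groups = default_study_groups(),
      maps_per_specimen = 15L, grid_points = 16L, map_side_um = 20,
      n_samples = 400L, seed = seed
    ),
    fit = list(theta_deg = 20, nu = 0.5, force_cap_nn = 1.8, r2_min = 0.80),
    spectra = list(rout_q = 0.01, rout_first = TRUE, em_seed = seed),
    collagen = list(
      image_size = 128L, noise_sd = 3, seed = seed + 1L,
      hue_col1 = rbind(c(0, 45), c(315, 360)), hue_col3 = rbind(c(75, 165)),
      value_min = 0.10,
      stage_col1 = c(control = 0.02, inflammation_d3 = 0.04,
                     transition_d14 = 0.10, chronic_d21 = 0.18),
      stage_col3 = c(control = 0.01, inflammation_d3 = 0.02,
                     transition_d14 = 0.04, chronic_d21 = 0.06)
    ),
    classify = list(
      n_control = 16L, n_case = 17L, effect = 2.5, k = 20L,
      kernel = "linear", seed = seed + 2L,
      image_tile = 128L, map_sub = 16L
    ),
    seed = seed
  ), class = "pipeline_config")
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in dependency order: cohort simulation, curve
#' fitting, per-specimen spectra and peak decomposition, collagen
#' quantification on stage-graded synthetic sections, group statistics and
#' stage correlation, grouped-CV classification, and a human-readable report.
#' Each stage writes the documented CSV/JSON formats under `config$out_dir`;
#' re-running with an identical config reproduces identical numeric tables.
#'
#' @param config A [default_pipeline_config()] (possibly modified).
#' @return A run manifest (list of class `run_manifest`): config echo, output
#'   file registry with md5 hashes, per-stage timing, seeds.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  timing <- list()
  files <- character(0)
  state <- new.env()

  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    fun()
    timing[[name]] <<- proc.time()[["elapsed"]] - t0
  }

  run_stage("simulate", function() {
    sim <- config$simulate
    design <- study_design(groups = sim$groups,
                           maps_per_specimen = sim$maps_per_specimen,
                           grid_points = sim$grid_points,
                           map_side_um = sim$map_side_um, seed = sim$seed)
    state$cohort <- simulate_cohort(design, n_samples = sim$n_samples)
    f <- file.path(config$out_dir, "cohort_manifest.csv")
    data.table::fwrite(state$cohort$manifest, f)
    files <<- c(files, f)
  })

  run_stage("fit", function() {
    if (is.null(state$cohort)) stop("fit stage needs the simulate stage output")
    fc <- config$fit
    long <- list()
    state$maps_by_specimen <- lapply(state$cohort$specimens, function(sp) {
      maps <- lapply(seq_along(sp$maps), function(mi) {
        analyze_map(sp$maps[[mi]], theta_deg = fc$theta_deg, nu = fc$nu,
                    force_cap_nn = fc$force_cap_nn, r2_min = fc$r2_min,
                    provenance = list(specimen = sp$specimen_id, map = mi))
      })
      for (mi in seq_along(maps)) {
        m <- maps[[mi]]
        g <- nrow(m$E_kpa)
        long[[length(long) + 1L]] <<- data.frame(
          specimen_id = sp$specimen_id, map = mi,
          row = rep(seq_len(g), each = g), col = rep(seq_len(g), g),
          E_kpa = as.vector(t(m$E_kpa)),
          r2 = as.vector(t(m$r_squared)),
          qc_flag = as.vector(t(m$qc)), stringsAsFactors = FALSE
        )
      }
      maps
    })
    names(state$maps_by_specimen) <-
      vapply(state$cohort$specimens, `[[`, character(1), "specimen_id")
    f <- file.path(config$out_dir, "elasticity_long.csv")
    data.table::fwrite(data.table::rbindlist(long), f)
    files <<- c(files, f)
  })

  run_stage("spectra", function() {
    if (is.null(state$maps_by_specimen)) stop("spectra stage needs fitted maps")
    rows <- list()
    state$spectra <- list()
    for (sp in state$cohort$specimens) {
      maps <- state$maps_by_specimen[[sp$specimen_id]]
      spec <- pool_specimen(maps, specimen_id = sp$specimen_id)
      if (isTRUE(config$spectra$rout_first)) {
        rr <- rout_outliers(spec$values_kpa, q = config$spectra$rout_q)
        if (length(rr$outlier_idx)) {
          kept <- spec$values_kpa[rr$inlier_mask]
          spec$values_kpa <- kept; spec$n <- length(kept)
        }
      }
      state$spectra[[sp$specimen_id]] <- spec
      nmf <- if (spec$n >= 50) decompose_peaks(spec, seed = config$spectra$em_seed) else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = sp$specimen_id, group = sp$stage_label,
        timepoint_days = sp$timepoint_days, n = spec$n,
        n_components = if (is.null(nmf)) NA_integer_ else nmf$n_components,
        lep_mode_kpa = if (is.null(nmf)) NA_real_ else nmf$lep_mode_kpa,
        hep_mode_kpa = if (is.null(nmf)) NA_real_ else nmf$hep_mode_kpa,
        lep_weight = if (is.null(nmf)) NA_real_ else nmf$lep_weight,
        hep_weight = if (is.null(nmf)) NA_real_ else nmf$hep_weight,
        median_kpa = stats::median(spec$values_kpa),
        cv_percent = if (is.null(nmf)) NA_real_ else nmf$cv_percent,
        iqr_kpa = if (is.null(nmf)) NA_real_ else nmf$iqr_kpa,
        fallback = if (is.null(nmf)) NA else nmf$fallback,
        stringsAsFactors = FALSE
      )
    }
    state$nmf_table <- do.call(rbind, rows)
    f <- file.path(config$out_dir, "nmf_summary.csv")
    data.table::fwrite(state$nmf_table, f)
    files <<- c(files, f)
  })

  run_stage("collagen", function() {
    cg <- config$collagen
    set.seed(cg$seed)
    rows <- list()
    stages <- names(cg$stage_col1)
    state$collagen <- list()
    for (st in stages) {
      for (rep_i in 1:3) {
        img <- simulate_polarized_image(cg$stage_col1[[st]], cg$stage_col3[[st]],
                                        size = cg$image_size,
                                        noise_sd = cg$noise_sd)
        qn <- quantify_collagen_polarized(img, hue_col1 = cg$hue_col1,
                                          hue_col3 = cg$hue_col3,
                                          value_min = cg$value_min)
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = sprintf("%s_%d", st, rep_i), group = st,
          tissue_area_px = qn$tissue_area_px,
          col1_fraction = qn$col1_fraction, col3_fraction = qn$col3_fraction,
          col1_truth = cg$stage_col1[[st]], col3_truth = cg$stage_col3[[st]],
          stringsAsFactors = FALSE
        )
      }
    }
    state$collagen_table <- do.call(rbind, rows)
    f <- file.path(config$out_dir, "collagen.csv")
    data.table::fwrite(state$collagen_table, f)
    files <<- c(files, f)
  })

  run_stage("stats", function() {
    if (is.null(state$nmf_table)) stop("stats stage needs the spectra stage output")
    tbl <- state$nmf_table
    tests <- group_tests(tbl$median_kpa, tbl$group)
    f <- file.path(config$out_dir, "group_tests.csv")
    data.table::fwrite(tests, f)
    files <<- c(files, f)
    state$tests <- tests
  })

  run_stage("classify", function() {
    cl <- config$classify
    cohort <- simulate_classification_cohort(
      n_control = cl$n_control, n_case = cl$n_case, effect = cl$effect,
      maps_per_specimen = cl$maps_per_specimen %||% 4L,
      image_size = cl$image_size %||% 256L,
      seed = cl$seed
    )
    segs <- augment_by_segmentation(cohort, image_tile = cl$image_tile,
                                    map_sub = cl$map_sub)
    feats <- featurize_segments(segs)
    modality <- vapply(feats, `[[`, character(1), "modality")
    results <- list()
    for (mod in c("optical", "afm", "fused")) {
      samples <- if (mod == "fused") {
        fuse_modalities(feats[modality == "optical"], feats[modality == "afm"])
      } else feats[modality == mod]
      sm <- sample_matrix(samples)
      cv <- grouped_cv_train_eval(sm$x, sm$y, sm$groups,
                                  kernel = kernel_spec(cl$kernel),
                                  k = cl$k, seed = cl$seed)
      results[[mod]] <- cv
    }
    state$classify <- results
    tab <- data.frame(
      modality = names(results),
      kernel = cl$kernel,
      accuracy_min_pct = vapply(results, function(r) r$accuracy_range_pct[1], numeric(1)),
      accuracy_max_pct = vapply(results, function(r) r$accuracy_range_pct[2], numeric(1)),
      accuracy_mean_pct = vapply(results, function(r) r$mean_accuracy_pct, numeric(1)),
      k = vapply(results, function(r) r$k, numeric(1)),
      stringsAsFactors = FALSE
    )
    state$classify_table <- tab
    f <- file.path(config$out_dir, "classifier_summary.csv")
    data.table::fwrite(tab, f)
    files <<- c(files, f)
  })

  manifest <- structure(list(
    config = config,
    files = stats::setNames(
      as.character(tools::md5sum(files)), basename(files)),
    timing = timing,
    seeds = list(master = config$seed),
    out_dir = config$out_dir
  ), class = "run_manifest")

  if (isTRUE(config$stages$report)) {
    rep_txt <- pipeline_report(manifest, state = state)
    f <- file.path(config$out_dir, "report.md")
    writeLines(rep_txt, f)
    manifest$files <- c(manifest$files,
                        stats::setNames(as.character(tools::md5sum(f)), "report.md"))
  }
  jsonlite::write_json(
    list(files = as.list(manifest$files),
         timing = lapply(timing, function(t) round(t, 3)),
         seed = config$seed),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)
  manifest
}

#' Render a human-readable pipeline report
#'
#' @param manifest A `run_manifest` from [run_pipeline()].
#' @param state Internal stage results (supplied by [run_pipeline()]); when
#'   NULL, tables are re-read from the run's CSV outputs.
#' @return Character vector of markdown lines.
#' @export
pipeline_report <- function(manifest, state = NULL) {
  out_dir <- manifest$out_dir
  read_if <- function(name) {
    f <- file.path(out_dir, name)
    if (file.exists(f)) as.data.frame(data.table::fread(f)) else NULL
  }
  nmf <- if (!is.null(state$nmf_table)) state$nmf_table else read_if("nmf_summary.csv")
  collagen <- if (!is.null(state$collagen_table)) state$collagen_table else read_if("collagen.csv")
  tests <- if (!is.null(state$tests)) state$tests else read_if("group_tests.csv")
  cls <- if (!is.null(state$classify_table)) state$classify_table else read_if("classifier_summary.csv")

  lines <- c("# Nanomechanical fingerprint pipeline report", "")
  if (!is.null(nmf) && nrow(nmf)) {
    lines <- c(lines, "## LEP/HEP summary by group", "")
    agg <- stats::aggregate(cbind(lep_mode_kpa, hep_mode_kpa, hep_weight,
                                  cv_percent, iqr_kpa) ~ group,
                            data = nmf, FUN = function(v) mean(v, na.rm = TRUE),
                            na.action = stats::na.pass)
    lines <- c(lines, utils::capture.output(print(agg, row.names = FALSE)), "")
  } else {
    lines <- c(lines, "## LEP/HEP summary by group", "", "(no specimens)", "")
  }
  if (!is.null(collagen) && nrow(collagen)) {
    lines <- c(lines, "## Collagen fractions by group", "")
    agg <- stats::aggregate(cbind(col1_fraction, col3_fraction) ~ group,
                            data = collagen, FUN = mean)
    lines <- c(lines, utils::capture.output(print(agg, row.names = FALSE)), "")
  }
  if (!is.null(tests) && nrow(tests)) {
    lines <- c(lines, "## Group tests", "",
               utils::capture.output(print(tests, row.names = FALSE)), "")
  }
  if (!is.null(cls) && nrow(cls)) {
    lines <- c(lines, "## Classifier accuracy (grouped CV, test folds)", "",
               utils::capture.output(print(cls, row.names = FALSE)), "")
  }
  lines
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", x$out_dir, "\n")
  cat("  files:", paste(names(x$files), collapse = ", "), "\n")
  invisible(x)
}
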