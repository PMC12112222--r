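#' Build a pipeline configuration
#'
#' Collects every knob of the end-to-end analysis with defaults mirroring
#' the standard optimized-maxent protocol: 2.5 km thinning, |r| >= 0.8
#' screening, 7 feature classes x 8 regularization multipliers, 10,000
#' background points, 10 bootstrap replicates with a 75/25 split, logistic
#' output averaged over replicates, automatic MTSPS thresholding, and
#' 20-year spacing between scenario periods.
#'
#' @param occurrences occurrence CSV path or data.frame
#'   (`name,longitude,latitude`).
#' @param scenarios named list of `sdm_stack`s (or directories of `.asc`
#'   layers); must include the entry named by `current`.
#' @param out_dir output directory for artifacts (`NULL` = don't write).
#' @param current name of the baseline scenario.
#' @param thin_km spatial thinning distance, km.
#' @param screen_threshold Pearson |r| exclusion threshold.
#' @param priority optional variable priority list for screening.
#' @param fcs,rms tuning grids.
#' @param background_n background sample size.
#' @param n_knots hinge/threshold knots per layer.
#' @param replicates bootstrap replicates.
#' @param train_fraction training fraction of each replicate.
#' @param years_between years between consecutive scenario periods.
#' @param mtsps `"auto"` (from pooled replicate test predictions) or a
#'   numeric override.
#' @param baseline_fc feature class of the contribution-screening baseline
#'   fit.
#' @param agg checkerboard-2 aggregation factors.
#' @param seed master seed; all stage seeds derive from it.
#' @param max_iter,tol optimizer controls.
#' @return config list of class `sdm_config`.
#' @export
sdm_config <- function(occurrences, scenarios, out_dir = NULL, current = "current",
                       thin_km = 2.5, screen_threshold = 0.8, priority = NULL,
                       fcs = c("L", "LQ", "H", "LQH", "LQP", "LQHP", "LQHPT"),
                       rms = seq(0.5, 4, by = 0.5), background_n = 10000,
                       n_knots = 50, replicates = 10, train_fraction = 0.75,
                       years_between = 20, mtsps = "auto", baseline_fc = "LQ",
                       agg = c(10, 2), seed = 1, max_iter = 5000, tol = 1e-5) {
  if (!current %in% names(scenarios))
    stop("scenarios must include the baseline entry '", current, "'")
  structure(as.list(environment()), class = "sdm_config")
}

read_stack_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) stop("no .asc layers found in ", dir)
  layers <- lapply(files, read_ascii_grid)
  names(layers) <- sub("\\.asc$", "", basename(files))
  raster_stack(layers)
}

subset_stack <- function(stack, keep) raster_stack(stack$layers[keep])

#' Run the full analysis pipeline
#'
#' Executes thin, screen, tune, bootstrap replicate fits, per-scenario mean
#' logistic surfaces, MTSPS thresholding, suitability grading and area
#' accounting, range-change maps and statistics against the baseline
#' scenario, and the centroid trajectory. Every stage logs its seed and
#' elapsed time; a rerun with the same config is bit-identical. With a
#' single scenario the change stage is skipped with a logged notice.
#'
#' @param config an [sdm_config()].
#' @return list with `occurrences`, `correlation`, `screening`, `tuning`,
#'   `mtsps`, `suitability` (mean logistic raster per scenario), `grades`,
#'   `areas`, `change` (maps, stats, centroid trajectory), `model`
#'   (selected full-data fit), and `log`.
#' @export
run_sdm_pipeline <- function(config) {
  stopifnot(inherits(config, "sdm_config"))
  log_lines <- character(0)
  stage <- function(name, seed = NA, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage=%s failed: %s", name, conditionMessage(e)), call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage=%s seed=%s elapsed=%.2fs", name,
                                       as.character(seed),
                                       proc.time()[["elapsed"]] - t0))
    res
  }
  scenarios <- lapply(config$scenarios, function(s)
    if (is.character(s)) read_stack_dir(s) else s)
  cur_name <- config$current
  stack <- scenarios[[cur_name]]

  occ <- stage("load_occurrences", NA,
               load_occurrences(config$occurrences, mask = stack$layers[[1]]))
  occ <- stage("thin", config$seed + 101,
               thin_occurrences(occ, min_km = config$thin_km, seed = config$seed + 101))

  bg_cells <- stage("background", config$seed + 202,
                    sample_background(stack, config$background_n, seed = config$seed + 202))
  pres_cells <- lonlat_cell(stack$layers[[1]], occ$longitude, occ$latitude)
  pres_X <- stack_values(stack, pres_cells)
  bg_X <- stack_values(stack, bg_cells)

  screening <- stage("screen_variables", config$seed + 303, {
    baseline <- fit_maxent(pres_X, bg_X, fc = config$baseline_fc, rm = 1,
                           n_knots = config$n_knots, max_iter = config$max_iter,
                           tol = config$tol)
    contribution <- percent_contribution(baseline)
    corr <- pearson_matrix(stack, seed = config$seed + 303)
    sel <- screen_variables(corr, contribution, threshold = config$screen_threshold,
                            priority = config$priority)
    sel$correlation <- corr
    sel$contribution <- contribution
    sel
  })
  kept <- screening$kept
  scenarios <- lapply(scenarios, subset_stack, keep = kept)
  stack <- scenarios[[cur_name]]
  pres_X <- pres_X[, kept, drop = FALSE]
  bg_X <- bg_X[, kept, drop = FALSE]

  tuning <- stage("tune", config$seed + 404,
                  tune_maxent(occ, stack, bg_cells = bg_cells, fcs = config$fcs,
                              rms = config$rms, agg = config$agg,
                              n_knots = config$n_knots, seed = config$seed + 404,
                              max_iter = config$max_iter, tol = config$tol))
  fc <- tuning$selected$fc; rm_sel <- tuning$selected$rm

  reps <- stage("replicates", config$seed + 505, {
    lapply(seq_len(config$replicates), function(r) {
      set.seed(config$seed + 505 + r)
      idx <- sample.int(nrow(pres_X), replace = TRUE)  # bootstrap resample
      n_tr <- max(5, floor(config$train_fraction * length(idx)))
      tr <- idx[seq_len(n_tr)]
      te <- idx[-seq_len(n_tr)]
      m <- fit_maxent(pres_X[tr, , drop = FALSE], bg_X, fc = fc, rm = rm_sel,
                      n_knots = config$n_knots, max_iter = config$max_iter,
                      tol = config$tol)
      list(model = m,
           test_pred = if (length(te)) predict(m, pres_X[te, , drop = FALSE]) else numeric(0),
           bg_pred = predict(m, bg_X))
    })
  })

  suit <- stage("mean_logistic", NA, {
    lapply(scenarios, function(s) {
      preds <- lapply(reps, function(r) predict(r$model, s))
      h <- s$header
      mean_vals <- Reduce(`+`, lapply(preds, `[[`, "values")) / length(preds)
      new_raster(mean_vals, h$xll, h$yll, h$cellsize, h$nodata)
    })
  })

  mtsps <- stage("mtsps", NA, {
    if (is.numeric(config$mtsps)) config$mtsps
    else mtsps_threshold(unlist(lapply(reps, `[[`, "test_pred")),
                         unlist(lapply(reps, `[[`, "bg_pred")))
  })
  scheme <- grade_scheme(mtsps)

  grades <- stage("classify", NA, lapply(suit, classify_suitability, scheme = scheme))
  areas <- stage("areas", NA, {
    out <- lapply(names(grades), function(nm) cbind(scenario = nm, area_report(grades[[nm]])))
    do.call(rbind, out)
  })

  change <- NULL
  other <- setdiff(names(scenarios), cur_name)
  if (length(other) == 0) {
    log_lines <- c(log_lines, "stage=change skipped: single scenario")
  } else {
    change <- stage("change", NA, {
      cur_bin <- binarize_suitability(suit[[cur_name]], mtsps)
      cur_centroid <- suitable_centroid(cur_bin)
      maps <- list(); stats <- list(); traj <- list()
      for (nm in other) {
        fut_bin <- binarize_suitability(suit[[nm]], mtsps)
        cm <- change_map(cur_bin, fut_bin)
        maps[[nm]] <- cm
        stats[[nm]] <- cbind(scenario = nm, change_stats(cm))
        sh <- centroid_shift(cur_centroid, suitable_centroid(fut_bin),
                             years = config$years_between)
        traj[[nm]] <- data.frame(scenario = nm, lon_from = sh$from[["lon"]],
                                 lat_from = sh$from[["lat"]], lon_to = sh$to[["lon"]],
                                 lat_to = sh$to[["lat"]], distance_km = sh$distance_km,
                                 bearing_deg = sh$bearing_deg, direction = sh$direction,
                                 speed_km_per_yr = sh$speed_km_per_yr)
      }
      list(maps = maps, stats = do.call(rbind, stats),
           centroids = do.call(rbind, traj), current_centroid = cur_centroid)
    })
  }

  results <- list(occurrences = occ, correlation = screening$correlation,
                  screening = screening[c("kept", "dropped", "steps", "contribution")],
                  tuning = tuning$results, selected = tuning$selected,
                  model = tuning$model, mtsps = mtsps, scheme = scheme,
                  suitability = suit, grades = grades, areas = areas,
                  change = change, log = log_lines)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    write.csv(occ, file.path(od, "occurrences_clean.csv"), row.names = FALSE)
    write.csv(as.data.frame(screening$correlation), file.path(od, "correlation.csv"))
    writeLines(kept, file.path(od, "variables_kept.txt"))
    write.csv(tuning$results, file.path(od, "tuning.csv"), row.names = FALSE)
    for (nm in names(suit)) {
      write_ascii_grid(suit[[nm]], file.path(od, paste0("suitability_", nm, ".asc")))
      write_ascii_grid(grades[[nm]], file.path(od, paste0("grades_", nm, ".asc")))
    }
    areas_out <- areas
    areas_out$area_1e4_km2 <- round(areas_out$area_km2 / 1e4, 2)
    write.csv(areas_out, file.path(od, "areas.csv"), row.names = FALSE)
    if (!is.null(change)) {
      for (nm in names(change$maps))
        write_ascii_grid(change$maps[[nm]], file.path(od, paste0("change_", nm, ".asc")))
      write.csv(change$stats, file.path(od, "change_stats.csv"), row.names = FALSE)
      write.csv(change$centroids, file.path(od, "centroids.csv"), row.names = FALSE)
    }
    write_maxent_model(tuning$model, file.path(od, "model.json"))
    writeLines(log_lines, file.path(od, "log.txt"))
  }
  results
}
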