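#' Merge plot-level indices and abundances into one plot table
#'
#' Computes every requested vegetation index from the reflectance image,
#' averages it per plot, and joins the plot-level abundance summaries
#' (`Abd_L`, `Abd_P`, `Abd_LP`) from the unmixing result.
#'
#' @param refl A [multiband_image()] of kind "reflectance".
#' @param abund The matching [abundance_map()].
#' @param layout A [plot_layout()].
#' @param vis Vegetation index names (default all ten).
#' @return Data frame with one row per plot.
#' @export
build_plot_table <- function(refl, abund, layout, vis = vi_names()) {
  tab <- aggregate_abundance(abund, layout)
  for (vi in vis) {
    agg <- aggregate_vi(compute_vi(refl, vi), layout)
    tab[[vi]] <- agg[[vi]]
  }
  tab
}

stage_msg <- function(...) message("[paddysma] ", ...)

#' Run the full yield-estimation pipeline on a synthetic scene
#'
#' Orchestrates every stage in order: scene simulation, empirical-line
#' calibration fitted from the rendered panels, DN-to-reflectance
#' conversion, fully constrained unmixing, vegetation indices, plot-level
#' aggregation, correlation and regression of the four predictor families,
#' and leave-one-out cross-validation of the selected final models. With an
#' output directory, every intermediate is written (rasters as float TIFF,
#' tables as CSV) together with a JSON run manifest recording the
#' configuration hash, seed, stage timings and headline metrics.
#'
#' @param config A [scene_config()].
#' @param out_dir Optional output directory; created if missing.
#' @param vis Vegetation indices to compute (default all ten).
#' @param modes Predictor families to compare (default all four).
#' @param final_models Indices whose `LP`-weighted predictors get the
#'   leave-one-out treatment; defaults to NDRE and GNDVI (intersected with
#'   `vis`).
#' @param exclude_plots Plot ids dropped from the statistical stage.
#' @return A list of class `pipeline_run`: `scene`, `calibration`, `refl`,
#'   `qc`, `abund`, `plot_table` (with yields), `correlations`, `ranking`,
#'   `cv` (one `cv_result` per final model), `manifest`.
#' @export
run_pipeline <- function(config = scene_config(), out_dir = NULL,
                         vis = vi_names(),
                         modes = c("plain", "L", "P", "LP"),
                         final_models = NULL,
                         exclude_plots = NULL) {
  if (is.null(final_models)) {
    final_models <- intersect(c("NDRE", "GNDVI"), vis)
  }
  if (!all(final_models %in% vis)) {
    stop("'final_models' must be a subset of 'vis'", call. = FALSE)
  }
  t0 <- Sys.time()
  timings <- c()
  tick <- function(stage) {
    t1 <- Sys.time()
    timings[stage] <<- round(as.numeric(t1 - t0, units = "secs"), 3)
    t0 <<- t1
  }

  stage_msg("simulate: seed ", config$seed, ", ", n_plots(config), " plots")
  scene <- generate_scene(config)
  tick("simulate")

  stage_msg("calibrate: ", length(scene$panels$nominals), " panels")
  model <- fit_empirical_line(scene$dn_image, scene$panels)
  refl <- apply_calibration(scene$dn_image, model)
  qc <- calibration_qc(refl)
  stage_msg("calibrate: out-of-range fraction ",
            signif(max(qc$frac_below_0 + qc$frac_above_1), 3))
  tick("calibrate")

  stage_msg("unmix: ", prod(dim(refl$values)[1:2]), " pixels x ",
            nrow(scene$library$matrix), " endmembers")
  abund <- unmix_image(refl, scene$library)
  tick("unmix")

  stage_msg("aggregate: ", length(vis), " indices over ",
            nrow(scene$layout), " plots")
  plot_table <- build_plot_table(refl, abund, scene$layout, vis)
  plot_table$yield <- scene$true_plot_table$yield
  tick("aggregate")

  keep <- !plot_table$plot_id %in% exclude_plots
  tab <- plot_table[keep, , drop = FALSE]
  predictors <- list()
  for (vi in vis) {
    for (mode in modes) {
      nm <- if (mode == "plain") vi else paste0(vi, "_", mode)
      predictors[[nm]] <- combined_index(tab[[vi]], tab, mode)
    }
  }
  for (ab in c("Abd_L", "Abd_P", "Abd_LP")) predictors[[ab]] <- tab[[ab]]
  correlations <- correlate(tab$yield, predictors)
  ranking <- rank_models(tab, vis, modes)
  # abundance-only predictors, reported alongside the VI grid
  abund_rows <- do.call(rbind, lapply(c("Abd_L", "Abd_P", "Abd_LP"),
                                      function(ab) {
    fit <- fit_linear(tab[[ab]], tab$yield)
    data.frame(vi = NA_character_, mode = "abundance",
               predictor = sub("Abd_LP", "Abd_L-P", ab),
               r = fit$pearson_r, adjusted_r2 = fit$adjusted_r2,
               rmse = fit$rmse, p_value = fit$p_value)
  }))
  ranking <- rbind(ranking, abund_rows)
  ranking <- ranking[order(-ranking$adjusted_r2), ]
  cv <- lapply(final_models, function(vi) {
    loocv_fit(combined_index(tab[[vi]], tab, "LP"), tab$yield)
  })
  names(cv) <- paste0(final_models, "_LP")
  tick("fit")

  best <- ranking[1, ]
  manifest <- list(
    package_version = as.character(utils::packageVersion("paddysma")),
    seed = config$seed,
    config_hash = config_hash(config),
    n_plots = nrow(plot_table),
    n_plots_fitted = sum(keep),
    n_abundance_planes = length(abund$names),
    excluded_plots = as.list(exclude_plots),
    stage_seconds = as.list(timings),
    qc_out_of_range_max = max(qc$frac_below_0 + qc$frac_above_1),
    best_model = list(predictor = best$predictor,
                      adjusted_r2 = best$adjusted_r2, rmse = best$rmse),
    cv = lapply(cv, function(m) {
      list(slope = m$slope, intercept = m$intercept,
           r_squared = m$r_squared, rmse = m$rmse, K = m$K)
    })
  )

  run <- structure(list(scene = scene, calibration = model, refl = refl,
                        qc = qc, abund = abund, plot_table = plot_table,
                        correlations = correlations, ranking = ranking,
                        cv = cv, manifest = manifest),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
  run
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_raster_tiff(run$scene$dn_image, p("dn.tif"))
  write_raster_tiff(run$refl, p("reflectance.tif"))
  write_abundance_tiff(run$abund, p("abundance.tif"),
                       grey8 = p("abundance_grey8.tif"))
  write_layout_json(run$scene$layout, p("layout.json"))
  write_panels_json(run$scene$panels, p("panels.json"))
  write_library_csv(run$scene$library, p("endmember_library.csv"))
  write_spectra_csv(run$scene$spectra, p("endmember_spectra.csv"))
  utils::write.csv(run$plot_table, p("plot_table.csv"), row.names = FALSE)
  utils::write.csv(run$scene$true_plot_table, p("true_plot_table.csv"),
                   row.names = FALSE)
  utils::write.csv(run$correlations, p("correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(run$ranking, p("model_ranking.csv"), row.names = FALSE)
  utils::write.csv(run$qc, p("calibration_qc.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> seed ", x$manifest$seed, ", ",
      x$manifest$n_plots_fitted, "/", x$manifest$n_plots,
      " plots fitted\n", sep = "")
  b <- x$manifest$best_model
  cat(sprintf("  best model: %s (adj R2 %.3f, RMSE %.3f)\n",
              b$predictor, b$adjusted_r2, b$rmse))
  for (nm in names(x$cv)) {
    m <- x$cv[[nm]]
    cat(sprintf("  LOOCV %s: yield = %.3f x + %.3f, R2 %.3f, RMSE %.3f\n",
                nm, m$slope, m$intercept, m$r_squared, m$rmse))
  }
  invisible(x)
}
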