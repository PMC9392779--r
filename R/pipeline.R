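## End-to-end pipeline orchestration with a single validated configuration
## and a reproducibility manifest.

.default_config <- list(
  schema_version = 1L,
  knn = 30L,
  percentile = 95,
  min_size = 100L,
  refine_knn = 10L,
  refine_cutoff_nm = 400,
  density_radius_nm = 100,
  grid_pixel_nm = 20,
  min_curve_points = 50L,
  frame_stride = 1L,
  seed = 1L)

#' Default pipeline configuration
#'
#' All stage parameters with their standard values: 30 EMST neighbor
#' candidates, 95th-percentile edge cut, 100-localization cluster filter,
#' 10-neighbor / 400 nm per-frame refinement, 100 nm neighbor-density
#' radius, 20 nm area grid.
#'
#' @return named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(.default_config, class = "run_config")
}

#' Read and validate a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return validated `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .default_config
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  stopifnot(cfg$knn >= 1, cfg$percentile > 0, cfg$percentile <= 100,
            cfg$min_size >= 1, cfg$refine_knn >= 1,
            cfg$refine_cutoff_nm > 0, cfg$density_radius_nm > 0,
            cfg$grid_pixel_nm > 0, cfg$frame_stride >= 1)
  structure(cfg, class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Ingests one or more localization tables (paths or in-memory tables),
#' segments aggregates, builds growth curves, fits and classifies both
#' growth models, extracts phase rates, runs the Arrhenius analysis when
#' the inputs span at least two temperatures, renders a neighbor-density
#' map per input, and writes everything plus a reproducibility manifest to
#' `out_dir`. With fixed seeds the run is deterministic; partial outputs
#' are retained if a stage fails.
#'
#' @param inputs character vector of localization-table paths, or a list of
#'   [localization_table()] objects (each should carry `frame_interval`
#'   and, for Arrhenius analysis, `temperature`).
#' @param config a `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the collected `clusters`, `curves`,
#'   `fits`, `rates` and (possibly `NULL`) `arrhenius` results; files are
#'   written under `out_dir`.
#' @export
run_pipeline <- function(inputs, config = default_run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- .stage("ingest", {
    if (is.character(inputs)) lapply(inputs, read_localizations)
    else if (is.list(inputs) &&
             all(vapply(inputs, inherits, TRUE, "localization_table"))) inputs
    else stop("inputs must be file paths or localization tables")
  })
  input_digests <- if (is.character(inputs))
    as.list(tools::md5sum(inputs)) else lapply(tables, function(tb) {
      f <- tempfile(); on.exit(unlink(f))
      write_localizations(tb, f)
      unname(tools::md5sum(f))
    })

  cluster_rows <- list(); curve_rows <- list(); fit_records <- list()
  rate_rows <- list()
  for (ti in seq_along(tables)) {
    tb <- tables[[ti]]
    temp <- attr(tb, "temperature")
    clusters <- .stage("segment",
                       segment_aggregates(tb, knn = config$knn,
                                          percentile = config$percentile,
                                          min_size = config$min_size))
    assign_col <- integer(nrow(tb))
    for (cl in clusters) {
      assign_col[cl$members] <- cl$id
      cluster_rows[[length(cluster_rows) + 1L]] <- data.frame(
        input = ti, cluster = cl$id, n = length(cl$members),
        xmin = cl$bbox["xmin"], xmax = cl$bbox["xmax"],
        ymin = cl$bbox["ymin"], ymax = cl$bbox["ymax"], row.names = NULL)
      curve <- .stage("growth", {
        f0 <- min(tb$frame[cl$members])
        frames <- seq.int(f0, max(tb$frame), by = config$frame_stride)
        build_growth_curve(cl, tb, frames = frames,
                           refine_k = config$refine_knn,
                           refine_cutoff = config$refine_cutoff_nm,
                           min_points = config$min_curve_points,
                           grid_pixel = config$grid_pixel_nm,
                           seed = config$seed)
      })
      if (nrow(curve) < 8) next
      curve_rows[[length(curve_rows) + 1L]] <-
        cbind(input = ti, cluster = cl$id, as.data.frame(curve))
      call <- .stage("fit", classify_morphology(curve))
      if (call$morphology == "unclassified") next
      fit <- call$fits[[call$kind]]
      fit_records[[length(fit_records) + 1L]] <- list(
        input = ti, cluster = cl$id, morphology = call$morphology,
        kind = call$kind, margin = call$margin,
        params = c(unclass(fit$params)), se = as.list(fit$se),
        chisq = fit$chisq, red_chisq = fit$red_chisq, n = fit$n,
        converged = fit$converged)
      rate_rows[[length(rate_rows) + 1L]] <-
        .stage("rates", cbind(input = ti,
                              extract_rates(fit, call$morphology,
                                            temperature = temp,
                                            aggregate_id = cl$id)))
    }
    tb2 <- as.data.frame(tb)
    tb2$cluster <- assign_col
    utils::write.csv(tb2, file.path(out_dir,
                                    sprintf("localizations_%02d.csv", ti)),
                     row.names = FALSE)
    .stage("render", {
      map <- render_density_map(tb, pixel = config$grid_pixel_nm,
                                radius = config$density_radius_nm)
      write_density_map(map, file.path(out_dir,
                                       sprintf("density_%02d.tif", ti)))
    })
  }
  clusters_df <- if (length(cluster_rows)) do.call(rbind, cluster_rows)
  curves_df <- if (length(curve_rows)) do.call(rbind, curve_rows)
  rates_df <- if (length(rate_rows)) do.call(rbind, rate_rows)
  if (!is.null(clusters_df))
    utils::write.csv(clusters_df, file.path(out_dir, "clusters.csv"),
                     row.names = FALSE)
  if (!is.null(curves_df))
    utils::write.csv(curves_df, file.path(out_dir, "growth_curves.csv"),
                     row.names = FALSE)
  jsonlite::write_json(fit_records, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(rates_df))
    utils::write.csv(rates_df, file.path(out_dir, "rates.csv"),
                     row.names = FALSE)

  arr <- NULL
  if (!is.null(rates_df)) {
    arr <- .stage("arrhenius", {
      fits <- list()
      for (ph in unique(rates_df$phase)) {
        sub <- rates_df[rates_df$phase == ph & !is.na(rates_df$temperature_C), ]
        temps <- table(sub$temperature_C)
        if (length(temps) >= 2 && all(temps >= 2))
          fits[[ph]] <- fit_arrhenius(sub)
      }
      if (length(fits)) {
        jsonlite::write_json(
          lapply(fits, function(f)
            list(Ea_kJmol = f$Ea_kJmol, Ea_se_kJmol = f$Ea_se_kJmol,
                 lnA = f$lnA, lnA_se = f$lnA_se,
                 per_temperature = f$per_temperature)),
          file.path(out_dir, "arrhenius.json"), auto_unbox = TRUE,
          digits = NA)
      }
      if (length(fits)) fits else NULL
    })
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("replom")),
    config = unclass(config),
    inputs = if (is.character(inputs)) inputs else
      sprintf("in-memory table %d", seq_along(tables)),
    input_md5 = input_digests,
    n_clusters = if (is.null(clusters_df)) 0L else nrow(clusters_df))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(clusters = clusters_df, curves = curves_df,
                 fits = fit_records, rates = rates_df, arrhenius = arr))
}
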