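# End-to-end orchestration: ingest -> extract -> fit -> diagnose ->
# predict-gc, with a reproducibility manifest (input checksums, config
# hash, exclusion counts, versions).

#' Pipeline configuration
#'
#' Bundles the per-stage settings of [run_pipeline]. Every extraction
#' threshold (humid-night VPD, steady-state tolerance, diurnal window,
#' averaging window) and fit setting is a config key with the study value
#' as default. Configurations can also be loaded from a YAML or JSON file
#' with the same keys via [read_pipeline_config].
#'
#' @param seed master seed for the fit and diagnostics.
#' @param extraction a list of [extraction_config] overrides.
#' @param fit a list of [fit_config] overrides.
#' @param vpd_grid,psi_grid grids for the conductance surface.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, extraction = list(), fit = list(),
                            vpd_grid = seq(0.05, 4, by = 0.05),
                            psi_grid = seq(0, -4, by = -0.05)) {
  ex <- do.call(extraction_config, extraction)
  ft <- do.call(fit_config, utils::modifyList(list(seed = seed), fit))
  structure(list(seed = as.integer(seed), extraction = ex, fit = ft,
                 vpd_grid = vpd_grid, psi_grid = psi_grid),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognized top-level keys: `seed`, `extraction` (keys of
#' [extraction_config]), `fit` (keys of [fit_config]), `vpd_grid`,
#' `psi_grid` (3-vectors from/to/by or explicit vectors).
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs need the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  grid <- function(g, default) {
    if (is.null(g)) default
    else if (length(g) == 3L && !is.null(names(g))) {
      seq(g[["from"]], g[["to"]], by = g[["by"]])
    } else as.numeric(g)
  }
  pipeline_config(seed = if (is.null(x$seed)) 1L else x$seed,
                  extraction = if (is.null(x$extraction)) list()
                  else x$extraction,
                  fit = if (is.null(x$fit)) list() else x$fit,
                  vpd_grid = grid(x$vpd_grid, seq(0.05, 4, by = 0.05)),
                  psi_grid = grid(x$psi_grid, seq(0, -4, by = -0.05)))
}

md5_of <- function(paths) {
  out <- tools::md5sum(paths[file.exists(paths)])
  names(out) <- basename(names(out))
  as.list(out)
}

#' Run the full pipeline on a study directory
#'
#' Stages: *ingest* (climate, width and calibration CSVs), *extract*
#' (calibration fits, predawn anchors, steady-state daily records),
#' *fit* (hierarchical Bayesian changepoint model), *diagnose*
#' (R-hat, PSIS-LOO, R-squared, predictive coverage) and *predict-gc*
#' (normalized conductance surface at posterior-mean parameters). Outputs
#' and a reproducibility manifest are written to `output_dir`; a stage
#' failure halts with that stage's error after writing a partial
#' manifest.
#'
#' @param input_dir directory with `climate.csv`, `widths.csv`,
#'   `calibration.csv` (the dialects of [write_study]).
#' @param output_dir output directory (created).
#' @param config a [pipeline_config].
#' @return the manifest (list), invisibly. `manifest$converged` reports
#'   the R-hat gate; the CLI turns `FALSE` into a nonzero exit.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         config = pipeline_config()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- file.path(input_dir, c("climate.csv", "widths.csv",
                                   "calibration.csv"))
  cfg_json <- jsonlite::toJSON(list(seed = config$seed,
                                    extraction = unclass(config$extraction)[
                                      !vapply(unclass(config$extraction),
                                              is.function, logical(1))],
                                    fit = unclass(config$fit)),
                               auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json"); writeLines(cfg_json, tf)
  manifest <- list(seed = config$seed,
                   config_hash = unname(tools::md5sum(tf)),
                   inputs = md5_of(inputs),
                   versions = list(r = as.character(getRversion()),
                                   stemdelta = as.character(
                                     utils::packageVersion("stemdelta"))),
                   stages = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(e))
    write_manifest()
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # ingest
  st <- tryCatch({
    for (f in inputs) if (!file.exists(f)) {
      stop("missing input file: ", f)
    }
    climate <- read_climate_csv(file.path(input_dir, "climate.csv"))
    widths <- read_width_csv(file.path(input_dir, "widths.csv"))
    cal <- utils::read.csv(file.path(input_dir, "calibration.csv"),
                           stringsAsFactors = FALSE)
    list(climate = climate, widths = widths, cal = cal)
  }, error = function(e) fail("ingest", e))
  manifest$stages$ingest <- list(status = "ok",
                                 n_climate = nrow(st$climate),
                                 n_width = nrow(st$widths))

  # extract
  ex <- tryCatch({
    psi_all <- do.call(rbind, lapply(unique(st$widths$plant_id), function(p) {
      obs <- st$cal[st$cal$plant_id == p, ]
      names(obs)[names(obs) == "psi_bomb_mpa"] <- "psi_bomb"
      names(obs)[names(obs) == "width_um"] <- "width_at_time"
      model <- fit_width_calibration(obs)
      apply_calibration(st$widths[st$widths$plant_id == p, ], model)
    }))
    class(psi_all) <- c("psi_series", "data.frame")
    anchors <- select_predawn_anchors(psi_all, st$climate,
                                      config$extraction)
    records <- build_daily_records(psi_all, anchors, st$climate,
                                   config$extraction)
    write_psi_csv(psi_all, file.path(output_dir, "psi_stem.csv"))
    write_vpd_csv(st$climate, file.path(output_dir, "vpd.csv"))
    write_records_csv(records, file.path(output_dir, "records.csv"))
    list(records = records, anchors = anchors)
  }, error = function(e) fail("extract", e))
  manifest$stages$extract <- list(
    status = "ok", n_records = nrow(ex$records),
    n_anchors = nrow(ex$anchors),
    exclusions = as.list(attr(ex$records, "exclusions")))

  # fit
  fit <- tryCatch(suppressWarnings(fit_posterior(ex$records, config$fit)),
                  error = function(e) fail("fit", e))
  utils::write.csv(summary(fit, pars = dimnames(fit$draws)[[3]]),
                   file.path(output_dir, "posterior_summary.csv"),
                   row.names = FALSE)
  pop <- grep("^u_", dimnames(fit$draws)[[3]], invert = TRUE, value = TRUE)
  flat <- do.call(rbind, lapply(seq_len(dim(fit$draws)[2]), function(ch) {
    data.frame(chain = ch, iteration = seq_len(dim(fit$draws)[1]),
               fit$draws[, ch, pop])
  }))
  utils::write.csv(flat, file.path(output_dir, "draws_population.csv"),
                   row.names = FALSE)
  manifest$stages$fit <- list(status = "ok",
                              max_rhat = max(fit$rhat, na.rm = TRUE),
                              converged = fit$converged)

  # diagnose
  diag <- tryCatch(diagnostics_report(fit, seed = config$seed),
                   error = function(e) fail("diagnose", e))
  jsonlite::write_json(
    list(max_rhat = max(diag$rhat, na.rm = TRUE),
         converged = diag$converged, loo_elpd = diag$loo_elpd,
         loo_se = diag$loo_se, loo_r2 = diag$loo_r2,
         loo_r2_ci = diag$loo_r2_ci, bayes_r2 = diag$bayes_r2,
         bayes_r2_ci = diag$bayes_r2_ci,
         ppc_coverage_95 = diag$ppc_coverage_95),
    file.path(output_dir, "diagnostics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$stages$diagnose <- list(status = "ok")

  # predict-gc
  surf <- tryCatch(gc_surface(posterior_params(fit),
                              vpd_grid = config$vpd_grid,
                              psi_grid = config$psi_grid),
                   error = function(e) fail("predict_gc", e))
  write_gc_csv(surf, file.path(output_dir, "gc_surface.csv"))
  manifest$stages$predict_gc <- list(status = "ok")

  manifest$outputs <- md5_of(file.path(output_dir,
                                       c("records.csv",
                                         "posterior_summary.csv",
                                         "diagnostics.json",
                                         "gc_surface.csv")))
  manifest$converged <- isTRUE(fit$converged)
  write_manifest()
  invisible(manifest)
}
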