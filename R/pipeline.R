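#' Pipeline run configuration
#'
#' Validated configuration for an end-to-end run: how many biopsies to
#' simulate per intestinal location, generator overrides, segmentation
#' training size, detection/threshold settings, and the statistics
#' parameters. Unknown keys (top level or inside the override blocks)
#' are rejected before any work happens.
#'
#' @param n_per_location named integer vector over
#'   `ILEUM`/`RIGHT_COLON`/`LEFT_COLON`.
#' @param gen named list of [gen_params()] overrides applied to every
#'   simulated biopsy (per-biopsy seeds are derived from the run seed).
#' @param n_train_images images simulated for segmenter training.
#' @param rois_per_image labeled ROIs drawn per training image.
#' @param seg named list of [seg_config()] overrides.
#' @param detect named list of [detect_config()] overrides.
#' @param threshold_od `"auto"` (calibrate on the training images'
#'   ground truth) or a positive number.
#' @param hotspot_window manual-emulation window size.
#' @param denominator IELs/100 denominator rule, see [iel_per_100()].
#' @param alpha,exact_cutoff statistics settings.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_per_location = c(ILEUM = 2, RIGHT_COLON = 2,
                                          LEFT_COLON = 2),
                       gen = list(), n_train_images = 3,
                       rois_per_image = 8, seg = list(),
                       detect = list(), threshold_od = "auto",
                       hotspot_window = 100,
                       denominator = "negative",
                       alpha = 0.05, exact_cutoff = 20, ...) {
  dots <- list(...)
  if (length(dots))
    iq_abort(sprintf("unknown config key(s): %s",
                     paste(names(dots), collapse = ", ")))
  cfg <- list(n_per_location = n_per_location, gen = gen,
              n_train_images = n_train_images,
              rois_per_image = rois_per_image, seg = seg,
              detect = detect, threshold_od = threshold_od,
              hotspot_window = hotspot_window,
              denominator = denominator, alpha = alpha,
              exact_cutoff = exact_cutoff)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    iq_abort(sprintf("unknown config key(s): %s",
                     paste(unknown, collapse = ", ")))
  for (blk in list(c("gen", "gen_params"), c("seg", "seg_config"),
                   c("detect", "detect_config"))) {
    bad <- setdiff(names(cfg[[blk[1]]]), names(formals(blk[2])))
    if (length(bad))
      iq_abort(sprintf("unknown key(s) in config$%s: %s", blk[1],
                       paste(bad, collapse = ", ")))
  }
  if (!all(names(cfg$n_per_location) %in% LOCATIONS))
    iq_abort(sprintf("n_per_location names must be among: %s",
                     paste(LOCATIONS, collapse = ", ")))
  if (!(identical(cfg$threshold_od, "auto") ||
        (is.numeric(cfg$threshold_od) && cfg$threshold_od > 0)))
    iq_abort("threshold_od must be \"auto\" or a positive number")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON or YAML
#' @param path file path (`.json`, `.yaml`/`.yml`).
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      iq_abort("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$n_per_location))
    x$n_per_location <- unlist(x$n_per_location)
  do.call(run_config, x)
}

#' Run one stage of the pipeline
#'
#' Stages (in `run_pipeline()` order): `"simulate"`, `"train"`,
#' `"calibrate"`, `"analyze"`, `"stats"`. Each takes the outputs of
#' previous stages through `inputs` and returns its own outputs; results
#' are identical to those inside a full run with the same config + seed.
#'
#' @param name stage name.
#' @param config a [run_config()].
#' @param seed master run seed.
#' @param inputs named list of upstream artifacts (stage-dependent:
#'   `train`/`calibrate` need `$train_biopsies`; `analyze` needs
#'   `$biopsies`, `$model`, `$threshold_od`; `stats` needs `$results`).
#' @return stage outputs (list or tibble).
#' @export
run_stage <- function(name, config, seed = 1, inputs = list()) {
  stopifnot(inherits(config, "run_config"))
  need <- function(key)
    inputs[[key]] %||%
      iq_abort(sprintf("stage '%s' missing upstream input '%s'",
                       name, key))
  switch(
    name,
    simulate = {
      specs <- tidyr::expand_grid(
        location = names(config$n_per_location)) |>
        dplyr::rowwise() |>
        dplyr::reframe(idx = seq_len(config$n_per_location[[.data$location]]),
                       location = .data$location)
      biopsies <- purrr::pmap(specs, function(idx, location) {
        pars <- do.call(gen_params, c(
          config$gen,
          list(seed = spawn_seed(seed, paste0("sim_", location, "_", idx)))))
        list(biopsy = simulate_biopsy(pars),
             biopsy_id = sprintf("%s_%02d", tolower(location), idx),
             location = location)
      })
      biopsies
    },
    train = {
      tb <- need("train_biopsies")
      rois <- do.call(c, purrr::imap(tb, function(b, i)
        sample_rois(b, n_rois = config$rois_per_image,
                    seed = spawn_seed(seed, paste0("roi_", i)))))
      cfg <- do.call(seg_config, config$seg)
      train_segmenter(extract_training_set(rois, cfg), cfg,
                      seed = spawn_seed(seed, "train"))
    },
    calibrate = {
      if (is.numeric(config$threshold_od)) return(config$threshold_od)
      tb <- need("train_biopsies")
      dcfg <- do.call(detect_config, config$detect)
      labeled <- purrr::map_dfr(tb, function(b) {
        profile <- stain_profile(b$image$stain_profile_id)
        conc <- unmix_stains(rgb_to_od(b$image$pixels, profile$I0),
                             profile)
        measure_dab(b$cells, conc[, , "dab"], radius_px = dcfg$radius_px)
      })
      calibrate_threshold(labeled)$threshold_od
    },
    analyze = {
      biopsies <- need("biopsies")
      model <- need("model")
      thr <- need("threshold_od")
      dcfg <- do.call(detect_config, config$detect)
      purrr::map_dfr(biopsies, function(e) {
        an <- analyze_biopsy(e$biopsy$image, model, thr, dcfg,
                             biopsy_id = e$biopsy_id,
                             location = e$location)
        surf <- order_surface_cells(an$cells, an$mask)
        hs <- hotspot_count(surf, config$hotspot_window)
        dplyr::mutate(an$quant,
                      hotspot_per_100 = hs$hotspot_per_100,
                      hotspot_fallback = hs$fallback)
      })
    },
    stats = {
      res <- need("results")
      summaries <- res |>
        dplyr::group_by(.data$location) |>
        dplyr::reframe(summarize_values(.data$surface_iel_per_100))
      tests <- NULL
      wide <- tidyr::pivot_wider(
        dplyr::mutate(res, rep = sub("^[a-z_]+_", "", .data$biopsy_id)),
        id_cols = "rep", names_from = "location",
        values_from = "surface_iel_per_100")
      if (all(c("RIGHT_COLON", "LEFT_COLON") %in% names(wide)) &&
          sum(stats::complete.cases(
            wide[, c("RIGHT_COLON", "LEFT_COLON")])) >= 2 &&
          stats::sd(wide$RIGHT_COLON - wide$LEFT_COLON) > 0) {
        tests <- dplyr::mutate(
          paired_t(wide, .data$RIGHT_COLON, .data$LEFT_COLON),
          comparison = "surface right vs left", .before = 1)
      }
      list(summaries = summaries, tests = tests)
    },
    iq_abort(sprintf(
      "unknown stage '%s' (stages: simulate, train, calibrate, analyze, stats)",
      name)))
}

#' Run the full pipeline end to end
#'
#' simulate -> train -> calibrate -> analyze -> stats, writing the
#' per-biopsy results CSV, the statistics report and a run manifest
#' (file hashes, seeds, timestamps) under `out_dir`. Deterministic for a
#' given config + seed: a rerun reproduces identical result files.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param seed master run seed; all stage seeds derive from it.
#' @return list of class `pipeline_run`: `results`, `stats`, `manifest`,
#'   `threshold_od`, `model`.
#' @export
run_pipeline <- function(config, out_dir, seed = 1) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, inputs = list()) {
    t0 <- Sys.time()
    out <- tryCatch(run_stage(name, config, seed, inputs),
                    error = function(e) iq_abort(sprintf(
                      "stage '%s' failed: %s", name,
                      conditionMessage(e))))
    message(sprintf("[ielquant] stage %-9s %6.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    out
  }
  train_pars <- lapply(seq_len(config$n_train_images), function(i)
    do.call(gen_params,
            c(config$gen, list(seed = spawn_seed(seed, paste0("train_sim_", i))))))
  train_biopsies <- lapply(train_pars, simulate_biopsy)

  biopsies <- stage("simulate")
  model <- stage("train", list(train_biopsies = train_biopsies))
  thr <- stage("calibrate", list(train_biopsies = train_biopsies))
  results <- stage("analyze", list(biopsies = biopsies, model = model,
                                   threshold_od = thr))
  stats_out <- stage("stats", list(results = results))

  quant_cols <- c("biopsy_id", "location", "surface_pos", "surface_neg",
                  "surface_iel_per_100", "crypt_pos", "crypt_neg",
                  "crypt_iel_per_100", "lp_pos_count", "lp_area_mm2",
                  "lp_density_per_mm2", "band_thickness_um",
                  "lymphocytic_call", "collagenous_call")
  res_path <- file.path(out_dir, "results.csv")
  utils::write.csv(results[, quant_cols], res_path, row.names = FALSE)
  hot_path <- file.path(out_dir, "hotspots.csv")
  utils::write.csv(results[, c("biopsy_id", "hotspot_per_100",
                               "hotspot_fallback")],
                   hot_path, row.names = FALSE)
  sum_path <- file.path(out_dir, "summary.csv")
  utils::write.csv(stats_out$summaries, sum_path, row.names = FALSE)
  files <- c(res_path, hot_path, sum_path)
  if (!is.null(stats_out$tests)) {
    tst_path <- file.path(out_dir, "tests.csv")
    utils::write.csv(stats_out$tests, tst_path, row.names = FALSE)
    files <- c(files, tst_path)
  }
  manifest <- list(
    version = as.character(utils::packageVersion("ielquant")),
    seed = seed, threshold_od = thr,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(results = results, stats = stats_out,
                 manifest = manifest, threshold_od = thr, model = model),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d biopsies, threshold_od %.3f\n",
              nrow(x$results), x$threshold_od))
  print(x$results)
  invisible(x)
}
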