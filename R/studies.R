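#' Parameter-recovery study for the full analysis pipeline
#'
#' Simulates biopsies over a grid of surface IEL rates and lamina
#' propria CD3+ densities, runs the complete pipeline (segment ->
#' detect -> classify -> quantify) on each, and compares the recovered
#' metrics with the generator's realised ground truth. One segmentation
#' model is trained (and one positivity threshold calibrated) on
#' separate training images and reused across all arms, mirroring how a
#' single trained application is applied to a cohort.
#'
#' Recovery is scored arm-wise on seed-averaged values: the relative
#' error of `mean(estimate)` against `mean(realised truth)` over the
#' seeds of an arm, which isolates pipeline error from the generator's
#' own sampling noise.
#'
#' @param rates surface IEL rates (per 100) to probe; the lamina
#'   propria density stays at its default in these arms.
#' @param densities lamina propria CD3+ densities (per mm^2); the
#'   default-density arm is shared with the rate arms.
#' @param n_seeds simulated biopsies per arm.
#' @param seed master seed.
#' @param n_train training images for the shared segmenter.
#' @param gen named list of [gen_params()] overrides for all arms.
#' @return list with `runs` (one row per simulated biopsy: arm, seed,
#'   estimated and realised metrics), `rate_summary` and
#'   `density_summary` (per-arm mean estimate, mean truth, relative
#'   error), `threshold_od`.
#' @export
iel_recovery_study <- function(rates = c(2, 5, 10, 20),
                               densities = c(100, 300, 1000),
                               n_seeds = 20, seed = 1, n_train = 4,
                               gen = list()) {
  base_gen <- function(...) do.call(gen_params, utils::modifyList(gen, list(...)))
  train_biopsies <- lapply(seq_len(n_train), function(i)
    simulate_biopsy(base_gen(seed = spawn_seed(seed, paste0("rec_train_", i)))))
  rois <- do.call(c, lapply(seq_along(train_biopsies), function(i)
    sample_rois(train_biopsies[[i]], n_rois = 8,
                seed = spawn_seed(seed, paste0("rec_roi_", i)))))
  cfg <- seg_config()
  model <- train_segmenter(extract_training_set(rois, cfg), cfg,
                           seed = spawn_seed(seed, "rec_train"))
  dcfg <- detect_config()
  labeled <- purrr::map_dfr(train_biopsies, function(b) {
    profile <- stain_profile(b$image$stain_profile_id)
    conc <- unmix_stains(rgb_to_od(b$image$pixels, profile$I0), profile)
    measure_dab(b$cells, conc[, , "dab"], radius_px = dcfg$radius_px)
  })
  thr <- calibrate_threshold(labeled)$threshold_od

  default_density <- base_gen()$lp_cd3_density
  arms <- dplyr::bind_rows(
    tibble(arm = paste0("rate_", rates), rate = rates,
           density = default_density),
    tibble(arm = paste0("density_", setdiff(densities, default_density)),
           rate = base_gen()$surface_iel_rate,
           density = setdiff(densities, default_density)))

  runs <- purrr::pmap_dfr(arms, function(arm, rate, density) {
    purrr::map_dfr(seq_len(n_seeds), function(k) {
      pars <- base_gen(surface_iel_rate = rate, lp_cd3_density = density,
                       seed = spawn_seed(seed, paste0(arm, "_", k)))
      b <- simulate_biopsy(pars)
      an <- analyze_biopsy(b$image, model, thr, dcfg)
      tr_s <- iel_per_100(b$cells, "SURFACE", class_col = "true_class")
      tr_lp <- lp_density(b$cells, b$mask, pars$um_per_px,
                          class_col = "true_class")
      tibble(arm = arm, rate = rate, density = density, k = k,
             est_surface = an$quant$surface_iel_per_100,
             truth_surface = tr_s$iel_per_100,
             est_lp = an$quant$lp_density_per_mm2,
             truth_lp = tr_lp$lp_density_per_mm2)
    })
  })

  rate_summary <- runs |>
    dplyr::group_by(.data$rate) |>
    dplyr::summarise(mean_est = mean(.data$est_surface),
                     mean_truth = mean(.data$truth_surface),
                     rel_err = abs(.data$mean_est - .data$mean_truth) /
                       .data$mean_truth, .groups = "drop")
  density_summary <- runs |>
    dplyr::group_by(.data$density) |>
    dplyr::summarise(mean_est = mean(.data$est_lp),
                     mean_truth = mean(.data$truth_lp),
                     rel_err = abs(.data$mean_est - .data$mean_truth) /
                       .data$mean_truth, .groups = "drop")
  list(runs = runs, rate_summary = rate_summary,
       density_summary = density_summary, threshold_od = thr)
}

#' Exact count recovery on a noise-free fixture
#'
#' With render noise at zero, detection, positivity calling and
#' compartment assignment (against the ground-truth mask) must
#' reproduce the per-compartment positive and negative counts exactly.
#'
#' @param seed master seed.
#' @param gen named list of [gen_params()] overrides.
#' @return list with `pred` and `truth` count tables and
#'   `max_discrepancy` (largest absolute per-cell-class count
#'   difference; 0 on success).
#' @export
noise_free_exact_check <- function(seed = 1, gen = list()) {
  pars <- do.call(gen_params,
                  utils::modifyList(gen, list(noise_sd = 0, seed = seed)))
  b <- simulate_biopsy(pars)
  profile <- stain_profile(b$image$stain_profile_id)
  od <- rgb_to_od(b$image$pixels, profile$I0)
  cells <- detect_nuclei(od[, , 1] + od[, , 2] + od[, , 3])
  conc <- unmix_stains(od, profile)
  cells <- classify_positivity(cells, conc[, , "dab"], threshold_od = 0.3)
  cells <- assign_compartment(cells, b$mask)
  lv_comp <- c("SURFACE", "CRYPT", "LAMINA_PROPRIA")
  pred <- table(factor(cells$compartment, lv_comp),
                factor(cells$predicted_class, CELL_CLASSES))
  truth <- table(factor(b$cells$compartment, lv_comp),
                 factor(b$cells$true_class, CELL_CLASSES))
  list(pred = pred, truth = truth,
       max_discrepancy = max(abs(pred - truth)))
}

#' Segmentation hold-out accuracy study
#'
#' Trains the four-class segmenter on labeled ROIs from `n_train`
#' synthetic images and scores full-frame pixel accuracy on `n_val`
#' unseen images (the 12-train / 22-validation design at fixture
#' scale).
#'
#' @param n_train,n_val number of training / held-out images.
#' @param seed master seed.
#' @param gen named list of [gen_params()] overrides (fixture-scale
#'   images by default).
#' @return list with `accuracy` (mean held-out pixel accuracy),
#'   `per_image` tibble, `per_class` (pooled confusion-derived recall),
#'   and the trained `model`.
#' @export
segmentation_floor_study <- function(n_train = 12, n_val = 22, seed = 1,
                                     gen = list(image_height_px = 384,
                                                image_width_px = 512,
                                                n_crypts = 3)) {
  base_gen <- function(...) do.call(gen_params, utils::modifyList(gen, list(...)))
  train_b <- lapply(seq_len(n_train), function(i)
    simulate_biopsy(base_gen(seed = spawn_seed(seed, paste0("segf_tr_", i)))))
  rois <- do.call(c, lapply(seq_along(train_b), function(i)
    sample_rois(train_b[[i]], n_rois = 8,
                seed = spawn_seed(seed, paste0("segf_roi_", i)))))
  cfg <- seg_config()
  model <- train_segmenter(extract_training_set(rois, cfg), cfg,
                           seed = spawn_seed(seed, "segf_train"))
  conf_sum <- matrix(0, 4, 4)
  per_image <- purrr::map_dfr(seq_len(n_val), function(i) {
    vb <- simulate_biopsy(base_gen(
      seed = spawn_seed(seed, paste0("segf_val_", i))))
    ev <- evaluate_segmentation(segment_image(model, vb$image), vb$mask)
    conf_sum <<- conf_sum + unclass(ev$confusion)
    tibble(image = i, accuracy = ev$accuracy)
  })
  per_class <- tibble(class = names(COMPARTMENT_LEVELS),
                      recall = diag(conf_sum) / rowSums(conf_sum))
  list(accuracy = sum(diag(conf_sum)) / sum(conf_sum),
       per_image = per_image, per_class = per_class, model = model)
}

#' Band-thickness recovery across stain profiles
#'
#' Renders the same tissue (fixed geometry seed per thickness) under
#' connective-tissue stains and HE, and measures the subepithelial band
#' from the thresholded stain-concentration evidence. Connective stains
#' should recover the generated thickness; HE should see nothing.
#'
#' @param thicknesses band thicknesses in um.
#' @param stains connective-stain profile ids to test.
#' @param seed master seed.
#' @param gen named list of [gen_params()] overrides.
#' @return tibble: `thickness_um`, `stain`, `measured_um`.
#' @export
band_recovery_study <- function(thicknesses = c(1, 2, 3),
                                stains = c("vg", "mt", "was"),
                                seed = 1,
                                gen = list(image_height_px = 320,
                                           image_width_px = 512,
                                           n_crypts = 2)) {
  purrr::map_dfr(thicknesses, function(tu) {
    pars <- do.call(gen_params, utils::modifyList(
      gen, list(band_thickness_um = tu,
                seed = spawn_seed(seed, paste0("band_", tu)))))
    geometry <- generate_tissue_geometry(pars)
    cells <- place_nuclei(geometry, pars)
    purrr::map_dfr(c(stains, "he"), function(st) {
      img <- render_biopsy(geometry, cells, st)
      ev <- band_evidence_from_image(img)
      bt <- band_thickness(ev, geometry$mask, pars$um_per_px)
      tibble(thickness_um = tu, stain = st,
             measured_um = bt$band_thickness_um)
    })
  })
}

#' Hotspot-vs-global ordering study
#'
#' Generates random ordered epithelial cell sequences (length, positive
#' count, arrangement and window size all randomised) and checks the
#' fraction in which the hotspot window count is at least the global
#' whole-compartment count.
#'
#' @param n_config number of random configurations.
#' @param seed master seed.
#' @return list with `fraction_ge` and the per-configuration tibble.
#' @export
hotspot_ordering_study <- function(n_config = 500, seed = 1) {
  runs <- with_seed(spawn_seed(seed, "hotspot"), {
    purrr::map_dfr(seq_len(n_config), function(i) {
      n <- sample(30:400, 1)
      p <- sample(0:max(1, round(n * 0.4)), 1)
      cls <- sample(rep(c("CD3_POS", "CD3_NEG"), c(p, n)))
      w <- sample(10:max(10, n), 1)
      cells <- tibble(true_class = cls)
      hs <- hotspot_count(cells, window = w)
      tibble(i = i, n_neg = n, n_pos = p, window = w,
             hotspot = hs$hotspot_per_100, global = hs$global_per_100,
             fallback = hs$fallback)
    })
  })
  list(fraction_ge = mean(runs$hotspot >= runs$global), runs = runs)
}
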