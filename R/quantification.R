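#' IELs per 100 epithelial cells in an epithelial compartment
#'
#' The digital IEL metric: `100 * n_CD3pos / n_CD3neg` within the given
#' compartment, the CD3-negative epithelial nuclei standing in for the
#' "per 100 epithelial cells" denominator (the only countable
#' epithelial-cell proxy on a CD3 stain). Set `denominator = "all"` to
#' include CD3+ cells in the denominator instead.
#'
#' @param cells cell table with a `compartment` column and a class
#'   column (`predicted_class` if present, else `true_class`).
#' @param compartment `"SURFACE"` or `"CRYPT"`.
#' @param class_col class column name; default picks `predicted_class`
#'   when available.
#' @param denominator `"negative"` (default) or `"all"`.
#' @return one-row tibble: `compartment`, `pos`, `neg`, `iel_per_100`.
#' @examples
#' cells <- tibble::tibble(
#'   compartment = "SURFACE",
#'   true_class = rep(c("CD3_POS", "CD3_NEG"), c(5, 100)))
#' iel_per_100(cells, "SURFACE")$iel_per_100  # 5
#' @export
iel_per_100 <- function(cells, compartment = c("SURFACE", "CRYPT"),
                        class_col = NULL,
                        denominator = c("negative", "all")) {
  compartment <- match.arg(compartment)
  denominator <- match.arg(denominator)
  class_col <- class_col %||%
    (if ("predicted_class" %in% names(cells)) "predicted_class"
     else "true_class")
  cl <- cells[[class_col]][cells$compartment == compartment]
  pos <- sum(cl == "CD3_POS")
  neg <- sum(cl == "CD3_NEG")
  den <- if (denominator == "negative") neg else pos + neg
  if (den == 0)
    iq_abort(sprintf(
      "IELs/100 undefined: no %s epithelial cells in compartment %s",
      if (denominator == "negative") "CD3-negative" else "", compartment))
  tibble(compartment = compartment, pos = pos, neg = neg,
         iel_per_100 = 100 * pos / den)
}

#' Lamina propria CD3+ density per square millimetre
#'
#' Density = CD3+ cells assigned to the lamina propria divided by the
#' lamina propria area, `area_mm2 = n_label3_pixels * um_per_px^2 / 1e6`.
#'
#' @param cells cell table with `compartment` and a class column.
#' @param mask compartment mask (label 3 = lamina propria).
#' @param um_per_px calibration (> 0).
#' @inheritParams iel_per_100
#' @return one-row tibble: `lp_pos_count`, `lp_area_mm2`,
#'   `lp_density_per_mm2`.
#' @export
lp_density <- function(cells, mask, um_per_px, class_col = NULL) {
  assert_scalar_num(um_per_px, "um_per_px", 0, strict = TRUE)
  class_col <- class_col %||%
    (if ("predicted_class" %in% names(cells)) "predicted_class"
     else "true_class")
  lp_px <- sum(mask == 3L)
  if (lp_px == 0) iq_abort("no lamina propria pixels in mask")
  area <- lp_px * um_per_px^2 / 1e6
  n <- sum(cells$compartment == "LAMINA_PROPRIA" &
             cells[[class_col]] == "CD3_POS")
  tibble(lp_pos_count = n, lp_area_mm2 = area,
         lp_density_per_mm2 = n / area)
}

#' Order surface-epithelium cells along the surface path
#'
#' Builds the surface skeleton (per-column mean row of surface pixels)
#' and orders surface cells by their projection onto it — for the
#' near-horizontal mucosal strips modeled here this is column order,
#' ties broken by row.
#'
#' @param cells cell table with `row_px`, `col_px`, `compartment`.
#' @param mask compartment mask (label 1 = surface epithelium).
#' @return the surface cells, ordered, with an `order_idx` column.
#' @export
order_surface_cells <- function(cells, mask) {
  surf <- cells[cells$compartment == "SURFACE", , drop = FALSE]
  has_surface <- colSums(mask == 1L) > 0
  if (!any(has_surface)) iq_abort("mask contains no surface epithelium")
  surf <- surf[order(surf$col_px, surf$row_px), , drop = FALSE]
  if (nrow(surf)) surf$order_idx <- seq_len(nrow(surf))
  surf
}

#' Hotspot IEL count: densest window of W epithelial cells
#'
#' Emulates manual hotspot counting: slide a window of exactly `window`
#' consecutive CD3-negative epithelial cells along the ordered surface
#' path and compute IELs per 100 within each (positives lying between
#' the window's boundary negatives, inclusive of its outer gaps); the
#' whole compartment counts as an admissible window too, so the hotspot
#' value can never fall below the global per-100. With fewer negatives
#' than `window` the global value is returned flagged as a fallback.
#'
#' @param cells ordered surface cells (see [order_surface_cells()]); row
#'   order is the arc-length order.
#' @param window number of consecutive CD3- epithelial cells per window
#'   (>= 10).
#' @param class_col see [iel_per_100()].
#' @return one-row tibble: `hotspot_per_100`, `global_per_100`,
#'   `window`, `n_neg`, `fallback`.
#' @export
hotspot_count <- function(cells, window = 100, class_col = NULL) {
  if (window < 10) iq_abort("window must be >= 10 epithelial cells")
  class_col <- class_col %||%
    (if ("predicted_class" %in% names(cells)) "predicted_class"
     else "true_class")
  cl <- cells[[class_col]]
  is_neg <- cl == "CD3_NEG"
  N <- sum(is_neg); P <- sum(cl == "CD3_POS")
  if (N == 0) iq_abort("no CD3-negative epithelial cells")
  global <- 100 * P / N
  if (N < window)
    return(tibble(hotspot_per_100 = global, global_per_100 = global,
                  window = window, n_neg = N, fallback = TRUE))
  # gap g_i = positives between negative i and i+1 (g_0 before the first,
  # g_N after the last); window j spans gaps j-1 .. j+W-1
  neg_pos <- which(is_neg)
  pos_pos <- which(!is_neg)
  g <- tabulate(findInterval(pos_pos, neg_pos) + 1L, N + 1L)
  cs <- c(0, cumsum(g))                       # cs[k+1] = sum g_0..g_{k-1}
  j <- seq_len(N - window + 1L)
  wins <- cs[pmin(j + window, N + 1L) + 1L] - cs[j - 1L + 1L]
  hot <- max(100 * wins / window, global)
  tibble(hotspot_per_100 = hot, global_per_100 = global,
         window = window, n_neg = N, fallback = FALSE)
}

#' Subepithelial band thickness in micrometres
#'
#' Samples the vertical run length of band evidence directly beneath the
#' bottom-most surface-epithelium pixel at every `sample_every`-th
#' column; the representative thickness is the median of the per-column
#' samples (in um), rounded half-up to an integer. Returns 0 um when no
#' band evidence exists.
#'
#' @param band_evidence logical matrix: ground-truth band mask or a
#'   thresholded connective-stain concentration map (see
#'   [band_evidence_from_image()]).
#' @param mask compartment mask (label 1 = surface epithelium) or a
#'   logical surface mask.
#' @param um_per_px calibration (> 0).
#' @param sample_every column sampling stride.
#' @return one-row tibble: `band_thickness_um` (integer), `n_samples`,
#'   and `samples_um` (list column of the per-column samples).
#' @export
band_thickness <- function(band_evidence, mask, um_per_px,
                           sample_every = 4) {
  assert_scalar_num(um_per_px, "um_per_px", 0, strict = TRUE)
  surface <- if (is.logical(mask)) mask else mask == 1L
  if (!any(surface)) iq_abort("mask contains no surface epithelium")
  if (!any(band_evidence))
    return(tibble(band_thickness_um = 0L, n_samples = 0L,
                  samples_um = list(numeric(0))))
  H <- nrow(surface)
  cols <- seq(1, ncol(surface), by = sample_every)
  cols <- cols[colSums(surface[, cols, drop = FALSE]) > 0]
  samples <- vapply(cols, function(cc) {
    rb <- max(which(surface[, cc]))
    run <- 0L
    r <- rb + 1L
    while (r <= H && band_evidence[r, cc]) { run <- run + 1L; r <- r + 1L }
    run * um_per_px
  }, numeric(1))
  tibble(band_thickness_um = as.integer(round_half_up(median(samples))),
         n_samples = length(samples), samples_um = list(samples))
}

#' Band evidence map from a rendered image
#'
#' Thresholds the connective-stain (non-hematoxylin) concentration from
#' colour deconvolution. Under an HE profile the eosin concentration of
#' the band matches the surrounding stroma and stays below the
#' threshold, so the band is invisible — mirroring its behaviour on real
#' HE sections.
#'
#' @param image a `calibrated_image`.
#' @param profile a [stain_profile()]; defaults to the image's profile.
#' @param threshold concentration threshold (default 0.5).
#' @return logical `H x W` evidence matrix.
#' @export
band_evidence_from_image <- function(image, profile = NULL,
                                     threshold = 0.5) {
  stopifnot(inherits(image, "calibrated_image"))
  profile <- profile %||% stain_profile(image$stain_profile_id)
  conc <- unmix_stains(rgb_to_od(image$pixels, profile$I0), profile)
  idx <- which(profile$stain_names != "hematoxylin")[1]
  if (is.na(idx)) iq_abort("profile has no non-hematoxylin stain")
  conc[, , idx] > threshold
}

#' Classify against the microscopic colitis criteria
#'
#' Lymphocytic axis: `LC` when surface IELs per 100 exceed 20 (strict),
#' `LCi` for 10-20 inclusive, `NORMAL` below. Collagenous axis: `CC`
#' when the band exceeds 10 um (strict), `CCi` for 5-10 um inclusive,
#' `NORMAL` below. Exact boundary values land in the incomplete
#' category.
#'
#' @param surface_iel_per_100 non-negative numeric vector.
#' @param band_thickness_um non-negative numeric vector.
#' @return tibble with columns `lymphocytic` and `collagenous`.
#' @examples
#' classify_mc(25, 1)    # LC, NORMAL
#' classify_mc(15, 7)    # LCi, CCi
#' @export
classify_mc <- function(surface_iel_per_100, band_thickness_um) {
  if (any(!is.finite(surface_iel_per_100)) ||
      any(!is.finite(band_thickness_um)) ||
      any(surface_iel_per_100 < 0) || any(band_thickness_um < 0))
    iq_abort("inputs must be finite and non-negative")
  lymph <- dplyr::case_when(
    surface_iel_per_100 > 20 ~ "LC",
    surface_iel_per_100 >= 10 ~ "LCi",
    TRUE ~ "NORMAL")
  coll <- dplyr::case_when(
    band_thickness_um > 10 ~ "CC",
    band_thickness_um >= 5 ~ "CCi",
    TRUE ~ "NORMAL")
  tibble(lymphocytic = lymph, collagenous = coll)
}

#' Per-biopsy quantification record
#'
#' Assembles the full per-biopsy metric row: surface and crypt IELs per
#' 100 epithelial cells (with the underlying counts), lamina propria
#' CD3+ density, band thickness, and the diagnostic calls. Crypt metrics
#' are `NA` when the biopsy contains no CD3-negative crypt cells.
#'
#' @param cells classified, compartment-assigned cell table.
#' @param mask compartment mask.
#' @param band_evidence logical band evidence matrix (or `NULL` for
#'   no band assessment, yielding 0 um).
#' @param um_per_px calibration.
#' @param biopsy_id identifier.
#' @param location one of `"ILEUM"`, `"RIGHT_COLON"`, `"LEFT_COLON"`
#'   (metadata only; no metric depends on it).
#' @inheritParams iel_per_100
#' @return one-row tibble with the per-biopsy results schema.
#' @export
quantify_biopsy <- function(cells, mask, band_evidence = NULL,
                            um_per_px, biopsy_id = "biopsy",
                            location = "RIGHT_COLON", class_col = NULL,
                            denominator = c("negative", "all")) {
  denominator <- match.arg(denominator)
  location <- match.arg(location, LOCATIONS)
  surf <- iel_per_100(cells, "SURFACE", class_col, denominator)
  crypt <- tryCatch(iel_per_100(cells, "CRYPT", class_col, denominator),
                    error = function(e) NULL)
  lp <- lp_density(cells, mask, um_per_px, class_col)
  band <- if (is.null(band_evidence))
    tibble(band_thickness_um = 0L) else
    band_thickness(band_evidence, mask, um_per_px)
  call <- classify_mc(surf$iel_per_100, band$band_thickness_um)
  tibble(
    biopsy_id = biopsy_id, location = location,
    surface_pos = surf$pos, surface_neg = surf$neg,
    surface_iel_per_100 = surf$iel_per_100,
    crypt_pos = if (is.null(crypt)) NA_integer_ else crypt$pos,
    crypt_neg = if (is.null(crypt)) NA_integer_ else crypt$neg,
    crypt_iel_per_100 = if (is.null(crypt)) NA_real_ else
      crypt$iel_per_100,
    lp_pos_count = lp$lp_pos_count, lp_area_mm2 = lp$lp_area_mm2,
    lp_density_per_mm2 = lp$lp_density_per_mm2,
    band_thickness_um = band$band_thickness_um,
    lymphocytic_call = call$lymphocytic,
    collagenous_call = call$collagenous)
}

#' Run the full analysis pipeline on a calibrated image
#'
#' segment -> colour-deconvolve -> detect nuclei -> call positivity ->
#' assign compartments -> quantify. The segmentation model must have
#' been trained on images rendered with the same stain profile; a
#' mismatch warns (and proceeds) per the `on_profile_mismatch` flag.
#'
#' @param image a `calibrated_image` (CD3 IHC render).
#' @param model a trained `mucosa_segmenter`.
#' @param threshold_od DAB positivity threshold (see
#'   [calibrate_threshold()]).
#' @param detect a [detect_config()].
#' @param band_evidence optional band evidence matrix (e.g. from a
#'   connective-stain render of the same block).
#' @param biopsy_id,location passed to [quantify_biopsy()].
#' @return list of class `biopsy_analysis`: `cells`, `mask`, `quant`
#'   (one-row tibble).
#' @export
analyze_biopsy <- function(image, model, threshold_od,
                           detect = detect_config(),
                           band_evidence = NULL,
                           biopsy_id = "biopsy",
                           location = "RIGHT_COLON") {
  stopifnot(inherits(image, "calibrated_image"))
  profile <- stain_profile(image$stain_profile_id)
  od <- rgb_to_od(image$pixels, profile$I0)
  mask <- segment_image(model, image)
  cells <- detect_nuclei(od[, , 1] + od[, , 2] + od[, , 3], detect)
  conc <- unmix_stains(od, profile)
  dab_idx <- match("dab", profile$stain_names)
  if (is.na(dab_idx))
    iq_abort("positivity calling requires a DAB-containing profile (ihc_cd3)")
  cells <- classify_positivity(cells, conc[, , dab_idx], threshold_od,
                               radius_px = detect$radius_px)
  cells <- assign_compartment(cells, mask)
  quant <- quantify_biopsy(cells, mask, band_evidence, image$um_per_px,
                           biopsy_id = biopsy_id, location = location)
  structure(list(cells = cells, mask = mask, quant = quant),
            class = "biopsy_analysis")
}

#' @export
print.biopsy_analysis <- function(x, ...) {
  cat("<biopsy_analysis>\n")
  print(x$quant)
  invisible(x)
}
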