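#' Detection configuration
#'
#' @param smooth_sigma Gaussian smoothing sigma (px) applied to the total
#'   OD before thresholding.
#' @param threshold total-OD threshold separating nuclei from background
#'   and counterstain.
#' @param min_area_px,max_area_px retained component area range.
#' @param watershed_tolerance,watershed_ext distance-transform watershed
#'   parameters used to split touching nuclei.
#' @param radius_px nucleus-statistic radius: positivity is called on the
#'   mean DAB signal over a disc of `radius_px` around the centroid
#'   (nucleus disc + 1-px halo, matching the renderer's DAB pattern).
#' @return list of class `detect_config`.
#' @export
detect_config <- function(smooth_sigma = 1, threshold = 0.45,
                          min_area_px = 8, max_area_px = 500,
                          watershed_tolerance = 1, watershed_ext = 1,
                          radius_px = 3) {
  structure(list(smooth_sigma = smooth_sigma, threshold = threshold,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 watershed_tolerance = watershed_tolerance,
                 watershed_ext = watershed_ext, radius_px = radius_px),
            class = "detect_config")
}

#' Total optical density of an image
#'
#' Sum of the per-channel OD — the generic "stained at all" signal used
#' by the nucleus detector.
#'
#' @param image a `calibrated_image` or `H x W x 3` intensity array.
#' @param I0 background intensity (taken from the image if calibrated).
#' @return `H x W` numeric matrix.
#' @export
total_od <- function(image, I0 = NULL) {
  if (inherits(image, "calibrated_image")) {
    I0 <- I0 %||% image$I0
    image <- image$pixels
  }
  od <- rgb_to_od(image, I0 %||% c(1, 1, 1))
  od[, , 1] + od[, , 2] + od[, , 3]
}

#' Detect nuclei in a total-OD image
#'
#' Deterministic detector: Gaussian-smooth the total OD, threshold,
#' split touching nuclei by distance-transform watershed, and filter
#' components by area. Centroids are intensity-weighted.
#'
#' @param od `H x W` total-OD matrix (see [total_od()]).
#' @param config a [detect_config()].
#' @return tibble with `cell_id`, `row_px`, `col_px`, `area_px`,
#'   `mean_total_od`; zero rows on a blank image.
#' @export
detect_nuclei <- function(od, config = detect_config()) {
  stopifnot(is.matrix(od))
  if (any(!is.finite(od))) iq_abort("od must be finite")
  empty <- tibble(cell_id = integer(), row_px = numeric(),
                  col_px = numeric(), area_px = integer(),
                  mean_total_od = numeric())
  sm <- if (config$smooth_sigma > 0)
    gauss_blur(od, config$smooth_sigma) else od
  bw <- sm > config$threshold
  if (!any(bw)) return(empty)
  dm <- EBImage::distmap(EBImage::Image(bw * 1))
  labels <- EBImage::imageData(EBImage::watershed(
    dm, tolerance = config$watershed_tolerance, ext = config$watershed_ext))
  idx <- which(labels > 0)
  if (!length(idx)) return(empty)
  lab <- labels[idx]
  H <- nrow(od)
  rr <- (idx - 1) %% H + 1
  cc <- (idx - 1) %/% H + 1
  w <- od[idx]
  area <- as.integer(rowsum(rep(1, length(lab)), lab))
  sw <- unname(rowsum(w, lab)[, 1])
  rbar <- unname(rowsum(w * rr, lab)[, 1]) / sw
  cbar <- unname(rowsum(w * cc, lab)[, 1]) / sw
  keep <- area >= config$min_area_px & area <= config$max_area_px
  out <- tibble(row_px = rbar[keep], col_px = cbar[keep],
                area_px = area[keep],
                mean_total_od = (sw / area)[keep])
  out <- out[order(out$col_px, out$row_px), ]
  out$cell_id <- seq_len(nrow(out))
  out[, c("cell_id", "row_px", "col_px", "area_px", "mean_total_od")]
}

# separable Gaussian blur with replicated boundary
gauss_blur <- function(m, sigma) {
  r <- as.integer(ceiling(2.5 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pass <- function(x) {
    xp <- rbind(x[rep(1, r), , drop = FALSE], x,
                x[rep(nrow(x), r), , drop = FALSE])
    out <- stats::filter(xp, k, sides = 2)
    matrix(out[(r + 1):(r + nrow(x)), ], nrow(x), ncol(x))
  }
  t(pass(t(pass(m))))
}

#' Call CD3 positivity from the DAB concentration map
#'
#' A cell is `CD3_POS` iff its mean DAB signal over the nucleus disc plus
#' 1-px halo (`config radius_px`) strictly exceeds `threshold_od`; a mean
#' exactly at the threshold is `CD3_NEG`.
#'
#' @param cells tibble with `row_px`, `col_px` (e.g. from
#'   [detect_nuclei()]).
#' @param dab_map `H x W` DAB concentration matrix from [unmix_stains()].
#' @param threshold_od positivity threshold (> 0), e.g. from
#'   [calibrate_threshold()].
#' @param radius_px statistic disc radius (default 3 = nucleus + halo at
#'   0.5 um/px).
#' @return `cells` with added `mean_dab_od` and `predicted_class`.
#' @export
classify_positivity <- function(cells, dab_map, threshold_od,
                                radius_px = 3) {
  assert_scalar_num(threshold_od, "threshold_od", 0, strict = TRUE)
  cells$mean_dab_od <- mean_disc_signal(cells, dab_map, radius_px)
  cells$predicted_class <- ifelse(cells$mean_dab_od > threshold_od,
                                  "CD3_POS", "CD3_NEG")
  cells
}

# mean of `map` over a disc of radius r around each cell centre
mean_disc_signal <- function(cells, map, radius_px) {
  H <- nrow(map); W <- ncol(map)
  if (nrow(cells) == 0) return(numeric(0))
  if (any(round(cells$row_px) < 1 | round(cells$row_px) > H |
          round(cells$col_px) < 1 | round(cells$col_px) > W))
    iq_abort("cell centroid outside the map bounds")
  off <- disc_offsets(radius_px)
  n <- nrow(cells); K <- nrow(off)
  rr <- rep(as.integer(round(cells$row_px)), each = K) + off$dr
  cc <- rep(as.integer(round(cells$col_px)), each = K) + off$dc
  inb <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  v <- numeric(n * K)
  v[inb] <- map[rr[inb] + (cc[inb] - 1) * H]
  colMeans(matrix(v * inb, K, n)) * K /
    colSums(matrix(as.numeric(inb), K, n))
}

#' Calibrate the CD3 positivity threshold from labeled cells
#'
#' The threshold is the midpoint of the two class-conditional means of
#' the per-cell mean DAB signal — the package's reproducible stand-in for
#' setting a threshold "by eye" on the staining intensity of a cohort.
#'
#' @param cells tibble with `true_class` and `mean_dab_od` columns (e.g.
#'   ground-truth cells passed through [classify_positivity()] with any
#'   provisional threshold, or [measure_dab()]).
#' @return one-row tibble: `threshold_od`, `mean_pos`, `mean_neg`,
#'   `separation` (difference of class means in pooled-SD units).
#' @export
calibrate_threshold <- function(cells) {
  if (!all(c("true_class", "mean_dab_od") %in% names(cells)))
    iq_abort("cells must have true_class and mean_dab_od columns")
  pos <- cells$mean_dab_od[cells$true_class == "CD3_POS"]
  neg <- cells$mean_dab_od[cells$true_class == "CD3_NEG"]
  if (!length(pos) || !length(neg))
    iq_abort("threshold calibration needs both CD3_POS and CD3_NEG cells")
  sp <- sqrt((stats::var(pos) * (length(pos) - 1) +
                stats::var(neg) * (length(neg) - 1)) /
               max(1, length(pos) + length(neg) - 2))
  tibble(threshold_od = (mean(pos) + mean(neg)) / 2,
         mean_pos = mean(pos), mean_neg = mean(neg),
         separation = if (is.finite(sp) && sp > 0)
           abs(mean(pos) - mean(neg)) / sp else Inf)
}

#' Measure the mean DAB signal of cells without classifying them
#'
#' @inheritParams classify_positivity
#' @return `cells` with an added `mean_dab_od` column.
#' @export
measure_dab <- function(cells, dab_map, radius_px = 3) {
  cells$mean_dab_od <- mean_disc_signal(cells, dab_map, radius_px)
  cells
}

#' Assign each cell to a tissue compartment by its centroid pixel
#'
#' @param cells tibble with `row_px`, `col_px`.
#' @param mask compartment mask (labels 0-3).
#' @return `cells` with an added/overwritten `compartment` column
#'   (`SURFACE`, `CRYPT`, `LAMINA_PROPRIA`, or `EXCLUDED` for background
#'   centroids).
#' @export
assign_compartment <- function(cells, mask) {
  H <- nrow(mask)
  rr <- pmin(pmax(as.integer(round(cells$row_px)), 1L), H)
  cc <- pmin(pmax(as.integer(round(cells$col_px)), 1L), ncol(mask))
  lab <- mask[rr + (cc - 1) * H]
  cells$compartment <- c("EXCLUDED", "SURFACE", "CRYPT",
                         "LAMINA_PROPRIA")[lab + 1L]
  cells
}

#' Detection precision / recall against ground truth
#'
#' One-to-one greedy nearest-distance matching within `match_radius_px`:
#' candidate pairs are sorted by distance and matched greedily, each
#' detection and each truth cell at most once.
#'
#' @param pred,truth tibbles with `row_px`, `col_px`.
#' @param match_radius_px maximum centre distance for a match (> 0).
#' @return one-row tibble: `true_positives`, `false_positives`,
#'   `false_negatives`, `precision`, `recall`, `f1`, `match_radius_px`.
#' @export
detection_metrics <- function(pred, truth, match_radius_px = 4) {
  assert_scalar_num(match_radius_px, "match_radius_px", 0, strict = TRUE)
  np <- nrow(pred); nt <- nrow(truth)
  tp <- 0L
  if (np > 0 && nt > 0) {
    d2 <- outer(pred$row_px, truth$row_px, "-")^2 +
      outer(pred$col_px, truth$col_px, "-")^2
    cand <- which(d2 <= match_radius_px^2, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d2[cand]), , drop = FALSE]
      used_p <- logical(np); used_t <- logical(nt)
      for (i in seq_len(nrow(cand))) {
        pi <- cand[i, 1]; ti <- cand[i, 2]
        if (!used_p[pi] && !used_t[ti]) {
          used_p[pi] <- TRUE; used_t[ti] <- TRUE; tp <- tp + 1L
        }
      }
    }
  }
  fp <- np - tp; fn <- nt - tp
  prec <- if (np > 0) tp / np else NA_real_
  rec <- if (nt > 0) tp / nt else NA_real_
  f1 <- if (isTRUE(prec + rec > 0)) 2 * prec * rec / (prec + rec)
        else NA_real_
  tibble(true_positives = tp, false_positives = fp, false_negatives = fn,
         precision = prec, recall = rec, f1 = f1,
         match_radius_px = match_radius_px)
}
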