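#' Segmentation configuration
#'
#' The pixel classifier works at a reduced working scale (default 4x
#' downsample, emulating training at 5x magnification on a 20x scan) on
#' colour/OD features with multi-scale Gaussian context, using a random
#' forest. Predictions are upsampled to native resolution and cleaned by
#' a mode filter and minimum-region-size relabeling.
#'
#' @param scale_factor integer downsampling factor for the working scale.
#' @param num_trees random-forest size.
#' @param min_samples_per_class minimum labeled pixels per class required
#'   to train.
#' @param max_samples_per_class per-class cap on training pixels (class
#'   balancing).
#' @param mode_radius radius (working-scale px) of the majority mode
#'   filter applied to predictions; ties go to the lowest class index.
#' @param min_region_px native-scale area below which a connected
#'   component is relabeled to its surrounding majority class.
#' @param context_sigmas Gaussian sigmas (working-scale px) of the
#'   multi-scale context features.
#' @return list of class `seg_config`.
#' @export
seg_config <- function(scale_factor = 4L, num_trees = 150L,
                       min_samples_per_class = 50L,
                       max_samples_per_class = 4000L,
                       mode_radius = 2L, min_region_px = 64L,
                       context_sigmas = c(2, 6, 16, 32)) {
  structure(list(scale_factor = as.integer(scale_factor),
                 num_trees = as.integer(num_trees),
                 min_samples_per_class = as.integer(min_samples_per_class),
                 max_samples_per_class = as.integer(max_samples_per_class),
                 mode_radius = as.integer(mode_radius),
                 min_region_px = as.integer(min_region_px),
                 context_sigmas = context_sigmas),
            class = "seg_config")
}

# block mean downsampling (crops to a multiple of s)
block_mean <- function(m, s) {
  if (s == 1) return(m)
  H2 <- nrow(m) %/% s; W2 <- ncol(m) %/% s
  m <- m[seq_len(H2 * s), seq_len(W2 * s), drop = FALSE]
  a <- matrix(colSums(array(m, c(s, H2 * W2 * s))), H2, W2 * s)
  t(matrix(colSums(array(t(a), c(s, W2 * H2))), W2, H2)) / s^2
}

# subsample (no averaging) — used for label masks
block_sub <- function(m, s) {
  if (s == 1) return(m)
  off <- ceiling(s / 2)
  m[seq(off, by = s, length.out = nrow(m) %/% s),
    seq(off, by = s, length.out = ncol(m) %/% s), drop = FALSE]
}

#' Per-pixel features for tissue segmentation
#'
#' Computed at the working scale: downsampled RGB, per-channel OD, total
#' OD, and Gaussian-smoothed total OD and brightness at the configured
#' context sigmas (these encode neighbourhood morphology — e.g. the large
#' lumen above the surface epithelium versus the small crypt lumina),
#' plus a local total-OD standard deviation capturing nuclear texture.
#'
#' @param image a `calibrated_image` or `H x W x 3` array.
#' @param config a [seg_config()].
#' @return list with `features` (matrix, one row per working-scale
#'   pixel, column-major order), `dim_ws` (working-scale image size),
#'   `feature_names`.
#' @export
compute_seg_features <- function(image, config = seg_config()) {
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  s <- config$scale_factor
  ch <- lapply(1:3, function(i) block_mean(px[, , i], s))
  od <- lapply(ch, function(m) -log10(pmax(m, 1 / 255)))
  tot <- od[[1]] + od[[2]] + od[[3]]
  bright <- (ch[[1]] + ch[[2]] + ch[[3]]) / 3
  sd_loc <- sqrt(pmax(0, gauss_blur(tot^2, 2) - gauss_blur(tot, 2)^2))
  feats <- c(ch, od, list(tot, sd_loc),
             lapply(config$context_sigmas,
                    function(sg) gauss_blur(tot, sg)),
             lapply(config$context_sigmas,
                    function(sg) gauss_blur(bright, sg)))
  nms <- c("r", "g", "b", "od_r", "od_g", "od_b", "od_tot", "od_sd",
           paste0("ctx_od_s", config$context_sigmas),
           paste0("ctx_br_s", config$context_sigmas))
  f <- vapply(feats, as.numeric, numeric(length(tot)))
  colnames(f) <- nms
  list(features = f, dim_ws = dim(tot), feature_names = nms)
}

#' Build a labeled ROI set from a biopsy with ground truth
#'
#' Emulates a pathologist drawing rectangular regions of interest on a
#' slide and labeling every structure inside them: random windows are
#' placed so that all four classes are covered, and pixels inside the
#' windows carry the ground-truth compartment label (NA elsewhere).
#'
#' @param biopsy a `synthetic_biopsy` (or list with `image` and `mask`).
#' @param n_rois number of rectangular ROIs.
#' @param roi_size window size in native px `c(height, width)`.
#' @param seed integer seed for window placement.
#' @return a one-element `labeled_roi_set` (a list of entries with
#'   `image` and `labels`); concatenate sets with `c()`.
#' @export
sample_rois <- function(biopsy, n_rois = 8, roi_size = c(160, 160),
                        seed = 1) {
  mask <- biopsy$mask
  H <- nrow(mask); W <- ncol(mask)
  labels <- matrix(NA_integer_, H, W)
  with_seed(spawn_seed(seed, "rois"), {
    for (i in seq_len(n_rois)) {
      cls <- (i - 1) %% 4
      pool <- which(mask == cls)
      if (!length(pool)) pool <- seq_along(mask)
      ctr <- sample(pool, 1)
      r0 <- (ctr - 1) %% H + 1; c0 <- (ctr - 1) %/% H + 1
      rs <- max(1, r0 - roi_size[1] %/% 2); re <- min(H, rs + roi_size[1] - 1)
      cs <- max(1, c0 - roi_size[2] %/% 2); ce <- min(W, cs + roi_size[2] - 1)
      labels[rs:re, cs:ce] <- mask[rs:re, cs:ce]
    }
  })
  structure(list(list(image = biopsy$image, labels = labels)),
            class = "labeled_roi_set")
}

#' @export
c.labeled_roi_set <- function(...) {
  structure(do.call("c", lapply(list(...), unclass)),
            class = "labeled_roi_set")
}

#' Extract a training set from labeled ROIs
#'
#' Features are computed on the full image at the working scale; labels
#' are subsampled from the ROI label masks at the same grid, and only
#' labeled pixels are kept.
#'
#' @param rois a `labeled_roi_set` (see [sample_rois()]).
#' @param config a [seg_config()]; `config$scale_factor` is the
#'   downsampling factor.
#' @return list of class `seg_training_set` with `features`, `labels`
#'   (integer vector, values 0-3) and `config`.
#' @export
extract_training_set <- function(rois, config = seg_config()) {
  stopifnot(inherits(rois, "labeled_roi_set"))
  parts <- lapply(rois, function(e) {
    fe <- compute_seg_features(e$image, config)
    lab <- block_sub(e$labels, config$scale_factor)
    keep <- which(!is.na(lab))
    list(f = fe$features[keep, , drop = FALSE],
         l = as.integer(lab[keep]),
         profile = if (inherits(e$image, "calibrated_image"))
           e$image$stain_profile_id else NA_character_)
  })
  profiles <- unique(stats::na.omit(
    vapply(parts, `[[`, character(1), "profile")))
  labels <- unlist(lapply(parts, `[[`, "l"))
  features <- do.call(rbind, lapply(parts, `[[`, "f"))
  missing <- setdiff(unname(COMPARTMENT_LEVELS), unique(labels))
  if (length(missing))
    iq_abort(sprintf(
      "class(es) absent from all ROIs: %s",
      paste(names(COMPARTMENT_LEVELS)[match(missing, COMPARTMENT_LEVELS)],
            collapse = ", ")))
  structure(list(features = features, labels = labels, config = config,
                 stain_profiles = profiles),
            class = "seg_training_set")
}

#' Merge training sets (incremental retraining with additional ROIs)
#' @param ... `seg_training_set` objects with identical feature sets.
#' @return a combined `seg_training_set`.
#' @export
merge_training_sets <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, TRUE, "seg_training_set")))
  structure(list(features = do.call(rbind, lapply(sets, `[[`, "features")),
                 labels = unlist(lapply(sets, `[[`, "labels")),
                 config = sets[[1]]$config,
                 stain_profiles = unique(unlist(
                   lapply(sets, `[[`, "stain_profiles")))),
            class = "seg_training_set")
}

#' Train the four-class tissue segmenter
#'
#' Random forest on working-scale pixel features, class-balanced by
#' capping samples per class. Deterministic given `seed`. Retraining with
#' additional corrective ROIs is done by [merge_training_sets()] and a
#' new `train_segmenter()` call.
#'
#' @param training a `seg_training_set`.
#' @param config a [seg_config()] (defaults to the one used at
#'   extraction).
#' @param seed integer seed.
#' @return object of class `mucosa_segmenter`.
#' @export
train_segmenter <- function(training, config = training$config, seed = 1) {
  stopifnot(inherits(training, "seg_training_set"))
  tab <- table(factor(training$labels, levels = COMPARTMENT_LEVELS))
  if (any(tab < config$min_samples_per_class))
    iq_abort(sprintf(
      "too few training samples for class(es): %s (need >= %d)",
      paste(names(COMPARTMENT_LEVELS)[tab < config$min_samples_per_class],
            collapse = ", "), config$min_samples_per_class))
  keep <- with_seed(spawn_seed(seed, "train_subsample"), {
    unlist(lapply(unname(COMPARTMENT_LEVELS), function(k) {
      idx <- which(training$labels == k)
      if (length(idx) > config$max_samples_per_class)
        sample(idx, config$max_samples_per_class) else idx
    }))
  })
  df <- as.data.frame(training$features[keep, , drop = FALSE])
  df$.class <- factor(training$labels[keep], levels = COMPARTMENT_LEVELS)
  rf <- ranger::ranger(.class ~ ., data = df,
                       num.trees = config$num_trees, seed = seed,
                       num.threads = 1, importance = "impurity")
  structure(list(rf = rf, config = config, seed = seed,
                 classes = COMPARTMENT_LEVELS,
                 n_train = nrow(df),
                 stain_profiles = training$stain_profiles,
                 feature_names = colnames(training$features)),
            class = "mucosa_segmenter")
}

#' @export
print.mucosa_segmenter <- function(x, ...) {
  cat(sprintf(
    "<mucosa_segmenter> %d trees, %d training px, OOB error %.3f\n",
    x$config$num_trees, x$n_train, x$rf$prediction.error))
  invisible(x)
}

#' Segment an image into the four tissue compartments
#'
#' Predicts at the working scale, upsamples to native resolution
#' (nearest neighbour), applies a majority mode filter (ties to the
#' lowest class index) and relabels connected components smaller than
#' `min_region_px` to their surrounding majority class.
#'
#' @param model a `mucosa_segmenter`.
#' @param image a `calibrated_image` or `H x W x 3` array.
#' @return integer compartment mask at native resolution (labels 0-3).
#' @export
segment_image <- function(model, image) {
  stopifnot(inherits(model, "mucosa_segmenter"))
  if (inherits(image, "calibrated_image") &&
      length(model$stain_profiles) &&
      !image$stain_profile_id %in% model$stain_profiles)
    warn(sprintf(
      "image stain profile '%s' differs from the model's training profile(s) %s; proceeding",
      image$stain_profile_id,
      paste(model$stain_profiles, collapse = "/")))
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  cfg <- model$config
  fe <- compute_seg_features(px, cfg)
  pred <- stats::predict(model$rf,
                         data = as.data.frame(fe$features),
                         num.threads = 1)$predictions
  lab_ws <- matrix(as.integer(as.character(pred)), fe$dim_ws[1],
                   fe$dim_ws[2])
  lab_ws <- mode_filter(lab_ws, cfg$mode_radius)
  # upsample to native size (replicate blocks, pad edges by replication)
  s <- cfg$scale_factor
  up <- lab_ws[rep(seq_len(nrow(lab_ws)), each = s),
               rep(seq_len(ncol(lab_ws)), each = s), drop = FALSE]
  H <- nrow(px); W <- ncol(px)
  up <- up[c(seq_len(nrow(up)), rep(nrow(up), H - nrow(up))),
           c(seq_len(ncol(up)), rep(ncol(up), W - ncol(up))),
           drop = FALSE]
  relabel_small_regions(up, cfg$min_region_px)
}

# majority filter over a (2r+1)^2 box; ties -> lowest class index
mode_filter <- function(lab, radius) {
  if (radius <= 0) return(lab)
  k <- matrix(1, 2 * radius + 1, 2 * radius + 1)
  counts <- vapply(unname(COMPARTMENT_LEVELS), function(cl) {
    as.numeric(box_filter(lab == cl, k))
  }, numeric(length(lab)))
  matrix(unname(COMPARTMENT_LEVELS)[max.col(counts, ties.method = "first")],
         nrow(lab), ncol(lab))
}

box_filter <- function(m, k) {
  r <- (nrow(k) - 1) / 2
  pass <- function(x, r) {
    xp <- rbind(x[rep(1, r), , drop = FALSE], x,
                x[rep(nrow(x), r), , drop = FALSE])
    out <- stats::filter(xp, rep(1, 2 * r + 1), sides = 2)
    matrix(out[(r + 1):(r + nrow(x)), ], nrow(x), ncol(x))
  }
  t(pass(t(pass(m * 1, r)), r))
}

# relabel connected components smaller than min_px to the majority label
# of their 1-px neighbourhood
relabel_small_regions <- function(lab, min_px) {
  if (min_px <= 1) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  for (cl in unname(COMPARTMENT_LEVELS)) {
    comp <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(
      (lab == cl) * 1)))
    if (max(comp) == 0) next
    sel <- which(comp > 0)
    cv <- comp[sel]
    sizes <- tabulate(cv)
    small <- which(sizes < min_px)
    if (!length(small)) next
    keep <- cv %in% small
    groups <- split(sel[keep], cv[keep])
    for (idx in groups) {
      rr <- (idx - 1) %% H + 1; cc <- (idx - 1) %/% H + 1
      nr <- c(pmax(rr - 1, 1), pmin(rr + 1, H), rr, rr)
      nc <- c(cc, cc, pmax(cc - 1, 1), pmin(cc + 1, W))
      nbl <- lab[nr + (nc - 1) * H]
      nbl <- nbl[nbl != cl]
      if (!length(nbl)) next
      cnt <- tabulate(nbl + 1L, 4L)
      lab[idx] <- which.max(cnt) - 1L
    }
  }
  lab
}

#' Score a predicted compartment mask against ground truth
#'
#' @param pred,truth integer masks of identical shape (labels 0-3).
#' @return list of class `seg_eval`: `confusion` (truth rows x pred
#'   columns), `accuracy`, and `per_class` tibble with recall, precision
#'   and IoU per class.
#' @export
evaluate_segmentation <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    iq_abort("pred and truth masks must have identical shape")
  lv <- unname(COMPARTMENT_LEVELS)
  conf <- table(truth = factor(truth, levels = lv),
                pred = factor(pred, levels = lv))
  acc <- sum(diag(conf)) / sum(conf)
  per_class <- tibble(
    class = names(COMPARTMENT_LEVELS),
    label = lv,
    n_truth = as.integer(rowSums(conf)),
    recall = diag(conf) / pmax(1, rowSums(conf)),
    precision = diag(conf) / pmax(1, colSums(conf)),
    iou = diag(conf) /
      pmax(1, rowSums(conf) + colSums(conf) - diag(conf)))
  structure(list(confusion = conf, accuracy = acc, per_class = per_class),
            class = "seg_eval")
}

#' @export
print.seg_eval <- function(x, ...) {
  cat(sprintf("<seg_eval> pixel accuracy %.4f\n", x$accuracy))
  print(x$per_class)
  invisible(x)
}
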