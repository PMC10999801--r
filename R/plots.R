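#' @importFrom ggplot2 ggplot aes geom_raster geom_boxplot geom_col
#'   scale_fill_manual coord_fixed labs theme_minimal autoplot
NULL

COMPARTMENT_COLORS <- c(background = "#3cb44b",
                        surface_epithelium = "#4363d8",
                        crypt_epithelium = "#e6194b",
                        lamina_propria = "#ffe119")

mask_to_long <- function(mask) {
  tibble(row = as.integer(row(mask)), col = as.integer(col(mask)),
         class = factor(names(COMPARTMENT_LEVELS)[as.integer(mask) + 1L],
                        levels = names(COMPARTMENT_LEVELS)))
}

#' Plot a compartment mask
#'
#' @param mask integer compartment mask (labels 0-3).
#' @return a ggplot object.
#' @export
plot_compartment_mask <- function(mask) {
  df <- mask_to_long(mask)
  ggplot(df, aes(.data$col, -.data$row, fill = .data$class)) +
    geom_raster() +
    scale_fill_manual(values = COMPARTMENT_COLORS, drop = FALSE) +
    coord_fixed() +
    labs(x = NULL, y = NULL, fill = "compartment") +
    theme_minimal()
}

#' Plot a rendered biopsy image
#'
#' @param image a `calibrated_image`.
#' @return a ggplot object (raster of the RGB render).
#' @export
plot_biopsy_image <- function(image) {
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  df <- tibble(
    row = as.integer(row(px[, , 1])), col = as.integer(col(px[, , 1])),
    fill = grDevices::rgb(px[, , 1], px[, , 2], px[, , 3]))
  ggplot(df, aes(.data$col, -.data$row)) +
    geom_raster(aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    coord_fixed() + labs(x = NULL, y = NULL) + theme_minimal()
}

#' Box plots of IEL counts by location and method
#'
#' The Figure-2/3-style comparison view: one box per location x method.
#'
#' @param data tibble with columns `location`, `value` and optionally
#'   `method`.
#' @param value column holding the metric (tidy-eval; default
#'   `surface_iel_per_100`).
#' @return a ggplot object.
#' @export
plot_iel_counts <- function(data, value = NULL) {
  vq <- rlang::enquo(value)
  if (rlang::quo_is_null(vq)) vq <- rlang::quo(.data$surface_iel_per_100)
  has_method <- "method" %in% names(data)
  p <- ggplot(data, aes(.data$location, !!vq)) +
    labs(x = NULL, y = "IELs per 100 epithelial cells") +
    theme_minimal()
  if (has_method)
    p + geom_boxplot(aes(fill = .data$method)) else
    p + geom_boxplot()
}

#' @export
autoplot.synthetic_biopsy <- function(object, ...) {
  plot_biopsy_image(object$image)
}

#' @export
autoplot.seg_eval <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot(df, aes(.data$pred, .data$truth, fill = .data$Freq)) +
    geom_raster() +
    labs(title = sprintf("pixel accuracy %.3f", object$accuracy)) +
    theme_minimal()
}

#' @export
autoplot.mucosa_segmenter <- function(object, ...) {
  imp <- sort(object$rf$variable.importance, decreasing = TRUE)
  df <- tibble(feature = factor(names(imp), levels = rev(names(imp))),
               importance = unname(imp))
  ggplot(df, aes(.data$importance, .data$feature)) +
    geom_col() + labs(y = NULL) + theme_minimal()
}
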