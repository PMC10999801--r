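#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.iq_test <- function(x, ...) as_tibble(x)

#' @export
glance.iq_test <- function(x, ...) as_tibble(x)

#' @export
tidy.mucosa_segmenter <- function(x, ...) {
  imp <- x$rf$variable.importance
  tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @export
glance.mucosa_segmenter <- function(x, ...) {
  tibble(n_train = x$n_train, num_trees = x$config$num_trees,
         scale_factor = x$config$scale_factor,
         oob_error = x$rf$prediction.error, seed = x$seed)
}

#' @export
tidy.seg_eval <- function(x, ...) x$per_class

#' @export
glance.seg_eval <- function(x, ...) tibble(accuracy = x$accuracy)

#' @export
tidy.biopsy_analysis <- function(x, ...) x$quant

#' @export
glance.biopsy_analysis <- function(x, ...) {
  tibble(n_cells = nrow(x$cells),
         n_pos = sum(x$cells$predicted_class == "CD3_POS"))
}

#' @export
tidy.pipeline_run <- function(x, ...) x$results

#' @export
glance.pipeline_run <- function(x, ...) {
  tibble(n_biopsies = nrow(x$results),
         threshold_od = x$threshold_od,
         seed = x$manifest$seed)
}
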