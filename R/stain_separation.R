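#' Convert transmitted RGB intensities to optical density
#'
#' Beer-Lambert inversion: `OD = -log10(I / I0)` per channel. Intensities
#' at or below the floor `eps` are clipped to `eps` before the log so
#' saturated-dark pixels map to a finite OD.
#'
#' @param image numeric array `H x W x 3` (or `N x 3` matrix) of
#'   transmitted intensities in `(0, 1]`.
#' @param I0 background intensity per channel (length 3 or scalar), > 0.
#' @param eps intensity floor applied before the log (default 1/255).
#' @return optical densities with the same shape as `image`; always >= 0
#'   for intensities <= `I0`.
#' @examples
#' od <- rgb_to_od(array(0.1, c(2, 2, 3)), I0 = 1)
#' od[1, 1, 1]  # == 1
#' @export
rgb_to_od <- function(image, I0 = c(1, 1, 1), eps = 1 / 255) {
  if (any(!is.finite(I0)) || any(I0 <= 0)) iq_abort("I0 must be > 0")
  if (length(I0) == 1) I0 <- rep(I0, 3)
  dm <- dim(image)
  flat <- to_pixel_matrix(image)
  flat <- pmax(flat, eps)
  od <- -log10(sweep(flat, 2, I0, "/"))
  od <- pmax(od, 0)
  from_pixel_matrix(od, dm)
}

# N x 3 (or N x k) view of an image array; inverse below
to_pixel_matrix <- function(image) {
  dm <- dim(image)
  if (is.null(dm) || length(dm) == 2) return(as.matrix(image))
  matrix(image, nrow = dm[1] * dm[2], ncol = dm[3])
}

from_pixel_matrix <- function(m, dm) {
  if (is.null(dm) || length(dm) == 2) return(m)
  array(m, dim = c(dm[1], dm[2], ncol(m)))
}

#' Unmix an OD image into per-stain concentration maps
#'
#' Least-squares projection of each pixel's OD vector onto the profile's
#' stain basis (via the pseudo-inverse). Negative concentrations are
#' clipped to zero: physical stain amounts are non-negative.
#'
#' @param od OD array `H x W x 3` (or `N x 3` matrix), e.g. from
#'   [rgb_to_od()].
#' @param profile a [stain_profile()].
#' @return array `H x W x k` (or `N x k` matrix) of stain concentrations,
#'   third-dimension order matching `profile$stain_names`.
#' @export
unmix_stains <- function(od, profile) {
  stopifnot(inherits(profile, "stain_profile"))
  M <- profile$od_matrix
  dm <- dim(od)
  flat <- to_pixel_matrix(od)
  if (ncol(flat) != 3) iq_abort("od must have 3 channels")
  conc <- flat %*% M %*% solve(crossprod(M))
  conc <- pmax(conc, 0)
  colnames(conc) <- profile$stain_names
  out <- from_pixel_matrix(conc, if (is.null(dm) || length(dm) == 2) NULL
                           else c(dm[1], dm[2], ncol(conc)))
  if (length(dim(out)) == 3)
    dimnames(out) <- list(NULL, NULL, profile$stain_names)
  out
}

#' Mix stain concentrations back into an OD image
#'
#' Exact inverse of [unmix_stains()] on the stain subspace:
#' `OD = od_matrix %*% c` per pixel.
#'
#' @param conc concentration array `H x W x k` (or `N x k` matrix),
#'   non-negative.
#' @param profile a [stain_profile()].
#' @return OD array `H x W x 3` (or `N x 3` matrix).
#' @export
mix_stains <- function(conc, profile) {
  stopifnot(inherits(profile, "stain_profile"))
  M <- profile$od_matrix
  dm <- dim(conc)
  flat <- to_pixel_matrix(conc)
  if (ncol(flat) != ncol(M))
    iq_abort(sprintf("conc has %d stain channels but profile defines %d",
                     ncol(flat), ncol(M)))
  od <- flat %*% t(M)
  from_pixel_matrix(od, if (is.null(dm) || length(dm) == 2) NULL
                    else c(dm[1], dm[2], 3L))
}
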