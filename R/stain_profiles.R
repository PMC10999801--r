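#' Stain profiles and optical-density vectors
#'
#' A stain profile bundles the per-stain optical density (OD) colour
#' vectors used for Beer-Lambert rendering and colour deconvolution, the
#' background (blank-glass) intensity `I0`, and the identity of the stain
#' combination. Hematoxylin, eosin and DAB use the published
#' Ruifrok-Johnston vectors; the connective-tissue chromogens (Van Gieson
#' picrofuchsin, Masson aniline blue, Weigert-Alcian-Sirius red) are
#' plausible synthetic vectors chosen to be well separated from
#' hematoxylin.
#'
#' @name stain_profiles
NULL

# Ruifrok & Johnston OD vectors (RGB order), unit-normalised below.
.OD_VECTORS <- list(
  hematoxylin = c(0.650, 0.704, 0.286),
  eosin       = c(0.072, 0.990, 0.105),
  dab         = c(0.268, 0.570, 0.776),
  # synthetic connective-tissue chromogens
  vg_fuchsin  = c(0.100, 0.780, 0.610),
  mt_blue     = c(0.760, 0.470, 0.450),
  was_red     = c(0.180, 0.830, 0.530)
)

.PROFILE_STAINS <- list(
  ihc_cd3 = c("hematoxylin", "dab"),
  he      = c("hematoxylin", "eosin"),
  vg      = c("hematoxylin", "vg_fuchsin"),
  mt      = c("hematoxylin", "mt_blue"),
  was     = c("hematoxylin", "was_red")
)

unit_cols <- function(m) sweep(m, 2, sqrt(colSums(m^2)), "/")

#' Construct a stain profile
#'
#' @param id one of `"ihc_cd3"`, `"he"`, `"vg"`, `"mt"`, `"was"`, or
#'   `"custom"` when `stain_names`/`od_matrix` are supplied directly.
#' @param stain_names optional character vector (<= 3 stains) overriding the
#'   profile's default stains.
#' @param od_matrix optional 3 x k matrix of OD column vectors (RGB rows);
#'   columns are re-normalised to unit Euclidean norm.
#' @param I0 background transmitted intensity per channel, in (0, 1].
#' @param max_condition maximum accepted condition number of the OD basis.
#' @return an object of class `stain_profile`.
#' @examples
#' p <- stain_profile("ihc_cd3")
#' p$stain_names
#' @export
stain_profile <- function(id, stain_names = NULL, od_matrix = NULL,
                          I0 = c(1, 1, 1), max_condition = 1e3) {
  if (is.null(stain_names)) {
    if (!id %in% names(.PROFILE_STAINS))
      iq_abort(sprintf(
        "unknown stain profile '%s'; known profiles: %s", id,
        paste(names(.PROFILE_STAINS), collapse = ", ")))
    stain_names <- .PROFILE_STAINS[[id]]
  }
  if (length(stain_names) > 3) iq_abort("at most 3 stains per profile")
  if (is.null(od_matrix)) {
    missing <- setdiff(stain_names, names(.OD_VECTORS))
    if (length(missing))
      iq_abort(sprintf("no OD vector known for stain(s): %s",
                       paste(missing, collapse = ", ")))
    od_matrix <- vapply(stain_names, function(s) .OD_VECTORS[[s]],
                        numeric(3))
  }
  od_matrix <- unit_cols(as.matrix(od_matrix))
  dimnames(od_matrix) <- list(NULL, stain_names)
  if (nrow(od_matrix) != 3 || ncol(od_matrix) != length(stain_names))
    iq_abort("od_matrix must be 3 x length(stain_names)")
  if (any(!is.finite(I0)) || any(I0 <= 0))
    iq_abort("I0 must be positive in every channel")
  kap <- kappa(od_matrix, exact = TRUE)
  if (kap > max_condition)
    iq_abort(sprintf(
      "stain OD basis is ill-conditioned (condition number %.3g > %.3g)",
      kap, max_condition))
  structure(list(id = id, stain_names = stain_names,
                 od_matrix = od_matrix, I0 = as.numeric(I0)),
            class = "stain_profile")
}

#' @export
print.stain_profile <- function(x, ...) {
  cat("<stain_profile>", x$id, ":",
      paste(x$stain_names, collapse = " + "), "\n")
  invisible(x)
}

#' Serialize / deserialize a stain profile as JSON
#'
#' The OD matrix is stored row-major; round-trips are value-identical.
#'
#' @param profile a [stain_profile()].
#' @param path file path.
#' @return `read_stain_profile` returns a `stain_profile`.
#' @export
write_stain_profile <- function(profile, path) {
  stopifnot(inherits(profile, "stain_profile"))
  jsonlite::write_json(
    list(id = profile$id, stain_names = profile$stain_names,
         od_matrix = as.numeric(t(profile$od_matrix)), I0 = profile$I0),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stain_profile
#' @export
read_stain_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(x$od_matrix, nrow = 3, byrow = TRUE)
  stain_profile(x$id, stain_names = x$stain_names, od_matrix = m, I0 = x$I0)
}

#' Names of the built-in stain profiles
#' @return character vector of profile ids.
#' @export
known_stain_profiles <- function() names(.PROFILE_STAINS)
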