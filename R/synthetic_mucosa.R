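#' Generation parameters for a synthetic biopsy
#'
#' Bundles everything the synthetic mucosa generator needs: image size and
#' calibration, crypt count, the target intraepithelial-lymphocyte (IEL)
#' rates per epithelial compartment, lamina propria cell densities, the
#' subepithelial band thickness, the stain to render, the noise level and
#' the master seed. The defaults emulate a 20x-scanned colon biopsy
#' (0.5 um/px) with a 30 um surface epithelium, vertically cut crypts and
#' a thin (1 um) subepithelial band.
#'
#' Rates are expressed the way the diagnostic criteria are:
#' `surface_iel_rate` / `crypt_iel_rate` are target CD3+ cells per 100
#' CD3- epithelial cells, realised by marking each placed epithelial
#' nucleus CD3+ independently with probability `r / (100 + r)` so the
#' expected positive:negative ratio is `r/100`. Lamina propria CD3+ and
#' CD3- cells follow homogeneous Poisson point processes with the given
#' intensities per mm^2.
#'
#' @param image_height_px,image_width_px image size in pixels.
#' @param um_per_px micrometres per pixel (> 0); 0.5 matches a typical
#'   20x scan.
#' @param n_crypts number of crypt cross-sections to place.
#' @param surface_iel_rate,crypt_iel_rate target IELs per 100 epithelial
#'   cells in the surface / crypt epithelium (>= 0).
#' @param lp_cd3_density CD3+ cells per mm^2 of lamina propria.
#' @param lp_negative_density CD3- stromal nuclei per mm^2.
#' @param band_thickness_um subepithelial band thickness in micrometres
#'   (>= 0; 0 disables the band).
#' @param stain_profile_id one of [known_stain_profiles()].
#' @param noise_sd additive Gaussian intensity noise (0-1 scale).
#' @param seed integer master seed; geometry, nuclei and render noise draw
#'   from independent substreams spawned from it.
#' @param epithelium_thickness_um thickness of the surface epithelium band.
#' @param epithelial_spacing_um centre-to-centre spacing of epithelial
#'   nuclei along the epithelium (linear density is its reciprocal).
#' @param nucleus_radius_um rendered nucleus radius.
#' @param min_spacing_um minimum centre-to-centre distance enforced
#'   between any two nuclei.
#' @param lumen_depth_um depth of the lumen background above the surface.
#' @param undulation_amp_um,undulation_period_um amplitude and period of
#'   the surface undulation.
#' @param crypt_col_radius_um,crypt_row_radius_um outer semi-axes of the
#'   elliptical crypt profiles (column/row direction).
#' @param crypt_ring_um thickness of the crypt epithelium ring.
#' @return an object of class `gen_params` (a validated named list that
#'   round-trips losslessly through JSON).
#' @examples
#' p <- gen_params(seed = 7, n_crypts = 2)
#' p$um_per_px
#' @export
gen_params <- function(image_height_px = 640L, image_width_px = 1024L,
                       um_per_px = 0.5, n_crypts = 7L,
                       surface_iel_rate = 5, crypt_iel_rate = 5,
                       lp_cd3_density = 300, lp_negative_density = 700,
                       band_thickness_um = 1,
                       stain_profile_id = "ihc_cd3",
                       noise_sd = 2 / 255, seed = 1L,
                       epithelium_thickness_um = 30,
                       epithelial_spacing_um = 4,
                       nucleus_radius_um = 1.2,
                       min_spacing_um = 4,
                       lumen_depth_um = 50,
                       undulation_amp_um = 10,
                       undulation_period_um = 160,
                       crypt_col_radius_um = 12,
                       crypt_row_radius_um = 26,
                       crypt_ring_um = 5.5) {
  p <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    um_per_px = as.numeric(um_per_px),
    n_crypts = as.integer(n_crypts),
    surface_iel_rate = as.numeric(surface_iel_rate),
    crypt_iel_rate = as.numeric(crypt_iel_rate),
    lp_cd3_density = as.numeric(lp_cd3_density),
    lp_negative_density = as.numeric(lp_negative_density),
    band_thickness_um = as.numeric(band_thickness_um),
    stain_profile_id = as.character(stain_profile_id),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed),
    epithelium_thickness_um = as.numeric(epithelium_thickness_um),
    epithelial_spacing_um = as.numeric(epithelial_spacing_um),
    nucleus_radius_um = as.numeric(nucleus_radius_um),
    min_spacing_um = as.numeric(min_spacing_um),
    lumen_depth_um = as.numeric(lumen_depth_um),
    undulation_amp_um = as.numeric(undulation_amp_um),
    undulation_period_um = as.numeric(undulation_period_um),
    crypt_col_radius_um = as.numeric(crypt_col_radius_um),
    crypt_row_radius_um = as.numeric(crypt_row_radius_um),
    crypt_ring_um = as.numeric(crypt_ring_um))
  validate_gen_params(p)
}

validate_gen_params <- function(p) {
  assert_scalar_num(p$image_height_px, "image_height_px", 32)
  assert_scalar_num(p$image_width_px, "image_width_px", 32)
  assert_scalar_num(p$um_per_px, "um_per_px", 0, strict = TRUE)
  assert_scalar_num(p$n_crypts, "n_crypts", 0)
  for (f in c("surface_iel_rate", "crypt_iel_rate", "lp_cd3_density",
              "lp_negative_density", "band_thickness_um", "noise_sd"))
    assert_scalar_num(p[[f]], f, 0)
  if (!p$stain_profile_id %in% known_stain_profiles())
    iq_abort(sprintf("unknown stain_profile_id '%s'; known profiles: %s",
                     p$stain_profile_id,
                     paste(known_stain_profiles(), collapse = ", ")))
  assert_scalar_num(p$seed, "seed", -Inf)
  structure(p, class = "gen_params")
}

#' @export
print.gen_params <- function(x, ...) {
  cat(sprintf("<gen_params> %dx%d px @ %.3g um/px, %d crypts, %s\n",
              x$image_height_px, x$image_width_px, x$um_per_px,
              x$n_crypts, x$stain_profile_id))
  invisible(x)
}

#' Read / write generation parameters as JSON
#' @param params a [gen_params()] object.
#' @param path file path.
#' @return `read_gen_params` returns a `gen_params` object equal
#'   field-by-field to the one written.
#' @export
write_gen_params <- function(params, path) {
  stopifnot(inherits(params, "gen_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_gen_params
#' @export
read_gen_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(gen_params, x)
}

# pixel offsets of a filled disc of radius r (includes the boundary)
disc_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
}

# write `value` into mat at discs of radius r around (rows, cols);
# existing larger values are kept so overlapping discs do not double up
paint_discs <- function(mat, rows, cols, r, value) {
  if (length(rows) == 0) return(mat)
  off <- disc_offsets(r)
  H <- nrow(mat); W <- ncol(mat)
  rr <- rep(round(rows), each = nrow(off)) + off$dr
  cc <- rep(round(cols), each = nrow(off)) + off$dc
  keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  idx <- rr[keep] + (cc[keep] - 1) * H
  mat[idx] <- pmax(mat[idx], value)
  mat
}

#' Generate the tissue geometry of a synthetic biopsy
#'
#' Builds the compartment mask — lumen background on top, an undulating
#' surface-epithelium band, lamina propria below, and `n_crypts`
#' vertically oriented elliptical-annulus crypt profiles (crypt lumina are
#' background) — together with the subepithelial band mask, a layer of
#' `band_thickness_um / um_per_px` pixels directly beneath the surface
#' epithelium. Deterministic given `params$seed`.
#'
#' @param params a [gen_params()] object.
#' @return an object of class `mucosa_geometry`: list with `mask`
#'   (integer matrix, labels 0 = background, 1 = surface epithelium,
#'   2 = crypt epithelium, 3 = lamina propria), `band_mask` (logical
#'   matrix), `surface_top` (top row of the epithelium per column),
#'   `crypts` (tibble of placed crypts) and `params`.
#' @export
generate_tissue_geometry <- function(params) {
  stopifnot(inherits(params, "gen_params"))
  p <- params
  H <- p$image_height_px; W <- p$image_width_px; um <- p$um_per_px
  amp <- p$undulation_amp_um / um
  per <- max(8, p$undulation_period_um / um)
  t_epi <- max(2L, as.integer(round(p$epithelium_thickness_um / um)))
  band_px <- as.integer(round(p$band_thickness_um / um))

  res <- with_seed(spawn_seed(p$seed, "geometry"), {
    ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
    cols <- seq_len(W)
    top <- round(p$lumen_depth_um / um + amp +
                   amp * sin(2 * pi * cols / per + ph1) +
                   0.35 * amp * sin(2 * pi * cols / (2.7 * per) + ph2))
    top <- pmax(2L, as.integer(top))
    if (max(top) + t_epi + band_px + 4 >= H)
      iq_abort("image_height_px too small for lumen + epithelium + band")

    R <- row(matrix(0L, H, W))
    Tm <- matrix(top, H, W, byrow = TRUE)
    mask <- matrix(3L, H, W)
    mask[R < Tm] <- 0L
    mask[R >= Tm & R < Tm + t_epi] <- 1L
    band_mask <- R >= (Tm + t_epi) & R < (Tm + t_epi + band_px)

    # crypts: vertical elliptical annuli fully inside the lamina propria
    a_c <- p$crypt_col_radius_um / um
    a_r <- p$crypt_row_radius_um / um
    ring <- p$crypt_ring_um / um
    placed <- list()
    if (p$n_crypts > 0) {
      for (i in seq_len(p$n_crypts)) {
        ok <- FALSE
        for (try in seq_len(300)) {
          c0 <- runif(1, a_c + 5, W - a_c - 4)
          span <- max(1, floor(c0 - a_c)):min(W, ceiling(c0 + a_c))
          top_bound <- max(top[span]) + t_epi + band_px + 6
          lo <- top_bound + a_r; hi <- H - a_r - 4
          if (lo >= hi) next
          r0 <- runif(1, lo, hi)
          clash <- FALSE
          for (q in placed) {
            if (((c0 - q$col0) / (2 * a_c + 10))^2 +
                ((r0 - q$row0) / (2 * a_r + 10))^2 < 1) {
              clash <- TRUE; break
            }
          }
          if (!clash) { ok <- TRUE; break }
        }
        if (!ok)
          iq_abort(sprintf(
            paste0("could not place crypt %d of %d without overlap: ",
                   "n_crypts too high for the image size / crypt radii"),
            i, p$n_crypts))
        placed[[i]] <- list(crypt_id = i, row0 = r0, col0 = c0,
                            a_r = a_r, a_c = a_c, ring_px = ring)
        rs <- max(1, floor(r0 - a_r)):min(H, ceiling(r0 + a_r))
        cs <- max(1, floor(c0 - a_c)):min(W, ceiling(c0 + a_c))
        Rl <- matrix(rs, length(rs), length(cs))
        Cl <- matrix(cs, length(rs), length(cs), byrow = TRUE)
        outer_e <- ((Cl - c0) / a_c)^2 + ((Rl - r0) / a_r)^2 <= 1
        inner_e <- ((Cl - c0) / (a_c - ring))^2 +
          ((Rl - r0) / (a_r - ring))^2 <= 1
        sub <- mask[rs, cs]
        sub[outer_e & !inner_e & sub == 3L] <- 2L
        sub[inner_e & sub != 1L] <- 0L
        mask[rs, cs] <- sub
      }
    }
    list(mask = mask, band_mask = band_mask, top = top, placed = placed)
  })

  crypts <- if (length(res$placed))
    dplyr::bind_rows(lapply(res$placed, as_tibble)) else
    tibble(crypt_id = integer(), row0 = numeric(), col0 = numeric(),
           a_r = numeric(), a_c = numeric(), ring_px = numeric())
  structure(list(mask = res$mask, band_mask = res$band_mask,
                 surface_top = res$top, crypts = crypts, params = params),
            class = "mucosa_geometry")
}

#' Place ground-truth nuclei in a tissue geometry
#'
#' Epithelial nuclei are placed along the surface-epithelium path and each
#' crypt ring at the configured linear spacing; each is independently
#' marked CD3+ with probability `r/(100 + r)` so the expected
#' positive:negative ratio equals `rate/100`. Lamina propria receives
#' CD3+ cells as a homogeneous Poisson process with expected count
#' `lp_cd3_density * area_mm2` (and CD3- stromal nuclei likewise), with a
#' hard minimum centre-to-centre distance against all previously placed
#' nuclei and the (dilated) subepithelial band. Deterministic given
#' `params$seed`.
#'
#' @param geometry a `mucosa_geometry` from [generate_tissue_geometry()].
#' @param params a [gen_params()]; defaults to `geometry$params`.
#' @return a `CellTable`: tibble with columns `cell_id`, `row_px`,
#'   `col_px`, `area_px`, `true_class` (`CD3_POS`/`CD3_NEG`),
#'   `compartment` (`SURFACE`/`CRYPT`/`LAMINA_PROPRIA`). Surface rows come
#'   first in arc-length order along the surface path.
#' @export
place_nuclei <- function(geometry, params = geometry$params) {
  stopifnot(inherits(geometry, "mucosa_geometry"))
  p <- params
  um <- p$um_per_px
  H <- p$image_height_px; W <- p$image_width_px
  r_px <- max(1L, as.integer(round(p$nucleus_radius_um / um)))
  spacing <- p$epithelial_spacing_um / um
  min_d <- max(p$min_spacing_um / um, 2 * r_px + 2)
  t_epi <- max(2L, as.integer(round(p$epithelium_thickness_um / um)))
  area_px <- nrow(disc_offsets(r_px))

  with_seed(spawn_seed(p$seed, "nuclei"), {
    ## --- surface epithelium: nuclei along the arc of the band centre
    ctr <- geometry$surface_top + t_epi / 2
    d_arc <- c(0, sqrt(1 + diff(ctr)^2))
    cum <- cumsum(d_arc)
    targets <- seq(spacing / 2, max(cum), by = spacing)
    s_col <- stats::approx(cum, seq_len(W), xout = targets)$y
    jit <- max(0, t_epi / 2 - r_px - 2)
    s_row <- stats::approx(seq_len(W), ctr, xout = s_col)$y +
      runif(length(s_col), -jit, jit)
    s_pos <- runif(length(s_col)) <
      p$surface_iel_rate / (100 + p$surface_iel_rate)
    surface <- tibble(row_px = s_row, col_px = s_col,
                      true_class = ifelse(s_pos, "CD3_POS", "CD3_NEG"),
                      compartment = "SURFACE")

    ## --- crypt epithelium: nuclei along each ring centreline
    crypt_list <- list()
    if (nrow(geometry$crypts)) {
      for (i in seq_len(nrow(geometry$crypts))) {
        q <- geometry$crypts[i, ]
        ac <- q$a_c - q$ring_px / 2; ar <- q$a_r - q$ring_px / 2
        th <- seq(0, 2 * pi, length.out = 721)[-721]
        px <- q$col0 + ac * sin(th); py <- q$row0 - ar * cos(th)
        seg <- sqrt(diff(c(px, px[1]))^2 + diff(c(py, py[1]))^2)
        cl <- cumsum(c(0, seg[-length(seg)]))
        L <- sum(seg)
        n_c <- max(0L, floor(L / spacing))
        if (n_c == 0) next
        offs <- runif(1, 0, spacing)
        at <- (offs + (seq_len(n_c) - 1) * spacing) %% L
        ii <- findInterval(at, cl)
        crypt_list[[i]] <- tibble(
          row_px = py[ii], col_px = px[ii],
          true_class = ifelse(
            runif(n_c) < p$crypt_iel_rate / (100 + p$crypt_iel_rate),
            "CD3_POS", "CD3_NEG"),
          compartment = "CRYPT")
      }
    }
    crypt <- dplyr::bind_rows(crypt_list)

    ## --- lamina propria: homogeneous point processes with hard core
    lp_px <- sum(geometry$mask == 3L)
    area_mm2 <- lp_px * um^2 / 1e6
    n_pos <- rpois(1, p$lp_cd3_density * area_mm2)
    n_neg <- rpois(1, p$lp_negative_density * area_mm2)

    occ <- matrix(FALSE, H, W)
    d_mark <- as.integer(ceiling(min_d))
    epi <- dplyr::bind_rows(surface, crypt)
    occ <- paint_discs(occ, epi$row_px, epi$col_px, d_mark, TRUE) > 0
    if (any(geometry$band_mask)) {
      bi <- which(geometry$band_mask, arr.ind = TRUE)
      # keep nuclei clear of the collagen band (it is acellular)
      occ <- paint_discs(occ, bi[, 1], bi[, 2], r_px + 2, TRUE) > 0
    }
    allowed <- geometry$mask == 3L & !occ
    allowed[c(seq_len(r_px + 1), (H - r_px):H), ] <- FALSE
    allowed[, c(seq_len(r_px + 1), (W - r_px):W)] <- FALSE

    mark_off <- disc_offsets(d_mark)
    place_lp <- function(n_target, occ) {
      picked <- integer(n_target)
      n_got <- 0L
      if (n_target > 0) {
        pool <- which(allowed & !occ)
        if (length(pool))
          pool <- sample(pool, min(length(pool), n_target * 60))
        for (idx in pool) {
          if (occ[idx]) next
          n_got <- n_got + 1L
          picked[n_got] <- idx
          rr <- (idx - 1L) %% H + 1L + mark_off$dr
          cc <- (idx - 1L) %/% H + 1L + mark_off$dc
          inb <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
          occ[rr[inb] + (cc[inb] - 1L) * H] <- TRUE
          if (n_got == n_target) break
        }
        if (n_got < n_target)
          iq_abort(paste0(
            "lamina propria cell density unplaceable at the minimum ",
            "centre-to-centre spacing; reduce densities or min_spacing_um"))
      }
      list(idx = picked[seq_len(n_got)], occ = occ)
    }
    pp <- place_lp(n_pos, occ)
    pn <- place_lp(n_neg, pp$occ)
    lp <- tibble(
      row_px = c((pp$idx - 1) %% H + 1, (pn$idx - 1) %% H + 1),
      col_px = c((pp$idx - 1) %/% H + 1, (pn$idx - 1) %/% H + 1),
      true_class = rep(c("CD3_POS", "CD3_NEG"), c(n_pos, n_neg)),
      compartment = "LAMINA_PROPRIA")

    cells <- dplyr::bind_rows(surface, crypt, lp)
    cells$cell_id <- seq_len(nrow(cells))
    cells$area_px <- area_px
    cells[, c("cell_id", "row_px", "col_px", "area_px",
              "true_class", "compartment")]
  })
}

# per-structure stain concentrations used by the renderer; the band gets
# a strong connective chromogen only under vg/mt/was (near-zero contrast
# against stroma under he, none under ihc_cd3)
render_scheme <- function(profile_id) {
  base <- list(nucleus_hem = 0.75, dab_pos = 0.65)
  extra <- switch(profile_id,
    ihc_cd3 = list(epi = 0.04, lp = 0.10, band = 0.00, counter = "hematoxylin"),
    he      = list(epi = 0.08, lp = 0.30, band = 0.00, counter = "eosin"),
    vg      = list(epi = 0.02, lp = 0.10, band = 0.85, counter = "vg_fuchsin"),
    mt      = list(epi = 0.02, lp = 0.12, band = 0.85, counter = "mt_blue"),
    was     = list(epi = 0.02, lp = 0.08, band = 0.85, counter = "was_red"),
    iq_abort(sprintf("unknown stain profile '%s'; known profiles: %s",
                     profile_id,
                     paste(known_stain_profiles(), collapse = ", "))))
  c(base, extra)
}

#' Per-stain concentration maps for a synthetic biopsy
#'
#' The structural layer under Beer-Lambert rendering: hematoxylin on every
#' nucleus disc plus a light counterstain of the tissue, DAB over CD3+
#' nucleus discs plus a 1-px halo (only under the `ihc_cd3` profile), and
#' a connective-tissue chromogen over the subepithelial band under the
#' `vg`/`mt`/`was` profiles. Noise-free and deterministic.
#'
#' @param geometry a `mucosa_geometry`.
#' @param cells a cell table from [place_nuclei()].
#' @param profile a [stain_profile()].
#' @return array `H x W x k` of concentrations, `k = length(stain_names)`.
#' @export
stain_concentrations <- function(geometry, cells, profile) {
  p <- geometry$params
  sch <- render_scheme(profile$id)
  H <- p$image_height_px; W <- p$image_width_px
  r_px <- max(1L, as.integer(round(p$nucleus_radius_um / p$um_per_px)))
  k <- length(profile$stain_names)
  conc <- array(0, c(H, W, k))

  hem <- matrix(0, H, W)
  if (sch$counter == "hematoxylin") {
    hem[geometry$mask %in% c(1L, 2L)] <- sch$epi
    hem[geometry$mask == 3L] <- sch$lp
  }
  hem <- paint_discs(hem, cells$row_px, cells$col_px, r_px,
                     sch$nucleus_hem)
  conc[, , match("hematoxylin", profile$stain_names)] <- hem

  if (sch$counter != "hematoxylin") {
    cm <- matrix(0, H, W)
    cm[geometry$mask %in% c(1L, 2L)] <- sch$epi
    cm[geometry$mask == 3L] <- sch$lp
    if (sch$band > 0) cm[geometry$band_mask] <- cm[geometry$band_mask] + sch$band
    conc[, , match(sch$counter, profile$stain_names)] <- cm
  }
  if (profile$id == "ihc_cd3") {
    dab <- matrix(0, H, W)
    pos <- cells[cells$true_class == "CD3_POS", ]
    dab <- paint_discs(dab, pos$row_px, pos$col_px, r_px + 1L,
                       sch$dab_pos)
    conc[, , match("dab", profile$stain_names)] <- dab
  }
  dimnames(conc) <- list(NULL, NULL, profile$stain_names)
  conc
}

#' Render a synthetic biopsy under a stain profile
#'
#' Transmitted intensity per pixel and channel follows Beer-Lambert:
#' `I = I0 * 10^(-sum_s c_s A_s)` with the profile's unit OD vectors
#' `A_s`, plus additive Gaussian noise of standard deviation
#' `params$noise_sd`, clipped to `[0, 1]` and quantised to the 8-bit
#' grid (so written PNGs round-trip bit-identically). The noise stream is
#' spawned from the master seed independently of geometry and nuclei.
#'
#' @param geometry a `mucosa_geometry`.
#' @param cells cell table from [place_nuclei()].
#' @param stain_profile_id profile to render; defaults to the one in
#'   `geometry$params`.
#' @return an object of class `calibrated_image`: list with `pixels`
#'   (`H x W x 3` array in `[0, 1]`), `um_per_px`, `stain_profile_id`,
#'   `I0`.
#' @export
render_biopsy <- function(geometry, cells,
                          stain_profile_id = geometry$params$stain_profile_id) {
  p <- geometry$params
  profile <- stain_profile(stain_profile_id)
  conc <- stain_concentrations(geometry, cells, profile)
  od <- mix_stains(conc, profile)
  img <- sweep(10^(-od), 3, profile$I0, "*")
  if (p$noise_sd > 0) {
    img <- img + with_seed(spawn_seed(p$seed, "render"),
                           array(rnorm(length(img), 0, p$noise_sd),
                                 dim(img)))
  }
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255
  structure(list(pixels = img, um_per_px = p$um_per_px,
                 stain_profile_id = stain_profile_id, I0 = profile$I0),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %dx%d px @ %.3g um/px, profile %s\n",
              d[1], d[2], x$um_per_px, x$stain_profile_id))
  invisible(x)
}

#' Simulate a complete synthetic biopsy with ground truth
#'
#' Convenience wrapper chaining [generate_tissue_geometry()],
#' [place_nuclei()] and [render_biopsy()].
#'
#' @param params a [gen_params()].
#' @return object of class `synthetic_biopsy`: list with `image`
#'   (`calibrated_image`), `mask`, `band_mask`, `cells`, `geometry`,
#'   `params`.
#' @examples
#' b <- simulate_biopsy(gen_params(image_height_px = 256,
#'                                 image_width_px = 256, n_crypts = 1,
#'                                 seed = 3))
#' table(b$cells$compartment)
#' @export
simulate_biopsy <- function(params) {
  geometry <- generate_tissue_geometry(params)
  cells <- place_nuclei(geometry, params)
  image <- render_biopsy(geometry, cells)
  structure(list(image = image, mask = geometry$mask,
                 band_mask = geometry$band_mask, cells = cells,
                 geometry = geometry, params = params),
            class = "synthetic_biopsy")
}

#' @export
print.synthetic_biopsy <- function(x, ...) {
  cat(sprintf("<synthetic_biopsy> %dx%d px, %d cells (%d CD3+), band %g um\n",
              x$params$image_height_px, x$params$image_width_px,
              nrow(x$cells), sum(x$cells$true_class == "CD3_POS"),
              x$params$band_thickness_um))
  invisible(x)
}

#' Write / read a synthetic biopsy fixture directory
#'
#' Writes `image.png` (8-bit RGB), `mask.png` (labels 0-3 stored as
#' 8-bit grey levels), `band.png` (binary), `cells.csv` (exact header
#' `cell_id,row_px,col_px,area_px,true_class,compartment`) and
#' `params.json`. [read_biopsy()] reconstructs the objects bit-identically
#' (images, masks) and value-identically (tables, params).
#'
#' @param biopsy a `synthetic_biopsy`.
#' @param dir output directory (created if needed).
#' @return `read_biopsy` returns a `synthetic_biopsy` without the
#'   `geometry` element.
#' @export
write_biopsy <- function(biopsy, dir) {
  stopifnot(inherits(biopsy, "synthetic_biopsy"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ok <- tryCatch({
    png::writePNG(biopsy$image$pixels, file.path(dir, "image.png"))
    png::writePNG(biopsy$mask / 255, file.path(dir, "mask.png"))
    png::writePNG((biopsy$band_mask * 255) / 255,
                  file.path(dir, "band.png"))
    utils::write.csv(biopsy$cells, file.path(dir, "cells.csv"),
                     row.names = FALSE, quote = FALSE)
    write_gen_params(biopsy$params, file.path(dir, "params.json"))
    TRUE
  }, error = function(e)
    iq_abort(sprintf("failed writing biopsy fixture to '%s': %s",
                     dir, conditionMessage(e))))
  invisible(dir)
}

#' @rdname write_biopsy
#' @export
read_biopsy <- function(dir) {
  for (f in c("image.png", "mask.png", "band.png", "cells.csv",
              "params.json"))
    if (!file.exists(file.path(dir, f)))
      iq_abort(sprintf("missing '%s' in biopsy directory '%s'", f, dir))
  params <- read_gen_params(file.path(dir, "params.json"))
  img <- png::readPNG(file.path(dir, "image.png"))
  mask <- matrix(as.integer(round(
    png::readPNG(file.path(dir, "mask.png")) * 255)),
    nrow = params$image_height_px)
  band <- png::readPNG(file.path(dir, "band.png")) > 0.5
  cells <- as_tibble(utils::read.csv(file.path(dir, "cells.csv"),
                                     stringsAsFactors = FALSE))
  image <- structure(list(pixels = img, um_per_px = params$um_per_px,
                          stain_profile_id = params$stain_profile_id,
                          I0 = stain_profile(params$stain_profile_id)$I0),
                     class = "calibrated_image")
  structure(list(image = image, mask = mask, band_mask = band,
                 cells = cells, params = params),
            class = "synthetic_biopsy")
}
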