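test_that("gen_params validates and round-trips through JSON", {
  expect_error(gen_params(um_per_px = 0), "um_per_px")
  expect_error(gen_params(surface_iel_rate = -1), "surface_iel_rate")
  expect_error(gen_params(stain_profile_id = "xyz"), "known profiles")
  p <- small_params(band_thickness_um = 2.5, noise_sd = 0.01)
  path <- withr::local_tempfile(fileext = ".json")
  write_gen_params(p, path)
  p2 <- read_gen_params(path)
  expect_identical(unclass(p2), unclass(p))
})

test_that("geometry honours crypt count, band thickness and label closure", {
  g0 <- generate_tissue_geometry(small_params(n_crypts = 0))
  expect_setequal(unique(as.integer(g0$mask)), c(0L, 1L, 3L))

  gb0 <- generate_tissue_geometry(small_params(band_thickness_um = 0))
  expect_false(any(gb0$band_mask))

  # per-column run-length oracle: band of 2 um at 0.5 um/px is 4 px deep
  g2 <- generate_tissue_geometry(small_params(band_thickness_um = 2,
                                              um_per_px = 0.5))
  runs <- vapply(seq_len(ncol(g2$mask)), function(cc) {
    col <- g2$band_mask[, cc]
    sum(col)
  }, numeric(1))
  expect_true(all(abs(runs - 4) <= 1))
  # band sits directly beneath the deepest surface-epithelium pixel
  for (cc in seq(1, ncol(g2$mask), by = 37)) {
    rb <- max(which(g2$mask[, cc] == 1L))
    expect_true(all(g2$band_mask[(rb + 1):(rb + 4), cc]))
  }

  g <- generate_tissue_geometry(small_params())
  expect_true(all(as.integer(g$mask) %in% 0:3))
  expect_error(generate_tissue_geometry(small_params(n_crypts = 400)),
               "crypt")
})

test_that("nuclei placement respects rates, compartments and spacing", {
  p <- small_params(surface_iel_rate = 0)
  g <- generate_tissue_geometry(p)
  cells <- place_nuclei(g, p)
  surf <- cells[cells$compartment == "SURFACE", ]
  expect_equal(sum(surf$true_class == "CD3_POS"), 0)

  # no centroid in background; all inside the declared compartment
  idx <- cbind(round(cells$row_px), round(cells$col_px))
  labs <- g$mask[idx]
  expect_true(all(labs != 0L))
  comp_of_label <- c("SURFACE", "CRYPT", "LAMINA_PROPRIA")[labs]
  expect_true(all(comp_of_label == cells$compartment))

  # hard minimum centre-to-centre distance
  d <- as.matrix(dist(cbind(cells$row_px, cells$col_px)))
  diag(d) <- Inf
  expect_gte(min(d), 2 * round(p$nucleus_radius_um / p$um_per_px) + 1)
})

test_that("generator is deterministic given params + seed", {
  p <- small_params(seed = 77)
  b1 <- simulate_biopsy(p)
  b2 <- simulate_biopsy(p)
  expect_identical(b1$mask, b2$mask)
  expect_identical(b1$cells, b2$cells)
  expect_identical(b1$image$pixels, b2$image$pixels)
  b3 <- simulate_biopsy(small_params(seed = 78))
  expect_false(identical(b1$image$pixels, b3$image$pixels))
})

test_that("lamina propria counts follow the Poisson oracle across seeds", {
  lambda <- 500
  n_rep <- 120
  devs <- vapply(seq_len(n_rep), function(k) {
    p <- gen_params(image_height_px = 256, image_width_px = 256,
                    n_crypts = 0, lp_cd3_density = lambda,
                    lp_negative_density = 0, seed = 3000 + k)
    g <- generate_tissue_geometry(p)
    cells <- place_nuclei(g, p)
    area <- sum(g$mask == 3L) * p$um_per_px^2 / 1e6
    c(sum(cells$compartment == "LAMINA_PROPRIA" &
            cells$true_class == "CD3_POS"), lambda * area)
  }, numeric(2))
  total_obs <- sum(devs[1, ]); total_exp <- sum(devs[2, ])
  # Poisson mean/variance oracle: |obs - exp| <= 3 * sqrt(exp)
  expect_lte(abs(total_obs - total_exp), 3 * sqrt(total_exp))
})

test_that("surface IEL marking matches the exact binomial oracle when pooled", {
  rate <- 10
  pos <- 0L; tot <- 0L; k <- 0L
  while (tot < 2000) {
    k <- k + 1L
    p <- gen_params(image_height_px = 256, image_width_px = 1024,
                    n_crypts = 0, surface_iel_rate = rate,
                    lp_cd3_density = 0, lp_negative_density = 0,
                    seed = 4000 + k)
    cells <- place_nuclei(generate_tissue_geometry(p), p)
    surf <- cells[cells$compartment == "SURFACE", ]
    pos <- pos + sum(surf$true_class == "CD3_POS")
    tot <- tot + nrow(surf)
  }
  p0 <- rate / (100 + rate)
  bounds <- qbinom(c(0.005, 0.995), tot, p0)
  expect_gte(pos, bounds[1])
  expect_lte(pos, bounds[2])
  # realised pooled per-100 lies inside the transformed 99% interval
  rate_bounds <- 100 * bounds / (tot - bounds)
  realised <- 100 * pos / (tot - pos)
  expect_gte(realised, rate_bounds[1])
  expect_lte(realised, rate_bounds[2])
})

test_that("rendering follows Beer-Lambert with the stated noise model", {
  # all concentrations zero -> uniform image at I0
  prof <- stain_profile("ihc_cd3")
  od0 <- mix_stains(array(0, c(2, 2, 2)), prof)
  expect_equal(10^(-od0), array(1, c(2, 2, 3)))
  # single pixel, hematoxylin c = 1 -> I = I0 * 10^(-A_hem) channel-wise
  od1 <- mix_stains(array(c(1, 0), c(1, 1, 2)), prof)
  expect_equal(as.numeric(10^(-od1)), 10^(-prof$od_matrix[, 1]),
               tolerance = 1e-12)

  # noise-free render is the quantised Beer-Lambert image exactly
  p <- small_params(noise_sd = 0)
  g <- generate_tissue_geometry(p)
  cells <- place_nuclei(g, p)
  img <- render_biopsy(g, cells)
  conc <- stain_concentrations(g, cells, prof)
  expected <- round(10^(-mix_stains(conc, prof)) * 255) / 255
  expect_equal(img$pixels, expected, tolerance = 1e-12)
})

test_that("band is invisible under HE but strong under connective stains", {
  p <- small_params(band_thickness_um = 2)
  g <- generate_tissue_geometry(p)
  cells <- place_nuclei(g, p)
  contrast <- function(stain) {
    img <- render_biopsy(g, cells, stain)
    od <- total_od(img)
    band_mean <- mean(od[g$band_mask])
    # reference stroma: lamina propria away from nuclei
    ref <- g$mask == 3L & !g$band_mask
    abs(band_mean - median(od[ref]))
  }
  eps <- 0.05
  expect_lt(contrast("he"), eps)
  expect_gt(contrast("vg"), 10 * eps)
})

test_that("fixture files round-trip", {
  b <- small_biopsy()
  dir <- withr::local_tempdir()
  write_biopsy(b, dir)
  r <- read_biopsy(dir)
  expect_identical(r$mask, b$mask)
  expect_identical(r$image$pixels, b$image$pixels)
  expect_identical(unname(r$band_mask), unname(b$band_mask))
  expect_equal(nrow(r$cells), nrow(b$cells))
  expect_equal(as.data.frame(r$cells), as.data.frame(b$cells),
               tolerance = 1e-12)
  expect_identical(unclass(read_gen_params(file.path(dir, "params.json"))),
                   unclass(b$params))
  expect_error(read_biopsy(withr::local_tempdir()), "missing")
})

test_that("lamina propria area bookkeeping matches the density oracle", {
  b <- small_biopsy()
  lp <- lp_density(b$cells, b$mask, b$params$um_per_px,
                   class_col = "true_class")
  manual_area <- sum(b$mask == 3L) * b$params$um_per_px^2 / 1e6
  expect_equal(lp$lp_area_mm2, manual_area, tolerance = 1e-12)
})
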