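mk_cells <- function(pos, neg, compartment = "SURFACE") {
  tibble::tibble(
    compartment = compartment,
    true_class = rep(c("CD3_POS", "CD3_NEG"), c(pos, neg)))
}

test_that("iel_per_100 arithmetic, errors and scale invariance", {
  expect_equal(iel_per_100(mk_cells(5, 100), "SURFACE")$iel_per_100, 5)
  expect_equal(iel_per_100(mk_cells(0, 50), "SURFACE")$iel_per_100, 0)
  expect_equal(iel_per_100(mk_cells(8, 50), "SURFACE")$iel_per_100, 16)
  expect_error(iel_per_100(mk_cells(3, 0), "SURFACE"), "undefined")
  # scale invariance
  for (k in c(2, 5)) {
    expect_equal(iel_per_100(mk_cells(8 * k, 50 * k), "SURFACE")$iel_per_100,
                 16)
  }
  # alternative denominator includes positives
  expect_equal(iel_per_100(mk_cells(10, 90), "SURFACE",
                           denominator = "all")$iel_per_100, 10)
})

test_that("lp_density divides counts by calibrated area", {
  mask1 <- matrix(3L, 100, 100)           # at 10 um/px: exactly 1 mm^2
  cells <- mk_cells(100, 0, "LAMINA_PROPRIA")
  expect_equal(lp_density(cells, mask1, 10)$lp_density_per_mm2, 100)

  mask2 <- matrix(3L, 50, 50)             # 0.25 mm^2
  expect_equal(lp_density(mk_cells(50, 0, "LAMINA_PROPRIA"),
                          mask2, 10)$lp_density_per_mm2, 200)
  # doubling area at fixed count halves density
  mask3 <- matrix(3L, 100, 200)
  expect_equal(lp_density(cells, mask3, 10)$lp_density_per_mm2, 50)
  expect_error(lp_density(cells, matrix(0L, 5, 5), 10), "lamina propria")
})

test_that("lp_density estimates recover the generator intensity across seeds", {
  lambda <- 300
  ests <- vapply(1:40, function(k) {
    p <- gen_params(image_height_px = 256, image_width_px = 256,
                    n_crypts = 0, lp_cd3_density = lambda,
                    lp_negative_density = 100, seed = 5000 + k)
    g <- generate_tissue_geometry(p)
    cells <- place_nuclei(g, p)
    lp_density(cells, g$mask, p$um_per_px)$lp_density_per_mm2
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lte(abs(mean(ests) - lambda), 3 * se)
})

test_that("hotspot window logic and fallback", {
  # all 20 positives inside one 100-negative window -> hotspot 20
  cls <- c(rep("CD3_NEG", 200), rep("CD3_POS", 20), rep("CD3_NEG", 300))
  cells <- tibble::tibble(true_class = cls)
  hs <- hotspot_count(cells, window = 100)
  expect_equal(hs$hotspot_per_100, 20)
  expect_false(hs$fallback)

  # fewer negatives than the window -> global value, flagged
  few <- tibble::tibble(true_class = rep(c("CD3_POS", "CD3_NEG"),
                                         c(4, 40)))
  fb <- hotspot_count(few, window = 100)
  expect_true(fb$fallback)
  expect_equal(fb$hotspot_per_100, 10)

  expect_error(hotspot_count(few, window = 5), ">= 10")
})

test_that("hotspot >= global in every random configuration", {
  st <- hotspot_ordering_study(n_config = 200, seed = 2)
  expect_equal(st$fraction_ge, 1)
  # uniform mixing: hotspot close to global on average
  set.seed(40)
  gaps <- replicate(30, {
    cls <- sample(rep(c("CD3_POS", "CD3_NEG"), c(30, 300)))
    hs <- hotspot_count(tibble::tibble(true_class = cls), window = 100)
    hs$hotspot_per_100 - hs$global_per_100
  })
  expect_lt(mean(gaps), 8)   # excess over global is sampling noise only
})

test_that("band_thickness measures run lengths beneath the epithelium", {
  surface <- matrix(FALSE, 40, 32); surface[5:10, ] <- TRUE
  none <- band_thickness(matrix(FALSE, 40, 32), surface, 0.5)
  expect_equal(none$band_thickness_um, 0L)

  # flat slab T px thick -> round(T * um_per_px)
  for (T_px in c(2, 4, 7)) {
    ev <- matrix(FALSE, 40, 32)
    ev[11:(10 + T_px), ] <- TRUE
    bt <- band_thickness(ev, surface, 0.5)
    expect_equal(bt$band_thickness_um,
                 as.integer(round_half_up(T_px * 0.5)))
  }
  expect_error(band_thickness(matrix(TRUE, 4, 4),
                              matrix(FALSE, 4, 4), 0.5), "surface")
})

test_that("generated bands round-trip through the stain-evidence pipeline", {
  st <- band_recovery_study(thicknesses = 2, stains = "vg", seed = 3)
  vg <- st[st$stain == "vg", ]
  he <- st[st$stain == "he", ]
  expect_equal(vg$measured_um, 2L)
  expect_equal(he$measured_um, 0L)
})

test_that("microscopic colitis calls follow the diagnostic cutoffs", {
  expect_equal(classify_mc(25, 0)$lymphocytic, "LC")
  both <- classify_mc(15, 7)
  expect_equal(both$lymphocytic, "LCi")
  expect_equal(both$collagenous, "CCi")
  norm <- classify_mc(5, 1)
  expect_equal(norm$lymphocytic, "NORMAL")
  expect_equal(norm$collagenous, "NORMAL")
  # boundary cases land in the incomplete category
  expect_equal(classify_mc(20, 10)$lymphocytic, "LCi")
  expect_equal(classify_mc(20, 10)$collagenous, "CCi")
  expect_equal(classify_mc(10, 5)$lymphocytic, "LCi")
  expect_equal(classify_mc(9.99, 4.99)$lymphocytic, "NORMAL")
  expect_error(classify_mc(-1, 0), "non-negative")

  # monotone: increasing either input never moves a call toward NORMAL
  sev <- c(NORMAL = 0, LCi = 1, LC = 2)
  sevc <- c(NORMAL = 0, CCi = 1, CC = 2)
  iels <- c(0, 5, 10, 15, 20, 20.5, 25)
  bands <- c(0, 4, 5, 8, 10, 10.5, 14)
  calls <- classify_mc(rep(iels, each = length(bands)),
                       rep(bands, times = length(iels)))
  lg <- matrix(sev[calls$lymphocytic], length(bands))
  cg <- matrix(sevc[calls$collagenous], length(bands))
  expect_true(all(apply(lg, 1, diff) >= 0))   # across iel grid
  expect_true(all(apply(cg, 2, diff) >= 0))   # across band grid
})

test_that("quantify_biopsy assembles a consistent per-biopsy record", {
  b <- small_biopsy()
  q <- quantify_biopsy(b$cells, b$mask, b$band_mask, b$params$um_per_px,
                       biopsy_id = "t1", location = "ILEUM")
  expect_equal(q$surface_iel_per_100,
               100 * q$surface_pos / q$surface_neg)
  expect_equal(q$crypt_iel_per_100, 100 * q$crypt_pos / q$crypt_neg)
  expect_equal(q$lp_density_per_mm2, q$lp_pos_count / q$lp_area_mm2)
  expect_equal(q$band_thickness_um,
               b$params$band_thickness_um)
  expect_true(q$lymphocytic_call %in% c("NORMAL", "LCi", "LC"))
})
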