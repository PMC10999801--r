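# paint a synthetic total-OD image with discs of radius r at the given
# centres (independent of the package's renderer)
disc_image <- function(H, W, centers, r = 2, value = 1.2) {
  od <- matrix(0, H, W)
  for (i in seq_len(nrow(centers))) {
    for (dr in -r:r) for (dc in -r:r) {
      if (dr^2 + dc^2 <= r^2) {
        rr <- centers[i, 1] + dr; cc <- centers[i, 2] + dc
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W)
          od[rr, cc] <- value
      }
    }
  }
  od
}

test_that("detect_nuclei finds isolated nuclei and nothing on blank images", {
  expect_equal(nrow(detect_nuclei(matrix(0, 60, 60))), 0)

  set.seed(9)
  centers <- as.matrix(expand.grid(row = seq(15, 95, by = 20),
                                   col = seq(15, 95, by = 20)))
  od <- disc_image(100, 100, centers)
  det <- detect_nuclei(od)
  expect_equal(nrow(det), 25)
  m <- detection_metrics(det,
                         tibble::tibble(row_px = centers[, 1],
                                        col_px = centers[, 2]),
                         match_radius_px = 3)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
})

test_that("two nuclei beyond 1.5 diameters stay separate; touching pairs split", {
  od <- disc_image(40, 60, rbind(c(20, 20), c(20, 34)), r = 3)
  expect_equal(nrow(detect_nuclei(od)), 2)
  # touching pair (one connected component): split by the watershed
  od2 <- disc_image(40, 60, rbind(c(20, 25), c(20, 33)), r = 4)
  det2 <- detect_nuclei(od2)
  expect_equal(nrow(det2), 2)
})

test_that("detection is translation-equivariant", {
  centers <- rbind(c(12, 14), c(25, 30), c(33, 11))
  od <- disc_image(60, 60, centers)
  d1 <- detect_nuclei(od)
  dy <- 7; dx <- 11
  od2 <- disc_image(60, 60, centers + rep(c(dy, dx), each = 3))
  d2 <- detect_nuclei(od2)
  expect_equal(nrow(d2), nrow(d1))
  expect_equal(d2$row_px, d1$row_px + dy, tolerance = 1e-9)
  expect_equal(d2$col_px, d1$col_px + dx, tolerance = 1e-9)
})

test_that("positivity uses a strict threshold on the disc+halo mean", {
  dab <- matrix(0, 30, 30)
  dab[10:20, 10:20] <- 0.6
  cells <- tibble::tibble(row_px = 15, col_px = 15)
  # disc entirely inside the plateau: mean exactly 0.6
  hit <- classify_positivity(cells, dab, threshold_od = 0.5, radius_px = 2)
  expect_equal(hit$predicted_class, "CD3_POS")
  expect_equal(hit$mean_dab_od, 0.6)
  # mean exactly equal to the threshold -> negative (strict >)
  tie <- classify_positivity(cells, dab, threshold_od = 0.6, radius_px = 2)
  expect_equal(tie$predicted_class, "CD3_NEG")
  expect_error(classify_positivity(tibble::tibble(row_px = 99, col_px = 1),
                                   dab, 0.3), "outside")
})

test_that("positivity calling is >= 98% accurate on rendered cells at default noise", {
  b <- small_biopsy()
  prof <- stain_profile("ihc_cd3")
  conc <- unmix_stains(rgb_to_od(b$image$pixels, prof$I0), prof)
  cells <- classify_positivity(b$cells, conc[, , "dab"],
                               threshold_od = 0.3)
  acc <- mean(cells$predicted_class == cells$true_class)
  expect_gte(acc, 0.98)
})

test_that("increasing the threshold never increases the positive count", {
  b <- small_biopsy()
  prof <- stain_profile("ihc_cd3")
  conc <- unmix_stains(rgb_to_od(b$image$pixels, prof$I0), prof)
  counts <- vapply(seq(0.05, 0.9, by = 0.05), function(thr)
    sum(classify_positivity(b$cells, conc[, , "dab"],
                            thr)$predicted_class == "CD3_POS"),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("calibrate_threshold is the class-means midpoint", {
  cells <- tibble::tibble(
    true_class = rep(c("CD3_POS", "CD3_NEG"), each = 4),
    mean_dab_od = rep(c(0.9, 0.1), each = 4))
  expect_equal(calibrate_threshold(cells)$threshold_od, 0.5)
  # order of classes in the table is irrelevant
  expect_equal(calibrate_threshold(cells[sample(8), ])$threshold_od, 0.5)
  expect_error(calibrate_threshold(cells[cells$true_class == "CD3_POS", ]),
               "both")
})

test_that("calibrated threshold classifies held-out fixtures at >= 98% accuracy", {
  b <- small_biopsy()
  prof <- stain_profile("ihc_cd3")
  conc <- unmix_stains(rgb_to_od(b$image$pixels, prof$I0), prof)
  labeled <- measure_dab(b$cells, conc[, , "dab"])
  thr <- calibrate_threshold(labeled)$threshold_od
  held <- simulate_biopsy(small_params(seed = 931))
  conc2 <- unmix_stains(rgb_to_od(held$image$pixels, prof$I0), prof)
  pred <- classify_positivity(held$cells, conc2[, , "dab"], thr)
  expect_gte(mean(pred$predicted_class == pred$true_class), 0.98)
})

test_that("compartment assignment follows the centroid pixel", {
  mask <- matrix(0L, 10, 10)
  mask[6:10, ] <- 3L
  mask[3, 3] <- 2L
  cells <- tibble::tibble(row_px = c(3, 1, 8), col_px = c(3, 1, 5))
  out <- assign_compartment(cells, mask)
  expect_equal(out$compartment, c("CRYPT", "EXCLUDED", "LAMINA_PROPRIA"))

  b <- small_biopsy()
  reassigned <- assign_compartment(b$cells, b$mask)
  expect_gte(mean(reassigned$compartment == b$cells$compartment), 0.95)
})

test_that("detection_metrics counts greedily matched pairs", {
  truth <- tibble::tibble(row_px = c(5, 15, 25), col_px = c(5, 15, 25))
  exact <- detection_metrics(truth, truth, 2)
  expect_equal(exact$precision, 1)
  expect_equal(exact$recall, 1)

  none <- detection_metrics(truth[0, ], truth, 2)
  expect_equal(none$recall, 0)

  # k spurious detections -> precision n / (n + k) exactly
  k <- 4
  spurious <- dplyr::bind_rows(
    truth, tibble::tibble(row_px = 40 + seq_len(k) * 3, col_px = 40))
  sp <- detection_metrics(spurious, truth, 2)
  expect_equal(sp$precision, 3 / (3 + k))
  expect_equal(sp$recall, 1)
})
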