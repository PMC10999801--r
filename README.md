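# ielquant

Digital quantification of intraepithelial lymphocytes (IELs) and the
subepithelial connective-tissue band in colonic and ileal mucosa.

## The problem

Microscopic colitis (MC) is diagnosed on histology in patients with
chronic watery diarrhea and a macroscopically normal colon. Its two forms
have quantitative criteria: **lymphocytic colitis** (LC) requires more
than 20 IELs per 100 surface epithelial cells (10–20 defines the
incomplete form, LCi), and **collagenous colitis** (CC) requires a
subepithelial collagen band thicker than 10 µm (5–10 µm defines CCi).
Both quantities depend heavily on *how* they are measured: CD3
immunohistochemistry highlights lymphocytes that HE hides, connective
stains reveal a thin subepithelial band invisible on HE, and digital
whole-compartment counting differs systematically from manual hotspot
counting. `ielquant` is for pathologists and image-analysis researchers
who want a fully reproducible, testable implementation of that digital
measurement chain.

## What the package implements

- **Synthetic stained-histology generator** with complete pixel-level
  ground truth: compartment masks (background, surface epithelium, crypt
  epithelium, lamina propria), per-cell class labels, and band masks,
  rendered under Beer–Lambert optics
  (`I = I0 · 10^(−Σ c_s A_s)`) for CD3-IHC, HE, Van Gieson, Masson
  Trichrome and Weigert-Alcian-Sirius profiles.
- **Colour deconvolution** (`rgb_to_od()`, `unmix_stains()`) with the
  Ruifrok–Johnston stain vectors.
- **Four-class tissue segmentation** at a reduced working scale
  (random-forest pixel classifier trained from labeled ROIs, mode filter
  and minimum-region cleanup).
- **Nucleus detection** (smooth → threshold → distance-transform
  watershed) and **CD3 positivity calling** by a strict threshold on the
  mean DAB signal over the nucleus disc + halo, with midpoint threshold
  calibration.
- **Per-biopsy metrics**: IELs per 100 epithelial cells per compartment
  (`100·pos/neg`), lamina propria CD3⁺ density per mm², hotspot window
  counts, band thickness in µm, and the MC diagnostic calls.
- **Statistics**: means with 95 % t-intervals and ranges, paired
  t-test, an exact **Wilcoxon–Pratt signed-rank test** (zeros ranked then
  discarded; exact enumeration up to m = 20, labeled normal approximation
  beyond), Bonferroni thresholds, frequency tables with not-assessed
  denominators, and a pairwise stain-comparison report.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and result types have `autoplot()`/`plot_*()`
helpers.

## Worked example

Simulate a biopsy with known ground truth, train the segmenter, calibrate
the positivity threshold, and quantify:

```r
library(ielquant)

# a synthetic biopsy: 10 IELs/100 target in the surface epithelium,
# 300 CD3+ cells/mm^2 in the lamina propria, 1 um band
params <- gen_params(surface_iel_rate = 10, lp_cd3_density = 300, seed = 42)
biopsy <- simulate_biopsy(params)

# train the 4-class segmenter on ROIs from three other synthetic slides
train <- lapply(1:3, function(i) simulate_biopsy(gen_params(seed = 100 + i)))
rois  <- do.call(c, lapply(seq_along(train), function(i)
  sample_rois(train[[i]], n_rois = 8, seed = 200 + i)))
model <- train_segmenter(extract_training_set(rois), seed = 1)

# calibrate the DAB threshold on labeled training cells
prof    <- stain_profile("ihc_cd3")
conc    <- unmix_stains(rgb_to_od(train[[1]]$image$pixels, prof$I0), prof)
labeled <- measure_dab(train[[1]]$cells, conc[, , "dab"])
thr     <- calibrate_threshold(labeled)$threshold_od

# full pipeline: segment -> detect -> classify -> quantify
res <- analyze_biopsy(biopsy$image, model, thr, location = "RIGHT_COLON")
res$quant
```

```
#> # A tibble: 1 × 14
#>   biopsy_id location    surface_pos surface_neg surface_iel_per_100 crypt_pos
#>   <chr>     <chr>             <int>       <int>               <dbl>     <int>
#> 1 biopsy    RIGHT_COLON          16         131                12.2        10
#>   crypt_neg crypt_iel_per_100 lp_pos_count lp_area_mm2 lp_density_per_mm2
#>       <int>             <dbl>        <int>       <dbl>              <dbl>
#> 1       166              6.02           33       0.111               296.
#> # ℹ 3 more variables: band_thickness_um <int>, lymphocytic_call <chr>,
#> #   collagenous_call <chr>
```

The generator realised 16 CD3⁺ and 125 CD3⁻ surface epithelial cells —
12.8 per 100, the target rate of 10 plus binomial sampling noise in a
single ~140-cell biopsy. The pipeline found all 16 positives and reports
12.2 per 100; the small denominator difference (131 vs 125) comes from a
few lamina propria nuclei landing on the predicted-mask side of the
epithelial boundary. Both land in the 10–20 band, so `lymphocytic_call`
is `LCi`. Comparing against truth:

```r
iel_per_100(biopsy$cells, "SURFACE", class_col = "true_class")
#> # A tibble: 1 × 4
#>   compartment   pos   neg iel_per_100
#>   <chr>       <int> <int>       <dbl>
#> 1 SURFACE        16   125        12.8
```

The statistics layer works on plain tibbles:

```r
wilcoxon_pratt(c(1, 2, 3), c(0, 0, 0))   # exact two-sided p = 0.25
bonferroni(0.05, 6)                      # threshold 0.00833, reported "<0.008"
frequency_table(rep(c(1, 2, 3), c(43, 8, 1)))$pct   # 82.7 15.4 1.9
```

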