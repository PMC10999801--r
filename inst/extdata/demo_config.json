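{
  "n_per_location": {"ILEUM": 2, "RIGHT_COLON": 2, "LEFT_COLON": 2},
  "gen": {"image_height_px": 512, "image_width_px": 768, "n_crypts": 4},
  "n_train_images": 3,
  "rois_per_image": 8,
  "threshold_od": "auto",
  "hotspot_window": 100,
  "denominator": "negative",
  "alpha": 0.05,
  "exact_cutoff": 20
}
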