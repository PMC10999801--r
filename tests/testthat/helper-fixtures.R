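# shared fixtures, built lazily once per test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), .fixtures)
  get(name, envir = .fixtures)
}

# small, fast biopsy parameters used across module tests
small_params <- function(...) {
  args <- utils::modifyList(
    list(image_height_px = 320, image_width_px = 512, n_crypts = 2,
         seed = 421),
    list(...))
  do.call(gen_params, args)
}

small_biopsy <- function() fixture("small_biopsy", function()
  simulate_biopsy(small_params()))

# a small trained segmenter + the held-out biopsy it is scored on
small_segmenter <- function() fixture("small_segmenter", function() {
  train_b <- lapply(1:3, function(i)
    simulate_biopsy(small_params(seed = 500 + i)))
  rois <- do.call(c, lapply(seq_along(train_b), function(i)
    sample_rois(train_b[[i]], n_rois = 8, seed = 600 + i)))
  train_segmenter(extract_training_set(rois), seed = 7)
})

# independent brute-force oracle for the Wilcoxon-Pratt exact test:
# explicit enumeration of all 2^m sign assignments via expand.grid
wilcoxon_pratt_bruteforce <- function(x, y) {
  d <- x - y
  r <- rank(abs(d))
  nz <- d != 0
  m <- sum(nz)
  w_obs <- sum(r[nz & d > 0])
  if (m == 0) return(list(statistic = w_obs, p_value = 1))
  rk <- r[nz]
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.numeric(signs %*% rk)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  list(statistic = w_obs, p_value = min(1, 2 * min(p_le, p_ge)))
}
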