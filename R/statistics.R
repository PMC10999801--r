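#' Summary statistics: mean, 95% CI and range
#'
#' Mean with the two-sided 95% t-interval
#' (`mean +/- t_{0.975, n-1} * sd / sqrt(n)`) and the range, the format
#' used for reporting IEL counts. With `n = 1` the CI is undefined and
#' flagged.
#'
#' @param x numeric vector (NAs dropped) or a data frame.
#' @param col column to summarise when `x` is a data frame.
#' @param conf confidence level (default 0.95).
#' @return one-row tibble: `n`, `mean`, `ci_low`, `ci_high`, `min`,
#'   `max`, `ci_defined`.
#' @examples
#' summarize_values(c(1, 2, 3, 4, 5))
#' @export
summarize_values <- function(x, col = NULL, conf = 0.95) {
  if (is.data.frame(x)) {
    col <- rlang::enquo(col)
    x <- dplyr::pull(x, !!col)
  }
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) iq_abort("no non-missing values to summarise")
  m <- mean(x)
  if (n >= 2) {
    half <- qt(1 - (1 - conf) / 2, n - 1) * stats::sd(x) / sqrt(n)
    tibble(n = n, mean = m, ci_low = m - half, ci_high = m + half,
           min = min(x), max = max(x), ci_defined = TRUE)
  } else {
    tibble(n = n, mean = m, ci_low = NA_real_, ci_high = NA_real_,
           min = min(x), max = max(x), ci_defined = FALSE)
  }
}

#' Assemble a paired sample from two measurement columns
#'
#' Pairs are matched by subject id; pairs with any missing member are
#' excluded from testing and counted.
#'
#' @param data data frame.
#' @param x,y columns with the two paired measurements (tidy-eval).
#' @param subject optional subject id column; defaults to row order.
#' @return list of class `paired_sample` with complete-case vectors
#'   `x`, `y` and `n_excluded`.
#' @export
paired_sample <- function(data, x, y, subject = NULL) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- !is.na(xv) & !is.na(yv)
  structure(list(x = xv[ok], y = yv[ok], n_excluded = sum(!ok)),
            class = "paired_sample")
}

as_paired <- function(data, x, y) {
  if (inherits(data, "paired_sample")) return(data)
  if (is.data.frame(data)) return(paired_sample(data, {{ x }}, {{ y }}))
  # two bare numeric vectors
  ok <- !is.na(data) & !is.na(x)
  structure(list(x = data[ok], y = x[ok], n_excluded = sum(!ok)),
            class = "paired_sample")
}

new_test_result <- function(method, statistic, p_value, n_used,
                            n_excluded) {
  structure(tibble(method = method, statistic = statistic,
                   p_value = p_value, n_used = n_used,
                   n_excluded = n_excluded),
            class = c("iq_test", "tbl_df", "tbl", "data.frame"))
}

#' Paired t-test
#'
#' Two-sided paired t-test, `t = dbar / (s_d / sqrt(n))` with `n - 1`
#' degrees of freedom (delegated to [stats::t.test()]).
#'
#' @param data a data frame (with `x`, `y` column selections), a
#'   `paired_sample`, or a numeric vector (with `x` the second vector).
#' @param x,y columns / second vector, see `data`.
#' @return one-row tibble (class `iq_test`): `method = "PAIRED_T"`,
#'   `statistic`, `p_value`, `n_used`, `n_excluded`.
#' @examples
#' paired_t(c(1, 2, 4), c(0, 0, 1))
#' @export
paired_t <- function(data, x = NULL, y = NULL) {
  ps <- as_paired(data, {{ x }}, {{ y }})
  n <- length(ps$x)
  if (n < 2) iq_abort("paired t-test needs >= 2 complete pairs")
  d <- ps$x - ps$y
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(new_test_result("PAIRED_T", 0, 1, n, ps$n_excluded))
    iq_abort("paired t-test degenerate: zero variance of differences")
  }
  tt <- stats::t.test(ps$x, ps$y, paired = TRUE)
  new_test_result("PAIRED_T", unname(tt$statistic), tt$p.value, n,
                  ps$n_excluded)
}

#' Exact Wilcoxon-Pratt signed-rank test
#'
#' Paired signed-rank test with Pratt handling of zero differences:
#' zeros participate in the ranking of `|d|` (mid-ranks for ties) and
#' their rank contribution is then discarded. For `m <= exact_cutoff`
#' nonzero differences the two-sided p-value is exact over all `2^m`
#' sign assignments (computed by dynamic-programming convolution of the
#' rank-sum distribution, which enumerates the assignments implicitly);
#' beyond the cutoff a zero- and tie-corrected normal approximation is
#' used and labeled as such. Two-sided p is
#' `min(1, 2 * min(P(W+ <= w), P(W+ >= w)))`.
#'
#' @inheritParams paired_t
#' @param exact_cutoff largest `m` for which the exact distribution is
#'   computed (default 20).
#' @return one-row tibble (class `iq_test`): `method`
#'   (`WILCOXON_PRATT_EXACT` or `WILCOXON_PRATT_APPROX`), `statistic`
#'   (`W+`, the positive rank sum), `p_value`, `n_used`, `n_excluded`.
#' @examples
#' wilcoxon_pratt(c(1, 2, 3), c(0, 0, 0))  # exact p = 0.25
#' @export
wilcoxon_pratt <- function(data, x = NULL, y = NULL, exact_cutoff = 20) {
  ps <- as_paired(data, {{ x }}, {{ y }})
  n <- length(ps$x)
  if (n < 1) iq_abort("wilcoxon_pratt needs >= 1 complete pair")
  d <- ps$x - ps$y
  r <- rank(abs(d))            # Pratt: zeros ranked, then discarded
  nz <- d != 0
  m <- sum(nz)
  w_pos <- sum(r[nz & d > 0])
  if (m == 0)
    return(new_test_result("WILCOXON_PRATT_EXACT", w_pos, 1, n,
                           ps$n_excluded))
  rk <- r[nz]
  if (m <= exact_cutoff) {
    # distribution of W+ over all 2^m sign assignments, on a half-rank
    # integer grid (mid-ranks are multiples of 1/2)
    ri <- as.integer(round(2 * rk))
    tot <- sum(ri)
    f <- numeric(tot + 1)      # f[s+1] = #assignments with 2*W+ == s
    f[1] <- 1
    for (v in ri) {
      g <- numeric(tot + 1)
      g[(v + 1):(tot + 1)] <- f[1:(tot + 1 - v)]
      f <- f + g
    }
    f <- f / 2^m
    w2 <- as.integer(round(2 * w_pos))
    p_le <- sum(f[seq_len(w2 + 1)])
    p_ge <- sum(f[(w2 + 1):(tot + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    new_test_result("WILCOXON_PRATT_EXACT", w_pos, p, n, ps$n_excluded)
  } else {
    # zero- and tie-corrected normal approximation (Pratt/Cureton)
    z0 <- n - m
    e_w <- (n * (n + 1) / 2 - z0 * (z0 + 1) / 2) / 2
    ties <- table(rk)
    v_w <- (n * (n + 1) * (2 * n + 1) -
              z0 * (z0 + 1) * (2 * z0 + 1)) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w_pos - e_w) / sqrt(v_w)
    p <- min(1, 2 * pnorm(-abs(z)))
    new_test_result("WILCOXON_PRATT_APPROX", w_pos, p, n, ps$n_excluded)
  }
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / m`, together with the conventional reporting threshold
#' truncated to three decimals (0.05 / 6 is reported as "<0.008").
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return one-row tibble: `alpha`, `m`, `threshold`,
#'   `reported_threshold` (numeric, truncated to 3 decimals) and
#'   `reported` (the "<x" string).
#' @examples
#' bonferroni(0.05, 6)
#' @export
bonferroni <- function(alpha = 0.05, m = 1) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    iq_abort("alpha must be in (0, 1)")
  if (!is.numeric(m) || m < 1) iq_abort("m must be >= 1")
  thr <- alpha / m
  rep_thr <- floor(thr * 1000) / 1000
  tibble(alpha = alpha, m = as.integer(m), threshold = thr,
         reported_threshold = rep_thr,
         reported = sprintf("<%.3g", rep_thr))
}

#' Ordinal frequency table with a not-assessed denominator
#'
#' Counts and percentages per category, the percentage denominator being
#' the assessed observations only (`NA` = not assessed, counted
#' separately). Percentages are rounded half-up to one decimal.
#'
#' @param x vector of ordinal values (`NA` = not assessed) or a data
#'   frame.
#' @param col column when `x` is a data frame.
#' @param categories category values; default the sorted unique assessed
#'   values. All assessed values must be covered.
#' @return tibble with one row per category: `category`, `n`, `pct`;
#'   attributes `n_assessed` and `n_not_assessed`.
#' @examples
#' ft <- frequency_table(rep(c(1, 2, 3), c(43, 8, 1)))
#' ft$pct  # 82.7 15.4 1.9
#' @export
frequency_table <- function(x, col = NULL, categories = NULL) {
  if (is.data.frame(x)) {
    col <- rlang::enquo(col)
    x <- dplyr::pull(x, !!col)
  }
  n_na <- sum(is.na(x))
  x <- x[!is.na(x)]
  if (!length(x)) iq_abort("no assessed values")
  categories <- categories %||% sort(unique(x))
  if (!all(x %in% categories))
    iq_abort("values outside the supplied categories")
  cnt <- vapply(categories, function(k) sum(x == k), numeric(1))
  out <- tibble(category = categories, n = as.integer(cnt),
                pct = round_half_up(100 * cnt / length(x), 1))
  attr(out, "n_assessed") <- length(x)
  attr(out, "n_not_assessed") <- n_na
  out
}

#' Pairwise comparison report for band thickness across stains
#'
#' For each intestinal location, runs one exact Wilcoxon-Pratt test per
#' stain comparison on the complete-case paired values, and flags
#' significance against the Bonferroni threshold derived from the number
#' of comparisons at that location.
#'
#' @param data long-format tibble with columns `biopsy_id`, `location`,
#'   `stain` (condition) and `value`.
#' @param comparisons list of length-2 character vectors naming the
#'   conditions to compare; default all pairs of observed stains.
#' @param alpha family-wise error rate per location.
#' @param exact_cutoff passed to [wilcoxon_pratt()].
#' @return tibble with one row per comparison x location: `location`,
#'   `comparison`, `method`, `statistic`, `p_value`, `n_used`,
#'   `n_excluded`, `bonferroni_threshold`, `significant`.
#' @export
pairwise_comparison_report <- function(data, comparisons = NULL,
                                       alpha = 0.05, exact_cutoff = 20) {
  stopifnot(all(c("biopsy_id", "location", "stain", "value") %in%
                  names(data)))
  stains <- unique(data$stain)
  comparisons <- comparisons %||%
    utils::combn(stains, 2, simplify = FALSE)
  m <- length(comparisons)
  thr <- bonferroni(alpha, m)$threshold
  purrr::map_dfr(unique(data$location), function(loc) {
    dloc <- data[data$location == loc, ]
    purrr::map_dfr(comparisons, function(cmp) {
      for (cond in cmp)
        if (!cond %in% dloc$stain)
          iq_abort(sprintf("condition '%s' missing at location %s",
                           cond, loc))
      wide <- tidyr::pivot_wider(
        dloc[dloc$stain %in% cmp, c("biopsy_id", "stain", "value")],
        names_from = "stain", values_from = "value")
      res <- wilcoxon_pratt(wide, !!rlang::sym(cmp[1]),
                            !!rlang::sym(cmp[2]),
                            exact_cutoff = exact_cutoff)
      dplyr::mutate(res,
                    location = loc,
                    comparison = paste(cmp[1], "vs", cmp[2]),
                    bonferroni_threshold = thr,
                    significant = .data$p_value < thr,
                    .before = 1)
    })
  })
}

#' Included-cohort arithmetic
#'
#' Applies stated exclusions to an enrolled count — bookkeeping for
#' flow-diagram style reporting.
#'
#' @param enrolled number enrolled.
#' @param exclusions named or unnamed numeric vector of exclusion counts.
#' @return one-row tibble: `enrolled`, `excluded`, `included`.
#' @examples
#' cohort_flow(78, c(diarrhea = 16, adenocarcinoma = 1))$included  # 61
#' @export
cohort_flow <- function(enrolled, exclusions = numeric(0)) {
  assert_scalar_num(enrolled, "enrolled", 0)
  if (any(exclusions < 0)) iq_abort("exclusion counts must be >= 0")
  excl <- sum(exclusions)
  if (excl > enrolled) iq_abort("cannot exclude more than enrolled")
  tibble(enrolled = as.integer(enrolled), excluded = as.integer(excl),
         included = as.integer(enrolled - excl))
}
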