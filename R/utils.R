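#' Round half away from zero
#'
#' Decimal rounding with the half-up tie rule used when reporting
#' percentages and band thickness, as opposed to [base::round()]'s
#' round-half-even behaviour (so 82.65 -> 82.7, 2.5 -> 3).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a per-stage substream seed from a master seed
#'
#' Each pipeline stage (geometry, nuclei, render noise, ...) draws from its
#' own deterministic substream so stages are independently reproducible:
#' changing the render noise seed does not perturb the placed nuclei.
#'
#' @param master integer master seed.
#' @param stage character stage tag.
#' @return an integer seed in `[0, 2^31)`.
#' @export
spawn_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  # small multiplicative hash over the stage tag, kept inside 32-bit range
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(master) %% 2147483647 * 7919 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# stop() with a consistent class so callers can distinguish package errors
iq_abort <- function(msg, class = "ielquant_error") {
  abort(msg, class = class)
}

assert_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    iq_abort(sprintf("`%s` must be a single finite number", name))
  if ((strict && x <= min) || (!strict && x < min))
    iq_abort(sprintf("`%s` must be %s %s", name,
                     if (strict) ">" else ">=", format(min)))
  invisible(x)
}
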