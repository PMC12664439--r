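# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched, so seeded operations are reproducible and composable.
with_local_seed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed)) {
    abort("`seed` must be a finite integer (reproducibility is never implicit).")
  }
  withr::with_seed(as.integer(seed), expr)
}

# Derive a per-unit seed from a master seed and an index, kept inside the
# 32-bit signed range R requires of set.seed().
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) + as.numeric(index)) %% .Machine$integer.max)
}

#' Round a fraction to an integer percent, half away from zero
#'
#' Reporting convention for DNA sensitive-volume fractions: the unrounded
#' fraction is always available, and the integer percent (half-up rounding,
#' so 0.065 -> 7) is what summary tables print.
#'
#' @param fraction Numeric fraction in `[0, 1]`.
#' @return Integer percent.
#' @examples
#' round_percent(0.066)
#' @export
round_percent <- function(fraction) {
  stopifnot(is.numeric(fraction))
  as.integer(floor(fraction * 100 + 0.5))
}

stop_if_not_positive <- function(..., .allow_zero = FALSE) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    bad <- if (.allow_zero) any(!is.finite(v) | v < 0) else any(!is.finite(v) | v <= 0)
    if (bad) {
      abort(sprintf(
        "`%s` must be %s and finite (got %s).",
        nms[i], if (.allow_zero) "non-negative" else "strictly positive",
        paste(format(head(v, 3)), collapse = ", ")
      ))
    }
  }
  invisible(TRUE)
}

# keV -> joule (CODATA elementary charge; 1 keV = 1e3 eV).
KEV_TO_JOULE <- 1.602176634e-16
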