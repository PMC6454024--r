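## Percentages in summary reports are rounded half up (95.49 -> 95,
## 88.63 -> 89), not to even, so printed overlap figures match the
## integer-percent style of the field's tables.

#' Round half up
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return `x` rounded with ties going away from zero toward +Inf.
#' @examples
#' roundHalfUp(c(0.5, 1.5, 95.49, 88.63))
#' @export
roundHalfUp <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Report a share as an integer percentage
#'
#' @param num,den numerator and denominator counts.
#' @return `100 * num/den` rounded half up to the nearest integer.
#' @examples
#' reportPercent(3156, 3305)  # 95
#' reportPercent(3156, 3561)  # 89
#' @export
reportPercent <- function(num, den) {
  roundHalfUp(100 * num / den)
}

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Deterministic sub-seed derivation so one user seed governs several
## independent random stages without reusing streams. Kept below 2^31.
deriveSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %%
             2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
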