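# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Print a double so that parsing it back reproduces the value bit-for-bit.
num17 <- function(x) sprintf("%.17g", x)

#' Round half away from zero
#'
#' Rounding used when comparing computed accuracy statistics with values
#' printed at a fixed number of decimals (base [round()] rounds half to
#' even, which never matches hand-rounded tables).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded half-up (away from zero) to `digits` decimals.
#' @export
#' @examples
#' round_half_up(80.75, 1) # 80.8
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
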