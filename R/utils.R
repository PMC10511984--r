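# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Display rounding used for reported statistics: 0.5 always rounds up in
#' magnitude (so 0.845 -> 0.85 at 2 dp), unlike [base::round()]'s
#' round-half-even. Used wherever values are compared against published
#' tables printed at fixed precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` places.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with the caller's function name stripped, keeping messages terse.
stop2 <- function(...) stop(..., call. = FALSE)

fmt_pct <- function(x, digits = 1) {
  paste0(formatC(round_half_up(100 * x, digits), format = "f",
                 digits = digits), "%")
}
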