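#' Round half up
#'
#' Commercial (round-half-up) rounding to a fixed number of decimals. Cohort
#' percentages are conventionally reported this way (14.715 -> 14.72), whereas
#' [base::round()] rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep (default 2).
#' @return numeric vector of `x` rounded half-up.
#' @export
#' @examples
#' round_half_up(c(14.715, 65.275), 2)
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # small epsilon guards against representation error (e.g. 30.155 stored
  # as 30.15499999...); magnitudes here are percentages, well within range
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Evaluate `expr` under a temporary RNG seed, restoring prior RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
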