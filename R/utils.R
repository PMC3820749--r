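#' Round half away from zero
#'
#' Deterministic "half-up" rounding at a fixed number of decimal digits,
#' matching how percentages are conventionally printed in tables (12.5 -> 13),
#' unlike [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep (default 0).
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.5)       # 1
#' round_half_up(52.78)     # 53
#' round_half_up(27.995, 1) # 28.0
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  f <- 10^digits
  # small epsilon guards against 42.000000000000004-style representation error
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the previous RNG state so
#' callers' random streams are not perturbed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# shared argument checks ------------------------------------------------------

stop_validation <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_validation(name, " must be a single value in [0, 1]")
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || any(is.na(x)) || (strict && any(x <= 0)) ||
      (!strict && any(x < 0)))
    stop_validation(name, if (strict) " must be > 0" else " must be >= 0")
  invisible(x)
}
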