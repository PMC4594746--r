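#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.005 -> 0.01), the convention used
#' for the percentage tables, as opposed to [round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# stopifnot with a formatted message
abort_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
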