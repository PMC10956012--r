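#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr as-is.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Population standard deviation (divisor n, not n-1): standardization of
# pixel features uses the population convention so that two values {0, 2}
# map to {-1, +1}.
#' @noRd
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
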