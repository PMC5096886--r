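#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations inside the
#' package do not disturb the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG stream untouched.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed and a stream label
#'
#' Deterministic, collision-poor mapping used so that one pipeline seed
#' drives every stochastic stage independently. Result is always a valid
#' 32-bit R integer.
#'
#' @param seed parent integer seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return integer seed.
#' @export
derive_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (cc in utf8ToInt(lab)) h <- (h * 31 + cc) %% 2147483563
  as.integer(h + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hv <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_hv <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# sd with explicit n-1 denominator (stats::sd already uses n-1; kept as a
# named alias so the convention is visible at call sites)
sd_n1 <- function(x) stats::sd(x)
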