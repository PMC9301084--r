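#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; interval widths are reported
#' with conventional half-up rounding (4.215 Mb prints as 4.22 Mb).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @keywords internal
roundHalfUp <- function(x, digits = 0L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Evaluate `expr` under a private RNG scope seeded with `seed`; the caller's
# .Random.seed is restored on exit. seed = NULL uses the ambient stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Greatest common divisor of a vector of non-negative integers.
.gcd <- function(x) {
  g2 <- function(a, b) if (b == 0) a else g2(b, a %% b)
  Reduce(g2, x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
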