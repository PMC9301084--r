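#' Simulate phenotyping records from known truth
#'
#' Inverts the pigment equations and emits raw records that, passed back
#' through \code{\link{pigmentsFromAbsorbance}} and
#' \code{\link{fluorescenceParams}} at zero noise, recover the generating
#' truth exactly (round-trip property).  The 2x2 linear system of the
#' Chl a / Chl b equations is solved for (OD663, OD645), and OD470 from
#' the carotenoid equation; Gaussian noise of standard deviation
#' \code{noiseSd} is added to every absorbance / fluorescence quantity.
#'
#' @param pigments list with \code{chlA}, \code{chlB}, \code{car} (mg/g)
#'   and optional \code{V} (ml, default 30), \code{N} (default 1),
#'   \code{W} (g, default 1).
#' @param trace optional true fluorescence trace (see
#'   \code{\link{fluorescenceParams}}); replicated with noise when given.
#' @param n number of replicate records (default 1).
#' @param noiseSd additive Gaussian noise standard deviation (default 0).
#' @param seed optional integer seed.
#' @return list with \code{absorbance} (data.frame of od663, od645,
#'   od470, V, N, W) and, when \code{trace} was given, \code{trace}
#'   (data.frame of noisy trace replicates).
#' @export
simulatePhenotypingRecords <- function(pigments, trace = NULL, n = 1,
                                       noiseSd = 0, seed = NULL) {
  stopifnot(noiseSd >= 0, n >= 1)
  V <- pigments$V %||% 30
  N <- pigments$N %||% 1
  W <- pigments$W %||% 1
  # (12.72 -2.69; -4.68 22.88) (od663, od645)' = (chlA, chlB)' * W/(V N)
  a <- pigments$chlA * W / (V * N)
  b <- pigments$chlB * W / (V * N)
  det <- 12.72 * 22.88 - 2.69 * 4.68
  od663 <- (22.88 * a + 2.69 * b) / det
  od645 <- (4.68 * a + 12.72 * b) / det
  od470 <- (198 * pigments$car + 3.27 * pigments$chlA +
              104 * pigments$chlB) * W / V
  if (any(c(od663, od645, od470) < 0))
    .stopf("pigment contents (%.3g, %.3g, %.3g) have no non-negative absorbance solution",
           pigments$chlA, pigments$chlB, pigments$car)
  .withSeed(seed, {
    noisy <- function(x) x + stats::rnorm(n, 0, noiseSd)
    abs <- data.frame(od663 = noisy(od663), od645 = noisy(od645),
                      od470 = noisy(od470), V = V, N = N, W = W)
    out <- list(absorbance = abs)
    if (!is.null(trace)) {
      t <- as.list(trace)
      .checkTrace(t)
      out$trace <- as.data.frame(lapply(t, noisy))
    }
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
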