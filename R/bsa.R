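#' Mapping configuration
#'
#' Collects the tuning parameters of SNP-index mapping.  The threshold is
#' applied to the mutant-pool SNP-index by default: at a recessive causal
#' site the expected MP index is 1.0 while the expected delta is only 2/3
#' (the WP of a recessive F2 has expected index 1/3 there), so a 0.9
#' threshold is only reachable in expectation on the MP index.  Both
#' statistics are supported.
#'
#' @param threshold statistic threshold for interval calling (default 0.9).
#' @param statistic \code{"mp"} (mutant-pool SNP-index, default) or
#'   \code{"delta"} (MP - WP).
#' @param minDepth minimum read depth required in each pool for a site to
#'   survive filtering (default 10).
#' @param windowSpan,windowStep optional sliding-window span/step in bp for
#'   \code{\link{windowProfile}}; windowing is off by default (per-site
#'   analysis).
#' @param minSites minimum sites for a window to count as supported
#'   (default 1).
#' @param gapTolerance number of consecutive below-threshold sites allowed
#'   inside a called interval (default 0).
#' @return a list of class \code{mappingConfig}.
#' @export
mappingConfig <- function(threshold = 0.9, statistic = c("mp", "delta"),
                          minDepth = 10, windowSpan = NULL,
                          windowStep = NULL, minSites = 1,
                          gapTolerance = 0) {
  statistic <- match.arg(statistic)
  stopifnot(threshold > 0, threshold <= 1, minDepth >= 0, gapTolerance >= 0)
  if (!is.null(windowSpan) && !is.null(windowStep) &&
      windowStep > windowSpan)
    .stopf("window step (%g) must not exceed span (%g)", windowStep,
           windowSpan)
  structure(list(threshold = threshold, statistic = statistic,
                 minDepth = minDepth, windowSpan = windowSpan,
                 windowStep = windowStep, minSites = minSites,
                 gapTolerance = gapTolerance),
            class = "mappingConfig")
}

#' Compute per-site SNP-index and delta SNP-index
#'
#' The SNP-index of a pool at a site is the fraction of reads supporting
#' the mutant (alt) allele: alt reads / total reads covering the position.
#' The delta SNP-index is the mutant-pool index minus the wild-type-pool
#' index.  Sites where either pool's depth is below \code{minDepth} (or
#' zero) are kept in the output but flagged filtered with a reason, never
#' dropped silently and never a division error.
#'
#' @param counts a \linkS4class{PooledCounts}.
#' @param config a \code{\link{mappingConfig}}.
#' @param wpCol,mpCol column names of the wild-type and mutant pools
#'   (defaults \code{"WP"}, \code{"MP"}).
#' @return a \code{GRanges}, one range per input site in coordinate order,
#'   with metadata columns \code{indexWP}, \code{indexMP}, \code{delta},
#'   \code{kept} (logical) and \code{filterReason} (NA when kept).
#' @export
computeSnpIndex <- function(counts, config = mappingConfig(),
                            wpCol = "WP", mpCol = "MP") {
  a <- altCounts(counts); d <- totalDepth(counts)
  for (cn in c(wpCol, mpCol))
    if (!cn %in% colnames(a)) .stopf("no pool column '%s' in counts", cn)
  dW <- d[, wpCol]; dM <- d[, mpCol]
  zero <- dW == 0 | dM == 0
  shallow <- !zero & (dW < config$minDepth | dM < config$minDepth)
  kept <- !zero & !shallow
  iW <- ifelse(dW > 0, a[, wpCol] / dW, NA_real_)
  iM <- ifelse(dM > 0, a[, mpCol] / dM, NA_real_)
  gr <- GenomicRanges::granges(SummarizedExperiment::rowRanges(counts))
  mcols(gr)$indexWP <- iW
  mcols(gr)$indexMP <- iM
  mcols(gr)$delta <- iM - iW
  mcols(gr)$kept <- kept
  mcols(gr)$filterReason <- ifelse(zero, "zero depth",
                            ifelse(shallow, "low depth", NA_character_))
  gr
}

.statOf <- function(records, config) {
  if (config$statistic == "mp") mcols(records)$indexMP
  else mcols(records)$delta
}

#' Sliding-window profile of the mapping statistic
#'
#' Unweighted mean of the chosen statistic over surviving sites in sliding
#' windows of \code{windowSpan} bp advanced by \code{windowStep} bp per
#' chromosome.  Windows with fewer than \code{minSites} surviving sites
#' are flagged unsupported (mean NA when empty).
#'
#' @param records output of \code{\link{computeSnpIndex}}.
#' @param config a \code{\link{mappingConfig}} with \code{windowSpan} and
#'   \code{windowStep} set.
#' @return data.frame with columns chrom, start, end, mid, nSites, mean,
#'   supported.
#' @export
windowProfile <- function(records, config) {
  if (is.null(config$windowSpan) || is.null(config$windowStep))
    .stopf("windowSpan and windowStep must be set for windowing")
  stat <- .statOf(records, config)
  chrom <- as.character(seqnames(records))
  pos <- start(records)
  kept <- mcols(records)$kept
  out <- list()
  for (cn in unique(chrom)) {
    j <- which(chrom == cn & kept)
    if (!length(j)) next
    p <- pos[j]; s <- stat[j]
    starts <- seq(min(p), max(p), by = config$windowStep)
    for (ws in starts) {
      we <- ws + config$windowSpan - 1
      inw <- p >= ws & p <= we
      n <- sum(inw)
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, start = ws, end = we, mid = (ws + we) / 2,
        nSites = n, mean = if (n) mean(s[inw]) else NA_real_,
        supported = n >= config$minSites)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), mid = numeric(), nSites = integer(),
                      mean = numeric(), supported = logical()))
  do.call(rbind, out)
}

#' Call candidate intervals above the mapping threshold
#'
#' Scans surviving sites in coordinate order per chromosome and merges
#' maximal runs of consecutive sites whose statistic is at or above the
#' threshold into candidate intervals; up to \code{gapTolerance}
#' consecutive below-threshold sites may be bridged inside a run (default
#' 0, no bridging).  Intervals span from the first to the last
#' above-threshold site of the run (1-based inclusive) and are returned
#' sorted by width descending, leftmost first among equal widths.
#'
#' @param records output of \code{\link{computeSnpIndex}} (per-site GRanges).
#' @param config a \code{\link{mappingConfig}}.
#' @return a \code{GRanges} of candidate intervals with metadata columns
#'   \code{widthMb} (width in Mb, half-up to 2 decimals), \code{peak}
#'   (maximum statistic in the run) and \code{nSites} (supporting
#'   above-threshold sites).  Empty input or no qualifying site gives an
#'   empty GRanges.
#' @export
callIntervals <- function(records, config = mappingConfig()) {
  empty <- GRanges()
  mcols(empty)$widthMb <- numeric()
  mcols(empty)$peak <- numeric()
  mcols(empty)$nSites <- integer()
  if (!length(records)) return(empty)
  stat <- .statOf(records, config)
  keep <- mcols(records)$kept & !is.na(stat)
  chrom <- as.character(seqnames(records))
  res <- list()
  for (cn in unique(chrom)) {
    j <- which(chrom == cn & keep)
    if (!length(j)) next
    j <- j[order(start(records)[j])]
    p <- start(records)[j]
    s <- stat[j]
    above <- s >= config$threshold
    runStart <- NA_integer_; lastAbove <- NA_integer_; gap <- 0L
    flush <- function(i1, i2) {
      sel <- seq(i1, i2)
      sel <- sel[above[sel]]
      res[[length(res) + 1L]] <<- data.frame(
        chrom = cn, start = p[min(sel)], end = p[max(sel)],
        peak = max(s[sel]), nSites = length(sel))
    }
    for (i in seq_along(p)) {
      if (above[i]) {
        if (is.na(runStart)) runStart <- i
        lastAbove <- i
        gap <- 0L
      } else if (!is.na(runStart)) {
        gap <- gap + 1L
        if (gap > config$gapTolerance) {
          flush(runStart, lastAbove)
          runStart <- NA_integer_; gap <- 0L
        }
      }
    }
    if (!is.na(runStart)) flush(runStart, lastAbove)
  }
  if (!length(res)) return(empty)
  df <- do.call(rbind, res)
  df$widthBp <- df$end - df$start
  df <- df[order(-df$widthBp, match(df$chrom, unique(chrom)), df$start), ]
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  mcols(gr)$widthMb <- roundHalfUp(df$widthBp / 1e6, 2L)
  mcols(gr)$peak <- df$peak
  mcols(gr)$nSites <- df$nSites
  gr
}
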