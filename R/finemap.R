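#' Count recombinant individuals at a marker
#'
#' Among mutant-phenotype F2 individuals, every true homozygote at the
#' causal locus must be homozygous mutant at a fully linked marker; a call
#' of 0 (homWT) or 1 (het) therefore evidences a crossover between the
#' marker and the causal locus.  Missing calls are excluded from both the
#' numerator and the denominator (never treated as recombinant).
#'
#' @param geno integer matrix of genotype calls (individuals x markers,
#'   values 0/1/2/NA) from mutant-phenotype individuals.
#' @param marker marker id (a column name of \code{geno}).
#' @return list with \code{count}, \code{individuals} (row names of the
#'   recombinants) and \code{nTyped} (non-missing calls).
#' @export
countRecombinants <- function(geno, marker) {
  if (!marker %in% colnames(geno))
    .stopf("unknown marker '%s'", marker)
  calls <- geno[, marker]
  typed <- !is.na(calls)
  rec <- typed & calls != 2L
  ids <- rownames(geno)[rec]
  if (is.null(rownames(geno))) ids <- as.character(which(rec))
  list(count = sum(rec), individuals = ids, nTyped = sum(typed))
}

#' Refine a candidate interval from marker recombinant counts
#'
#' Locates the maximal (longest, leftmost on ties) run of markers with
#' zero recombinants and reports the interval between the nearest
#' recombinant-bearing marker on each side of that run.  The interval
#' endpoints are those flanking markers' own positions (1-based
#' inclusive).  If the zero-recombinant run touches the first or last
#' marker, that side is flagged open-ended and the terminal marker is used
#' as the endpoint.
#'
#' @param geno integer genotype matrix from mutant-phenotype individuals
#'   (see \code{\link{countRecombinants}}).
#' @param markers data.frame with columns \code{id}, \code{chrom},
#'   \code{pos}, coordinate-ordered on one chromosome; every id must be a
#'   column of \code{geno}.
#' @return a \linkS4class{RefinedInterval}.
#' @export
refineInterval <- function(geno, markers) {
  if (nrow(markers) < 2L) .stopf("need at least 2 markers")
  if (length(unique(as.character(markers$chrom))) != 1L)
    .stopf("markers must lie on one chromosome")
  if (is.unsorted(markers$pos, strictly = TRUE))
    .stopf("markers must be strictly coordinate-ordered")
  ids <- as.character(markers$id)
  counts <- vapply(ids, function(m) countRecombinants(geno, m)$count,
                   integer(1))
  zero <- counts == 0L
  if (!any(zero))
    .stopf("locus not contained: no marker with zero recombinants")
  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  zi <- which(r$values)
  best <- zi[which.max(r$lengths[zi])]
  runL <- starts[best]; runR <- ends[best]
  openLeft <- runL == 1L
  openRight <- runR == length(ids)
  li <- if (openLeft) 1L else runL - 1L
  ri <- if (openRight) length(ids) else runR + 1L
  startPos <- markers$pos[li]; endPos <- markers$pos[ri]
  wkb <- if (endPos > startPos) intervalWidthKb(startPos, endPos)
         else NA_real_
  new("RefinedInterval", chrom = as.character(markers$chrom[1]),
      start = startPos, end = endPos, widthKb = wkb,
      leftMarker = ids[li], rightMarker = ids[ri], counts = counts,
      openLeft = openLeft, openRight = openRight)
}

#' Interval width in kilobases
#'
#' \code{round((end - start)/1000)}, half away from zero, so e.g. a span
#' of 274,473 bp reports as 274 kb.
#'
#' @param start,end physical positions in bp with \code{start < end}.
#' @return integer width in kb.
#' @export
intervalWidthKb <- function(start, end) {
  if (any(start >= end)) .stopf("start must be less than end")
  as.integer(roundHalfUp((end - start) / 1000))
}

setMethod("show", "RefinedInterval", function(object) {
  cat(sprintf("RefinedInterval: %s:%d-%d (%s kb)\n", object@chrom,
              as.integer(object@start), as.integer(object@end),
              format(object@widthKb)))
  cat(sprintf("  flanked by %s%s and %s%s\n",
              object@leftMarker, if (object@openLeft) " (open)" else "",
              object@rightMarker, if (object@openRight) " (open)" else ""))
  cat("  recombinants per marker: ",
      paste(names(object@counts), object@counts, sep = "=",
            collapse = ", "), "\n", sep = "")
})
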