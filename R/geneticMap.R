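#' Construct a genetic map
#'
#' @param chromosomes data.frame with columns \code{name}, \code{lengthBp},
#'   \code{lengthCM}; one row per chromosome.
#' @param markers optional data.frame of anchor markers with columns
#'   \code{chrom}, \code{posBp}, \code{posCM}.  Genetic position between
#'   anchors (and the implicit chromosome-end anchors) is linearly
#'   interpolated.
#' @return a \linkS4class{GeneticMap}.
#' @examples
#' gm <- geneticMap(data.frame(name = "chr1", lengthBp = 1e7, lengthCM = 50))
#' geneticPos(gm, "chr1", 5e6)  # 25 cM under the uniform map
#' @export
geneticMap <- function(chromosomes, markers = NULL) {
  if (is.null(markers))
    markers <- data.frame(chrom = character(), posBp = numeric(),
                          posCM = numeric())
  chromosomes$name <- as.character(chromosomes$name)
  markers$chrom <- as.character(markers$chrom)
  new("GeneticMap", chromosomes = chromosomes, markers = markers)
}

#' Interpolate genetic position (cM) from physical position (bp)
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param chrom chromosome name (scalar).
#' @param bp numeric vector of physical positions.
#' @return numeric vector of genetic positions in cM.
#' @export
geneticPos <- function(map, chrom, bp) {
  ch <- map@chromosomes
  i <- match(chrom, ch$name)
  if (is.na(i)) .stopf("unknown chromosome '%s'", chrom)
  mk <- map@markers[map@markers$chrom == chrom, , drop = FALSE]
  xs <- c(0, mk$posBp, ch$lengthBp[i])
  ys <- c(0, mk$posCM, ch$lengthCM[i])
  o <- order(xs)
  xs <- xs[o]; ys <- ys[o]
  keep <- !duplicated(xs)
  if (any(bp < 1 | bp > ch$lengthBp[i]))
    .stopf("position outside chromosome '%s'", chrom)
  stats::approx(xs[keep], ys[keep], xout = bp, rule = 2)$y
}

setMethod("show", "GeneticMap", function(object) {
  ch <- object@chromosomes
  cat(sprintf("GeneticMap: %d chromosome(s), %.1f Mb / %.1f cM total, %d anchor marker(s)\n",
              nrow(ch), sum(ch$lengthBp) / 1e6, sum(ch$lengthCM),
              nrow(object@markers)))
  for (i in seq_len(nrow(ch)))
    cat(sprintf("  %s: %.2f Mb, %.1f cM\n", ch$name[i],
                ch$lengthBp[i] / 1e6, ch$lengthCM[i]))
})

#' Specify the causal locus
#'
#' @param chrom chromosome name.
#' @param pos physical position (bp, 1-based).
#' @param lethal logical; if TRUE homozygous mutants are removed from the
#'   simulated population before phenotyping (albino-lethal alleles).
#' @return a \linkS4class{CausalLocus}.
#' @export
causalLocus <- function(chrom, pos, lethal = FALSE) {
  new("CausalLocus", chrom = as.character(chrom), pos = as.numeric(pos),
      mode = "recessive", lethal = lethal)
}

setMethod("show", "CausalLocus", function(object) {
  cat(sprintf("CausalLocus: %s:%d, recessive%s\n", object@chrom,
              as.integer(object@pos),
              if (object@lethal) ", homozygote-lethal" else ""))
})
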