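#' Construct a variant set from explicit sites
#'
#' @param chrom,pos,ref,alt vectors describing biallelic SNV sites.
#' @param origin which parental line carries the alt allele at each site;
#'   \code{"mutant"} (default) or \code{"wildtype"}.
#' @return a \linkS4class{VariantSet}.
#' @export
variantSet <- function(chrom, pos, ref, alt, origin = "mutant") {
  n <- length(pos)
  gr <- GRanges(chrom, IRanges(pos, width = 1L))
  mcols(gr)$ref <- rep_len(ref, n)
  mcols(gr)$alt <- rep_len(alt, n)
  mcols(gr)$origin <- rep_len(origin, n)
  gr <- GenomicRanges::sort(gr)
  new("VariantSet", sites = gr)
}

#' Simulate an EMS-induced SNV set
#'
#' EMS (ethyl methanesulfonate) alkylates guanine and produces
#' predominantly G:C -> A:T transitions.  A fixed fraction \code{emsBias}
#' of the generated sites (the ceiling, so the realised fraction is never
#' below the configured bias) are G>A or C>T transitions; the remainder are
#' drawn uniformly from the other substitution types.  Positions are
#' sampled uniformly over the genome, proportionally to physical
#' chromosome length, without replacement.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param n number of sites.
#' @param emsBias minimum fraction of G>A / C>T transitions (default 0.7).
#' @param origin parental origin of the alt alleles (default
#'   \code{"mutant"}: an EMS library in the mutant line's background).
#' @param seed optional integer seed for reproducibility.
#' @return a \linkS4class{VariantSet} in coordinate order.
#' @export
emsVariantSet <- function(map, n, emsBias = 0.7, origin = "mutant",
                          seed = NULL) {
  stopifnot(n >= 1, emsBias >= 0, emsBias <= 1)
  .withSeed(seed, {
    ch <- map@chromosomes
    chrom <- sample(ch$name, n, replace = TRUE,
                    prob = ch$lengthBp / sum(ch$lengthBp))
    pos <- vapply(chrom, function(cn) {
      L <- ch$lengthBp[ch$name == cn]
      sample.int(as.integer(L), 1L)
    }, numeric(1))
    # resample duplicated chrom:pos pairs until unique
    repeat {
      dup <- duplicated(paste(chrom, pos))
      if (!any(dup)) break
      pos[dup] <- vapply(chrom[dup], function(cn) {
        sample.int(as.integer(ch$lengthBp[ch$name == cn]), 1L)
      }, numeric(1))
    }
    nEms <- as.integer(ceiling(emsBias * n))
    isEms <- logical(n)
    isEms[sample.int(n, nEms)] <- TRUE
    ref <- character(n); alt <- character(n)
    gc <- sample(c("G", "C"), n, replace = TRUE)
    ref[isEms] <- gc[isEms]
    alt[isEms] <- ifelse(gc[isEms] == "G", "A", "T")
    if (any(!isEms)) {
      other <- rbind(c("A", "G"), c("A", "C"), c("A", "T"),
                     c("T", "C"), c("T", "G"), c("T", "A"),
                     c("G", "C"), c("G", "T"), c("C", "A"), c("C", "G"))
      pick <- sample.int(nrow(other), sum(!isEms), replace = TRUE)
      ref[!isEms] <- other[pick, 1L]
      alt[!isEms] <- other[pick, 2L]
    }
    variantSet(chrom, pos, ref, alt, origin)
  })
}

#' @rdname VariantSet-class
#' @export
setMethod("variantSites", "VariantSet", function(x) x@sites)

setMethod("show", "VariantSet", function(object) {
  s <- object@sites
  m <- mcols(s)
  ems <- mean((m$ref == "G" & m$alt == "A") | (m$ref == "C" & m$alt == "T"))
  cat(sprintf("VariantSet: %d biallelic SNVs on %d chromosome(s); %.0f%% G>A/C>T\n",
              length(s), length(unique(as.character(seqnames(s)))),
              100 * ems))
})

#' @rdname VariantSet-class
#' @export
setMethod("length", "VariantSet", function(x) length(x@sites))

# index of a chrom:pos site within a VariantSet, NA if absent
.siteIndex <- function(variants, chrom, pos) {
  s <- variants@sites
  which(as.character(seqnames(s)) == chrom & start(s) == pos)[1]
}
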