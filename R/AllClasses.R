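#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' Genetic map of a simulated genome
#'
#' Chromosome physical/genetic lengths plus optional anchor markers tying
#' physical (bp) to genetic (cM) coordinates.  Between anchors, genetic
#' position is linearly interpolated; the chromosome ends (position 0 and
#' the physical length) are implicit anchors at 0 cM and the full genetic
#' length.  Physical coordinates are 1-based inclusive throughout, the VCF
#' convention.
#'
#' @slot chromosomes data.frame with columns \code{name}, \code{lengthBp},
#'   \code{lengthCM}.
#' @slot markers data.frame with columns \code{chrom}, \code{posBp},
#'   \code{posCM}; may have zero rows.
#' @export
setClass("GeneticMap", representation(
  chromosomes = "data.frame",
  markers = "data.frame"
))

setValidity("GeneticMap", function(object) {
  ch <- object@chromosomes
  mk <- object@markers
  if (nrow(ch) < 1L) return("need at least one chromosome")
  if (!all(c("name", "lengthBp", "lengthCM") %in% names(ch)))
    return("chromosomes needs columns name, lengthBp, lengthCM")
  if (anyDuplicated(ch$name)) return("duplicated chromosome names")
  if (any(ch$lengthBp < 1) || any(ch$lengthCM < 0))
    return("chromosome lengths must be positive (genetic length may be 0)")
  if (nrow(mk)) {
    if (!all(c("chrom", "posBp", "posCM") %in% names(mk)))
      return("markers needs columns chrom, posBp, posCM")
    if (!all(mk$chrom %in% ch$name)) return("marker on unknown chromosome")
    for (cn in unique(mk$chrom)) {
      sub <- mk[mk$chrom == cn, ]
      sub <- sub[order(sub$posBp), ]
      L <- ch[ch$name == cn, ]
      if (any(sub$posBp < 1) || any(sub$posBp > L$lengthBp))
        return(sprintf("marker outside chromosome %s", cn))
      if (any(sub$posCM < 0) || any(sub$posCM > L$lengthCM))
        return(sprintf("marker genetic position outside map on %s", cn))
      if (is.unsorted(sub$posCM))
        return(sprintf("genetic positions not non-decreasing on %s", cn))
    }
  }
  TRUE
})

#' Causal locus specification
#'
#' A single recessive locus; \code{lethal} models alleles whose homozygotes
#' die before phenotyping (e.g. a transposon insertion whose homozygous
#' carriers are albino lethal) and removes them from the simulated
#' population.
#'
#' @slot chrom chromosome name.
#' @slot pos physical position, bp (1-based).
#' @slot mode inheritance mode; only \code{"recessive"} is supported.
#' @slot lethal logical; drop homozygous mutants before phenotyping.
#' @export
setClass("CausalLocus", representation(
  chrom = "character", pos = "numeric", mode = "character",
  lethal = "logical"
))

setValidity("CausalLocus", function(object) {
  if (object@mode != "recessive") return("only recessive mode is supported")
  if (length(object@pos) != 1L || object@pos < 1) return("pos must be >= 1")
  TRUE
})

#' Set of biallelic variant sites
#'
#' Sites are held as a \code{GRanges} with metadata columns \code{ref},
#' \code{alt} (single bases) and \code{origin} (which parental line carries
#' the alt allele: \code{"mutant"} or \code{"wildtype"}).
#'
#' @slot sites GRanges of width-1 positions with mcols ref, alt, origin.
#' @export
setClass("VariantSet", representation(sites = "GRanges"))

setValidity("VariantSet", function(object) {
  s <- object@sites
  m <- mcols(s)
  if (!all(c("ref", "alt", "origin") %in% names(m)))
    return("sites need mcols ref, alt, origin")
  if (length(s) && any(width(s) != 1L)) return("sites must be width-1 SNVs")
  if (!all(m$ref %in% c("A", "C", "G", "T"))) return("ref must be A/C/G/T")
  if (!all(m$alt %in% c("A", "C", "G", "T"))) return("alt must be A/C/G/T")
  if (any(m$ref == m$alt)) return("alt must differ from ref")
  if (!all(m$origin %in% c("mutant", "wildtype")))
    return("origin must be 'mutant' or 'wildtype'")
  key <- paste(as.character(seqnames(s)), start(s))
  if (anyDuplicated(key)) return("duplicated site positions")
  TRUE
})

#' Simulated F2 population
#'
#' Individuals from selfing the F1 of mutant x wild-type.  The genotype
#' matrix stores, per individual and variant site, the number of copies
#' (0/1/2) of the alt allele; phenotype is \code{"pale"} iff the causal
#' genotype is homozygous mutant (subject to penetrance).
#'
#' @slot genotypes integer matrix, individuals x sites.
#' @slot phenotype character vector, \code{"green"} or \code{"pale"}.
#' @slot variants the \linkS4class{VariantSet} the columns refer to.
#' @slot map the \linkS4class{GeneticMap} used for meiosis.
#' @slot causal the \linkS4class{CausalLocus}.
#' @export
setClass("F2Population", representation(
  genotypes = "matrix", phenotype = "character",
  variants = "VariantSet", map = "GeneticMap", causal = "CausalLocus"
))

setValidity("F2Population", function(object) {
  g <- object@genotypes
  if (nrow(g) != length(object@phenotype))
    return("one phenotype per individual required")
  if (ncol(g) != length(object@variants@sites))
    return("one genotype column per variant site required")
  if (length(g) && !all(g %in% 0:2)) return("genotype codes must be 0/1/2")
  if (!all(object@phenotype %in% c("green", "pale")))
    return("phenotype must be 'green' or 'pale'")
  TRUE
})

#' Phenotype-selected pools of F2 individuals
#'
#' Row indices into an \linkS4class{F2Population}: a wild-type pool (WP) of
#' green individuals and a mutant pool (MP) of pale individuals, sampled
#' without replacement.
#'
#' @slot population the source \linkS4class{F2Population}.
#' @slot wp integer indices of the wild-type pool members.
#' @slot mp integer indices of the mutant pool members.
#' @export
setClass("F2Pools", representation(
  population = "F2Population", wp = "integer", mp = "integer"
))

setValidity("F2Pools", function(object) {
  n <- nrow(object@population@genotypes)
  ph <- object@population@phenotype
  if (anyDuplicated(object@wp) || anyDuplicated(object@mp))
    return("pool indices must be unique (sampling without replacement)")
  if (any(object@wp < 1) || any(object@wp > n) ||
      any(object@mp < 1) || any(object@mp > n))
    return("pool indices out of range")
  if (!all(ph[object@wp] == "green")) return("WP must contain only green")
  if (!all(ph[object@mp] == "pale")) return("MP must contain only pale")
  TRUE
})

#' Per-site, per-pool pooled read counts
#'
#' A \code{RangedSummarizedExperiment} with assays \code{alt} (reads
#' supporting the alt allele) and \code{depth} (total reads covering the
#' site); columns are pools.  This is the raw material of SNP-index
#' mapping.
#'
#' @export
setClass("PooledCounts", contains = "RangedSummarizedExperiment")

setValidity("PooledCounts", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("alt", "depth") %in% an))
    return("assays 'alt' and 'depth' are required")
  a <- SummarizedExperiment::assay(object, "alt")
  d <- SummarizedExperiment::assay(object, "depth")
  if (any(a < 0) || any(d < 0)) return("negative read counts")
  if (any(a > d)) return("alt reads exceed total depth")
  TRUE
})

#' One- or two-gene recessive allele model
#'
#' Alleles are written as a letter plus a locus subscript (\code{A1},
#' \code{a1}, \code{A2}, \code{a2}); upper case is functional, lower case
#' non-functional.  Under the allelic model all four symbols are alleles of
#' one gene, so the compound heterozygote a1/a2 has no functional copy and
#' is mutant.  Under the non-allelic (two-gene) model, subscript 1 and 2
#' alleles belong to different, unlinked genes and each mutation is
#' recessive at its own gene.
#'
#' @slot allelic logical; TRUE for the same-gene model.
#' @export
setClass("AlleleModel", representation(allelic = "logical"))

#' Expected progeny phenotype distribution
#'
#' Result of exact gamete enumeration: integer class counts out of a common
#' denominator, plus the green:pale ratio reduced to lowest terms.
#'
#' @slot table data.frame with columns phenotype, count, prob.
#' @slot total integer common denominator (number of equally likely
#'   surviving gamete combinations, after lethality filtering).
#' @slot ratio named integer vector, reduced green:pale ratio.
#' @export
setClass("ProgenyDistribution", representation(
  table = "data.frame", total = "integer", ratio = "integer"
))

#' Fine-mapped interval between flanking recombinant-bearing markers
#'
#' @slot chrom chromosome name.
#' @slot start,end physical positions (bp, 1-based inclusive) of the
#'   flanking markers.
#' @slot widthKb integer width, round half-up of (end - start)/1000.
#' @slot leftMarker,rightMarker flanking marker ids.
#' @slot counts named integer vector of recombinant counts per marker.
#' @slot openLeft,openRight logical; TRUE when the zero-recombinant run
#'   touches the first/last marker so that side is unbounded.
#' @export
setClass("RefinedInterval", representation(
  chrom = "character", start = "numeric", end = "numeric",
  widthKb = "numeric", leftMarker = "character", rightMarker = "character",
  counts = "integer", openLeft = "logical", openRight = "logical"
))
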