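#' @importFrom stats rpois runif rbinom
NULL

# Simulate `ngam` gametes for one chromosome under the Haldane model:
# crossover count ~ Poisson(genetic length in Morgans), crossover positions
# uniform in genetic distance, no interference.  `gposCM` are the genetic
# positions of the sites.  Returns a 0/1 matrix (ngam x sites) giving, per
# gamete, which parental haplotype (1 = mutant line) is carried at each
# site.
.simGametes <- function(gposCM, lengthCM, ngam) {
  k <- length(gposCM)
  phase0 <- sample(c(0L, 1L), ngam, replace = TRUE)
  m <- matrix(phase0, nrow = ngam, ncol = k)
  if (lengthCM > 0) {
    nx <- rpois(ngam, lengthCM / 100)
    for (g in which(nx > 0L)) {
      xo <- sort(runif(nx[g], 0, lengthCM))
      m[g, ] <- (phase0[g] + findInterval(gposCM, xo)) %% 2L
    }
  }
  m
}

#' Simulate an F2 population
#'
#' Forward-simulates the cross mutant x wild type followed by selfing of
#' the (uniformly heterozygous) F1.  Each F2 individual is formed from two
#' independent recombinant F1 gametes; meiosis follows the Haldane model
#' (Poisson crossovers on genetic length, positions uniform in cM, no
#' interference), so the recombination fraction between two sites d Morgans
#' apart is (1 - exp(-2d))/2.  Site genetic positions come from linear
#' interpolation on the map.  Phenotype is \code{"pale"} iff the causal
#' genotype is homozygous mutant, subject to \code{penetrance}.
#'
#' With \code{lethal} set on the causal locus, homozygous-mutant
#' individuals are removed before phenotyping (so fewer than \code{n}
#' individuals are returned and none is pale).
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param variants a \linkS4class{VariantSet}; must contain the causal site.
#' @param causal a \linkS4class{CausalLocus}.
#' @param n number of F2 individuals to simulate.
#' @param penetrance probability that a homozygous mutant expresses the
#'   pale phenotype (default 1).
#' @param seed optional integer seed.
#' @return an \linkS4class{F2Population}.
#' @export
simulateF2Population <- function(map, variants, causal, n, penetrance = 1,
                                 seed = NULL) {
  stopifnot(n >= 1, penetrance >= 0, penetrance <= 1)
  ci <- .siteIndex(variants, causal@chrom, causal@pos)
  if (is.na(ci))
    .stopf("causal site %s:%d is not in the variant set", causal@chrom,
           as.integer(causal@pos))
  s <- variants@sites
  chromOf <- as.character(seqnames(s))
  .withSeed(seed, {
    G <- matrix(0L, nrow = n, ncol = length(s))
    for (cn in unique(chromOf)) {
      j <- which(chromOf == cn)
      gpos <- geneticPos(map, cn, start(s)[j])
      Lcm <- map@chromosomes$lengthCM[map@chromosomes$name == cn]
      gam <- .simGametes(gpos, Lcm, 2L * n)
      G[, j] <- gam[seq_len(n), , drop = FALSE] +
        gam[n + seq_len(n), , drop = FALSE]
    }
    # genotype code = copies of the alt allele; for wildtype-origin sites
    # the alt allele rides the wild-type haplotype
    wt <- which(mcols(s)$origin == "wildtype")
    if (length(wt)) G[, wt] <- 2L - G[, wt, drop = FALSE]
    homMut <- G[, ci] == 2L
    if (causal@lethal) {
      keep <- !homMut
      G <- G[keep, , drop = FALSE]
      homMut <- homMut[keep]
    }
    pheno <- rep("green", nrow(G))
    expressed <- homMut & (rbinom(nrow(G), 1L, penetrance) == 1L)
    pheno[expressed] <- "pale"
    new("F2Population", genotypes = G, phenotype = pheno,
        variants = variants, map = map, causal = causal)
  })
}

#' @rdname F2Population-class
#' @export
setMethod("genotypes", "F2Population", function(x) x@genotypes)

#' @rdname F2Population-class
#' @export
setMethod("phenotypes", "F2Population", function(x) x@phenotype)

#' @rdname F2Population-class
#' @export
setMethod("length", "F2Population", function(x) nrow(x@genotypes))

setMethod("show", "F2Population", function(object) {
  ph <- table(factor(object@phenotype, c("green", "pale")))
  cat(sprintf("F2Population: %d individuals (%d green, %d pale), %d variant sites\n",
              nrow(object@genotypes), ph[["green"]], ph[["pale"]],
              ncol(object@genotypes)))
  cat(sprintf("  causal locus %s:%d\n", object@causal@chrom,
              as.integer(object@causal@pos)))
})

#' Build phenotype-selected pools
#'
#' Samples, without replacement, \code{wpSize} green individuals into the
#' wild-type pool (WP) and \code{mpSize} pale individuals into the mutant
#' pool (MP).
#'
#' @param pop an \linkS4class{F2Population}.
#' @param wpSize,mpSize pool sizes (defaults 200, the usual scale for
#'   bulked segregant pools).
#' @param seed optional integer seed.
#' @return an \linkS4class{F2Pools}.
#' @export
buildPools <- function(pop, wpSize = 200, mpSize = 200, seed = NULL) {
  stopifnot(wpSize >= 1, mpSize >= 1)
  green <- which(pop@phenotype == "green")
  pale <- which(pop@phenotype == "pale")
  if (length(green) < wpSize)
    .stopf("need %d green individuals for WP but only %d available (short by %d)",
           wpSize, length(green), wpSize - length(green))
  if (length(pale) < mpSize)
    .stopf("need %d pale individuals for MP but only %d available (short by %d)",
           mpSize, length(pale), mpSize - length(pale))
  .withSeed(seed, {
    new("F2Pools", population = pop,
        wp = sort(sample(green, wpSize)),
        mp = sort(sample(pale, mpSize)))
  })
}

#' @rdname poolFrequencies
#' @export
setMethod("poolFrequencies", "F2Pools", function(x) {
  G <- x@population@genotypes
  cbind(WP = colSums(G[x@wp, , drop = FALSE]) / (2 * length(x@wp)),
        MP = colSums(G[x@mp, , drop = FALSE]) / (2 * length(x@mp)))
})

setMethod("show", "F2Pools", function(object) {
  cat(sprintf("F2Pools: WP n=%d (green), MP n=%d (pale)\n",
              length(object@wp), length(object@mp)))
})

#' Simulate pooled sequencing read counts
#'
#' Per site and pool, total depth is Poisson(\code{meanDepth}) (or negative
#' binomial when \code{overdispersion} is given, with
#' \code{size = overdispersion} and the same mean) and alt reads are
#' Binomial(depth, f(1 - e) + (1 - f)e) where f is the pool's true
#' alt-allele frequency and e the per-read miscall rate.
#'
#' @param pools an \linkS4class{F2Pools}.
#' @param meanDepth mean reads per site per pool (default 50).
#' @param errorRate per-read miscall probability, in [0, 0.5) (default
#'   0.005).
#' @param overdispersion optional negative-binomial size parameter; NULL
#'   (default) keeps the Poisson depth model.
#' @param seed optional integer seed.
#' @return a \linkS4class{PooledCounts} with columns \code{WP}, \code{MP}.
#' @export
simulatePoolReadCounts <- function(pools, meanDepth = 50, errorRate = 0.005,
                                   overdispersion = NULL, seed = NULL) {
  stopifnot(meanDepth > 0, errorRate >= 0, errorRate < 0.5)
  f <- poolFrequencies(pools)
  ns <- nrow(f)
  .withSeed(seed, {
    drawDepth <- function(n) {
      if (is.null(overdispersion)) rpois(n, meanDepth)
      else stats::rnbinom(n, size = overdispersion, mu = meanDepth)
    }
    depth <- cbind(WP = drawDepth(ns), MP = drawDepth(ns))
    p <- f * (1 - errorRate) + (1 - f) * errorRate
    alt <- cbind(WP = rbinom(ns, depth[, "WP"], p[, "WP"]),
                 MP = rbinom(ns, depth[, "MP"], p[, "MP"]))
    pooledCounts(pools@population@variants, alt, depth)
  })
}

#' Construct a PooledCounts object
#'
#' @param variants a \linkS4class{VariantSet} (or a GRanges with mcols ref,
#'   alt) giving the sites.
#' @param alt,depth integer matrices, sites x pools, of alt-supporting and
#'   total read counts.
#' @param poolNames column names (default taken from \code{alt}, falling
#'   back to WP/MP).
#' @return a \linkS4class{PooledCounts}.
#' @export
pooledCounts <- function(variants, alt, depth, poolNames = NULL) {
  gr <- if (is(variants, "VariantSet")) variants@sites else variants
  alt <- as.matrix(alt); depth <- as.matrix(depth)
  if (is.null(poolNames))
    poolNames <- if (!is.null(colnames(alt))) colnames(alt)
                 else c("WP", "MP")[seq_len(ncol(alt))]
  colnames(alt) <- colnames(depth) <- poolNames
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(alt = alt, depth = depth), rowRanges = gr,
    colData = DataFrame(pool = poolNames, row.names = poolNames))
  new("PooledCounts", se)
}

#' @rdname PooledCounts-class
#' @export
setMethod("altCounts", "PooledCounts", function(x)
  SummarizedExperiment::assay(x, "alt"))

#' @rdname PooledCounts-class
#' @export
setMethod("totalDepth", "PooledCounts", function(x)
  SummarizedExperiment::assay(x, "depth"))

#' Simulate marker genotype calls
#'
#' Reads the true genotype codes at the requested marker sites from the
#' simulated individuals, emulating an error-free HRM (high-resolution
#' melting) assay; an optional per-call miscall rate replaces calls with a
#' uniformly chosen different code.
#'
#' @param pop an \linkS4class{F2Population}.
#' @param markers data.frame with columns \code{id}, \code{chrom},
#'   \code{pos}; every row must match a site of the population's variant
#'   set.
#' @param miscallRate per-call error probability (default 0).
#' @param individuals optional row indices to genotype (default all).
#' @param seed optional integer seed.
#' @return integer matrix, individuals x markers (colnames = marker ids),
#'   values 0 (homWT), 1 (het), 2 (homMut).
#' @export
simulateMarkerGenotypes <- function(pop, markers, miscallRate = 0,
                                    individuals = NULL, seed = NULL) {
  stopifnot(miscallRate >= 0, miscallRate <= 1)
  idx <- mapply(function(cn, p) .siteIndex(pop@variants, cn, p),
                as.character(markers$chrom), markers$pos)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    .stopf("unknown marker '%s' (%s:%d): not a site of the variant set",
           markers$id[bad], markers$chrom[bad], as.integer(markers$pos[bad]))
  }
  if (is.null(individuals)) individuals <- seq_len(nrow(pop@genotypes))
  M <- pop@genotypes[individuals, idx, drop = FALSE]
  colnames(M) <- as.character(markers$id)
  rownames(M) <- paste0("ind", individuals)
  if (miscallRate > 0) {
    M <- .withSeed(seed, {
      err <- matrix(rbinom(length(M), 1L, miscallRate) == 1L, nrow(M))
      shift <- matrix(sample(1:2, length(M), replace = TRUE), nrow(M))
      M[err] <- (M[err] + shift[err]) %% 3L
      M
    })
  }
  M
}
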