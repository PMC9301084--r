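# Small in-code fixtures shared across test files.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# A uniform-rate map: one or more chromosomes of equal size.
fixMap <- function(nChrom = 1, lengthBp = 1e7, lengthCM = 100) {
  geneticMap(data.frame(name = paste0("chr", seq_len(nChrom)),
                        lengthBp = lengthBp, lengthCM = lengthCM))
}

# Evenly spaced G>A variants, `perChrom` per chromosome.
gridVariants <- function(map, perChrom, origin = "mutant") {
  ch <- map@chromosomes
  chrom <- rep(ch$name, each = perChrom)
  pos <- unlist(lapply(seq_len(nrow(ch)), function(i)
    round(seq(ch$lengthBp[i] / (perChrom + 1), by = ch$lengthBp[i] /
                (perChrom + 1), length.out = perChrom))))
  variantSet(chrom, pos, "G", "A", origin)
}

# Build an F2Population directly from an engineered genotype matrix.
manualPop <- function(G, phenotype, map, variants, causal) {
  new("F2Population", genotypes = G, phenotype = phenotype,
      variants = variants, map = map, causal = causal)
}

# Per-site records GRanges for the interval caller, built through the real
# pipeline: depth `depth` everywhere, alt counts chosen to give the wanted
# MP index; WP held at index 0.3.
recordsWithIndex <- function(chrom, pos, mpIndex, depth = 100) {
  n <- length(pos)
  vs <- variantSet(rep(chrom, n), pos, "G", "A")
  alt <- cbind(WP = rep(round(0.3 * depth), n),
               MP = round(mpIndex * depth))
  dep <- cbind(WP = rep(depth, n), MP = rep(depth, n))
  computeSnpIndex(pooledCounts(vs, alt, dep))
}

# A physiologically plausible fluorescence trace.
fixTrace <- function() {
  list(fo = 400, fm = 2000, fs = 600, fmP = 1500, foP = 380, tau = 12,
       pm = 1.1, p0 = 1.3, abs940 = 0.8, abs650 = 0.5, refAbs940 = 0.7,
       refAbs650 = 0.6)
}

# Random valid traces for property tests; guarantees every invariant of
# the trace record.  With `openCondition` the physiological regime is
# enforced too (fo' <= fs and fm' <= fm, i.e. light-adapted fluorescence
# quenched below the dark-adapted maximum), under which all yield
# parameters are proper fractions.
randomTraces <- function(n, openCondition = FALSE) {
  fo <- runif(n, 100, 900)
  fm <- fo * runif(n, 1.5, 6)
  foP <- fo * runif(n, 0.5, 1.4)
  fs <- if (openCondition) foP * runif(n, 1, 2) else runif(n, 200, 1500)
  fs <- pmin(fs, fm * 0.95)
  foP <- pmin(foP, fs)  # keep fo' <= fs after clipping
  fmP <- if (openCondition) {
    maxv <- pmax(fs, foP)
    maxv + (fm - maxv) * runif(n, 0.05, 1)
  } else pmax(pmax(fs, foP) * runif(n, 1.05, 2.5), fs)
  list(fo = fo, fm = fm, fs = fs, fmP = fmP, foP = foP,
       tau = runif(n, 1, 50), pm = runif(n, 0.5, 2),
       p0 = runif(n, 0.5, 2), abs940 = runif(n, 0.1, 2),
       abs650 = runif(n, 0.1, 2), refAbs940 = runif(n, 0.1, 2),
       refAbs650 = runif(n, 0.1, 2))
}
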