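test_that("F2 simulation reproduces Mendelian recessive segregation", {
  gm <- fixMap(1, 1e7, 100)
  vs <- gridVariants(gm, 5)
  cl <- causalLocus("chr1", start(variantSites(vs))[3])
  pop <- simulateF2Population(gm, vs, cl, 10000, seed = 11)
  frac <- mean(phenotypes(pop) == "pale")
  # Monte-Carlo CI: 0.25 +/- 3*sqrt(0.25*0.75/10000)
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 1e4))
  # phenotype is exactly the causal homozygote at full penetrance
  ci <- which(start(variantSites(vs)) == cl@pos)
  expect_identical(phenotypes(pop) == "pale", genotypes(pop)[, ci] == 2L)
})

test_that("genotype classes at a single site converge to 1:2:1", {
  gm <- fixMap(1, 1e7, 50)
  vs <- gridVariants(gm, 3)
  cl <- causalLocus("chr1", start(variantSites(vs))[2])
  expected <- c("0" = 0.25, "1" = 0.5, "2" = 0.25)
  rejections <- 0L
  pooled <- c("0" = 0, "1" = 0, "2" = 0)
  for (s in 1:20) {
    pop <- simulateF2Population(gm, vs, cl, 10000, seed = 100 + s)
    g <- factor(genotypes(pop)[, 1], levels = 0:2)
    pooled <- pooled + table(g)
    if (chiSquareGof(table(g), expected)$p.value < 0.01)
      rejections <- rejections + 1L
  }
  # no systematic deviation: the aggregate over 200,000 individuals fits,
  # and per-seed rejections stay consistent with the alpha = 0.01 level
  # (P(>3 of 20) ~ 5e-5 for a calibrated simulator)
  expect_gt(chiSquareGof(pooled, expected)$p.value, 0.01)
  expect_lte(rejections, 3L)
})

test_that("a 0 cM chromosome is perfectly co-inherited", {
  gm <- geneticMap(data.frame(name = c("chr1", "chr2"),
                              lengthBp = c(1e6, 1e6),
                              lengthCM = c(50, 0)))
  vs <- gridVariants(gm, 4)
  cl <- causalLocus("chr1", start(variantSites(vs))[1])
  pop <- simulateF2Population(gm, vs, cl, 500, seed = 5)
  onChr2 <- which(as.character(seqnames(variantSites(vs))) == "chr2")
  G <- genotypes(pop)[, onChr2]
  # no crossover possible: every individual identical across chr2 sites
  expect_true(all(apply(G, 1, function(r) length(unique(r)) == 1L)))
})

test_that("gametic recombination follows the Haldane map function", {
  # two sites 10 cM apart: r = (1 - exp(-0.2))/2 ~ 0.0906
  gpos <- c(20, 30)
  gam <- PoolBSA:::.withSeed(42, PoolBSA:::.simGametes(gpos, 100, 50000))
  rf <- mean(gam[, 1] != gam[, 2])
  r <- (1 - exp(-0.2)) / 2
  expect_lt(abs(rf - r), 3 * sqrt(r * (1 - r) / 50000))
})

test_that("causal site absent from the variant set is an error", {
  gm <- fixMap()
  vs <- gridVariants(gm, 5)
  expect_error(
    simulateF2Population(gm, vs, causalLocus("chr1", 12345), 10),
    "chr1:12345")
})

test_that("pools contain only their phenotype class, without replacement", {
  gm <- fixMap(1, 1e7, 80)
  vs <- gridVariants(gm, 6)
  cl <- causalLocus("chr1", start(variantSites(vs))[3])
  pop <- simulateF2Population(gm, vs, cl, 1600, seed = 7)
  pools <- buildPools(pop, wpSize = 300, mpSize = 100, seed = 8)
  expect_length(pools@wp, 300)
  expect_length(pools@mp, 100)
  expect_true(all(phenotypes(pop)[pools@wp] == "green"))
  expect_true(all(phenotypes(pop)[pools@mp] == "pale"))
  expect_false(anyDuplicated(pools@wp) > 0)
  # shortfall is reported with the missing number
  expect_error(buildPools(pop, wpSize = 300, mpSize = 2000), "short by")
})

test_that("pool allele frequencies: MP 1 at causal, WP 1/3 in expectation", {
  gm <- fixMap(2, 1e7, 100)
  vs <- gridVariants(gm, 10)
  ci <- 5L
  cl <- causalLocus("chr1", start(variantSites(vs))[ci])
  fWPs <- vapply(1:30, function(i) {
    pop <- simulateF2Population(gm, vs, cl, 900, seed = 500 + i)
    pools <- buildPools(pop, 200, 150, seed = 600 + i)
    poolFrequencies(pools)[ci, ]
  }, numeric(2))
  expect_true(all(fWPs["MP", ] == 1))
  # WP genotypes at the causal site are 1(AA):2(Aa) -> allele freq 1/3;
  # 30 pools x 400 chromosomes, 3 SE band
  se <- sd(fWPs["WP", ]) / sqrt(ncol(fWPs))
  expect_lt(abs(mean(fWPs["WP", ]) - 1 / 3), 3 * se + 1e-3)
})

test_that("read-count sampling is exact at frequency extremes", {
  gm <- fixMap(1, 1e6, 10)
  vs <- gridVariants(gm, 4)
  cl <- causalLocus("chr1", start(variantSites(vs))[1])
  # engineered population: MP all hom-mut everywhere, WP all hom-WT
  G <- rbind(matrix(0L, 50, 4), matrix(2L, 50, 4))
  ph <- rep(c("green", "pale"), each = 50)
  pop <- manualPop(G, ph, gm, vs, cl)
  pools <- buildPools(pop, 50, 50, seed = 1)
  pc <- simulatePoolReadCounts(pools, meanDepth = 40, errorRate = 0,
                               seed = 2)
  expect_true(all(altCounts(pc)[, "MP"] == totalDepth(pc)[, "MP"]))
  expect_true(all(altCounts(pc)[, "WP"] == 0L))
})

test_that("mean SNP-index at f = 0.5 sits within binomial sampling error", {
  nSites <- 10000
  gm <- fixMap(1, 1e8, 10)
  vs <- gridVariants(gm, nSites)
  cl <- causalLocus("chr1", start(variantSites(vs))[1])
  # all-heterozygous pool members give true f = 0.5 at every site
  G <- matrix(1L, 40, nSites)
  G[1:20, 1] <- 2L
  ph <- c(rep("pale", 20), rep("green", 20))
  pop <- manualPop(G, ph, gm, vs, cl)
  pools <- buildPools(pop, 20, 20, seed = 3)
  pc <- simulatePoolReadCounts(pools, meanDepth = 100, errorRate = 0,
                               seed = 4)
  idx <- altCounts(pc)[-1, "WP"] / totalDepth(pc)[-1, "WP"]
  se <- sd(idx) / sqrt(length(idx))
  expect_lt(abs(mean(idx) - 0.5), 3 * se)
})

test_that("marker genotypes mirror the simulated individuals", {
  gm <- fixMap(2, 1e7, 100)
  vs <- gridVariants(gm, 8)
  s <- variantSites(vs)
  cl <- causalLocus("chr1", start(s)[4])
  pop <- simulateF2Population(gm, vs, cl, 3000, seed = 21)
  pale <- which(phenotypes(pop) == "pale")
  mk <- data.frame(id = c("causal", "unlinked"),
                   chrom = c("chr1", "chr2"),
                   pos = c(start(s)[4], start(s)[12]))
  M <- simulateMarkerGenotypes(pop, mk, individuals = pale)
  expect_true(all(M[, "causal"] == 2L))
  tab <- table(factor(M[, "unlinked"], 0:2))
  gof <- chiSquareGof(tab, c("0" = 0.25, "1" = 0.5, "2" = 0.25))
  expect_gt(gof$p.value, 0.001)
  expect_error(simulateMarkerGenotypes(
    pop, data.frame(id = "x", chrom = "chr1", pos = 999)), "unknown marker")
})

test_that("recombinant counts near the causal locus match 2n * Haldane r", {
  # marker 1 cM away, 885 mutant-class individuals:
  # E[recombinants] = 2 * 885 * (1 - exp(-0.02))/2 ~ 17.5
  gm <- fixMap(1, 1e7, 100)
  pos <- c(4e6, 4.1e6, 8e6)  # 1 cM and 40 cM from the causal site
  vs <- variantSet(rep("chr1", 3), pos, "G", "A")
  cl <- causalLocus("chr1", 4e6)
  counts <- vapply(1:8, function(s) {
    pop <- simulateF2Population(gm, vs, cl, 3800, seed = 300 + s)
    pale <- which(phenotypes(pop) == "pale")[1:885]
    M <- genotypes(pop)[pale, , drop = FALSE]
    colnames(M) <- c("causal", "near", "far")
    c(near = countRecombinants(M, "near")$count,
      far = countRecombinants(M, "far")$count)
  }, numeric(2))
  r1 <- (1 - exp(-0.02)) / 2
  expected <- 2 * 885 * r1
  expect_lt(abs(mean(counts["near", ]) - expected),
            4 * sd(counts["near", ]) / sqrt(8) + 2)
  # counts grow with genetic distance
  expect_gt(mean(counts["far", ]), mean(counts["near", ]))
})

test_that("EMS variant sets honour the transition bias and uniqueness", {
  gm <- fixMap(3, 5e6, 60)
  vs <- emsVariantSet(gm, 500, emsBias = 0.7, seed = 9)
  m <- mcols(variantSites(vs))
  ems <- (m$ref == "G" & m$alt == "A") | (m$ref == "C" & m$alt == "T")
  expect_gte(mean(ems), 0.7)
  expect_true(all(m$ref != m$alt))
  key <- paste(seqnames(variantSites(vs)), start(variantSites(vs)))
  expect_false(anyDuplicated(key) > 0)
})

test_that("lethal causal alleles remove homozygotes before phenotyping", {
  gm <- fixMap(1, 1e7, 60)
  vs <- gridVariants(gm, 4)
  cl <- causalLocus("chr1", start(variantSites(vs))[2], lethal = TRUE)
  pop <- simulateF2Population(gm, vs, cl, 4000, seed = 13)
  ci <- 2L
  expect_true(all(genotypes(pop)[, ci] != 2L))
  expect_true(all(phenotypes(pop) == "green"))
  expect_lt(length(pop), 4000)
})

test_that("simulation is deterministic under a fixed seed", {
  gm <- fixMap(2, 1e7, 90)
  vs1 <- emsVariantSet(gm, 50, seed = 77)
  vs2 <- emsVariantSet(gm, 50, seed = 77)
  expect_identical(vs1, vs2)
  cl <- causalLocus(as.character(seqnames(variantSites(vs1)))[10],
                    start(variantSites(vs1))[10])
  p1 <- simulateF2Population(gm, vs1, cl, 400, seed = 5)
  p2 <- simulateF2Population(gm, vs1, cl, 400, seed = 5)
  expect_identical(genotypes(p1), genotypes(p2))
  pc1 <- simulatePoolReadCounts(buildPools(p1, 50, 50, seed = 6), seed = 7)
  pc2 <- simulatePoolReadCounts(buildPools(p2, 50, 50, seed = 6), seed = 7)
  expect_identical(altCounts(pc1), altCounts(pc2))
  # and the caller's RNG stream is left untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulateF2Population(gm, vs1, cl, 10, seed = 1))
  expect_identical(runif(1), before)
})

test_that("phenotyping records round-trip through the calculators", {
  truth <- list(chlA = 2, chlB = 1, car = 0.5, V = 30, N = 1, W = 1)
  rec <- simulatePhenotypingRecords(truth, trace = fixTrace())
  p <- pigmentsFromAbsorbance(rec$absorbance$od663, rec$absorbance$od645,
                              rec$absorbance$od470, V = 30, N = 1, W = 1)
  expect_lt(abs(p$chlA - 2) / 2, 1e-9)
  expect_lt(abs(p$chlB - 1), 1e-9)
  expect_lt(abs(p$car - 0.5) / 0.5, 1e-9)
  expect_equal(as.list(rec$trace), fixTrace())
  # all-zero pigment state maps to all-zero ODs
  z <- simulatePhenotypingRecords(list(chlA = 0, chlB = 0, car = 0))
  expect_equal(unlist(z$absorbance[, c("od663", "od645", "od470")]),
               c(od663 = 0, od645 = 0, od470 = 0))
  # no non-negative absorbance solution
  expect_error(
    simulatePhenotypingRecords(list(chlA = 0, chlB = 0, car = -5)),
    "non-negative")
})

test_that("noisy phenotyping records are unbiased", {
  truth <- list(chlA = 1.5, chlB = 0.8, car = 0.4, V = 1, N = 1, W = 1)
  rec <- simulatePhenotypingRecords(truth, n = 1000, noiseSd = 0.01,
                                    seed = 31)
  p <- suppressWarnings(
    pigmentsFromAbsorbance(rec$absorbance$od663, rec$absorbance$od645,
                           rec$absorbance$od470, 1, 1, 1))
  expect_lt(abs(mean(p$chlA) - 1.5), 3 * sd(p$chlA) / sqrt(1000))
  expect_lt(abs(mean(p$chlB) - 0.8), 3 * sd(p$chlB) / sqrt(1000))
})
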