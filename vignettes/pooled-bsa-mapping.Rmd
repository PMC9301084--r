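---
title: "Mapping recessive loci by pooled-sequencing BSA: models and choices"
author: "PoolBSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive loci by pooled-sequencing BSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PoolBSA)
```

# The mapping model

PoolBSA targets the standard forward-genetics design for a monogenic
recessive trait: mutant × wild-type cross, F1 selfed, and two
phenotype-selected pools of F2 individuals sequenced — a wild-type pool
(WP) of phenotypically normal plants and a mutant pool (MP) of mutant
plants. At each biallelic variant site the per-pool **SNP-index** is the
fraction of reads carrying the mutant allele, and **ΔSNP-index** is
MP − WP.

Under Mendelian segregation the expectations are sharp. The MP contains
only homozygous mutants, so at the causal site its expected SNP-index is
exactly 1; the WP at that site is a 1(AA):2(Aa) mixture with expected
index 1/3; and at sites unlinked to the locus both pools hover around
1/2. The expected ΔSNP-index at the causal site is therefore 2/3, not 1.
This asymmetry drives the package's central design decision:

- **The interval-calling threshold (default 0.9) is applied to the MP
  SNP-index, not to Δ.** A 0.9 threshold is reachable in expectation only
  by the MP index (expected 1.0 at the causal site); the expected Δ of
  2/3 would never clear it. Both statistics are supported
  (`mappingConfig(statistic = "mp")` or `"delta"`), and the choice is an
  explicit configuration field rather than a hidden constant.

`computeSnpIndex` divides alt by total reads per pool with no
intermediate rounding, flags (never drops, never divides by zero) sites
where either pool is below `minDepth`, and records the reason. The
`minDepth` default of 10 reads per pool stabilises the ratio at
moderate sequencing depths; it is a declared default, not an inference —
pooled experiments rarely publish their depth filters.

`callIntervals` merges maximal runs of consecutive surviving sites at or
above the threshold. Interval ends are the first and last above-threshold
site positions (1-based inclusive); `gapTolerance` (default 0) may
bridge isolated below-threshold sites inside a run. Intervals are
reported widest first — the top interval is the mapping call — with the
leftmost first among ties, so output order is deterministic. Widths are
printed in Mb rounded *half-up* to two decimals (base R's `round` is
half-to-even; a span of 4,220,000 bp must print as 4.22, and a span
ending in .005 rounds up). Windowed smoothing (`windowProfile`) is
available but off by default: per-site dots are the native resolution of
pooled index plots, and smoothing only adds a bandwidth choice.

# Fine mapping

Among mutant-phenotype F2 individuals, every individual is homozygous
mutant at the causal locus, so a genotype call of homozygous wild type
or heterozygous at a marker evidences a crossover between marker and
locus. `countRecombinants` counts such calls, excluding missing
genotypes from numerator and denominator both — a missing call is never
treated as a recombinant, which is the conservative direction for
interval narrowing. `refineInterval` finds the longest run of
zero-recombinant markers and reports the interval between the nearest
recombinant-bearing marker on each side, using those flanking markers'
own positions as inclusive endpoints; a zero-recombinant run touching
the marker panel's edge leaves that side flagged open-ended rather than
silently bounded. Widths print in integer kb, again half-up (274,473 bp
→ 274 kb).

Genotyping error tolerance (e.g. requiring a recombinant to appear so at
two adjacent markers) is deliberately not the default: assays such as
high-resolution melting are accurate enough that the simple definition
is standard, and no error model is assumed where none is known.

# Cross genetics and the complementation test

`expectedProgeny` enumerates gametes exactly with integer weights —
each parent transmits each of its two alleles per gene with probability
1/2, genes unlinked — so class probabilities are exact rationals and
ratios are reduced to lowest terms; no floating-point ratio artifacts
are possible. Alleles are written `A1/a1/A2/a2` (upper case
functional). The **allelic model** places all four on one gene, making
the compound heterozygote a1/a2 mutant; the **non-allelic model** gives
each mutation its own gene, recessive at that gene. These two models
disagree exactly where the complementation test is informative: for the
heterozygous-carrier × homozygous-mutant cross (A2a2 × a1a1) the allelic
model predicts 1:1 green:pale while the two-gene model predicts uniform
green. A `lethal` genotype class (for insertion alleles whose
homozygotes die before scoring) is removed with exact renormalisation:
removing prior mass *q* rescales survivors by 1/(1−q) in integer
arithmetic.

`chiSquareGof` computes the Pearson statistic from its defining formula,
Σ(O−E)²/E, with the upper tail taken from the regularized incomplete
gamma function Q(df/2, x/2) (`pchisq`). Yates continuity correction is
available but off by default; published segregation tests rarely state
it, and the uncorrected statistic is the one with the textbook null
calibration checked below. `classifyAllelism` rejects a model in a cross
if it assigns probability zero to an observed class or its fit p-value
falls below α (default 0.05; the handful of pre-planned crosses are
tested without multiplicity correction, which is the field's practice
and is stated rather than hidden). The verdict requires the winning
model to survive every cross while its rival fails at least one
informative cross; anything else is `"inconclusive"`, and a design in
which the models do not differ anywhere is an error, not a verdict.

# Phenotyping calculators

`pigmentsFromAbsorbance` implements the acetone/ethanol-extract
equations verbatim, with the extract volume V (ml), dilution factor N
and fresh weight W (g) exactly where the printed formulas put them. That
includes the carotenoid equation's 104 coefficient and its missing ×N
factor, which differ from the common Lichtenthaler form (1000·A470 −
1.82·Chl a − 85.02·Chl b)/198; the latter is available behind
`variant = "lichtenthaler"` for comparison but is never the default —
the package computes what the protocol states, and a possible
typographical origin of the 104 is a documentation note, not a silent
correction. Negative pigment values are returned unclamped with a
warning; clamping would hide reading errors.

`fluorescenceParams` computes relative chlorophyll content
(k·log10[(Abs940·refAbs650)/(Abs650·refAbs940)]), Fv/Fm, Phi2, qL,
PhiNPQ, gH⁺ = 1/τ and the active-PSI fraction P_M/P_0. The instrument
constant k defaults to 1 and P_M, P_0 are accepted as given: the
device's calibration and PSI measurement protocol are not interpreted.
Trace invariants (Fm ≥ Fo > 0, Fm′ ≥ Fs > 0, Fm′ > Fo′ > 0, τ > 0,
positive absorbances) are validated with the offending quantity named.
Two properties are worth noting: Phi2 + PhiNPQ + Fs/Fm = 1 is an
algebraic identity of the formulas and is property-tested to 1e-12; and
the yield parameters are proper fractions only in the physiological
regime Fo′ ≤ Fs and Fm′ ≤ Fm, which the tests impose explicitly rather
than pretending it follows from the bare invariants.

`ddctRelativeExpression` pairs target and reference Ct values per
replicate, takes ΔΔCt as the difference of mean ΔCt between treatment
and control, and reports 2^−ΔΔCt with a spread interval
2^−(ΔΔCt ± se), se² = var_t/n_t + var_c/n_c.

# What the simulator emulates — and what it does not

The generator's defaults are the study conditions of a typical
maize-scale pooled mapping experiment: pools of 200 + 200 individuals,
mean pooled depth 50× per site, per-read miscall rate 0.005, a
predominantly G:C→A:T variant spectrum (70% minimum, the EMS
signature), full penetrance, and 1-based physical coordinates matching
VCF convention.

- **Meiosis** follows the Haldane model: crossover counts
  Poisson-distributed on genetic length in Morgans, positions uniform in
  genetic distance, no interference; physical↔genetic conversion is
  linear interpolation through the map's anchor points. Haldane is the
  simplest standard model and the only defensible choice when no
  species-specific interference map is assumed; its closed form
  r = (1 − e^(−2d))/2 is verified against 50,000 simulated gametes.
- **Read sampling** is Poisson depth × Binomial(depth,
  f(1−ε) + (1−f)ε) per site and pool, with an optional
  negative-binomial depth overdispersion parameter (off by default: the
  Poisson keeps the statistics interpretable, and pooled DNA depth
  heterogeneity is modest compared with expression data).
- **Phenotyping records** are generated by inverting the pigment
  equations (solving the 2×2 linear system for OD663/OD645 and the
  carotenoid equation for OD470), so zero-noise records reproduce their
  generating truth to machine precision — a round-trip oracle for both
  generator and calculator. Pigment states whose absorbance solution
  would be negative are rejected as errors.
- **Penetrance** (default 1.0) and **homozygote lethality** (default
  off) are exposed for robustness studies; clean segregation ratios are
  the default regime.

The simulator does **not** emulate read-level artifacts (no FASTQ, no
alignment or variant-calling errors), RNA-seq expression-coverage
heterogeneity across genes, allele-specific expression, segregation
distortion, or crossover interference. Passing tests therefore
demonstrate the statistical machinery under idealised sampling; on real
RNA-seq-derived pools, coverage will vary with expression and the
effective depth filter matters more than it does here.

# Validation design and problem sizes

The test suite validates each stage against an independent oracle:
interval calls against an exhaustive brute-force scan on random ≤500-site
profiles; window means against site-by-site recomputation; the
chi-square tail against `chisq.test` to 1e-10; segregation and
recombination rates against closed-form expectations with 3-standard-error
Monte-Carlo bands.

End-to-end locus recovery is measured over 200 simulated experiments on
a 3-chromosome genome (50 Mb / 100 cM each) carrying 100 variant sites
per chromosome (≈1 cM spacing, the density a transcriptome-wide EMS
variant set typically yields), with the causal site placed uniformly at
random, 1,100 F2 individuals feeding 200 + 200 pools at 50× depth and
ε = 0.005: the top called interval must contain the causal position in
at least 95% of runs. Site density matters here — at a few cM between
sites, neighbours of the causal locus sit near the 0.9 boundary and
fragment the peak; ≈1 cM spacing reflects realistic data and gives a
contiguous supporting run.

Test calibration of the 3:1 goodness-of-fit test deserves a note. A
true-3:1 F2 sample of n = 400 is fully described by its binomial pale
count, so the type-I error of the α = 0.05 test can be **enumerated
exactly** (it is 0.0565 — slightly above nominal, the usual discreteness
effect); the suite asserts the 0.04–0.06 calibration band on that exact
value and separately checks that a 10,000-replicate simulation agrees
with it within Monte-Carlo error. Likewise the 1:2:1 genotype-frequency
invariant is asserted on counts pooled across 20 independent simulations
of 10,000 individuals, with the per-seed rejection count bounded at its
binomial α = 0.01 expectation — per-seed all-must-pass assertions at
α = 0.01 would fail about one run in five for a perfectly calibrated
simulator, which is a property of the assertion, not the simulator.

# Numerical and interface choices

- Exact arithmetic where exactness is the point: gamete enumeration and
  ratio reduction are integer; SNP-index division is a single
  floating-point operation per pool with no premature rounding.
- All stochastic functions take an optional `seed` applied in a local
  RNG scope: the caller's random stream is untouched, and a fixed
  seed + configuration reproduces outputs exactly.
- Ties and degenerate inputs are resolved deterministically: leftmost
  interval first among equal widths, empty profiles give empty calls,
  zero-depth sites are filtered with reason `"zero depth"`.
- I/O is minimal VCF 4.2 (AD/DP FORMAT fields, parsed via
  VariantAnnotation) and documented TSVs; write→read round-trips are
  lossless for every field used downstream. Multi-allelic and indel
  records are skipped with a logged count — the analysis is defined on
  biallelic SNVs.

# Known limitations

- No confidence envelopes on the SNP-index profile (QTL-seq style
  permutation bands); the threshold rule is the published practice this
  package reproduces.
- The two-locus cross model assumes unlinked genes; a linked
  complementation design would need a recombination-aware extension.
- `RefinedInterval` endpoints are marker positions; the true locus lies
  strictly inside, so the reported width is an upper bound tied to
  marker density.
- The simulator's idealisations listed above mean real-data performance
  depends on variant density and depth uniformity in ways the recovery
  rate here does not capture.
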