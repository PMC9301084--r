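#' Construct an allele model
#'
#' @param allelic logical; TRUE (default) for the same-gene model in which
#'   a1 and a2 are alleles of one gene (so the compound heterozygote a1/a2
#'   is mutant), FALSE for the two-gene model in which each mutation is
#'   recessive at its own, unlinked gene.
#' @return an \linkS4class{AlleleModel}.
#' @export
alleleModel <- function(allelic = TRUE) {
  new("AlleleModel", allelic = allelic)
}

setMethod("show", "AlleleModel", function(object) {
  cat(if (object@allelic) "AlleleModel: allelic (a1, a2 same gene)\n"
      else "AlleleModel: non-allelic (two unlinked genes)\n")
})

# "A2a2" -> c("A2", "a2"); validates the allele alphabet
.parseGenotype <- function(s) {
  s <- gsub("[[:space:]/]", "", s)
  al <- regmatches(s, gregexpr("[A-Za-z][0-9]?", s))[[1]]
  ok <- grepl("^[Aa][12]$", al)
  if (length(al) == 0L || any(!ok) ||
      nchar(s) != sum(nchar(al)))
    .stopf("cannot parse genotype '%s': alleles must be A1/a1/A2/a2", s)
  al
}

.isFunctional <- function(allele) substr(allele, 1, 1) == "A"
.locusOf <- function(allele) substr(allele, 2, 2)

# Expand a parent's parsed alleles to a per-gene list of 2 alleles each.
# Under the two-gene model, a gene not mentioned is implicitly homozygous
# functional.
.parentLoci <- function(alleles, allelic) {
  if (allelic) {
    if (length(alleles) != 2L)
      .stopf("each parent needs exactly two alleles, got '%s'",
             paste(alleles, collapse = ""))
    return(list(g = alleles))
  }
  out <- list()
  for (g in c("1", "2")) {
    mine <- alleles[.locusOf(alleles) == g]
    if (length(mine) == 0L) mine <- rep(paste0("A", g), 2L)
    if (length(mine) != 2L)
      .stopf("parent must carry exactly two alleles at gene %s", g)
    out[[g]] <- mine
  }
  out
}

# mutant iff no functional allele at the affected gene(s)
.isMutant <- function(offspring, allelic) {
  if (allelic) return(!any(.isFunctional(offspring$g)))
  any(vapply(offspring, function(pair) !any(.isFunctional(pair)),
             logical(1)))
}

#' Expected progeny phenotype distribution for a cross
#'
#' Enumerates all gamete combinations of the two parents with exact
#' integer weights (each parent transmits each of its two alleles per gene
#' with probability 1/2; genes are unlinked), applies the recessive
#' phenotype rule of the model, optionally removes a lethal genotype class
#' and renormalizes exactly, and reduces the green:pale ratio to lowest
#' terms.
#'
#' @param cross parent genotypes: a length-2 character vector such as
#'   \code{c("A2a2", "a1a1")} or a single string \code{"A2a2 x a1a1"}.
#'   Upper case = functional allele; subscript = mutation 1 or 2.  Under
#'   the two-gene model a gene not mentioned in a parent is homozygous
#'   functional.
#' @param model an \linkS4class{AlleleModel} (default allelic).
#' @param lethal optional genotype string (e.g. \code{"a2a2"}) naming a
#'   zygote class removed before phenotyping, with exact renormalization
#'   of the survivors.
#' @return a \linkS4class{ProgenyDistribution}.
#' @examples
#' expectedProgeny(c("A1a1", "A1a1"))            # F2 self: 3:1
#' expectedProgeny("A2a2 x a1a1")                # allelic test: 1:1
#' expectedProgeny("A2a2 x a1a1", alleleModel(FALSE))  # two genes: all green
#' @export
expectedProgeny <- function(cross, model = alleleModel(TRUE),
                            lethal = NULL) {
  if (length(cross) == 1L) cross <- strsplit(cross, "[xX×]")[[1]]
  if (length(cross) != 2L) .stopf("a cross needs exactly two parents")
  p1 <- .parentLoci(.parseGenotype(cross[1]), model@allelic)
  p2 <- .parentLoci(.parseGenotype(cross[2]), model@allelic)
  lethalPair <- if (is.null(lethal)) NULL
                else sort(.parseGenotype(lethal))
  genes <- names(p1)
  # per-gene offspring allele pairs: 4 equally weighted combinations
  combos <- lapply(genes, function(g)
    expand.grid(a = p1[[g]], b = p2[[g]], stringsAsFactors = FALSE))
  idx <- expand.grid(lapply(combos, function(d) seq_len(nrow(d))))
  total <- nrow(idx)
  green <- 0L; pale <- 0L; removed <- 0L
  for (r in seq_len(total)) {
    offspring <- lapply(seq_along(genes), function(k) {
      d <- combos[[k]][idx[r, k], ]
      c(d$a, d$b)
    })
    names(offspring) <- genes
    if (!is.null(lethalPair) &&
        any(vapply(offspring, function(pair)
          identical(sort(pair), lethalPair), logical(1)))) {
      removed <- removed + 1L
      next
    }
    if (.isMutant(offspring, model@allelic)) pale <- pale + 1L
    else green <- green + 1L
  }
  surv <- total - removed
  if (surv == 0L) .stopf("all progeny classes are lethal")
  counts <- c(green = green, pale = pale)
  g <- .gcd(counts[counts > 0])
  ratio <- as.integer(ifelse(counts > 0, counts / g, 0L))
  names(ratio) <- names(counts)
  tab <- data.frame(phenotype = c("green", "pale"),
                    count = as.integer(counts),
                    prob = counts / surv, row.names = NULL)
  new("ProgenyDistribution", table = tab, total = as.integer(surv),
      ratio = ratio)
}

#' @rdname ProgenyDistribution-class
#' @export
setMethod("ratioOf", "ProgenyDistribution", function(x) x@ratio)

#' @rdname ProgenyDistribution-class
#' @export
setMethod("probabilities", "ProgenyDistribution", function(x) {
  stats::setNames(x@table$prob, x@table$phenotype)
})

setMethod("show", "ProgenyDistribution", function(object) {
  r <- object@ratio
  cat(sprintf("ProgenyDistribution: green %d/%d, pale %d/%d (green:pale = %d:%d)\n",
              object@table$count[1], object@total,
              object@table$count[2], object@total, r[["green"]],
              r[["pale"]]))
})

#' Pearson chi-square goodness-of-fit test
#'
#' The statistic is computed from its defining formula,
#' sum((O - E)^2 / E) with E = total x expected probability; the upper
#' tail probability is the regularized incomplete gamma function
#' Q(df/2, x/2), evaluated via \code{pchisq}.
#'
#' @param observed named numeric vector of class counts.
#' @param expected expected class probabilities: a named numeric vector or
#'   a \linkS4class{ProgenyDistribution}.
#' @param correct logical; apply the Yates continuity correction
#'   (default FALSE).
#' @return list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{expected}.
#' @export
chiSquareGof <- function(observed, expected, correct = FALSE) {
  if (is(expected, "ProgenyDistribution")) expected <- probabilities(expected)
  if (is.null(names(observed)) || is.null(names(expected)))
    .stopf("observed and expected must be named by phenotype class")
  expected <- expected[names(observed)]
  if (anyNA(expected)) .stopf("expected probabilities missing for a class")
  if (any(observed < 0)) .stopf("negative observed count")
  total <- sum(observed)
  if (total <= 0) .stopf("total observed count must be positive")
  zero <- expected == 0
  if (any(zero & observed > 0))
    .stopf("class '%s' has expected probability 0 but %d observed",
           names(observed)[zero & observed > 0][1],
           observed[zero & observed > 0][1])
  observed <- observed[!zero]
  expected <- expected[!zero]
  E <- total * expected / sum(expected)
  dev <- abs(observed - E)
  if (correct) dev <- pmax(dev - 0.5, 0)
  statistic <- sum(dev^2 / E)
  df <- length(observed) - 1L
  p <- if (df == 0L) 1 else stats::pchisq(statistic, df, lower.tail = FALSE)
  list(statistic = statistic, df = df, p.value = p, expected = E)
}

#' Classify a complementation test as allelic or non-allelic
#'
#' Fits observed progeny counts of one or more crosses against the
#' predictions of the allelic (same-gene) and non-allelic (two-gene)
#' models.  A model is rejected in a cross when a phenotype class it
#' predicts impossible was observed, or when the chi-square
#' goodness-of-fit p-value falls below \code{alpha}.  The verdict names a
#' model when it is rejected in no cross while its rival is rejected in at
#' least one informative cross (a cross whose two predicted distributions
#' differ); otherwise \code{"inconclusive"}.
#'
#' @param crosses list; each element a list with \code{parents} (length-2
#'   character) and \code{observed} (named counts, classes green/pale).
#' @param alpha significance level (default 0.05; the few pre-planned
#'   crosses are tested without multiplicity correction).
#' @param lethal optional lethal genotype class passed to
#'   \code{\link{expectedProgeny}}.
#' @return list with \code{verdict} (\code{"allelic"},
#'   \code{"non-allelic"} or \code{"inconclusive"}) and \code{perCross}
#'   data.frame of per-cross fit statistics.
#' @export
classifyAllelism <- function(crosses, alpha = 0.05, lethal = NULL) {
  fit <- function(obs, dist) {
    pr <- probabilities(dist)[names(obs)]
    if (any(pr == 0 & obs > 0))
      return(list(p = 0, rejected = TRUE))
    gof <- chiSquareGof(obs, dist)
    list(p = gof$p.value, rejected = gof$p.value < alpha)
  }
  rows <- lapply(crosses, function(cr) {
    dA <- expectedProgeny(cr$parents, alleleModel(TRUE), lethal)
    dN <- expectedProgeny(cr$parents, alleleModel(FALSE), lethal)
    info <- !isTRUE(all.equal(probabilities(dA), probabilities(dN)))
    fA <- fit(cr$observed, dA)
    fN <- fit(cr$observed, dN)
    data.frame(cross = paste(cr$parents, collapse = " x "),
               informative = info, pAllelic = fA$p,
               pNonAllelic = fN$p, rejAllelic = fA$rejected,
               rejNonAllelic = fN$rejected)
  })
  perCross <- do.call(rbind, rows)
  if (!any(perCross$informative))
    .stopf("designs do not discriminate: no informative cross")
  inf <- perCross$informative
  allelicOk <- !any(perCross$rejAllelic)
  nonOk <- !any(perCross$rejNonAllelic)
  verdict <- if (allelicOk && any(perCross$rejNonAllelic[inf])) "allelic"
             else if (nonOk && any(perCross$rejAllelic[inf])) "non-allelic"
             else "inconclusive"
  list(verdict = verdict, perCross = perCross)
}
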