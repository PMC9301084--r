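#' Write pooled counts as minimal VCF 4.2
#'
#' One sample column per pool with \code{AD} (ref,alt read depths) and
#' \code{DP} (total depth) FORMAT fields; INFO is left empty.  This is
#' the dialect \code{\link{readPooledVcf}} consumes.
#'
#' @param counts a \linkS4class{PooledCounts}.
#' @param path output file path (a plain-text .vcf).
#' @return \code{path}, invisibly.
#' @export
writePooledVcf <- function(counts, path) {
  gr <- SummarizedExperiment::rowRanges(counts)
  a <- altCounts(counts); d <- totalDepth(counts)
  pools <- colnames(a)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=PoolBSA",
    sprintf("##contig=<ID=%s>",
            unique(as.character(seqnames(gr)))),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", pools), collapse = "\t")), con)
  sampleCols <- vapply(seq_along(gr), function(i) {
    paste(vapply(pools, function(p)
      sprintf("%d,%d:%d", d[i, p] - a[i, p], a[i, p], d[i, p]),
      character(1)), collapse = "\t")
  }, character(1))
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD:DP\t%s",
                     as.character(seqnames(gr)), start(gr),
                     mcols(gr)$ref, mcols(gr)$alt, sampleCols), con)
  invisible(path)
}

#' Read pooled allelic depths from a VCF
#'
#' Parses a VCF 4.x file (plain or bgzip) whose sample columns carry
#' \code{AD} (and optionally \code{DP}) FORMAT fields.  Only biallelic
#' SNVs are kept; multi-allelic and indel records are skipped and their
#' count reported via \code{message()} and stored in
#' \code{metadata()$skipped}.  Depth is taken from \code{DP} when present,
#' otherwise as the sum of \code{AD}.
#'
#' @param path VCF file path.
#' @param wpCol,mpCol names the wild-type and mutant pool sample columns
#'   are renamed to; NULL keeps the file's sample names.  The default
#'   assumes the file's first sample is the wild-type pool and the second
#'   the mutant pool.
#' @return a \linkS4class{PooledCounts} in the file's coordinate order.
#' @export
readPooledVcf <- function(path, wpCol = "WP", mpCol = "MP") {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  g <- VariantAnnotation::geno(vcf)
  samples <- colnames(vcf)
  if (!"AD" %in% names(g))
    .stopf("sample(s) %s lack the AD FORMAT field in %s",
           paste(samples, collapse = ", "), path)
  gr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(seqnames(gr))
  for (cn in unique(chrom)) {
    if (is.unsorted(start(gr)[chrom == cn]))
      .stopf("input VCF is not coordinate-sorted (chromosome %s)", cn)
  }
  refs <- VariantAnnotation::ref(vcf)
  alts <- VariantAnnotation::alt(vcf)
  nAlt <- S4Vectors::elementNROWS(alts)
  altW <- rep(0L, length(vcf))
  altW[nAlt == 1L] <- BiocGenerics::width(unlist(alts[nAlt == 1L]))
  snv <- nAlt == 1L & BiocGenerics::width(refs) == 1L & altW == 1L
  skipped <- sum(!snv)
  if (skipped)
    message(sprintf("skipped %d multi-allelic or indel record(s)", skipped))
  vcf <- vcf[snv]
  g <- VariantAnnotation::geno(vcf)
  n <- nrow(vcf)
  alt <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
  depth <- alt
  AD <- g$AD
  for (s in seq_along(samples)) {
    # readVcf returns Number=R fields as an n x samples x alleles array
    # when allele counts are uniform, else a matrix of integer vectors
    ads <- if (is.array(AD) && length(dim(AD)) == 3L)
      lapply(seq_len(n), function(i) AD[i, s, ])
    else as.list(AD[, s])
    bad <- vapply(ads, function(x) length(x) < 2L || anyNA(x), logical(1))
    if (n && any(bad))
      .stopf("sample '%s' is missing AD values (first at record %d)",
             samples[s], which(bad)[1])
    alt[, s] <- vapply(ads, function(x) as.integer(x[2L]), integer(1))
    depth[, s] <- if ("DP" %in% names(g)) as.integer(g$DP[, s])
                  else vapply(ads, sum, numeric(1))
  }
  poolNames <- samples
  if (!is.null(wpCol) && length(samples) == 2L)
    poolNames <- c(wpCol, mpCol)
  out <- SummarizedExperiment::rowRanges(vcf)
  sites <- GRanges(as.character(seqnames(out)),
                   IRanges(start(out), width = 1L))
  mcols(sites)$ref <- as.character(refs[snv])
  mcols(sites)$alt <- as.character(unlist(alts[snv]))
  mcols(sites)$origin <- "mutant"
  pc <- pooledCounts(sites, alt, depth, poolNames)
  metadata(pc)$skipped <- skipped
  pc
}

#' Write / read pooled counts as TSV
#'
#' Columns: \code{chrom}, \code{pos}, \code{ref}, \code{alt}, then
#' \code{alt_<pool>} and \code{depth_<pool>} per pool.
#'
#' @param counts a \linkS4class{PooledCounts}.
#' @param path file path.
#' @return \code{writePooledTsv}: \code{path} invisibly;
#'   \code{readPooledTsv}: a \linkS4class{PooledCounts}.
#' @export
writePooledTsv <- function(counts, path) {
  gr <- SummarizedExperiment::rowRanges(counts)
  a <- altCounts(counts); d <- totalDepth(counts)
  df <- data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
                   ref = mcols(gr)$ref, alt = mcols(gr)$alt)
  for (p in colnames(a)) {
    df[[paste0("alt_", p)]] <- a[, p]
    df[[paste0("depth_", p)]] <- d[, p]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePooledTsv
#' @export
readPooledTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  altCols <- grep("^alt_", names(df), value = TRUE)
  pools <- sub("^alt_", "", altCols)
  alt <- as.matrix(df[paste0("alt_", pools)])
  depth <- as.matrix(df[paste0("depth_", pools)])
  colnames(alt) <- colnames(depth) <- pools
  sites <- GRanges(df$chrom, IRanges(df$pos, width = 1L))
  mcols(sites)$ref <- df$ref
  mcols(sites)$alt <- df$alt
  mcols(sites)$origin <- "mutant"
  pooledCounts(sites, alt, depth, pools)
}

#' Read a marker genotype matrix from TSV
#'
#' First column: individual id; remaining columns: marker calls in
#' \{0, 1, 2, NA\}.  Missing calls are preserved as NA, never imputed;
#' any other cell value is an error reporting its row and column.
#'
#' @param path TSV file path.
#' @return integer matrix, individuals x markers, with dimnames.
#' @export
readGenotypeMatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) .stopf("genotype TSV needs an id column plus markers")
  ids <- df[[1]]
  M <- as.matrix(df[, -1, drop = FALSE])
  ok <- M %in% c("0", "1", "2", "NA", "") | is.na(M)
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow(M)), arr.ind = TRUE)[1, ]
    .stopf("invalid genotype '%s' at row %d (individual '%s'), column '%s'",
           M[bad[1], bad[2]], bad[1], ids[bad[1]],
           colnames(M)[bad[2]])
  }
  M[M %in% c("NA", "")] <- NA
  storage.mode(M) <- "integer"
  rownames(M) <- ids
  M
}

#' Write a marker genotype matrix to TSV
#'
#' @param geno integer matrix (individuals x markers).
#' @param path TSV file path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeMatrix <- function(geno, path) {
  df <- data.frame(id = rownames(geno) %||% seq_len(nrow(geno)), geno,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
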