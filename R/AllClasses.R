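#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

#' GenotypePanel: hard-call genotypes with a sorted variant map
#'
#' A \code{GenotypePanel} holds biallelic SNP hard calls (counts of the minor
#' allele, values 0/1/2 or \code{NA}) for a set of unrelated individuals,
#' together with the variant map (chromosome, 1-based bp position, minor and
#' major allele, minor-allele frequency). It extends
#' \code{RangedSummarizedExperiment}: variants are rows, samples are columns,
#' and the single assay is named \code{"calls"}.
#'
#' Invariants enforced by the validity method: variants sorted by
#' (chromosome, position); every column of calls counts the \emph{minor}
#' allele, so no variant has empirical allele frequency above 0.5 (+ tie
#' tolerance); calls take values in \{0, 1, 2, NA\}.
#'
#' @export
setClass("GenotypePanel", contains = "RangedSummarizedExperiment")

.chromOrder <- function(chrom) {
  ## numeric chromosomes sort numerically, others lexicographically after
  num <- suppressWarnings(as.numeric(chrom))
  ord <- order(is.na(num), num, chrom)
  ord
}

setValidity("GenotypePanel", function(object) {
  msg <- character()
  if (!("calls" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'calls' is missing")
  else {
    g <- SummarizedExperiment::assay(object, "calls")
    bad <- g[!is.na(g)]
    if (length(bad) && !all(bad %in% 0:2))
      msg <- c(msg, "calls must be 0, 1, 2 or NA")
    if (nrow(g)) {
      frq <- rowMeans(g, na.rm = TRUE) / 2
      frq[is.nan(frq)] <- 0
      if (any(frq > 0.5 + 1e-9))
        msg <- c(msg, "calls must count the minor allele (frequency <= 0.5)")
    }
  }
  need <- c("id", "alleleMinor", "alleleMajor", "maf")
  if (!all(need %in% names(mcols(object))))
    msg <- c(msg, paste("rowRanges mcols must contain",
                        paste(need, collapse = ", ")))
  map <- data.frame(chrom = as.character(seqnames(object)),
                    pos = BiocGenerics::start(object))
  if (nrow(map) > 1) {
    ord <- order(match(map$chrom, unique(map$chrom)[.chromOrder(unique(map$chrom))]),
                 map$pos)
    if (!identical(ord, seq_len(nrow(map))))
      msg <- c(msg, "variants must be sorted by (chrom, pos)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' Builds the panel from a calls matrix and a variant map, re-orienting each
#' variant so that calls count the minor allele (at frequency exactly 0.5 the
#' lexicographically smaller allele is declared minor), recomputing MAF from
#' the data, and sorting variants by (chromosome, position).
#'
#' @param calls integer matrix, variants x samples, allele counts of
#'   \code{allele1} in \{0,1,2,NA\}.
#' @param chrom,pos,id variant map vectors (pos is 1-based bp as in PLINK bim).
#' @param allele1 allele counted by \code{calls}; \code{allele2} the other.
#' @param allele2 see \code{allele1}.
#' @param samples sample identifiers (columns of \code{calls}).
#' @return a \code{GenotypePanel}.
#' @export
GenotypePanel <- function(calls, chrom, pos, id, allele1, allele2, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(nrow(calls) == length(chrom), length(chrom) == length(pos),
            length(id) == length(pos), ncol(calls) == length(samples))
  if (any(pos < 1)) stop("positions must be >= 1 (1-based, bim convention)")
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  chrom <- as.character(chrom)
  allele1 <- as.character(allele1); allele2 <- as.character(allele2)

  frq <- rowMeans(calls, na.rm = TRUE) / 2
  frq[is.nan(frq)] <- 0
  flip <- frq > 0.5 | (abs(frq - 0.5) < 1e-12 & allele2 < allele1)
  if (any(flip)) {
    calls[flip, ] <- 2L - calls[flip, , drop = FALSE]
    tmp <- allele1[flip]; allele1[flip] <- allele2[flip]; allele2[flip] <- tmp
    frq[flip] <- 1 - frq[flip]
  }

  ord <- order(match(chrom, unique(chrom)[.chromOrder(unique(chrom))]), pos)
  calls <- calls[ord, , drop = FALSE]
  rr <- GRanges(chrom[ord], IRanges(pos[ord], width = 1L))
  mcols(rr) <- DataFrame(id = as.character(id)[ord],
                         alleleMinor = allele1[ord],
                         alleleMajor = allele2[ord],
                         maf = frq[ord])
  names(rr) <- mcols(rr)$id
  rownames(calls) <- mcols(rr)$id
  colnames(calls) <- as.character(samples)
  se <- SummarizedExperiment(assays = list(calls = calls), rowRanges = rr)
  new("GenotypePanel", se)
}

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel with", nrow(object), "variants x", ncol(object),
      "samples\n")
  map <- variantInfo(object)
  cat("  chromosomes:", paste(unique(map$chrom), collapse = ", "), "\n")
  cat("  MAF range: [", sprintf("%.4g", min(map$maf)), ", ",
      sprintf("%.4g", max(map$maf)), "]\n", sep = "")
  miss <- mean(is.na(SummarizedExperiment::assay(object, "calls")))
  cat("  missing call rate:", sprintf("%.4g", miss), "\n")
})

#' CollapsingMatrix: map from the 3x3 two-SNP genotype grid to pseudo-genotypes
#'
#' A total map from each genotype combination (g1, g2) in \{0,1,2\}^2 to a
#' pseudo-genotype category (consecutive integers from 0), encoding the joint
#' genetic model under which two nearby SNPs are collapsed into one
#' pseudo-marker.
#'
#' @slot name one of "recessive_default", "additive_alternative", "custom".
#' @slot map 3x3 integer matrix; \code{map[g1+1, g2+1]} is the category.
#' @export
setClass("CollapsingMatrix",
         representation(name = "character", map = "matrix"))

setValidity("CollapsingMatrix", function(object) {
  m <- object@map
  if (!identical(dim(m), c(3L, 3L))) return("map must be 3x3")
  v <- sort(unique(as.integer(m)))
  if (!identical(v, seq(0L, max(v))))
    return("categories must be consecutive integers starting at 0")
  TRUE
})

#' Built-in collapsing matrices
#'
#' \code{additiveMatrix()} is the alternative collapsing matrix for a joint
#' additive effect of the minor alleles: the pseudo-marker counts 0, 1, or
#' "2 or more" minor alleles across both SNPs, i.e. \code{min(g1 + g2, 2)}.
#' \code{recessiveMatrix()} is the default matrix for a joint recessive model:
#' category 0 for at most one minor allele, category 1 for two or more.
#' \code{customMatrix(map)} wraps a user 3x3 category map.
#'
#' @return a \code{CollapsingMatrix}.
#' @export
additiveMatrix <- function() {
  m <- outer(0:2, 0:2, function(a, b) pmin(a + b, 2L))
  storage.mode(m) <- "integer"
  new("CollapsingMatrix", name = "additive_alternative", map = m)
}

#' @rdname additiveMatrix
#' @export
recessiveMatrix <- function() {
  m <- outer(0:2, 0:2, function(a, b) as.integer(a + b >= 2))
  storage.mode(m) <- "integer"
  new("CollapsingMatrix", name = "recessive_default", map = m)
}

#' @rdname additiveMatrix
#' @param map 3x3 integer matrix of pseudo-genotype categories.
#' @export
customMatrix <- function(map) {
  map <- as.matrix(map)
  storage.mode(map) <- "integer"
  new("CollapsingMatrix", name = "custom", map = map)
}

#' Number of pseudo-genotype categories of a collapsing matrix
#' @param x a \code{CollapsingMatrix}.
#' @export
nCategories <- function(x) length(unique(as.integer(x@map)))

setMethod("show", "CollapsingMatrix", function(object) {
  cat("CollapsingMatrix <", object@name, "> with ", nCategories(object),
      " categories\n", sep = "")
  print(object@map)
})

#' WindowSpec: sliding-window parameters of the GCDH scan
#'
#' @slot k maximum number of pairing SNPs (= tests) per index-SNP window.
#' @slot d maximum index-to-partner distance in bp.
#' @slot pFilter marginal single-SNP P-value inclusion threshold.
#' @slot rule which pair member must pass the p-filter: "either" (default),
#'   "both", or "index".
#' @export
setClass("WindowSpec",
         representation(k = "integer", d = "numeric", pFilter = "numeric",
                        rule = "character"))

setValidity("WindowSpec", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (object@d < 1) return("d must be >= 1")
  if (object@pFilter <= 0 || object@pFilter > 1)
    return("pFilter must be in (0, 1]")
  if (!object@rule %in% c("either", "both", "index"))
    return("rule must be 'either', 'both' or 'index'")
  TRUE
})

#' Construct a WindowSpec
#'
#' Defaults follow the genome-wide height screen: k = 300 pairing SNPs,
#' d = 500 kbp, p-filter = 0.1, with the "either" member rule (a pair enters
#' the scan when at least one member passes the marginal filter).
#'
#' @param k,d,pFilter,rule see slots of \code{\linkS4class{WindowSpec}}.
#' @export
windowSpec <- function(k = 300L, d = 5e5, pFilter = 0.1,
                       rule = c("either", "both", "index")) {
  new("WindowSpec", k = as.integer(k), d = as.numeric(d),
      pFilter = as.numeric(pFilter), rule = match.arg(rule))
}

setMethod("show", "WindowSpec", function(object) {
  cat("WindowSpec: k =", object@k, ", d =", format(object@d, big.mark = ","),
      "bp, p-filter =", object@pFilter, paste0("(", object@rule, ")\n"))
})

#' HaplotypeFreqs: two-locus haplotype frequency estimates
#'
#' EM estimates of the four haplotype frequencies of a SNP pair. Labels use
#' A/B for the major and a/b for the minor allele at SNP1/SNP2, so \code{fab}
#' is the both-minor haplotype.
#'
#' @slot freqs named numeric of length 4 (\code{AB}, \code{Ab}, \code{aB},
#'   \code{ab}), summing to 1.
#' @slot logLik final observed-data log-likelihood.
#' @slot iterations EM iterations used.
#' @slot converged logical convergence flag.
#' @export
setClass("HaplotypeFreqs",
         representation(freqs = "numeric", logLik = "numeric",
                        iterations = "integer", converged = "logical"))

setValidity("HaplotypeFreqs", function(object) {
  f <- object@freqs
  if (!identical(names(f), c("AB", "Ab", "aB", "ab")))
    return("freqs must be named AB, Ab, aB, ab")
  if (any(f < -1e-12) || abs(sum(f) - 1) > 1e-12)
    return("freqs must be a probability vector summing to 1")
  TRUE
})

#' Haplotype frequency accessor
#' @param x a \code{HaplotypeFreqs}.
#' @export
haplotypeFreqs <- function(x) x@freqs

setMethod("show", "HaplotypeFreqs", function(object) {
  cat("Two-locus haplotype frequencies (EM,", object@iterations,
      if (object@converged) "iterations, converged)\n" else
        "iterations, NOT converged)\n")
  print(round(object@freqs, 6))
  cat("log-likelihood:", object@logLik, "\n")
})

#' GcdhScan: result of a genome-wide GCDH sliding-window scan
#'
#' @slot scan one row per index SNP with at least one eligible pair: minimum
#'   P in the window, best partner, effect of the best pair, tests performed.
#' @slot pairs all fitted pseudo-marker tests (one row per pair).
#' @slot spec the \code{WindowSpec} used.
#' @slot matrixName name of the collapsing matrix used.
#' @slot threshold derived per-window Bonferroni significance threshold
#'   (genome-wide alpha / k).
#' @slot nSkipped pairs skipped as degenerate or under the complete-case
#'   minimum.
#' @export
setClass("GcdhScan",
         representation(scan = "data.frame", pairs = "data.frame",
                        spec = "WindowSpec", matrixName = "character",
                        threshold = "numeric", nSkipped = "integer"))

#' Accessors for GcdhScan results
#'
#' \code{scanRecords} returns the per-index-SNP minimum-P table,
#' \code{pairResults} every fitted pair, and \code{significantPairs} the scan
#' records below the derived threshold.
#'
#' @param x a \code{GcdhScan}.
#' @export
scanRecords <- function(x) x@scan

#' @rdname scanRecords
#' @export
pairResults <- function(x) x@pairs

#' @rdname scanRecords
#' @export
significantPairs <- function(x) x@scan[x@scan$minP < x@threshold, , drop = FALSE]

#' @rdname scanRecords
#' @export
gcdhThresholdOf <- function(x) x@threshold

setMethod("show", "GcdhScan", function(object) {
  cat("GCDH scan (", object@matrixName, "): ", nrow(object@scan),
      " index SNPs, ", nrow(object@pairs), " pseudo-marker tests\n", sep = "")
  show(object@spec)
  cat("significance threshold:", format(object@threshold, digits = 3),
      "-", nrow(significantPairs(object)), "significant index SNPs\n")
})
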