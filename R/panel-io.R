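## Genotype, phenotype, weight and result-table I/O.
##
## PLINK binary filesets are read and written directly (SNP-major bed v1.00,
## magic 0x6c 0x1b 0x01; 2-bit codes 00 = hom A1, 10 = het, 11 = hom A2,
## 01 = missing). VCF input goes through vcfR; DS dosages are hard-called by
## round-half-to-even, GT by counting ALT alleles.

## 256 x 4 lookup: byte value -> A1 dosage of its four packed genotypes
.bedLut <- local({
  codeToDose <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  lut <- matrix(NA_integer_, 256L, 4L)
  for (b in 0:255) {
    x <- b
    for (s in 1:4) {
      lut[b + 1L, s] <- codeToDose[as.character(x %% 4L)]
      x <- x %/% 4L
    }
  }
  lut
})

.readBed <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "character", "character"))
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = "character")
  nSnp <- nrow(bim); nInd <- nrow(fam)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(nInd / 4) * nSnp)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b) ||
      raw[3] != as.raw(0x01))
    stop("not a SNP-major PLINK v1.00 bed file: ", prefix, ".bed")
  bps <- ceiling(nInd / 4)
  if (length(raw) - 3 != bps * nSnp)
    stop("bed size inconsistent with bim/fam dimensions for ", prefix)
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bps, ncol = nSnp)
  calls <- matrix(NA_integer_, nSnp, nInd)
  for (s in 1:4) {
    ind <- seq(s, by = 4L, length.out = bps)
    ind <- ind[ind <= nInd]
    if (!length(ind)) next
    sub <- body[seq_along(ind), , drop = FALSE]
    calls[, ind] <- t(matrix(.bedLut[sub + 1L, s], nrow = nrow(sub)))
  }
  list(calls = calls, bim = bim, samples = fam[[2]])
}

.writeBed <- function(panel, prefix) {
  g <- SummarizedExperiment::assay(panel, "calls")
  map <- variantInfo(panel)
  nInd <- ncol(g); nSnp <- nrow(g)
  ## dosage of A1 (minor) -> 2-bit code
  doseToCode <- function(d) {
    code <- integer(length(d))
    code[is.na(d)] <- 1L
    code[!is.na(d) & d == 2L] <- 0L
    code[!is.na(d) & d == 1L] <- 2L
    code[!is.na(d) & d == 0L] <- 3L
    code
  }
  bps <- ceiling(nInd / 4)
  pad <- bps * 4L - nInd
  out <- vapply(seq_len(nSnp), function(j) {
    code <- c(doseToCode(g[j, ]), rep(3L, pad))
    dim(code) <- c(4L, bps)
    as.integer(code[1, ] + 4L * code[2, ] + 16L * code[3, ] + 64L * code[4, ])
  }, integer(bps))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(out), con)
  utils::write.table(
    data.frame(map$chrom, map$id, 0, map$pos, map$alleleMinor, map$alleleMajor),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  sam <- sampleIds(panel)
  utils::write.table(data.frame(sam, sam, 0, 0, 0, -9),
                     paste0(prefix, ".fam"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(NULL)
}

.readVcfPanel <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  nSkip <- sum(!keep)
  if (nSkip) message(nSkip, " non-biallelic-SNP VCF record(s) skipped")
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  fmt <- v@gt[, 1]
  hasDS <- all(grepl("(^|:)DS(:|$)", fmt))
  if (hasDS) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    calls <- round(ds)  # round-half-to-even hard call
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    cnt <- function(x) {
      a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
      vapply(a, function(z) {
        if (any(is.na(z)) || any(z == ".")) NA_integer_
        else sum(z == "1")
      }, integer(1))
    }
    calls <- apply(gt, 2, cnt)
    if (is.null(dim(calls))) calls <- matrix(calls, nrow = nrow(gt))
  }
  calls <- calls[keep, , drop = FALSE]
  storage.mode(calls) <- "integer"
  id <- fix[keep, "ID"]
  noid <- is.na(id) | id == "."
  id[noid] <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])[noid]
  GenotypePanel(calls,
                chrom = fix[keep, "CHROM"],
                pos = as.numeric(fix[keep, "POS"]),
                id = id,
                allele1 = alt[keep], allele2 = ref[keep],
                samples = colnames(v@gt)[-1])
}

#' Read a genotype panel from a PLINK fileset or a VCF
#'
#' For a PLINK prefix, reads \code{<prefix>.bed/.bim/.fam} (SNP-major v1.00).
#' For a \code{.vcf}/\code{.vcf.gz} path, keeps biallelic SNP records only
#' (others are skipped with a message) and hard-calls DS dosages by rounding
#' to the nearest integer (half to even), or counts ALT alleles from GT.
#' Calls are re-oriented so that they always count the minor allele.
#'
#' @param path PLINK fileset prefix (no extension) or VCF file path.
#' @return a \code{\link{GenotypePanel}}.
#' @export
readPanel <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) return(.readVcfPanel(path))
  if (!file.exists(paste0(path, ".bed")))
    stop("no such PLINK fileset: ", path, ".bed")
  x <- .readBed(path)
  GenotypePanel(x$calls, chrom = x$bim$chrom, pos = x$bim$pos, id = x$bim$id,
                allele1 = x$bim$a1, allele2 = x$bim$a2, samples = x$samples)
}

#' Write a genotype panel as a PLINK bed/bim/fam fileset
#'
#' A1 in the bim is the minor allele (the allele the calls count), A2 the
#' major allele. \code{readPanel(writePanel(p, prefix))} reproduces the calls
#' matrix, positions and allele orientation exactly.
#'
#' @param panel a \code{\link{GenotypePanel}}.
#' @param prefix output fileset prefix.
#' @export
writePanel <- function(panel, prefix) .writeBed(panel, prefix)

#' Filter a panel on minor-allele frequency
#'
#' Retains variants with MAF strictly greater than \code{minMaf} (the screen
#' used MAF > 0.01), preserving variant order.
#'
#' @param panel a \code{\link{GenotypePanel}}.
#' @param minMaf frequency threshold in [0, 0.5).
#' @export
applyMafFilter <- function(panel, minMaf) {
  stopifnot(minMaf >= 0, minMaf < 0.5)
  keep <- variantInfo(panel)$maf > minMaf
  if (!any(keep)) stop("MAF filter removed every variant")
  panel[keep, ]
}

#' Panel accessors
#'
#' \code{calls} returns the variants x samples minor-allele count matrix,
#' \code{variantInfo} the variant map as a data.frame, \code{sampleIds} the
#' sample identifiers.
#'
#' @param panel a \code{\link{GenotypePanel}}.
#' @export
calls <- function(panel) SummarizedExperiment::assay(panel, "calls")

#' @rdname calls
#' @export
variantInfo <- function(panel) {
  rr <- SummarizedExperiment::rowRanges(panel)
  data.frame(id = mcols(rr)$id,
             chrom = as.character(seqnames(rr)),
             pos = BiocGenerics::start(rr),
             alleleMinor = mcols(rr)$alleleMinor,
             alleleMajor = mcols(rr)$alleleMajor,
             maf = mcols(rr)$maf,
             row.names = NULL)
}

#' @rdname calls
#' @export
sampleIds <- function(panel) colnames(panel)

#' Read a phenotype/covariate table
#'
#' Tab-separated with header; requires columns \code{sample_id},
#' \code{height}, \code{sex}, \code{age}; further numeric columns (e.g.
#' principal components) are kept as covariates. Rows with any missing value
#' are dropped with a message (complete-case filtering at load time).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readPhenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "height", "sex", "age")
  if (!all(need %in% names(ph)))
    stop("phenotype table must contain columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(ph$sample_id)) stop("duplicate sample ids in ", path)
  cc <- stats::complete.cases(ph)
  if (any(!cc))
    message(sum(!cc), " phenotype row(s) dropped as incomplete")
  ph[cc, , drop = FALSE]
}

#' Write a phenotype table
#' @param pheno data.frame as returned by \code{\link{readPhenotypes}}.
#' @param path TSV path.
#' @export
writePhenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a polygenic-score weight table
#'
#' Tab-separated with header columns \code{snp}, \code{effect_allele},
#' \code{weight} (per-allele effect in trait units).
#'
#' @param path TSV path.
#' @export
readWeights <- function(path) {
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp", "effect_allele", "weight")
  if (!all(need %in% names(w)))
    stop("weight table must contain columns ", paste(need, collapse = ", "))
  if (anyDuplicated(w$snp)) stop("duplicate snp ids in weight table")
  w
}

.pColRegex <- "(^|[._])(P|p|minP|pvalue)([._0-9]*)$"

#' Write a result table as TSV
#'
#' Fixed column order (as in the data.frame); numeric columns are serialized
#' at full precision (\code{\%.17g}, value-exact on re-parse) and P-value
#' columns in scientific notation.
#'
#' @param records data.frame (may be empty; the header is still written).
#' @param path output TSV path.
#' @export
writeResults <- function(records, path) {
  out <- records
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      fmt <- if (grepl(.pColRegex, nm)) "%.16e" else "%.17g"
      v <- sprintf(fmt, out[[nm]])
      v[is.na(out[[nm]])] <- "NA"
      out[[nm]] <- v
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write results to ", path)
  invisible(NULL)
}

#' Read back a result table written by \code{writeResults}
#' @param path TSV path.
#' @export
readResults <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Intersect a panel and a phenotype table on sample id
#'
#' Keeps the panel's relative sample order; unmatched ids on either side are
#' reported with a message, not an error.
#'
#' @param panel a \code{\link{GenotypePanel}}.
#' @param pheno phenotype data.frame with a \code{sample_id} column.
#' @return list with the subsetted \code{panel} and row-aligned \code{pheno}.
#' @export
matchSamples <- function(panel, pheno) {
  ids <- sampleIds(panel)
  keep <- ids %in% pheno$sample_id
  if (any(!keep))
    message(sum(!keep), " panel sample(s) missing from the phenotype table")
  extra <- sum(!(pheno$sample_id %in% ids))
  if (extra)
    message(extra, " phenotype row(s) missing from the panel")
  if (!any(keep)) stop("no overlapping samples between panel and phenotypes")
  panel <- panel[, keep]
  pheno <- pheno[match(sampleIds(panel), pheno$sample_id), , drop = FALSE]
  rownames(pheno) <- NULL
  list(panel = panel, pheno = pheno)
}
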