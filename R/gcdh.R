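## The GCDH sliding-window scan: collapse nearby SNP pairs into pseudo-markers,
## test each against the phenotype in a covariate-adjusted linear model, assign
## the per-window minimum P to the index SNP, and screen genome-wide against
## the per-window Bonferroni threshold alpha / k. Includes the
## phenotype-permutation empirical null.

#' Collapse a SNP pair into a pseudo-marker
#'
#' Elementwise application of a collapsing matrix to two genotype vectors;
#' a missing call in either input yields a missing pseudo-genotype.
#'
#' @param g1,g2 genotype vectors over \{0,1,2,NA\} (minor-allele counts).
#' @param matrix a \code{\link{additiveMatrix}},
#'   \code{\link{recessiveMatrix}} or \code{\link{customMatrix}}.
#' @return integer pseudo-genotype vector.
#' @export
collapsePair <- function(g1, g2, matrix = additiveMatrix()) {
  stopifnot(is(matrix, "CollapsingMatrix"), length(g1) == length(g2))
  matrix@map[cbind(g1 + 1L, g2 + 1L)]
}

#' Derived GCDH significance threshold
#'
#' Per-window Bonferroni correction of the genome-wide level: alpha / k
#' (with the defaults alpha = 5e-8 and k = 300 this is 1.67e-10).
#'
#' @param spec a \code{\link{windowSpec}}.
#' @param alpha genome-wide significance level.
#' @export
gcdhThreshold <- function(spec = windowSpec(), alpha = 5e-8) alpha / spec@k

#' Test one pseudo-marker against the phenotype
#'
#' OLS of height on the pseudo-genotype (numeric 0/1/2 dose, reflecting the
#' assumed joint additive effect of the minor alleles) plus covariates, with
#' a two-sided t-test P for the pseudo-marker coefficient. A pseudo-marker
#' with fewer than two observed categories is flagged degenerate
#' (\code{P = NA}).
#'
#' @param pseudo pseudo-genotype vector (\code{\link{collapsePair}}).
#' @param pheno phenotype data.frame aligned with \code{pseudo}.
#' @param covariates covariate column names.
#' @param categorical fit the pseudo-marker as a factor instead of a numeric
#'   dose (non-default; the P value is then the partial F test).
#' @return list(beta, se, P, n, counts, degenerate).
#' @export
fitPseudoMarker <- function(pseudo, pheno,
                            covariates = setdiff(names(pheno),
                                                 c("sample_id", "height")),
                            categorical = FALSE) {
  ok <- !is.na(pseudo) & stats::complete.cases(pheno[, c("height", covariates),
                                                     drop = FALSE])
  ps <- pseudo[ok]
  counts <- tabulate(ps + 1L, nbins = 3L)
  names(counts) <- paste0("n", 0:2)
  if (length(unique(ps)) < 2L)
    return(list(beta = NA_real_, se = NA_real_, P = NA_real_, n = sum(ok),
                counts = counts, degenerate = TRUE))
  C <- .covariateDesign(pheno[ok, , drop = FALSE], covariates)
  y <- pheno$height[ok]
  if (categorical) {
    fit0 <- stats::lm.fit(C, y)
    X <- cbind(C, stats::model.matrix(~ factor(ps))[, -1, drop = FALSE])
    fit1 <- stats::lm.fit(X, y)
    df1 <- length(unique(ps)) - 1L
    df2 <- sum(ok) - ncol(X)
    rss0 <- sum(fit0$residuals^2); rss1 <- sum(fit1$residuals^2)
    F <- ((rss0 - rss1) / df1) / (rss1 / df2)
    return(list(beta = NA_real_, se = NA_real_,
                P = stats::pf(F, df1, df2, lower.tail = FALSE), n = sum(ok),
                counts = counts, degenerate = FALSE))
  }
  qrC <- qr(C)
  ry <- qr.resid(qrC, y)
  rg <- qr.resid(qrC, ps)
  st <- .olsGenoStats(qrC, ry, sum(ry^2), sum(ok) - ncol(C) - 1L, rg)
  list(beta = unname(st["beta"]), se = unname(st["se"]),
       P = unname(st["P"]), n = sum(ok), counts = counts,
       degenerate = FALSE)
}

#' Enumerate sliding windows
#'
#' For each index SNP, the pairing SNPs are the subsequent SNPs on the same
#' chromosome within \code{d} bp, screened by the marginal p-filter (a pair
#' is retained under the default "either" rule when at least one member has
#' marginal P at or below the filter), then truncated to at most \code{k},
#' so the maximal number of tests per window is k.
#'
#' @param variants variant map data.frame (\code{chrom}, \code{pos}), sorted
#'   by (chrom, pos) as in a \code{\link{GenotypePanel}}.
#' @param spec a \code{\link{windowSpec}}.
#' @param marginalP marginal single-SNP P values aligned with
#'   \code{variants}; if NULL the p-filter is not applied.
#' @return list of integer partner-index vectors, one per index SNP (empty
#'   vector when the window has no eligible pair).
#' @export
enumerateWindows <- function(variants, spec = windowSpec(),
                             marginalP = NULL) {
  m <- nrow(variants)
  pos <- variants$pos
  chrom <- variants$chrom
  if (is.null(marginalP)) marginalP <- rep(0, m)
  pf <- marginalP <= spec@pFilter
  ## last index on the same chromosome within d of each index SNP
  out <- vector("list", m)
  start <- 1L
  for (i in seq_len(m)) {
    if (i > 1 && chrom[i] != chrom[i - 1L]) start <- i
    out[[i]] <- integer(0)
  }
  chromEnd <- c(which(chrom[-1] != chrom[-m]), m)
  names(chromEnd) <- NULL
  endOf <- rep(chromEnd, diff(c(0L, chromEnd)))
  for (i in seq_len(m)) {
    hi <- endOf[i]
    if (i >= hi) next
    j <- seq(i + 1L, hi)
    j <- j[pos[j] - pos[i] <= spec@d]
    if (!length(j)) next
    j <- switch(spec@rule,
                either = j[pf[i] | pf[j]],
                both   = j[pf[i] & pf[j]],
                index  = if (pf[i]) j else integer(0))
    out[[i]] <- utils::head(j, spec@k)
  }
  out
}

#' Genome-wide GCDH scan
#'
#' Slides over the sorted variant map one SNP per step; within each window
#' the index SNP is collapsed with every eligible pairing SNP and each
#' pseudo-marker is tested against the phenotype; the minimum P value in the
#' window is assigned to the index SNP (ties broken by smallest partner
#' position). Index SNPs with minimum P below \code{alpha / k} form the
#' significant set.
#'
#' @param panel a \code{\link{GenotypePanel}}.
#' @param pheno phenotype data.frame.
#' @param covariates covariate column names.
#' @param spec a \code{\link{windowSpec}}.
#' @param matrix a \code{CollapsingMatrix} (default additive).
#' @param marginal optional precomputed \code{\link{runGwas}} result for the
#'   p-filter; computed internally when NULL.
#' @param alpha genome-wide significance level (threshold = alpha / k).
#' @param minN minimum complete-case sample size per pair (smaller pairs are
#'   skipped and counted).
#' @param keepPairs keep the full pairwise result table (set FALSE to save
#'   memory in permutation replicates).
#' @return a \code{\linkS4class{GcdhScan}}.
#' @export
gcdhScan <- function(panel, pheno,
                     covariates = setdiff(names(pheno),
                                          c("sample_id", "height")),
                     spec = windowSpec(), matrix = additiveMatrix(),
                     marginal = NULL, alpha = 5e-8, minN = 30L,
                     keepPairs = TRUE) {
  mt <- matchSamples(panel, pheno)
  panel <- mt$panel; pheno <- mt$pheno
  if (is.null(marginal)) marginal <- runGwas(panel, pheno, covariates)
  map <- variantInfo(panel)
  if (!identical(marginal$snp, map$id))
    marginal <- marginal[match(map$id, marginal$snp), ]
  windows <- enumerateWindows(map, spec, marginal$P)

  G <- calls(panel)
  C <- .covariateDesign(pheno, covariates)
  y <- pheno$height
  n <- length(y)
  qrC <- qr(C)
  ry <- qr.resid(qrC, y)
  ssy <- sum(ry^2)
  df <- n - ncol(C) - 1L
  hasNA <- rowSums(is.na(G)) > 0L
  cmap <- matrix@map

  scanRows <- vector("list", length(windows))
  pairRows <- if (keepPairs) vector("list", length(windows)) else NULL
  nSkipped <- 0L
  for (i in seq_along(windows)) {
    js <- windows[[i]]
    if (!length(js)) next
    best <- NULL
    pr <- if (keepPairs)
      data.frame(snp1 = map$id[i], snp2 = map$id[js],
                 n0 = NA_integer_, n1 = NA_integer_, n2 = NA_integer_,
                 beta = NA_real_, se = NA_real_, P = NA_real_,
                 n = NA_integer_)
    else NULL
    keepRow <- logical(length(js))
    tests <- 0L
    minP <- Inf; bestJ <- NA_integer_; bestBeta <- NA_real_; bestSe <- NA_real_
    cleanPair <- !hasNA[i] & !hasNA[js]
    PS <- cmap[cbind(rep(G[i, ] + 1L, length(js)),
                     as.vector(t(G[js, , drop = FALSE])) + 1L)]
    dim(PS) <- c(n, length(js))
    for (q in seq_along(js)) {
      j <- js[q]
      ps <- PS[, q]
      if (cleanPair[q]) {
        cnt <- tabulate(ps + 1L, nbins = 3L)
        if (sum(cnt > 0L) < 2L || n < minN) { nSkipped <- nSkipped + 1L; next }
        rg <- qr.resid(qrC, ps)
        st <- .olsGenoStats(qrC, ry, ssy, df, rg)
        nn <- n
      } else {
        ok <- !is.na(ps)
        nn <- sum(ok)
        cnt <- tabulate(ps[ok] + 1L, nbins = 3L)
        if (sum(cnt > 0L) < 2L || nn < minN) { nSkipped <- nSkipped + 1L; next }
        qrCj <- qr(C[ok, , drop = FALSE])
        ryj <- qr.resid(qrCj, y[ok])
        rgj <- qr.resid(qrCj, ps[ok])
        st <- .olsGenoStats(qrCj, ryj, sum(ryj^2), nn - ncol(C) - 1L, rgj)
      }
      tests <- tests + 1L
      if (keepPairs) {
        keepRow[q] <- TRUE
        pr$n0[q] <- cnt[1]; pr$n1[q] <- cnt[2]; pr$n2[q] <- cnt[3]
        pr$beta[q] <- st["beta"]; pr$se[q] <- st["se"]; pr$P[q] <- st["P"]
        pr$n[q] <- nn
      }
      ## tie-break on equal min P: smallest partner position
      if (st["P"] < minP ||
          (st["P"] == minP && !is.na(bestJ) && map$pos[j] < map$pos[bestJ])) {
        minP <- st["P"]; bestJ <- j
        bestBeta <- unname(st["beta"]); bestSe <- unname(st["se"])
      }
    }
    if (tests == 0L) next
    scanRows[[i]] <- data.frame(
      snp = map$id[i], chrom = map$chrom[i], pos = map$pos[i],
      partner = map$id[bestJ], partner_pos = map$pos[bestJ],
      minP = minP, beta = bestBeta, se = bestSe, tests = tests)
    if (keepPairs) pairRows[[i]] <- pr[keepRow, , drop = FALSE]
  }
  scan <- do.call(rbind, scanRows[!vapply(scanRows, is.null, TRUE)])
  if (is.null(scan)) {
    warning("no eligible pair anywhere in the genome")
    scan <- data.frame(snp = character(), chrom = character(),
                       pos = numeric(), partner = character(),
                       partner_pos = numeric(), minP = numeric(),
                       beta = numeric(), se = numeric(), tests = integer())
  }
  rownames(scan) <- NULL
  pairs <- if (keepPairs && !is.null(pairRows)) {
    pp <- do.call(rbind, pairRows[!vapply(pairRows, is.null, TRUE)])
    if (is.null(pp)) data.frame() else { rownames(pp) <- NULL; pp }
  } else data.frame()
  new("GcdhScan", scan = scan, pairs = pairs, spec = spec,
      matrixName = matrix@name, threshold = gcdhThreshold(spec, alpha),
      nSkipped = nSkipped)
}

#' Phenotype-permutation empirical null for the GCDH scan
#'
#' Each replicate breaks the genotype-phenotype relationship by shuffling
#' whole phenotype rows (height, sex, age, PCs move together, preserving
#' their within-row linkage) against the sample ids, then reruns the full
#' scan including recomputation of the marginal GWAS feeding the p-filter.
#' Replicate r uses seed + r.
#'
#' @param panel,pheno,covariates,spec,matrix,alpha as in
#'   \code{\link{gcdhScan}}.
#' @param nPerm number of permutation replicates (the screen used 5).
#' @param seed base seed.
#' @return list(replicates = per-replicate scan records with a
#'   \code{replicate} column, qq = pooled QQ data of the min-P distribution,
#'   seeds = seeds used).
#' @export
permutationNull <- function(panel, pheno,
                            covariates = setdiff(names(pheno),
                                                 c("sample_id", "height")),
                            spec = windowSpec(), matrix = additiveMatrix(),
                            nPerm = 5L, seed = 1L, alpha = 5e-8) {
  stopifnot(nPerm >= 1)
  reps <- vector("list", nPerm)
  seeds <- seed + seq_len(nPerm)
  valueCols <- setdiff(names(pheno), "sample_id")
  for (r in seq_len(nPerm)) {
    set.seed(seeds[r])
    idx <- sample(nrow(pheno))
    php <- pheno
    php[, valueCols] <- pheno[idx, valueCols]
    sc <- gcdhScan(panel, php, covariates, spec, matrix, marginal = NULL,
                   alpha = alpha, keepPairs = FALSE)
    rec <- scanRecords(sc)
    if (nrow(rec)) rec$replicate <- r
    reps[[r]] <- rec
  }
  replicates <- do.call(rbind, reps)
  rownames(replicates) <- NULL
  qq <- if (nrow(replicates))
    qqManhattanData(data.frame(chrom = replicates$chrom,
                               pos = replicates$pos,
                               P = replicates$minP))$qq
  else data.frame(expected = numeric(), observed = numeric())
  list(replicates = replicates, qq = qq, seeds = seeds)
}
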