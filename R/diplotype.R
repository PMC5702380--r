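## Two-locus haplotype EM and compound-heterozygote validation.
##
## At a significant pair, compound (trans) and double (cis) heterozygotes are
## collapsed into the same pseudo-genotype during the screen; they are
## separated here by estimating the four haplotype frequencies with EM (only
## the double-heterozygote genotype is phase-ambiguous) and computing each
## double heterozygote's posterior probability of the trans configuration.

.genoClassProbs <- function(f) {
  ## 3x3 matrix of genotype-class probabilities P(g1 = i, g2 = j) under
  ## random union of haplotypes; f named (AB, Ab, aB, ab); g counts minors.
  fAB <- f["AB"]; fAb <- f["Ab"]; faB <- f["aB"]; fab <- f["ab"]
  p <- matrix(0, 3, 3)
  p[1, 1] <- fAB^2
  p[1, 2] <- 2 * fAB * fAb
  p[1, 3] <- fAb^2
  p[2, 1] <- 2 * fAB * faB
  p[2, 2] <- 2 * fAb * faB + 2 * fAB * fab
  p[2, 3] <- 2 * fAb * fab
  p[3, 1] <- faB^2
  p[3, 2] <- 2 * faB * fab
  p[3, 3] <- fab^2
  p
}

.twoLocusLogLik <- function(f, counts) {
  p <- .genoClassProbs(f)
  use <- counts > 0
  sum(counts[use] * log(pmax(p[use], 1e-300)))
}

#' Two-locus haplotype frequencies by EM
#'
#' Estimates the four haplotype frequencies (AB, Ab, aB, ab; capital = major
#' allele) from unphased genotypes of a SNP pair. Only the (1,1)
#' double-heterozygote class is phase-ambiguous: the E-step splits it between
#' the cis (AB/ab) and trans (Ab/aB) configurations in proportion
#' 2 f_AB f_ab : 2 f_Ab f_aB; the M-step recounts haplotypes. Initialization
#' is at linkage equilibrium (products of the observed allele frequencies);
#' iteration stops when the log-likelihood gain drops below \code{tol}.
#' The observed-data log-likelihood is non-decreasing across iterations and
#' the estimated haplotype marginals equal the observed allele frequencies
#' at every M-step.
#'
#' @param g1,g2 genotype vectors (minor-allele counts, 0/1/2; missing values
#'   are dropped pairwise).
#' @param tol convergence tolerance on the log-likelihood.
#' @param maxIter maximum EM iterations.
#' @return a \code{\linkS4class{HaplotypeFreqs}}.
#' @export
emHaplotypeFreqs <- function(g1, g2, tol = 1e-8, maxIter = 1000L) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  N <- length(g1)
  if (!N) stop("no complete cases")
  counts <- table(factor(g1, 0:2), factor(g2, 0:2))
  counts <- matrix(as.numeric(counts), 3, 3)
  pa <- mean(g1) / 2; pb <- mean(g2) / 2
  f <- c(AB = (1 - pa) * (1 - pb), Ab = (1 - pa) * pb,
         aB = pa * (1 - pb), ab = pa * pb)
  ## LE start can have zero cross-products when a locus is monomorphic;
  ## those stay zero throughout, which is the correct degenerate solution.
  ll <- .twoLocusLogLik(f, counts)
  iter <- 0L; converged <- FALSE
  n11 <- counts[2, 2]
  while (iter < maxIter) {
    iter <- iter + 1L
    num <- 2 * f["Ab"] * f["aB"]
    den <- num + 2 * f["AB"] * f["ab"]
    pTrans <- if (den > 0) num / den else 0.5
    cAB <- 2 * counts[1, 1] + counts[1, 2] + counts[2, 1] + n11 * (1 - pTrans)
    cAb <- counts[1, 2] + 2 * counts[1, 3] + counts[2, 3] + n11 * pTrans
    caB <- counts[2, 1] + 2 * counts[3, 1] + counts[3, 2] + n11 * pTrans
    cab <- counts[2, 3] + counts[3, 2] + 2 * counts[3, 3] + n11 * (1 - pTrans)
    f <- c(AB = cAB, Ab = cAb, aB = caB, ab = cab) / (2 * N)
    names(f) <- c("AB", "Ab", "aB", "ab")
    llNew <- .twoLocusLogLik(f, counts)
    if (llNew < ll - 1e-9)
      stop("EM log-likelihood decreased (", ll, " -> ", llNew, ")")
    if (llNew - ll < tol) { ll <- llNew; converged <- TRUE; break }
    ll <- llNew
  }
  if (!converged)
    warning("haplotype EM did not converge in ", maxIter, " iterations")
  new("HaplotypeFreqs", freqs = f, logLik = ll, iterations = iter,
      converged = converged)
}

#' Posterior trans (compound-heterozygote) probability per individual
#'
#' For each double heterozygote (g1 = g2 = 1), the posterior probability of
#' the trans configuration Ab/aB is
#' 2 f_Ab f_aB / (2 f_Ab f_aB + 2 f_AB f_ab). All other genotypes have
#' deterministic phase; their entry is \code{NA}. When both cross-products
#' are zero the posterior is undefined (\code{NaN}, flagged by a warning).
#'
#' @param freqs a \code{\linkS4class{HaplotypeFreqs}}.
#' @param g1,g2 genotype vectors.
#' @return numeric vector of P(trans), \code{NA} off the double-het class.
#' @export
classifyDoubleHets <- function(freqs, g1, g2) {
  f <- haplotypeFreqs(freqs)
  num <- 2 * f["Ab"] * f["aB"]
  den <- num + 2 * f["AB"] * f["ab"]
  pt <- if (den > 0) unname(num / den) else {
    warning("both diplotype configurations have zero probability; ",
            "posterior undefined")
    NaN
  }
  out <- rep(NA_real_, length(g1))
  out[!is.na(g1) & !is.na(g2) & g1 == 1 & g2 == 1] <- pt
  out
}

#' Validate the compound-heterozygote model at a pair
#'
#' The CH group contains the double heterozygotes whose maximum-a-posteriori
#' configuration is trans (P(trans) > 0.5); the reference group carries no
#' minor allele at either SNP (pseudo-genotype 0). The verdict is
#' \code{CH_supported} when the CH group is non-empty and its mean
#' covariate-adjusted height differs from the reference group in the same
#' direction as the GCDH effect estimate; \code{no_CH_group} when there are
#' no CH carriers (an indication of other genetic mechanisms); and
#' \code{other_mechanism} otherwise. A CH group smaller than 5 sets a
#' low-confidence flag.
#'
#' @param betaGcdh GCDH effect estimate of the pair's pseudo-marker.
#' @param adjHeight covariate-adjusted heights
#'   (\code{\link{adjustHeights}}).
#' @param g1,g2 genotype vectors aligned with \code{adjHeight}.
#' @param pTrans per-individual P(trans) from
#'   \code{\link{classifyDoubleHets}}.
#' @return list(verdict, nCH, nCisDH, nRef, meanCH, meanCisDH, meanRef,
#'   lowConfidence).
#' @export
validateCH <- function(betaGcdh, adjHeight, g1, g2, pTrans) {
  ok <- !is.na(g1) & !is.na(g2) & !is.na(adjHeight)
  dh <- ok & g1 == 1 & g2 == 1
  ch <- dh & !is.na(pTrans) & pTrans > 0.5
  cis <- dh & !is.na(pTrans) & pTrans <= 0.5
  ref <- ok & g1 == 0 & g2 == 0
  meanCH <- if (any(ch)) mean(adjHeight[ch]) else NA_real_
  meanCis <- if (any(cis)) mean(adjHeight[cis]) else NA_real_
  meanRef <- if (any(ref)) mean(adjHeight[ref]) else NA_real_
  verdict <- if (!any(ch)) "no_CH_group"
  else if (!is.na(meanRef) &&
           sign(meanCH - meanRef) == sign(betaGcdh)) "CH_supported"
  else "other_mechanism"
  list(verdict = verdict, nCH = sum(ch), nCisDH = sum(cis), nRef = sum(ref),
       meanCH = meanCH, meanCisDH = meanCis, meanRef = meanRef,
       lowConfidence = sum(ch) < 5)
}

#' Diplotype analysis of a table of SNP pairs
#'
#' Convenience wrapper running \code{\link{emHaplotypeFreqs}},
#' \code{\link{classifyDoubleHets}} and \code{\link{validateCH}} for each
#' pair of a scan's significant set.
#'
#' @param panel a \code{\link{GenotypePanel}}.
#' @param pheno phenotype data.frame.
#' @param pairs data.frame with columns \code{snp1}, \code{snp2},
#'   \code{beta} (GCDH effect of the pair).
#' @param covariates covariates regressed out of height before group means
#'   (default sex and age).
#' @return data.frame, one row per pair: haplotype frequencies, EM
#'   convergence, group sizes and means, verdict.
#' @export
analyzeDiplotypes <- function(panel, pheno, pairs,
                              covariates = c("sex", "age")) {
  stopifnot(all(c("snp1", "snp2", "beta") %in% names(pairs)))
  mt <- matchSamples(panel, pheno)
  panel <- mt$panel; pheno <- mt$pheno
  G <- calls(panel)
  adj <- adjustHeights(pheno, covariates)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    i1 <- match(pairs$snp1[i], rownames(G))
    i2 <- match(pairs$snp2[i], rownames(G))
    if (is.na(i1) || is.na(i2))
      stop("pair SNP not in panel: ", pairs$snp1[i], " / ", pairs$snp2[i])
    g1 <- G[i1, ]; g2 <- G[i2, ]
    em <- emHaplotypeFreqs(g1, g2)
    pt <- classifyDoubleHets(em, g1, g2)
    v <- validateCH(pairs$beta[i], adj, g1, g2, pt)
    f <- haplotypeFreqs(em)
    data.frame(snp1 = pairs$snp1[i], snp2 = pairs$snp2[i],
               beta = pairs$beta[i],
               fAB = f["AB"], fAb = f["Ab"], faB = f["aB"], fab = f["ab"],
               emConverged = em@converged,
               pTransDH = unique(pt[!is.na(pt)])[1],
               nCH = v$nCH, nCisDH = v$nCisDH, nRef = v$nRef,
               meanCH = v$meanCH, meanCisDH = v$meanCisDH,
               meanRef = v$meanRef, verdict = v$verdict,
               lowConfidence = v$lowConfidence, row.names = NULL)
  })
  do.call(rbind, rows)
}
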