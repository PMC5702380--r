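## Conventional single-SNP GWAS stage: per-SNP additive OLS with covariates,
## genomic-control lambda, and QQ/Manhattan plot data.

.covariateDesign <- function(pheno, covariates) {
  if (length(covariates)) {
    miss <- setdiff(covariates, names(pheno))
    if (length(miss))
      stop("covariate column(s) not in phenotype table: ",
           paste(miss, collapse = ", "))
    as.matrix(cbind(`(Intercept)` = 1, pheno[, covariates, drop = FALSE]))
  } else {
    matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)"))
  }
}

## OLS of y on (C, g) returning the g coefficient's (beta, se, P, n) with
## two-sided t reference; exact lm semantics via Frisch-Waugh-Lovell.
.olsGenoStats <- function(qrC, ry, ssy, df, rg) {
  sxx <- sum(rg^2)
  if (sxx < 1e-12) return(c(beta = 0, se = NA, t = NA, P = 1))
  beta <- sum(rg * ry) / sxx
  sse <- ssy - beta^2 * sxx
  se <- sqrt(max(sse, 0) / df / sxx)
  tval <- beta / se
  c(beta = beta, se = se, t = tval,
    P = 2 * stats::pt(-abs(tval), df))
}

#' Single-SNP additive GWAS
#'
#' For every variant, ordinary least squares of height on the minor-allele
#' count plus covariates, with a two-sided t-test P value for the genotype
#' coefficient (PLINK linear-model semantics). Complete cases per SNP;
#' monomorphic SNPs are flagged and reported with P = 1, beta = 0.
#'
#' @param panel a \code{\link{GenotypePanel}}.
#' @param pheno phenotype data.frame (\code{sample_id}, \code{height},
#'   covariate columns).
#' @param covariates covariate column names; default every column except
#'   \code{sample_id} and \code{height} (e.g. sex, age and four PCs).
#' @return data.frame with one row per SNP: id, chrom, pos, effect
#'   (minor) allele, MAF, beta (cm/allele), se, P, n, flag.
#' @export
runGwas <- function(panel, pheno,
                    covariates = setdiff(names(pheno),
                                         c("sample_id", "height"))) {
  mt <- matchSamples(panel, pheno)
  panel <- mt$panel; pheno <- mt$pheno
  G <- calls(panel)                      # variants x samples
  map <- variantInfo(panel)
  C <- .covariateDesign(pheno, covariates)
  y <- pheno$height
  n <- length(y)
  df <- n - ncol(C) - 1L
  qrC <- qr(C)
  ry <- qr.resid(qrC, y)
  ssy <- sum(ry^2)

  m <- nrow(G)
  beta <- numeric(m); se <- rep(NA_real_, m); P <- rep(1, m)
  nUsed <- integer(m); flag <- character(m)

  hasNA <- rowSums(is.na(G)) > 0L
  if (any(!hasNA)) {
    Gt <- t(G[!hasNA, , drop = FALSE])
    RG <- qr.resid(qrC, Gt)
    sxx <- colSums(RG^2)
    sxy <- colSums(RG * ry)
    mono <- sxx < 1e-12
    b <- ifelse(mono, 0, sxy / pmax(sxx, 1e-300))
    sse <- pmax(ssy - b^2 * sxx, 0)
    s <- sqrt(sse / df / pmax(sxx, 1e-300))
    tv <- b / s
    p <- 2 * stats::pt(-abs(tv), df)
    idx <- which(!hasNA)
    beta[idx] <- b
    se[idx] <- ifelse(mono, NA, s)
    P[idx] <- ifelse(mono, 1, p)
    nUsed[idx] <- n
    flag[idx] <- ifelse(mono, "monomorphic", "")
  }
  for (j in which(hasNA)) {
    ok <- !is.na(G[j, ])
    nUsed[j] <- sum(ok)
    if (nUsed[j] < ncol(C) + 2L || stats::var(G[j, ok]) < 1e-12) {
      flag[j] <- if (nUsed[j] >= 2 && stats::var(G[j, ok]) < 1e-12)
        "monomorphic" else "degenerate"
      next
    }
    qrCj <- qr(C[ok, , drop = FALSE])
    ryj <- qr.resid(qrCj, y[ok])
    rgj <- qr.resid(qrCj, G[j, ok])
    st <- .olsGenoStats(qrCj, ryj, sum(ryj^2), nUsed[j] - ncol(C) - 1L, rgj)
    beta[j] <- st["beta"]; se[j] <- st["se"]; P[j] <- st["P"]
  }
  data.frame(snp = map$id, chrom = map$chrom, pos = map$pos,
             effect_allele = map$alleleMinor,
             other_allele = map$alleleMajor, maf = map$maf,
             beta = beta, se = se, P = P, n = nUsed, flag = flag,
             stringsAsFactors = FALSE)
}

#' Genomic inflation factor
#'
#' lambda = median of the 1-df chi-square quantiles implied by the P values,
#' divided by the null median 0.4549364. lambda ~ 1 indicates calibrated
#' tests.
#'
#' @param p vector of P values in (0, 1].
#' @return list(lambda, nTests).
#' @export
genomicLambda <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no P values supplied")
  if (any(p <= 0 | p > 1)) stop("P values must lie in (0, 1]")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  list(lambda = stats::median(chisq) / stats::qchisq(0.5, df = 1),
       nTests = length(p))
}

#' Manhattan and QQ plot data
#'
#' Returns a Manhattan table (chrom, pos, -log10 P) and a QQ table with
#' expected quantiles -log10((i - 0.5) / m) for observed rank i of m,
#' sorted by decreasing expected quantile.
#'
#' @param records data.frame with columns \code{chrom}, \code{pos}, \code{P}.
#' @return list(manhattan, qq).
#' @export
qqManhattanData <- function(records) {
  stopifnot(all(c("chrom", "pos", "P") %in% names(records)),
            nrow(records) > 0)
  man <- data.frame(chrom = records$chrom, pos = records$pos,
                    negLog10P = -log10(records$P))
  m <- nrow(records)
  obs <- sort(records$P)
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = -log10(obs))
  list(manhattan = man, qq = qq)
}

#' Residual heights after covariate adjustment
#'
#' Regresses height on the covariates (default sex and age, mirroring
#' sex- and age-regressed height residuals) and returns the residuals.
#'
#' @param pheno phenotype data.frame.
#' @param covariates covariate column names.
#' @export
adjustHeights <- function(pheno, covariates = c("sex", "age")) {
  C <- .covariateDesign(pheno, covariates)
  drop(qr.resid(qr(C), pheno$height))
}
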