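## Polygenic score construction, the iterative variance-explained ledger,
## pseudo-marker vs. SNP-pair R-squared comparison, and exact replication.

#' Weighted allele-sum polygenic score
#'
#' score_i = sum over matched weights of weight * (count of the effect
#' allele). Weights whose SNP is absent from the panel, or whose effect
#' allele matches neither panel allele, are dropped with a message. A missing
#' genotype contributes the SNP's mean effect-allele dosage.
#'
#' @param panel a \code{\link{GenotypePanel}}.
#' @param weights data.frame (\code{snp}, \code{effect_allele},
#'   \code{weight}), see \code{\link{readWeights}}.
#' @return named numeric vector of per-sample scores.
#' @export
computePRS <- function(panel, weights) {
  map <- variantInfo(panel)
  G <- calls(panel)
  idx <- match(weights$snp, map$id)
  missing <- is.na(idx)
  if (any(missing))
    message(sum(missing), " weight(s) dropped: SNP not in panel")
  w <- weights[!missing, , drop = FALSE]
  idx <- idx[!missing]
  isMinor <- w$effect_allele == map$alleleMinor[idx]
  isMajor <- w$effect_allele == map$alleleMajor[idx]
  bad <- !isMinor & !isMajor
  if (any(bad))
    message(sum(bad), " weight(s) dropped: effect allele matches neither ",
            "panel allele")
  w <- w[!bad, , drop = FALSE]; idx <- idx[!bad]; isMinor <- isMinor[!bad]
  if (!nrow(w)) stop("no weights could be matched to the panel")
  D <- G[idx, , drop = FALSE]
  nImp <- sum(is.na(D))
  if (nImp) {
    mu <- rowMeans(D, na.rm = TRUE)
    na <- which(is.na(D), arr.ind = TRUE)
    D[na] <- mu[na[, 1]]
    message(nImp, " missing genotype(s) imputed with the SNP mean dosage")
  }
  D[!isMinor, ] <- 2 - D[!isMinor, , drop = FALSE]
  drop(crossprod(D, w$weight))[seq_len(ncol(G))] |>
    stats::setNames(sampleIds(panel))
}

#' Iterative variance-explained ledger
#'
#' Reproduces the iterative multivariable procedure: (1) fit the full
#' multivariable linear model of the adjusted height residuals on every
#' predictor and record each term's -log10 P; (2) order the terms by
#' ascending full-model P (ties by input order); (3) refit nested models
#' adding one predictor at a time in that order, each increment being the
#' R-squared difference between the current and the previous model. The
#' increments telescope to the full-model R-squared by construction.
#'
#' @param y dependent variable (sex- and age-regressed height residuals).
#' @param predictors data.frame or named matrix of numeric predictors (e.g.
#'   a PRS column, single-SNP dosages, pseudo-marker dosages).
#' @param classes optional character vector labelling each predictor (e.g.
#'   "PRS", "SNP", "pseudo-marker") for the subtotals.
#' @param orderBy "full" (default, ascending P from the joint model) or
#'   "marginal" (ascending univariate P).
#' @return list(ledger = data.frame(term, class, negLog10P, r2pct, cumR2pct),
#'   subtotals = named vector of per-class R-squared sums (\%),
#'   totalR2pct = full-model R-squared (\%)).
#' @export
iterativeR2 <- function(y, predictors, classes = NULL,
                        orderBy = c("full", "marginal")) {
  orderBy <- match.arg(orderBy)
  X <- as.data.frame(predictors)
  stopifnot(nrow(X) == length(y), ncol(X) >= 1)
  if (is.null(classes)) classes <- rep("predictor", ncol(X))
  stopifnot(length(classes) == ncol(X))
  cc <- stats::complete.cases(cbind(y, X))
  y <- y[cc]; X <- X[cc, , drop = FALSE]

  full <- stats::lm(y ~ ., data = X)
  coefTab <- summary(full)$coefficients
  ## map terms to coefficient rows (make.names handles non-syntactic ids)
  rows <- match(make.names(names(X)), rownames(coefTab))
  fullP <- coefTab[rows, "Pr(>|t|)"]
  fullP[is.na(fullP)] <- 1  # aliased (collinear) predictors sort last
  keyP <- if (orderBy == "full") fullP else
    vapply(X, function(x) summary(stats::lm(y ~ x))$coefficients[2, 4],
           numeric(1))
  ord <- order(keyP, seq_along(keyP))

  r2 <- numeric(ncol(X))
  prev <- 0
  for (i in seq_along(ord)) {
    fit <- stats::lm(y ~ ., data = X[, ord[seq_len(i)], drop = FALSE])
    cur <- summary(fit)$r.squared
    r2[i] <- cur - prev
    prev <- cur
  }
  if (any(r2 < -1e-10)) warning("negative R-squared increment beyond ",
                                "numerical tolerance")
  ledger <- data.frame(term = names(X)[ord],
                       class = classes[ord],
                       negLog10P = -log10(pmax(fullP[ord], 1e-300)),
                       r2pct = 100 * r2,
                       cumR2pct = 100 * cumsum(r2),
                       row.names = NULL)
  subtotals <- tapply(ledger$r2pct, ledger$class, sum)
  list(ledger = ledger,
       subtotals = subtotals[unique(classes)],
       totalR2pct = 100 * prev)
}

#' Variance explained: pseudo-marker vs. the SNP pair
#'
#' Four OLS fits on the same complete-case samples: the collapsed
#' pseudo-marker alone, each member SNP alone, and both SNPs jointly.
#' Because the pseudo-marker is a (nonlinear) function of the pair, its
#' R-squared can exceed either single SNP's and approach or match the joint
#' two-SNP model.
#'
#' @param adjY covariate-adjusted height residuals.
#' @param g1,g2 genotype vectors.
#' @param matrix collapsing matrix (default additive).
#' @return named list of R-squared values: \code{pseudo}, \code{snp1},
#'   \code{snp2}, \code{joint}.
#' @export
comparePairVsPseudo <- function(adjY, g1, g2, matrix = additiveMatrix()) {
  ok <- !is.na(adjY) & !is.na(g1) & !is.na(g2)
  y <- adjY[ok]; g1 <- g1[ok]; g2 <- g2[ok]
  pseudo <- collapsePair(g1, g2, matrix)
  r2 <- function(X) {
    X <- cbind(1, X)
    fit <- stats::lm.fit(X, y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  list(pseudo = r2(pseudo), snp1 = r2(g1), snp2 = r2(g2),
       joint = r2(cbind(g1, g2)))
}

#' Exact replication of discovery hits in a second cohort
#'
#' Applies the discovery-defined markers unchanged to a replication panel:
#' for a pair, the two member SNPs are oriented to the stored discovery
#' effect alleles and collapsed with the same matrix; for a single SNP, its
#' effect-allele dosage is used directly. Each marker is tested by OLS
#' adjusted for sex and age; P < 0.05 flags significant replication, and
#' sign agreement with the discovery effect is reported separately. Hits
#' whose SNPs (or effect alleles) are absent from the replication panel are
#' returned as untestable.
#'
#' @param hits data.frame with columns \code{snp1}, \code{ea1},
#'   \code{beta_discovery}, and optionally \code{snp2}, \code{ea2} (NA for
#'   single-SNP hits).
#' @param panel replication \code{\link{GenotypePanel}}.
#' @param pheno replication phenotype data.frame.
#' @param covariates adjustment covariates (default sex and age).
#' @param matrix collapsing matrix for pairs (default additive).
#' @param alpha replication significance level.
#' @return data.frame of \code{ReplicationRecord}s: marker, beta, se, P,
#'   replicated flag, sign agreement, testable flag.
#' @export
replicateHits <- function(hits, panel, pheno, covariates = c("sex", "age"),
                          matrix = additiveMatrix(), alpha = 0.05) {
  stopifnot(all(c("snp1", "ea1", "beta_discovery") %in% names(hits)))
  mt <- matchSamples(panel, pheno)
  panel <- mt$panel; pheno <- mt$pheno
  G <- calls(panel)
  map <- variantInfo(panel)
  dosage <- function(snp, ea) {
    i <- match(snp, map$id)
    if (is.na(i)) return(NULL)
    if (ea == map$alleleMinor[i]) G[i, ]
    else if (ea == map$alleleMajor[i]) 2L - G[i, ]
    else NULL
  }
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    isPair <- "snp2" %in% names(hits) && !is.na(hits$snp2[i]) &&
      nzchar(hits$snp2[i])
    marker <- if (isPair) paste0(hits$snp1[i], "_", hits$snp2[i]) else
      hits$snp1[i]
    d1 <- dosage(hits$snp1[i], hits$ea1[i])
    d2 <- if (isPair) dosage(hits$snp2[i], hits$ea2[i]) else NA
    out <- data.frame(marker = marker, beta = NA_real_, se = NA_real_,
                      P = NA_real_, n = NA_integer_, replicated = FALSE,
                      signAgrees = NA, testable = FALSE)
    if (is.null(d1) || (isPair && is.null(d2))) return(out)
    x <- if (isPair) collapsePair(d1, d2, matrix) else d1
    st <- fitPseudoMarker(x, pheno, covariates)
    if (st$degenerate) return(out)
    out$beta <- st$beta; out$se <- st$se; out$P <- st$P; out$n <- st$n
    out$replicated <- st$P < alpha
    out$signAgrees <- sign(st$beta) == sign(hits$beta_discovery[i])
    out$testable <- TRUE
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
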