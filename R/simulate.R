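## Synthetic cohorts with the statistical structure the scan assumes:
## LD-blocked haplotypes (Markov allele-copying within blocks), planted
## additive single-SNP and collapsed-pair effects, sex/age/PC covariates,
## Gaussian residual noise, and optional extreme-tall ascertainment.

#' Simulation configuration
#'
#' Bundles every generator parameter with study-like defaults: cohorts of
#' unrelated adults, biallelic SNPs in LD blocks along chromosomes, additive
#' single-SNP effects in cm per minor allele, trans-phased pair effects in cm
#' per collapsed pseudo-genotype unit, sex/age/PC covariates and Gaussian
#' residual noise.
#'
#' Defaults: residual SD 6.5 cm (covariate-adjusted adult height), sex effect
#' 13 cm, age slope -0.05 cm/year over ages 45-90, four standard-normal PCs
#' with 0.3 cm loadings, MAF range [0.01, 0.5], blocks of 10 SNPs with
#' within-block adjacent-haplotype correlation 0.8, mean bp spacing 5000.
#'
#' @param nIndividuals,nSnps,nChromosomes cohort and map dimensions.
#' @param blockLength SNPs per LD block.
#' @param rho within-block adjacent-site haplotype correlation, in [0, 1).
#' @param mafRange length-2 frequency range for block minor-allele
#'   frequencies.
#' @param bpSpacingMean mean bp distance between adjacent SNPs.
#' @param singleEffects data.frame(snp, beta): additive effects, cm/allele.
#' @param pairEffects data.frame(snp1, snp2, beta, phase) with phase in
#'   \{"trans","cis","random"\}; beta in cm per pseudo-genotype unit. An
#'   optional logical column \code{chOnly} confines the effect to compound
#'   (trans) heterozygotes (an extension used to exercise diplotype
#'   validation).
#' @param residualSd Gaussian residual SD, cm.
#' @param intercept baseline height, cm.
#' @param sexEffect,ageSlope,pcEffect covariate coefficients (cm; cm/year).
#' @param nPcs number of principal-component covariates.
#' @param tallAscertainment NULL, or list(cutoff, nExtra): append nExtra
#'   individuals from the height tail above the given SDS cutoff (1.88
#'   corresponds to the upper 3\% tail).
#' @param seed integer seed driving all randomness.
#' @return a classed list of parameters.
#' @export
simulationConfig <- function(nIndividuals = 2000L, nSnps = 2000L,
                             nChromosomes = 2L, blockLength = 10L,
                             rho = 0.8, mafRange = c(0.01, 0.5),
                             bpSpacingMean = 5000,
                             singleEffects = NULL, pairEffects = NULL,
                             residualSd = 6.5, intercept = 162,
                             sexEffect = 13, ageSlope = -0.05,
                             pcEffect = 0.3, nPcs = 4L,
                             tallAscertainment = NULL, seed = 1L) {
  stopifnot(residualSd > 0, rho >= 0, rho < 1,
            mafRange[1] > 0, mafRange[2] <= 0.5, mafRange[1] <= mafRange[2],
            nSnps >= nChromosomes, blockLength >= 1)
  if (!is.null(singleEffects)) {
    stopifnot(all(c("snp", "beta") %in% names(singleEffects)),
              all(singleEffects$snp >= 1), all(singleEffects$snp <= nSnps))
  }
  if (!is.null(pairEffects)) {
    stopifnot(all(c("snp1", "snp2", "beta", "phase") %in% names(pairEffects)),
              all(pairEffects$phase %in% c("trans", "cis", "random")),
              all(pairEffects$snp1 >= 1), all(pairEffects$snp2 <= nSnps),
              all(pairEffects$snp1 != pairEffects$snp2))
    if (is.null(pairEffects$chOnly)) pairEffects$chOnly <- FALSE
  }
  cfg <- list(nIndividuals = as.integer(nIndividuals),
              nSnps = as.integer(nSnps),
              nChromosomes = as.integer(nChromosomes),
              blockLength = as.integer(blockLength), rho = rho,
              mafRange = mafRange, bpSpacingMean = bpSpacingMean,
              singleEffects = singleEffects, pairEffects = pairEffects,
              residualSd = residualSd, intercept = intercept,
              sexEffect = sexEffect, ageSlope = ageSlope,
              pcEffect = pcEffect, nPcs = as.integer(nPcs),
              tallAscertainment = tallAscertainment, seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate phased LD-blocked haplotypes
#'
#' Within a block all sites share one minor-allele frequency p (drawn from
#' \code{mafRange}); along the block each haplotype copies the previous
#' site's allele with probability \code{rho} and otherwise redraws
#' Bernoulli(p). This Markov allele-copying is frequency-preserving and gives
#' adjacent-site haplotype correlation rho; blocks (and chromosomes) are
#' mutually independent.
#'
#' Also assigns bp positions as cumulative 1 + Exponential(mean spacing)
#' gaps per chromosome, so distance windowing is exercised.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param nHaplotypes number of haplotypes (default 2 * nIndividuals).
#' @return list(haplotypes = 0/1 matrix of 2n rows, map = data.frame(chrom,
#'   pos, id, block, freq)).
#' @export
simulateHaplotypes <- function(config, nHaplotypes = 2L * config$nIndividuals) {
  m <- config$nSnps
  perChrom <- rep(m %/% config$nChromosomes, config$nChromosomes)
  if (m %% config$nChromosomes)
    perChrom[seq_len(m %% config$nChromosomes)] <-
      perChrom[seq_len(m %% config$nChromosomes)] + 1L
  H <- matrix(0L, nHaplotypes, m)
  chrom <- integer(m); pos <- numeric(m); block <- integer(m); pfreq <- numeric(m)
  j <- 0L; blk <- 0L
  for (cc in seq_len(config$nChromosomes)) {
    gaps <- 1 + stats::rexp(perChrom[cc], 1 / config$bpSpacingMean)
    cpos <- ceiling(cumsum(gaps))
    for (jj in seq_len(perChrom[cc])) {
      j <- j + 1L
      chrom[j] <- cc; pos[j] <- cpos[jj]
      newBlock <- (jj - 1L) %% config$blockLength == 0L
      if (newBlock) {
        blk <- blk + 1L
        p <- stats::runif(1, config$mafRange[1], config$mafRange[2])
        H[, j] <- stats::rbinom(nHaplotypes, 1L, p)
      } else {
        copy <- stats::runif(nHaplotypes) < config$rho
        H[, j] <- ifelse(copy, H[, j - 1L],
                         stats::rbinom(nHaplotypes, 1L, p))
      }
      block[j] <- blk; pfreq[j] <- p
    }
  }
  list(haplotypes = H,
       map = data.frame(chrom = chrom, pos = pos,
                        id = sprintf("snp%05d", seq_len(m)),
                        block = block, freq = pfreq))
}

#' Plant the phase structure of a CH / DH pair
#'
#' Rearranges the minor alleles of \code{snp2} across the haplotype pool so
#' that the pair's population phase matches the request, preserving both
#' allele frequencies exactly:
#' \describe{
#'   \item{trans}{both-minor haplotypes are eliminated wherever feasible
#'     (repulsion LD, f_ab ~ 0): every double heterozygote is a compound
#'     heterozygote, carrying the two minor alleles on opposite haplotypes.}
#'   \item{cis}{minor alleles of snp2 are concentrated on haplotypes already
#'     carrying the snp1 minor allele (coupling LD): double heterozygotes
#'     carry both minor alleles on one haplotype.}
#'   \item{random}{phase left as generated.}
#' }
#'
#' @param haplotypes 0/1 matrix, 2n rows (consecutive row pairs form
#'   individuals).
#' @param snp1,snp2 column indices of the pair.
#' @param phase "trans", "cis" or "random".
#' @return list(haplotypes = modified matrix, truth = realized phase record:
#'   counts of compound- and cis-double-heterozygous individuals and the
#'   realized both-minor haplotype frequency).
#' @export
plantPairEffect <- function(haplotypes, snp1, snp2,
                            phase = c("trans", "cis", "random")) {
  phase <- match.arg(phase)
  H <- haplotypes
  stopifnot(nrow(H) %% 2 == 0)
  if (sum(H[, snp1]) == 0 || sum(H[, snp2]) == 0)
    stop("both SNPs of a planted pair must be polymorphic")
  if (phase != "random") {
    aCar <- H[, snp1] == 1L
    nb <- sum(H[, snp2])
    H[, snp2] <- 0L
    if (phase == "trans") {
      host <- which(!aCar)
      if (nb > length(host)) {
        extra <- nb - length(host)
        H[host, snp2] <- 1L
        H[sample(which(aCar), extra), snp2] <- 1L
      } else {
        H[sample(host, nb), snp2] <- 1L
      }
    } else { # cis
      onA <- min(nb, sum(aCar))
      if (onA) H[sample(which(aCar), onA), snp2] <- 1L
      if (nb > onA) H[sample(which(!aCar), nb - onA), snp2] <- 1L
    }
  }
  odd <- seq(1, nrow(H), by = 2); even <- odd + 1
  g1 <- H[odd, snp1] + H[even, snp1]
  g2 <- H[odd, snp2] + H[even, snp2]
  dh <- g1 == 1L & g2 == 1L
  cisHap <- (H[odd, snp1] & H[odd, snp2]) | (H[even, snp1] & H[even, snp2])
  nDouble <- sum(g1 >= 1L & g2 >= 1L)
  if (nDouble < 10)
    warning("fewer than 10 double-carrier individuals after planting (",
            nDouble, ")")
  list(haplotypes = H,
       truth = list(snp1 = snp1, snp2 = snp2, phase = phase,
                    nDoubleHet = sum(dh),
                    nCH = sum(dh & !cisHap), nCisDH = sum(dh & cisHap),
                    fBothMinorHap = mean(H[, snp1] & H[, snp2])))
}

#' Genotypes from a phased haplotype matrix
#'
#' Sums consecutive row pairs: individual i has haplotype rows 2i-1 and 2i.
#'
#' @param haplotypes 0/1 matrix with an even number of rows.
#' @return integer matrix, individuals x SNPs.
#' @export
haplotypesToGenotypes <- function(haplotypes) {
  odd <- seq(1, nrow(haplotypes), by = 2)
  g <- haplotypes[odd, , drop = FALSE] + haplotypes[odd + 1, , drop = FALSE]
  storage.mode(g) <- "integer"
  g
}

#' Generate phenotypes from genotypes and planted effects
#'
#' height = intercept + sum(single beta * g) + sum(pair beta * min(g1+g2, 2))
#' + sexEffect * sex + ageSlope * age + sum(pcEffect * PC) + N(0, residualSd).
#' Covariates are simulated independently: sex ~ Bernoulli(0.5), age ~
#' Uniform(45, 90), PCs standard normal. For a pair flagged \code{chOnly},
#' the effect applies only to compound (trans) heterozygotes.
#'
#' @param genotypes individuals x SNPs matrix (from
#'   \code{\link{haplotypesToGenotypes}}).
#' @param config a \code{\link{simulationConfig}}.
#' @param haplotypes optional phased matrix, required for chOnly effects.
#' @return list(pheno = data.frame(sample_id, height, sex, age, PC...),
#'   genetic = per-individual planted genetic value).
#' @export
generatePhenotype <- function(genotypes, config, haplotypes = NULL) {
  n <- nrow(genotypes)
  sex <- stats::rbinom(n, 1L, 0.5)
  age <- stats::runif(n, 45, 90)
  pcs <- if (config$nPcs > 0)
    matrix(stats::rnorm(n * config$nPcs), n,
           dimnames = list(NULL, paste0("PC", seq_len(config$nPcs))))
  else NULL
  genetic <- numeric(n)
  se <- config$singleEffects
  if (!is.null(se))
    for (i in seq_len(nrow(se)))
      genetic <- genetic + se$beta[i] * genotypes[, se$snp[i]]
  pe <- config$pairEffects
  if (!is.null(pe)) {
    for (i in seq_len(nrow(pe))) {
      pseudo <- pmin(genotypes[, pe$snp1[i]] + genotypes[, pe$snp2[i]], 2L)
      if (isTRUE(pe$chOnly[i])) {
        if (is.null(haplotypes))
          stop("chOnly pair effects need the phased haplotypes")
        odd <- seq(1, nrow(haplotypes), by = 2); even <- odd + 1
        h1a <- haplotypes[odd, pe$snp1[i]]; h2a <- haplotypes[even, pe$snp1[i]]
        h1b <- haplotypes[odd, pe$snp2[i]]; h2b <- haplotypes[even, pe$snp2[i]]
        isCH <- (h1a & h2b & !h1b & !h2a) | (h2a & h1b & !h2b & !h1a)
        pseudo <- ifelse(isCH, pseudo, 0L)
      }
      genetic <- genetic + pe$beta[i] * pseudo
    }
  }
  height <- config$intercept + genetic + config$sexEffect * sex +
    config$ageSlope * age +
    (if (is.null(pcs)) 0 else drop(pcs %*% rep(config$pcEffect, config$nPcs))) +
    stats::rnorm(n, 0, config$residualSd)
  pheno <- data.frame(sample_id = sprintf("S%06d", seq_len(n)),
                      height = height, sex = sex, age = age)
  if (!is.null(pcs)) pheno <- cbind(pheno, as.data.frame(pcs))
  list(pheno = pheno, genetic = genetic)
}

#' Ascertain extreme-tall individuals from a pool
#'
#' Standardizes height within sex using the pool mean and SD, then samples
#' \code{nExtra} individuals from those with a standard deviation score (SDS)
#' above \code{cutoff} (1.88 corresponds to the upper ~3\% tail).
#'
#' @param pheno pool phenotype data.frame.
#' @param cutoff SDS cutoff; \code{-Inf} samples uniformly from the pool.
#' @param nExtra number of individuals to draw (without replacement).
#' @param seed optional seed for the draw.
#' @return the selected phenotype rows (with an \code{sds} column).
#' @export
ascertainTall <- function(pheno, cutoff, nExtra, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sds <- stats::ave(pheno$height, pheno$sex,
                    FUN = function(h) (h - mean(h)) / stats::sd(h))
  eligible <- which(sds > cutoff)
  if (length(eligible) < nExtra) {
    frac <- max(length(eligible) / nrow(pheno), 1e-6)
    stop("only ", length(eligible), " pool individuals above SDS ", cutoff,
         "; need a pool of roughly ", ceiling(nExtra / frac), " for nExtra = ",
         nExtra)
  }
  take <- sample(eligible, nExtra)
  out <- pheno[take, , drop = FALSE]
  out$sds <- sds[take]
  rownames(out) <- NULL
  out
}

#' Simulate a complete cohort
#'
#' Orchestrates \code{\link{simulateHaplotypes}},
#' \code{\link{plantPairEffect}} for every configured pair,
#' \code{\link{generatePhenotype}}, optional tall-tail ascertainment, and
#' panel assembly. All randomness comes from \code{config$seed}.
#'
#' With tall ascertainment, a larger haplotype pool is simulated; the first
#' \code{nIndividuals} form the base cohort and \code{nExtra} individuals
#' with SDS above the cutoff (standardized within sex on pool statistics) are
#' appended from the remainder.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list(panel, pheno, truth, config); truth holds the per-effect
#'   records (realized phase counts for pairs) and the generator seed.
#' @export
simulateCohort <- function(config) {
  set.seed(config$seed)
  tall <- config$tallAscertainment
  nBase <- config$nIndividuals
  nPool <- if (is.null(tall)) nBase else {
    tailFrac <- stats::pnorm(tall$cutoff, lower.tail = FALSE)
    nBase + max(4 * ceiling(tall$nExtra / max(tailFrac, 1e-4)), 100L)
  }
  sim <- simulateHaplotypes(config, nHaplotypes = 2L * nPool)
  H <- sim$haplotypes
  truth <- list(seed = config$seed, singleEffects = config$singleEffects,
                pairEffects = config$pairEffects, pairs = list())
  pe <- config$pairEffects
  if (!is.null(pe)) {
    for (i in seq_len(nrow(pe))) {
      if (sim$map$chrom[pe$snp1[i]] != sim$map$chrom[pe$snp2[i]])
        stop("planted pair members must lie on the same chromosome")
      pl <- plantPairEffect(H, pe$snp1[i], pe$snp2[i], pe$phase[i])
      H <- pl$haplotypes
      truth$pairs[[i]] <- pl$truth
    }
  }
  G <- haplotypesToGenotypes(H)
  gen <- generatePhenotype(G, config, haplotypes = H)
  pheno <- gen$pheno
  if (!is.null(tall)) {
    base <- seq_len(nBase)
    poolRest <- pheno[-base, , drop = FALSE]
    sdsAll <- stats::ave(pheno$height, pheno$sex,
                         FUN = function(h) (h - mean(h)) / stats::sd(h))
    eligible <- poolRest[sdsAll[-base] > tall$cutoff, , drop = FALSE]
    if (nrow(eligible) < tall$nExtra)
      stop("tall-ascertainment pool too small: ", nrow(eligible),
           " eligible, need ", tall$nExtra)
    pick <- sample(nrow(eligible), tall$nExtra)
    keepIds <- c(pheno$sample_id[base], eligible$sample_id[pick])
  } else {
    keepIds <- pheno$sample_id
  }
  keep <- match(keepIds, pheno$sample_id)
  panel <- GenotypePanel(t(G[keep, , drop = FALSE]),
                         chrom = sim$map$chrom, pos = sim$map$pos,
                         id = sim$map$id,
                         allele1 = rep("A", config$nSnps),
                         allele2 = rep("G", config$nSnps),
                         samples = pheno$sample_id[keep])
  truth$genetic <- gen$genetic[keep]
  list(panel = panel, pheno = pheno[keep, , drop = FALSE], truth = truth,
       config = config)
}
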