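## Shared fixture builders. All fixtures are generated in code; the suite's
## standard seed is 42.

quietly <- function(expr) suppressMessages(expr)

## Panel from a raw samples-x-variants integer matrix (helper transposes).
toyPanel <- function(genoBySample, chrom = NULL, pos = NULL, id = NULL,
                     a1 = "A", a2 = "G") {
  m <- ncol(genoBySample)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  if (is.null(id)) id <- sprintf("snp%05d", seq_len(m))
  GenotypePanel(t(genoBySample), chrom = chrom, pos = pos, id = id,
                allele1 = rep(a1, length.out = m),
                allele2 = rep(a2, length.out = m),
                samples = sprintf("S%06d", seq_len(nrow(genoBySample))))
}

## Null cohort: no planted effects, independent SNPs.
nullCohort <- function(n = 500, m = 50, seed = 42, rho = 0, nChrom = 2) {
  quietly(simulateCohort(simulationConfig(
    nIndividuals = n, nSnps = m, nChromosomes = nChrom, rho = rho,
    seed = seed)))
}

## Cohort with one planted pair effect.
pairCohort <- function(n = 4000, m = 60, beta = 0.8, phase = "trans",
                       maf = c(0.05, 0.05), residualSd = 6.5, seed = 42,
                       snp1 = 21, snp2 = 26, chOnly = FALSE) {
  quietly(simulateCohort(simulationConfig(
    nIndividuals = n, nSnps = m, nChromosomes = 1, rho = 0,
    mafRange = maf,
    pairEffects = data.frame(snp1 = snp1, snp2 = snp2, beta = beta,
                             phase = phase, chOnly = chOnly),
    residualSd = residualSd, seed = seed)))
}

## Phenotype with no covariate columns beyond the required ones.
barePheno <- function(height, sex = NULL, age = NULL) {
  n <- length(height)
  data.frame(sample_id = sprintf("S%06d", seq_len(n)), height = height,
             sex = if (is.null(sex)) rep(0L, n) else sex,
             age = if (is.null(age)) rep(50, n) else age)
}

## Independent profile-grid oracle for the two-locus likelihood: maximizes
## over the both-minor haplotype frequency with marginals fixed at the
## observed allele frequencies (the full-simplex maximum lies on this slice
## because per-locus allele counts are observed exactly).
gridLogLikMax <- function(g1, g2, step = 1e-5) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  pa <- mean(g1) / 2; pb <- mean(g2) / 2
  lo <- max(0, pa + pb - 1); hi <- min(pa, pb)
  ts <- seq(lo, hi, by = step)
  n <- table(factor(g1, 0:2), factor(g2, 0:2))
  ll <- vapply(ts, function(t) {
    f <- c(AB = 1 - pa - pb + t, Ab = pb - t, aB = pa - t, ab = t)
    p <- c(f["AB"]^2, 2 * f["AB"] * f["Ab"], f["Ab"]^2,
           2 * f["AB"] * f["aB"], 2 * f["Ab"] * f["aB"] + 2 * f["AB"] * f["ab"],
           2 * f["Ab"] * f["ab"],
           f["aB"]^2, 2 * f["aB"] * f["ab"], f["ab"]^2)
    cnt <- as.numeric(t(n))  # row-major: (g1=0,g2=0..2), (g1=1, ...), ...
    sum(cnt[cnt > 0] * log(pmax(p[cnt > 0], 1e-300)))
  }, numeric(1))
  max(ll)
}

## Genotypes drawn from explicit haplotype frequencies (AB, Ab, aB, ab).
genoFromHapFreqs <- function(f, n) {
  hap <- function() sample(1:4, n, TRUE, f)
  h1 <- hap(); h2 <- hap()
  ## hap codes: 1=AB 2=Ab 3=aB 4=ab; a = minor at locus1, b at locus2
  list(g1 = (h1 >= 3) + (h2 >= 3),
       g2 = (h1 %in% c(2, 4)) + (h2 %in% c(2, 4)))
}
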