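test_that("polygenic scores are weighted effect-allele sums", {
  set.seed(51)
  geno <- matrix(rbinom(100 * 4, 2, 0.3), 100, 4)
  p <- toyPanel(geno)
  vi <- variantInfo(p)
  ## all-zero weights give all-zero scores
  w0 <- data.frame(snp = vi$id, effect_allele = vi$alleleMinor,
                   weight = 0)
  expect_true(all(computePRS(p, w0) == 0))
  ## single unit weight equals the effect-allele count
  w1 <- data.frame(snp = vi$id[2], effect_allele = vi$alleleMinor[2],
                   weight = 1)
  expect_equal(unname(computePRS(p, w1)), unname(calls(p)[2, ]))
  ## flipping the effect allele and negating the weight shifts scores by a
  ## constant (R^2 unchanged)
  set.seed(52)
  w <- data.frame(snp = vi$id, effect_allele = vi$alleleMinor,
                  weight = rnorm(4))
  wf <- data.frame(snp = vi$id, effect_allele = vi$alleleMajor,
                   weight = -w$weight)
  d <- computePRS(p, w) - computePRS(p, wf)
  expect_lt(diff(range(d)), 1e-12)
  ## unmatched SNPs and impossible effect alleles are dropped with messages
  wb <- rbind(w, data.frame(snp = "rs_absent", effect_allele = "A",
                            weight = 1))
  wb$effect_allele[1] <- "T"
  expect_message(expect_message(prs <- computePRS(p, wb), "not in panel"),
                 "neither")
  expect_equal(length(prs), 100)
})

test_that("PRS from truth-matched weights recovers the planted variance fraction", {
  cfg <- simulationConfig(nIndividuals = 5000, nSnps = 12, rho = 0,
                          mafRange = c(0.2, 0.4), residualSd = 4,
                          singleEffects = data.frame(snp = c(2, 5, 9),
                                                     beta = c(0.6, -0.8, 0.5)),
                          seed = 42)
  sim <- quietly(simulateCohort(cfg))
  vi <- variantInfo(sim$panel)
  w <- data.frame(snp = vi$id[c(2, 5, 9)],
                  effect_allele = vi$alleleMinor[c(2, 5, 9)],
                  weight = c(0.6, -0.8, 0.5))
  prs <- computePRS(sim$panel, w)
  adj <- adjustHeights(sim$pheno,
                       setdiff(names(sim$pheno), c("sample_id", "height")))
  r2 <- summary(lm(adj ~ prs))$r.squared
  varG <- var(sim$truth$genetic)
  expect_lt(abs(r2 - varG / (varG + cfg$residualSd^2)), 0.03)
})

test_that("iterative R2 increments telescope and match a nested-refit oracle", {
  set.seed(53)
  n <- 200
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 0.5 * X$a + 0.2 * X$c + rnorm(n)
  led <- iterativeR2(y, X, classes = c("SNP", "SNP", "pseudo-marker"))
  full <- summary(lm(y ~ a + b + c, data = X))$r.squared
  expect_equal(sum(led$ledger$r2pct), led$totalR2pct, tolerance = 1e-10)
  expect_equal(led$totalR2pct, 100 * full, tolerance = 1e-10)
  expect_equal(sum(led$subtotals), led$totalR2pct, tolerance = 1e-10)
  ## independent oracle: order by full-model P, refit nested models by hand
  fp <- summary(lm(y ~ a + b + c, data = X))$coefficients[-1, 4]
  ord <- names(sort(fp))
  prev <- 0; want <- numeric(3)
  for (i in 1:3) {
    cur <- summary(lm(y ~ ., data = X[, ord[1:i], drop = FALSE]))$r.squared
    want[i] <- cur - prev; prev <- cur
  }
  expect_equal(led$ledger$term, ord)
  expect_equal(led$ledger$r2pct, 100 * want, tolerance = 1e-10)
  expect_equal(led$ledger$negLog10P, -log10(fp[ord]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("orthogonal predictors contribute their marginal R2 as increments", {
  set.seed(54)
  ## columns orthonormal and orthogonal to the intercept
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(300 * 3), 300, 3))))[, 2:4]
  X <- data.frame(Q)
  y <- drop(Q %*% c(1, 2, 0.5)) + rnorm(300)
  led <- iterativeR2(y, X)
  marg <- vapply(X, function(x) summary(lm(y ~ x))$r.squared, numeric(1))
  expect_equal(led$ledger$r2pct[order(led$ledger$term)],
               unname(100 * marg), tolerance = 1e-8)
})

test_that("pseudo-marker R2 comparisons behave across planted, reduced, null cases", {
  ## monomorphic partner: R2(pseudo) reduces to R2(SNP1)
  set.seed(55)
  g1 <- rbinom(1000, 2, 0.3); y <- 0.3 * g1 + rnorm(1000)
  r <- comparePairVsPseudo(y, g1, rep(0L, 1000))
  expect_equal(r$pseudo, r$snp1, tolerance = 1e-12)
  ## planted trans pseudo-effect: pseudo beats either single SNP
  sim <- pairCohort(n = 4000, m = 10, beta = 1, phase = "trans",
                    maf = c(0.1, 0.2), residualSd = 4, seed = 56,
                    snp1 = 3, snp2 = 7)
  G <- calls(sim$panel)
  adj <- adjustHeights(sim$pheno,
                       setdiff(names(sim$pheno), c("sample_id", "height")))
  rp <- comparePairVsPseudo(adj, G["snp00003", ], G["snp00007", ])
  expect_gt(rp$pseudo, max(rp$snp1, rp$snp2))
  expect_gte(rp$joint + 1e-12, max(rp$snp1, rp$snp2))
  ## independent null SNPs explain essentially nothing
  g1n <- rbinom(4000, 2, 0.2); g2n <- rbinom(4000, 2, 0.2)
  rn <- comparePairVsPseudo(rnorm(4000), g1n, g2n)
  expect_true(all(unlist(rn) < 0.005))
})

test_that("replication freezes discovery definitions and flags P < 0.05", {
  sim <- pairCohort(n = 4000, m = 20, beta = 0.8, phase = "trans",
                    maf = c(0.1, 0.3), residualSd = 4, seed = 57,
                    snp1 = 4, snp2 = 8)
  vi <- variantInfo(sim$panel)
  hits <- data.frame(snp1 = "snp00004", ea1 = vi$alleleMinor[4],
                     snp2 = "snp00008", ea2 = vi$alleleMinor[8],
                     beta_discovery = 0.8)
  ## self-replication: same cohort, sex/age adjustment only
  self <- quietly(replicateHits(hits, sim$panel, sim$pheno))
  expect_true(self$testable)
  expect_true(self$replicated)
  expect_true(self$signAgrees)
  G <- calls(sim$panel)
  ps <- collapsePair(G["snp00004", ], G["snp00008", ])
  want <- fitPseudoMarker(ps, sim$pheno, c("sex", "age"))
  expect_equal(self$P, want$P, tolerance = 1e-12)

  ## a second cohort sharing the planted pair replicates it; null pairs
  ## replicate at roughly the nominal 5% rate
  sim2 <- pairCohort(n = 4000, m = 20, beta = 0.8, phase = "trans",
                     maf = c(0.1, 0.3), residualSd = 4, seed = 58,
                     snp1 = 4, snp2 = 8)
  nullHits <- data.frame(snp1 = sprintf("snp%05d", c(1, 2, 11:18)),
                         ea1 = "A",
                         snp2 = sprintf("snp%05d", c(2, 3, 12:19)),
                         ea2 = "A",
                         beta_discovery = 1)
  nullHits$ea1 <- vi$alleleMinor[match(nullHits$snp1, vi$id)]
  nullHits$ea2 <- vi$alleleMinor[match(nullHits$snp2, vi$id)]
  rep2 <- quietly(replicateHits(rbind(hits, nullHits), sim2$panel,
                                sim2$pheno))
  expect_true(rep2$replicated[1])
  expect_lt(mean(rep2$replicated[-1]), 0.35)

  ## absent SNPs are untestable, not errors
  miss <- data.frame(snp1 = "rs_nowhere", ea1 = "A", snp2 = NA, ea2 = NA,
                     beta_discovery = 1)
  rm1 <- quietly(replicateHits(miss, sim$panel, sim$pheno))
  expect_false(rm1$testable)
  expect_true(is.na(rm1$P))
})
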