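test_that("collapsing matrices implement their genetic models over all 9 cells", {
  add <- additiveMatrix(); rec <- recessiveMatrix()
  for (g1 in 0:2) for (g2 in 0:2) {
    expect_equal(collapsePair(g1, g2, add), min(g1 + g2, 2))
    expect_equal(collapsePair(g1, g2, rec), as.integer(g1 + g2 >= 2))
    ## symmetry in the pair members
    expect_equal(collapsePair(g1, g2, add), collapsePair(g2, g1, add))
    expect_equal(collapsePair(g1, g2, rec), collapsePair(g2, g1, rec))
  }
  expect_equal(nCategories(add), 3)   # 0, 1, "2 or more" minor alleles
  expect_equal(nCategories(rec), 2)   # 0-1 vs "2 or more"
  ## double heterozygotes (CH and cis alike) collapse to the top category
  expect_equal(collapsePair(1, 1, add), 2)
  expect_equal(collapsePair(1, 0, rec), 0)
  expect_equal(collapsePair(2, 0, rec), 1)
  ## missing propagates
  expect_true(is.na(collapsePair(NA, 1, add)))
  expect_true(is.na(collapsePair(2, NA, rec)))
  expect_error(customMatrix(matrix(c(0, 2, 2, 2, 2, 2, 2, 2, 2), 3)),
               "consecutive")
})

test_that("window enumeration honours distance, step, k-cap and chromosomes", {
  ## two SNPs 600 kb apart with d = 500 kb: no pairs
  far <- data.frame(chrom = c("1", "1"), pos = c(1e5, 7e5))
  expect_true(all(lengths(enumerateWindows(far, windowSpec(d = 5e5),
                                           rep(0, 2))) == 0))
  ## 10 SNPs 10 kb apart, d = 35 kb: index 1 pairs with SNPs 2-4 only
  ten <- data.frame(chrom = rep("1", 10), pos = (1:10) * 10000)
  w <- enumerateWindows(ten, windowSpec(k = 300, d = 35000), rep(0, 10))
  expect_equal(w[[1]], 2:4)
  expect_equal(w[[8]], 9:10)
  expect_equal(w[[10]], integer(0))
  ## 400 SNPs within d: truncated to k = 300 tests
  many <- data.frame(chrom = rep("1", 401), pos = (1:401) * 1000)
  w4 <- enumerateWindows(many, windowSpec(k = 300, d = 5e5), rep(0, 401))
  expect_equal(length(w4[[1]]), 300)
  expect_equal(w4[[1]], 2:301)
  ## no cross-chromosome pairs
  twoChr <- data.frame(chrom = rep(c("1", "2"), each = 5),
                       pos = rep((1:5) * 1000, 2))
  w2 <- enumerateWindows(twoChr, windowSpec(d = 5e5), rep(0, 10))
  expect_equal(w2[[5]], integer(0))
  expect_equal(w2[[6]], 7:10)
  ## brute-force cross-check on a random map
  set.seed(11)
  rnd <- data.frame(chrom = as.character(rep(1:2, each = 30)),
                    pos = as.numeric(c(sort(sample(1e6, 30)),
                                       sort(sample(1e6, 30)))))
  spec <- windowSpec(k = 7, d = 120000)
  got <- enumerateWindows(rnd, spec, rep(0, 60))
  for (i in seq_len(60)) {
    want <- setdiff(which(rnd$chrom == rnd$chrom[i] & rnd$pos > rnd$pos[i] &
                            rnd$pos - rnd$pos[i] <= spec@d), seq_len(i))
    expect_equal(got[[i]], head(sort(want), spec@k))
  }
})

test_that("the marginal p-filter supports either, both and index rules", {
  map <- data.frame(chrom = rep("1", 4), pos = (1:4) * 1000)
  P <- c(0.05, 0.5, 0.08, 0.9)
  either <- enumerateWindows(map, windowSpec(pFilter = 0.1, rule = "either"),
                             P)
  expect_equal(either[[1]], 2:4)          # index passes, all pairs kept
  expect_equal(either[[2]], 3L)           # only the passing partner
  both <- enumerateWindows(map, windowSpec(pFilter = 0.1, rule = "both"), P)
  expect_equal(both[[1]], 3L)
  expect_equal(both[[2]], integer(0))
  index <- enumerateWindows(map, windowSpec(pFilter = 0.1, rule = "index"), P)
  expect_equal(index[[1]], 2:4)
  expect_equal(index[[2]], integer(0))
  expect_equal(index[[3]], 4L)
})

test_that("pseudo-marker fits flag degenerate markers and recover planted effects", {
  ph <- barePheno(rnorm(100, 170, 7))
  expect_true(fitPseudoMarker(rep(1L, 100), ph)$degenerate)
  sim <- pairCohort(n = 5000, m = 10, beta = 0.8, phase = "trans",
                    maf = c(0.2, 0.3), residualSd = 4, seed = 44,
                    snp1 = 3, snp2 = 7)
  G <- calls(sim$panel)
  ps <- collapsePair(G["snp00003", ], G["snp00007", ])
  fit <- fitPseudoMarker(ps, sim$pheno)
  expect_lt(abs(fit$beta - 0.8), 2 * fit$se)
  expect_equal(sum(fit$counts), 5000)
})

test_that("a monomorphic partner reduces additive GCDH to the single-SNP test", {
  set.seed(12)
  geno <- cbind(rbinom(500, 2, 0.3), 0L)          # partner monomorphic
  p <- toyPanel(geno, pos = c(1000, 2000))
  ph <- barePheno(rnorm(500, 170, 7) + 0.5 * geno[, 1],
                  sex = rbinom(500, 1, 0.5))
  gw <- quietly(runGwas(p, ph, covariates = "sex"))
  sc <- quietly(gcdhScan(p, ph, covariates = "sex",
                         spec = windowSpec(pFilter = 1), marginal = gw))
  rec <- scanRecords(sc)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$minP, gw$P[1], tolerance = 1e-12)
  expect_equal(rec$beta, gw$beta[1], tolerance = 1e-12)
})

test_that("scan minima match an exhaustive brute-force oracle on a toy genome", {
  sim <- nullCohort(n = 500, m = 20, seed = 42, rho = 0.5, nChrom = 2)
  ## a couple of mild effects so the p-filter has structure to chew on
  ph <- sim$pheno
  G <- calls(sim$panel)
  ph$height <- ph$height + 0.8 * G[3, ] + 0.6 * collapsePair(G[8, ], G[9, ])
  covs <- setdiff(names(ph), c("sample_id", "height"))
  gw <- quietly(runGwas(sim$panel, ph, covs))
  spec <- windowSpec(k = 5, d = 40000, pFilter = 0.3)
  sc <- quietly(gcdhScan(sim$panel, ph, covs, spec, marginal = gw))
  rec <- scanRecords(sc)
  map <- variantInfo(sim$panel)
  ## independent oracle: direct lm() over every eligible pair
  oracle <- new.env(); oracle$minP <- rep(NA_real_, nrow(map))
  pf <- gw$P <= spec@pFilter
  for (i in seq_len(nrow(map))) {
    js <- which(map$chrom == map$chrom[i] & map$pos > map$pos[i] &
                  map$pos - map$pos[i] <= spec@d)
    js <- head(js[pf[i] | pf[js]], spec@k)
    ps <- numeric(0)
    for (j in js) {
      pseudo <- pmin(G[i, ] + G[j, ], 2)
      if (length(unique(pseudo)) < 2) next
      fml <- as.formula(paste("height ~ pseudo +",
                              paste(covs, collapse = "+")))
      fit <- summary(lm(fml, data = cbind(ph, pseudo = pseudo)))
      ps <- c(ps, fit$coefficients["pseudo", 4])
    }
    if (length(ps)) oracle$minP[i] <- min(ps)
  }
  want <- oracle$minP[match(rec$snp, map$id)]
  expect_equal(rec$minP, want, tolerance = 1e-9)
  ## dominance: the scan minimum never exceeds any recomputed pair P
  expect_true(all(!is.na(want)))
  expect_equal(sort(rec$snp), sort(map$id[!is.na(oracle$minP)]))
})

test_that("equal minimum P ties break to the smallest partner position", {
  set.seed(13)
  g <- rbinom(300, 2, 0.3)
  geno <- cbind(rbinom(300, 2, 0.4), g, g)        # duplicated partner column
  p <- toyPanel(geno, pos = c(1000, 2000, 3000))
  ph <- barePheno(rnorm(300, 170, 7))
  sc <- quietly(gcdhScan(p, ph, covariates = character(0),
                         spec = windowSpec(pFilter = 1)))
  rec <- scanRecords(sc)
  row1 <- rec[rec$snp == "snp00001", ]
  pr <- pairResults(sc)
  dup <- pr[pr$snp1 == "snp00001" & pr$snp2 %in% c("snp00002", "snp00003"), ]
  expect_equal(dup$P[1], dup$P[2], tolerance = 1e-12)
  expect_equal(row1$partner, "snp00002")
})

test_that("permutation replicates shuffle whole phenotype rows deterministically", {
  sim <- nullCohort(n = 200, m = 12, seed = 42)
  spec <- windowSpec(k = 5, d = 50000, pFilter = 1)
  pn1 <- quietly(permutationNull(sim$panel, sim$pheno, spec = spec,
                                 nPerm = 2, seed = 7))
  pn2 <- quietly(permutationNull(sim$panel, sim$pheno, spec = spec,
                                 nPerm = 2, seed = 7))
  expect_identical(pn1$replicates, pn2$replicates)   # same seed, same result
  expect_equal(pn1$seeds, c(8, 9))                   # replicate r: seed + r
  ## row integrity of the shuffle: the permuted table must be a permutation
  ## of whole rows
  set.seed(8)
  idx <- sample(nrow(sim$pheno))
  valueCols <- setdiff(names(sim$pheno), "sample_id")
  shuffled <- sim$pheno
  shuffled[, valueCols] <- sim$pheno[idx, valueCols]
  expect_equal(sort(shuffled$height), sort(sim$pheno$height))
  key <- function(df) do.call(paste, c(df[valueCols], sep = "|"))
  expect_setequal(key(shuffled), key(sim$pheno))
})

test_that("identical seed and configuration give byte-identical result tables", {
  sim <- nullCohort(n = 300, m = 15, seed = 42)
  spec <- windowSpec(k = 4, d = 60000, pFilter = 1)
  s1 <- quietly(gcdhScan(sim$panel, sim$pheno, spec = spec))
  s2 <- quietly(gcdhScan(sim$panel, sim$pheno, spec = spec))
  f1 <- file.path(tempdir(), "scan1.tsv"); f2 <- file.path(tempdir(), "scan2.tsv")
  writeResults(scanRecords(s1), f1); writeResults(scanRecords(s2), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
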