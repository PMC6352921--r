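test_that("leave-one-chromosome-out association is calibrated at null
          SNPs in a family-structured polygenic sample", {
  # polygenic background confined to chromosomes 2-3: chromosome 1 is
  # truly null and its leave-one-out GRM spans the causal space exactly
  lambdas <- vapply(1:3, function(r) {
    ped <- simulatePedigree(150, 2, seed = 220 + r)    # 600 individuals
    gm <- simulateGenotypes(ped, 4500, nChromosomes = 3,
                            seed = 240 + r)
    offc <- which(snpMap(gm)$chr != 1)
    set.seed(260 + r)
    u <- drop(scale(genotypes(gm)[, offc]) %*% rnorm(length(offc)))
    y <- drop(scale(u)) * sqrt(0.4) + rnorm(600, 0, sqrt(0.6))
    ss <- mlmaLoco(y, NULL, gm)
    genomicInflation(ss$p[ss$chr == 1])
  }, numeric(1))
  expect_true(all(lambdas > 0.9 & lambdas < 1.1))
  expect_gt(mean(lambdas), 0.95)
  expect_lt(mean(lambdas), 1.05)
})

test_that("a planted causal variant is the top association", {
  hits <- vapply(1:3, function(r) {
    ped <- simulatePedigree(0, 0, nSingletons = 1500, seed = 70 + r)
    gm <- simulateGenotypes(ped, 600, nChromosomes = 3, seed = 80 + r)
    g <- genotypes(gm)
    causal <- 250L
    set.seed(90 + r)
    y <- drop(scale(g[, causal])) * sqrt(0.05) + rnorm(1500, 0, sqrt(0.95))
    ss <- mlmaLoco(y, NULL, gm)
    ss$snp[which.min(ss$p)] == snpMap(gm)$snp[causal]
  }, logical(1))
  expect_true(all(hits))
})

test_that("without family structure the mixed model collapses to plain
          regression", {
  ped <- simulatePedigree(0, 0, nSingletons = 500, seed = 1)
  gm <- simulateGenotypes(ped, 300, nChromosomes = 3, seed = 2)
  set.seed(3)
  y <- rnorm(500)
  ss <- mlmaLoco(y, NULL, gm)
  pLm <- vapply(seq_len(300), function(j)
    summary(lm(y ~ genotypes(gm)[, j]))$coefficients[2, 4], numeric(1))
  ss <- ss[match(snpMap(gm)$snp, ss$snp), ]
  expect_gt(cor(-log10(ss$p), -log10(pLm)), 0.99)
  expect_lt(median(abs(ss$p - pLm)), 0.02)
  expect_error(mlmaLoco(y, NULL, simulateGenotypes(ped, 50, seed = 4)),
               ">= 2 chromosomes")
})

test_that("LOCO effect estimates ignore the SNP order of the excluded
          chromosomes", {
  ped <- simulatePedigree(100, 1, seed = 5)
  gm <- simulateGenotypes(ped, 200, nChromosomes = 2, seed = 6)
  y <- simulatePhenotypes(ped, gm, varG = 0.3, nCausal = 50,
                          seed = 7)$pheno
  # the chromosome-1 tests depend on the other chromosomes only
  # through the leave-one-out GRM, which is order-invariant
  ix2 <- which(snpMap(gm)$chr == 2)
  set.seed(8)
  g1 <- relValues(buildGRM(gm, snps = ix2))
  g2 <- relValues(buildGRM(gm, snps = sample(ix2)))
  expect_equal(g1, g2, tolerance = 1e-12)
  # and the full scan is deterministic
  ss1 <- mlmaLoco(y, NULL, gm)
  ss2 <- mlmaLoco(y, NULL, gm)
  expect_identical(ss1, ss2)
})

test_that("LD scores are unity in linkage equilibrium, two for a
          perfect pair, and match the brute-force double loop", {
  ped <- simulatePedigree(0, 0, nSingletons = 600, seed = 8)
  gm <- simulateGenotypes(ped, 80, seed = 9)
  l <- ldScores(gm)
  expect_lt(max(abs(l$ldScore - 1)), 0.15)
  expect_lt(abs(mean(l$ldScore) - 1), 0.01)

  g <- genotypes(gm)[, 1:10]
  g[, 2] <- g[, 1]   # perfect LD pair
  gm2 <- makeGenotypeMatrix(g, bp = (1:10) * 1000L)
  l2 <- ldScores(gm2)
  expect_equal(l2$ldScore[1], 2, tolerance = 0.05)
  expect_equal(l2$ldScore[2], 2, tolerance = 0.05)

  ped3 <- simulatePedigree(0, 0, nSingletons = 300, seed = 10)
  gm3 <- simulateGenotypes(ped3, 50, ldBlockSize = 5, ldRho = 0.7,
                           seed = 11)
  l3 <- ldScores(gm3, windowKb = 20)
  z <- scale(genotypes(gm3))
  n <- 300
  bf <- vapply(seq_len(50), function(j) {
    r2 <- (crossprod(z[, j], z)/(n - 1))^2
    r2a <- r2 - (1 - r2)/(n - 2)
    inWin <- abs(snpMap(gm3)$bp - snpMap(gm3)$bp[j]) <= 20000
    1 + sum(r2a[inWin]) - r2a[j]
  }, numeric(1))
  expect_equal(l3$ldScore, bf, tolerance = 1e-10)
})

test_that("LD score regression recovers simulated heritability and is
          invariant to SNP order and z-sign flips", {
  set.seed(12)
  lsc <- runif(5000, 0.5, 3)
  ld <- data.frame(snp = sprintf("snp%06d", 1:5000), chr = 1,
                   bp = 10000 * (1:5000), ldScore = lsc)
  ss <- simulateSumstats(20000, 5000, h2 = 0.3, ldScores = lsc,
                         seed = 13)
  h <- ldscH2(ss[[1]], ld)
  expect_lt(abs(h$h2 - 0.3), 2 * h$se)
  expect_lt(abs(h$intercept - 1), 4 * h$interceptSE)
  # order invariance
  h2 <- ldscH2(ss[[1]][sample(5000), ], ld)
  expect_equal(h2$h2, h$h2, tolerance = 1e-10)
  # uniform sign flip of the effects
  flip <- ss[[1]]; flip$beta <- -flip$beta
  expect_equal(ldscH2(flip, ld)$h2, h$h2, tolerance = 1e-10)
  # doubling the simulated sample leaves the estimate centred
  ssBig <- simulateSumstats(40000, 5000, h2 = 0.3, ldScores = lsc,
                            seed = 14)
  hBig <- ldscH2(ssBig[[1]], ld)
  expect_lt(abs(hBig$h2 - 0.3), 2 * hBig$se)
  # null trait
  ss0 <- simulateSumstats(20000, 5000, h2 = 0, ldScores = lsc,
                          seed = 15)
  h0 <- ldscH2(ss0[[1]], ld)
  expect_lt(abs(h0$h2), 2 * h0$se)
  expect_lt(abs(h0$intercept - 1), 3 * h0$interceptSE)
})

test_that("genetic correlation is recovered, self-correlation is unity
          and independent traits are null", {
  set.seed(16)
  lsc <- runif(5000, 0.5, 3)
  ld <- data.frame(snp = sprintf("snp%06d", 1:5000), chr = 1,
                   bp = 10000 * (1:5000), ldScore = lsc)
  ss <- simulateSumstats(20000, 5000, h2 = 0.3, rG = 0.33,
                         ldScores = lsc, seed = 17)
  rg <- ldscRg(ss[[1]], ss[[2]], ld)
  expect_lt(abs(rg$rG - 0.33), 2 * rg$se)
  self <- ldscRg(ss[[1]], ss[[1]], ld)
  expect_equal(self$rG, 1, tolerance = 1e-8)
  expect_equal(self$gencov, ldscH2(ss[[1]], ld)$h2, tolerance = 1e-10)
  ss0 <- simulateSumstats(20000, 5000, h2 = 0.3, rG = 0,
                          ldScores = lsc, seed = 18)
  rg0 <- ldscRg(ss0[[1]], ss0[[2]], ld)
  expect_lt(abs(rg0$rG), 2 * rg0$se)
  expect_error(ldscRg(ss[[1]][1:100, ], ss[[2]], ld), "200")
})

test_that("the correlation-difference Z test does its arithmetic", {
  expect_equal(zDiff(0.4, 0.1, 0.4, 0.2)$Z, 0)
  expect_equal(round(zDiff(0.25, 0.10, 0.06, 0.07)$Z, 2), 1.56)
  expect_equal(zDiff(1.0, 0.1, 0.0, 0.1)$Z, 7.07, tolerance = 1e-3)
  z <- zDiff(0.25, 0.10, 0.06, 0.07)
  expect_equal(z$pTwoSided, 2 * z$pOneSided, tolerance = 1e-12)
})
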