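mkStats <- function(snp, chr, bp, p, beta = 1, a1 = "A", a2 = "G") {
  data.frame(snp = snp, chr = chr, bp = bp, a1 = a1, a2 = a2,
             beta = beta, se = 1, p = p, n = 1000,
             stringsAsFactors = FALSE)
}

test_that("SNPs beyond the clumping window are never pruned", {
  set.seed(1)
  g <- matrix(rbinom(100 * 5, 2, 0.3), 100, 5)
  gm <- makeGenotypeMatrix(g, bp = (1:5) * 400000L)  # 400 kb apart
  st <- mkStats(colnames(genotypes(gm)), 1, (1:5) * 400000L,
                c(1e-8, 1e-6, 1e-4, 1e-3, 0.05))
  expect_equal(sort(clumpSumstats(st, gm)$snp), sort(st$snp))
})

test_that("of two SNPs in tight LD the more significant survives", {
  set.seed(2)
  x <- rbinom(400, 2, 0.4)
  flip <- runif(400) < 0.15
  y <- ifelse(flip, rbinom(400, 2, 0.4), x)   # r2 well above 0.1
  gm <- makeGenotypeMatrix(cbind(a = x, b = y), bp = c(1000L, 11000L))
  st <- mkStats(c("a", "b"), 1, c(1000L, 11000L), c(1e-8, 1e-4))
  out <- clumpSumstats(st, gm)
  expect_equal(out$snp, "a")
})

test_that("greedy clumping matches the exhaustive oracle on a block
          panel", {
  ped <- simulatePedigree(0, 0, nSingletons = 400, seed = 3)
  gm <- simulateGenotypes(ped, 100, mafRange = c(0.1, 0.45),
                          ldBlockSize = 5, ldRho = 0.8, seed = 4)
  set.seed(5)
  st <- snpMap(gm)
  st$beta <- rnorm(100); st$se <- 1; st$p <- runif(100); st$n <- 1000
  out <- clumpSumstats(st, gm, r2Max = 0.1, windowKb = 250)
  expect_equal(sort(out$snp),
               clumpOracle(st, genotypes(gm), 0.1, 250))
  # absent reference SNPs are dropped with a message
  st2 <- rbind(st, within(st[1, ], snp <- "ghost"))
  expect_message(clumpSumstats(st2, gm), "absent")
})

test_that("scores accumulate exactly over the threshold grid", {
  g <- matrix(c(0, 1,
                2, 1,
                1, 2), 2, 3,
              dimnames = list(c("i1", "i2"), c("s1", "s2", "s3")))
  gm <- makeGenotypeMatrix(g, bp = c(1000L, 500000L, 990000L))
  st <- mkStats(c("s1", "s2", "s3"), 1, c(1000L, 500000L, 990000L),
                p = c(0.005, 0.25, 0.60), beta = c(0.5, -1, 2))
  prof <- scorePRS(gm, st, thresholds = c(0.01, 0.3, 1))
  sc <- prof@scores
  expect_equal(sc[, 1], c(i1 = 0 * 0.5, i2 = 1 * 0.5))
  expect_equal(sc[, 2], c(i1 = 0 - 2, i2 = 0.5 - 1))
  expect_equal(sc[, 3], c(i1 = -2 + 2 * 1, i2 = -0.5 + 2 * 2))
  expect_equal(prof@nSnps, c(1L, 2L, 3L))
  # all-zero effects score zero; a single unit effect counts alleles
  st0 <- st; st0$beta <- 0
  expect_true(all(scorePRS(gm, st0)@scores == 0))
  st1 <- mkStats("s2", 1, 500000L, 0.5, beta = 1)
  expect_equal(scorePRS(gm, st1)@scores[, 100], g[, "s2"],
               ignore_attr = TRUE)
})

test_that("scoring is linear in the effect sizes and clumping only
          removes SNPs, never reweights them", {
  ped <- simulatePedigree(0, 0, nSingletons = 150, seed = 6)
  gm <- simulateGenotypes(ped, 40, ldBlockSize = 4, ldRho = 0.7,
                          seed = 7)
  set.seed(8)
  st <- snpMap(gm)
  st$se <- 1; st$p <- runif(40); st$n <- 500
  b1 <- rnorm(40); b2 <- rnorm(40)
  sc <- function(b) {
    st$beta <- b
    scorePRS(gm, st)@scores
  }
  expect_equal(sc(b1 + b2), sc(b1) + sc(b2), tolerance = 1e-12)
  st$beta <- b1
  cl <- clumpSumstats(st, gm)
  full <- scorePRS(gm, st)@scores[, 100]
  pruned <- scorePRS(gm, cl)@scores[, 100]
  removed <- setdiff(st$snp, cl$snp)
  manual <- full - drop(genotypes(gm)[, removed, drop = FALSE] %*%
                          st$beta[match(removed, st$snp)])
  expect_equal(pruned, manual, tolerance = 1e-12)
})

test_that("strand-ambiguous SNPs are dropped and swapped alleles flip
          the effect sign", {
  g <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2,
              dimnames = list(c("i1", "i2", "i3"), c("s1", "s2")))
  gm <- makeGenotypeMatrix(g, bp = c(1000L, 600000L),
                           a1 = c("A", "C"), a2 = c("G", "T"))
  # s1 swapped (effect allele = target other allele), s2 matching
  st <- data.frame(snp = c("s1", "s2"), chr = 1,
                   bp = c(1000L, 600000L),
                   a1 = c("G", "C"), a2 = c("A", "T"),
                   beta = c(1, 1), se = 1, p = c(0.5, 0.5), n = 100,
                   stringsAsFactors = FALSE)
  sc <- scorePRS(gm, st)@scores[, 100]
  # swapped s1 contributes -(dosage) ... i.e. dosage of the other allele
  expect_equal(unname(sc), -g[, "s1"] + g[, "s2"], ignore_attr = TRUE)
  stAmb <- st
  stAmb$a1 <- c("A", "C"); stAmb$a2 <- c("T", "G")  # A/T and C/G
  expect_error(suppressMessages(scorePRS(gm, stAmb)), "no SNPs overlap")
})

test_that("the best threshold maximises incremental r2 by construction
          and is found on a shared-architecture simulation", {
  ped <- simulatePedigree(150, 2, seed = 9)
  gm <- simulateGenotypes(ped, 600, seed = 10)
  ph <- simulatePhenotypes(ped, gm, varG = 0.5, nCausal = 60, seed = 11)
  disco <- simulateDiscoveryStats(gm, attr(ph, "effects"), 20000,
                                  seed = 12)
  K <- buildPedigreeMatrix(ped)
  prof <- scorePRS(gm, clumpSumstats(disco, gm))
  prof <- bestThreshold(prof, ph$pheno, NULL, K)
  r2 <- attr(prof, "r2")
  expect_equal(prof@bestR2, max(r2))
  expect_true(all(prof@bestR2 >= r2))
  expect_gt(prof@bestR2, 0.05)  # real signal found
})

test_that("mixed-model association reduces to OLS on singleton
          pedigrees and keeps its size under the null", {
  ped <- simulatePedigree(0, 0, nSingletons = 200, seed = 13)
  K <- buildPedigreeMatrix(ped)   # identity
  set.seed(14)
  y <- rnorm(200); x <- rnorm(200); Xc <- cbind(1, rnorm(200))
  res <- prsAssoc(y, x, Xc, K)
  ols <- summary(lm(y ~ Xc - 1 + scale(x)))
  expect_equal(res$beta, coef(ols)[3, 1], tolerance = 1e-8)
  expect_equal(res$se, coef(ols)[3, 2], tolerance = 1e-6)
  # size under the null with real family structure
  ped2 <- simulatePedigree(100, 0, seed = 15)
  K2 <- buildPedigreeMatrix(ped2)
  set.seed(16)
  pv <- replicate(120, prsAssoc(rnorm(200), rnorm(200), NULL, K2)$p)
  expect_lte(mean(pv < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 120))
})

test_that("a discovery-derived score transfers to a genetically
          correlated target trait with positive effect", {
  ped <- simulatePedigree(250, 2, seed = 17)
  gm <- simulateGenotypes(ped, 800, seed = 18)
  pair <- simulateTraitPair(ped, gm, rG = 0.5,
                            spec1 = list(varG = 0.4),
                            spec2 = list(varG = 0.4),
                            nCausal = 100, seed = 19)
  disco <- simulateDiscoveryStats(gm, attr(pair$pheno2, "effects"),
                                  50000, seed = 20)
  K <- buildPedigreeMatrix(ped)
  prof <- scorePRS(gm, clumpSumstats(disco, gm))
  prof <- bestThreshold(prof, pair$pheno1$pheno, NULL, K)
  sc <- prof@scores[, match(prof@bestThreshold, prof@thresholds)]
  res <- prsAssoc(pair$pheno1$pheno, sc, NULL, K)
  expect_gt(res$beta, 0)
  expect_lt(res$p, 0.01)
})
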