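test_that("clean genotypes pass every QC filter untouched", {
  set.seed(1)
  g <- matrix(rbinom(200 * 50, 2, 0.25), 200, 50)
  gm <- makeGenotypeMatrix(g)
  out <- qcGenotypes(gm)
  expect_equal(out$report$snpsRemaining, 50)
  expect_equal(out$report$snpsRemovedMaf, 0)
  expect_equal(out$report$snpsRemovedHwe, 0)
  expect_equal(out$report$individualsRemovedMissing, 0)
})

test_that("a rare variant below one percent frequency is removed", {
  set.seed(2)
  g <- matrix(rbinom(600 * 10, 2, 0.3), 600, 10)
  g[, 4] <- rbinom(600, 2, 0.005)
  out <- qcGenotypes(makeGenotypeMatrix(g))
  expect_equal(out$report$snpsRemovedMaf, 1)
  expect_false("s4" %in% snpMap(out$genotypes)$snp)
})

test_that("a planted-violations panel matches brute-force re-application
          of each rule", {
  set.seed(3)
  n <- 300
  g <- matrix(rbinom(n * 100, 2, runif(100, 0.05, 0.45)), n, 100,
              byrow = TRUE)
  g[sample(length(g), 400)] <- NA             # scattered missingness
  g[, 7] <- c(rbinom(n - 20, 2, 0.2), rep(NA, 20))   # low call rate
  g[, 13] <- rbinom(n, 2, 0.004)              # rare
  g[, 21] <- sample(c(0, 2), n, replace = TRUE)      # het deficit
  g[1, ] <- c(rep(NA, 30), rbinom(70, 2, 0.3))       # bad individual
  gm <- makeGenotypeMatrix(g)
  out <- qcGenotypes(gm, callrateMin = 0.95, indivMissingMax = 0.2,
                     mafMin = 0.01, hwePMin = 1e-6)

  # brute force, same order: individuals -> call rate -> MAF -> HWE
  keepInd <- rowMeans(is.na(g)) < 0.2
  gg <- g[keepInd, ]
  keep1 <- colMeans(!is.na(gg)) >= 0.95
  gg <- gg[, keep1]
  p <- colMeans(gg, na.rm = TRUE) / 2
  keep2 <- pmin(p, 1 - p) >= 0.01
  gg <- gg[, keep2]
  hwe <- apply(gg, 2, function(x)
    hweOracle(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
              sum(x == 2, na.rm = TRUE)))
  gg <- gg[, hwe > 1e-6]
  expect_equal(out$report$snpsRemaining, ncol(gg))
  expect_equal(out$report$individualsRemovedMissing, sum(!keepInd))
  expect_equal(genotypes(out$genotypes), gg, ignore_attr = TRUE)
})

test_that("removing every SNP is an explicit error, not empty success", {
  g <- matrix(rbinom(100 * 5, 2, 0.003), 100, 5)
  expect_error(qcGenotypes(makeGenotypeMatrix(g)), "every SNP")
})

test_that("the exact HWE test agrees with direct enumeration", {
  cases <- list(c(30, 40, 30), c(80, 15, 5), c(5, 90, 5),
                c(200, 0, 10), c(50, 50, 0), c(12, 1, 12))
  for (cs in cases)
    expect_equal(hweExactP(cs[1], cs[2], cs[3]),
                 hweOracle(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  expect_equal(hweExactP(10, 0, 0), 1)  # monomorphic
})

test_that("the GRM formula reproduces the hand-worked single-SNP case", {
  g <- matrix(c(0, 1, 2), 3, 1,
              dimnames = list(c("a", "b", "c"), "s1"))
  A <- relValues(buildGRM(makeGenotypeMatrix(g)))
  expect_equal(diag(A), c(a = 2, b = 0, c = 2))
  expect_equal(A["a", "c"], -2)
  expect_equal(A["a", "b"], 0)
})

test_that("the GRM equals a double-loop brute force, with and without
          missing genotypes", {
  set.seed(4)
  g <- matrix(rbinom(50 * 200, 2, runif(200, 0.1, 0.45)), 50, 200,
              byrow = TRUE)
  gm <- makeGenotypeMatrix(g)
  expect_equal(relValues(buildGRM(gm)), grmOracle(g),
               tolerance = 1e-10, ignore_attr = TRUE)
  gNA <- g
  gNA[sample(length(gNA), 300)] <- NA
  expect_equal(relValues(buildGRM(makeGenotypeMatrix(gNA))),
               grmOracle(gNA), tolerance = 1e-10, ignore_attr = TRUE)
  gm2 <- makeGenotypeMatrix(cbind(g, 0))
  expect_error(buildGRM(gm2), "monomorphic")
})

test_that("on a large unrelated panel the GRM concentrates at identity", {
  ped <- simulatePedigree(0, 0, nSingletons = 800, seed = 5)
  gm <- simulateGenotypes(ped, 4000, seed = 6)
  A <- relValues(buildGRM(gm))
  n <- nrow(A)
  expect_lt(abs(mean(diag(A)) - 1), 0.02)
  off <- A[upper.tri(A)]
  # sample-frequency centring makes every row sum to zero, so the mean
  # off-diagonal is exactly -mean(diag)/(n - 1); around that centre the
  # entries scatter with variance ~ 1/m
  expect_equal(mean(off), -mean(diag(A)) / (n - 1), tolerance = 1e-10)
  expect_lt(abs(mean(off)), 0.005)
  expect_lt(abs(sd(off) - 1 / sqrt(4000)), 0.005)
})

test_that("pedigree relationships reproduce the textbook coefficients
          and the path-counting oracle", {
  ped <- threeGenPedigree()
  A <- relValues(buildPedigreeMatrix(ped))
  expect_equal(A["gpa", "s1"], 0.5)    # parent-offspring
  expect_equal(A["s1", "s2"], 0.5)     # full sibs
  expect_equal(A["gpa", "c1"], 0.25)   # grandparent-grandchild
  expect_equal(A["c1", "c2"], 0.125)   # first cousins
  expect_equal(A["s2", "c1"], 0.25)    # avuncular
  expect_equal(A["w1", "w2"], 0)       # married-in founders
  expect_equal(diag(A), rep(1, 8), ignore_attr = TRUE)

  ped2 <- simulatePedigree(6, c(`1` = .4, `2` = .4, `3` = .2), 2,
                           seed = 7)
  expect_equal(relValues(buildPedigreeMatrix(ped2)),
               kinshipOracle(ped2), tolerance = 1e-12)
  expect_equal(relValues(buildPedigreeMatrix(ped)), kinshipOracle(ped),
               tolerance = 1e-12)
})

test_that("environment matrices enumerate a four-person family exactly
          and nest as couple/sib within family", {
  ped <- simulatePedigree(1, 2, seed = 8)
  env <- buildEnvMatrices(ped)
  expect_equal(nNonzeroOffdiag(env$C), 2)   # one spouse pair
  expect_equal(nNonzeroOffdiag(env$S), 2)   # one sib pair
  expect_equal(nNonzeroOffdiag(env$F), 12)  # all 6 pairs of 4 members
  for (m in env) expect_equal(diag(relValues(m)), rep(1, 4),
                              ignore_attr = TRUE)
  # support nesting on a mixed pedigree
  ped2 <- simulatePedigree(10, c(`0` = .3, `2` = .4, `3` = .3), 5,
                           seed = 9)
  env2 <- buildEnvMatrices(ped2)
  Fm <- relValues(env2$F)
  expect_true(all(Fm[relValues(env2$C) == 1] == 1))
  expect_true(all(Fm[relValues(env2$S) == 1] == 1))
})

test_that("a GRM built over a family cohort tracks the pedigree
          expectation", {
  ped <- simulatePedigree(100, 2, seed = 10)
  gm <- simulateGenotypes(ped, 20000, seed = 11)
  G <- relValues(buildGRM(gm))
  K <- relValues(buildPedigreeMatrix(ped))
  ut <- upper.tri(G)
  expect_gt(cor(G[ut], K[ut]), 0.8)
})

test_that("bending makes a singular structure factorable", {
  ped <- simulatePedigree(50, 0, seed = 12)
  C <- buildEnvMatrices(ped, "C")$C
  expect_error(chol(relValues(C)), "not positive definite|leading minor")
  expect_silent(chol(relValues(bendMatrix(C))))
})
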