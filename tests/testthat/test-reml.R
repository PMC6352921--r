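test_that("the identity-only model reproduces the OLS residual variance
          with the REML denominator", {
  set.seed(1)
  n <- 120
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  y <- drop(X %*% c(1, 0.5, -0.3)) + rnorm(n, sd = 1.3)
  fit <- remlFit(y, X, list())
  ols <- lm(y ~ X - 1)
  expect_equal(fit@varcomps[["E"]], sum(resid(ols)^2) / (n - 3),
               tolerance = 1e-8)
  expect_equal(estimates(fit), c(E = 1))
})

test_that("a balanced sibling design recovers the ANOVA closed-form
          components", {
  set.seed(2)
  s <- 60; k <- 4                       # 60 sibships of 4
  grp <- rep(seq_len(s), each = k)
  sigS <- 0.7; sigE <- 1.4
  y <- rnorm(s)[grp] * sqrt(sigS) + rnorm(s * k, sd = sqrt(sigE))
  # sibling-environment block structure
  M <- diag(1, s * k)
  for (g in seq_len(s)) M[grp == g, grp == g] <- 1
  dimnames(M) <- list(seq_len(s * k), seq_len(s * k))
  S <- new("RelationshipMatrix", component = "S", values = M)
  fit <- remlFit(y, matrices = list(S))
  gm <- tapply(y, grp, mean)
  msb <- k * sum((gm - mean(y))^2) / (s - 1)
  msw <- sum((y - gm[grp])^2) / (s * (k - 1))
  expect_equal(fit@varcomps[["S"]], (msb - msw) / k, tolerance = 1e-5)
  expect_equal(fit@varcomps[["E"]], msw, tolerance = 1e-5)
})

test_that("the boundary-mixture likelihood ratio test follows the half
          chi-square convention", {
  mkfit <- function(ll, comps) {
    est <- setNames(rep(0.1, length(comps) + 1), c(comps, "E"))
    new("VarianceFit", estimates = est, se = est, varcomps = est,
        varcompSE = est, loglik = ll,
        waldP = setNames(rep(0.5, length(comps)), comps),
        lrtP = setNames(rep(NA_real_, length(comps)), comps),
        converged = TRUE, constrained = TRUE, n = 10L, vp = 1)
  }
  full <- mkfit(-100, c("G", "C"))
  same <- mkfit(-100, "G")
  expect_equal(lrtVariance(full, same)$statistic, 0)
  expect_equal(lrtVariance(full, same)$p, 0.5)
  red <- mkfit(-100 - 3.84 / 2, "G")
  expect_equal(lrtVariance(full, red)$p,
               0.5 * pchisq(3.84, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(lrtVariance(full, red)$p, 0.025, tolerance = 1e-3)
  expect_error(lrtVariance(same, full), "not nested")
  expect_error(lrtVariance(full, mkfit(-99, c("F", "K"))), "not nested")
})

test_that("the boundary LRT holds its size on a null component", {
  set.seed(3)
  ped <- simulatePedigree(100, 0, seed = 30)   # 200 individuals
  C <- buildEnvMatrices(ped, "C")$C
  pvals <- replicate(200, {
    y <- rnorm(200)
    f1 <- remlFit(y, matrices = list(C))
    f0 <- remlFit(y, matrices = list())
    lrtVariance(f1, f0)$p
  })
  # type-I error at alpha = 0.05 within binomial slack
  expect_lte(mean(pvals < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("REML estimates are invariant to reordering individuals and
          component matrices", {
  ped <- simulatePedigree(120, 1, seed = 4)
  gm <- simulateGenotypes(ped, 1500, seed = 5)
  ph <- simulatePhenotypes(ped, gm, varG = 0.3, varC = 0.25,
                           nCausal = 200, seed = 6)
  G <- buildGRM(gm)
  C <- buildEnvMatrices(ped, "C")$C
  f1 <- remlFit(ph$pheno, matrices = list(G, C))
  f2 <- remlFit(ph$pheno, matrices = list(C, G))
  expect_equal(estimates(f1)[c("G", "C", "E")],
               estimates(f2)[c("G", "C", "E")], tolerance = 1e-6)
  perm <- sample(length(ph$pheno))
  Gp <- new("RelationshipMatrix", component = "G",
            values = relValues(G)[perm, perm])
  Cp <- new("RelationshipMatrix", component = "C",
            values = relValues(C)[perm, perm])
  f3 <- remlFit(ph$pheno[perm], matrices = list(Gp, Cp))
  expect_equal(estimates(f1), estimates(f3), tolerance = 1e-5)
  expect_equal(f1@loglik, f3@loglik, tolerance = 1e-5)
})

test_that("single-component designs are recovered without bias", {
  # one generating component at a time; the mean over replicates must
  # sit within two Monte-Carlo standard errors of the truth
  designs <- list(C = list(varC = 0.3), S = list(varS = 0.3),
                  F = list(varF = 0.3), K = list(varK = 0.3))
  ped <- simulatePedigree(350, 2, seed = 7)    # 1400 individuals
  env <- buildEnvMatrices(ped)
  K <- buildPedigreeMatrix(ped)
  mats <- list(C = env$C, S = env$S, F = env$F, K = K)
  for (lab in names(designs)) {
    ests <- vapply(1:8, function(r) {
      ph <- do.call(simulatePhenotypes,
                    c(list(ped = ped, seed = 100 * r + match(lab, names(designs))),
                      designs[[lab]]))
      estimates(remlFit(ph$pheno, matrices = mats[lab]))[[lab]]
    }, numeric(1))
    mcse <- sd(ests) / sqrt(length(ests))
    expect_lt(abs(mean(ests) - 0.3), 2 * mcse + 0.02)
  }
})

test_that("missing phenotypes are dropped with a message and collinear
          covariates are named", {
  ped <- simulatePedigree(50, 0, seed = 8)
  C <- buildEnvMatrices(ped, "C")$C
  y <- simulatePhenotypes(ped, varC = 0.3, seed = 9)$pheno
  y[1:5] <- NA
  expect_message(fit <- remlFit(y, matrices = list(C)), "dropping 5")
  expect_equal(fit@n, 95L)
  X <- cbind(a = rep(1, 100), b = rnorm(100))
  X <- cbind(X, c = X[, "b"] * 2)
  expect_error(remlFit(rnorm(100), X, list(C)), "collinear.*c")
})

test_that("Wald and boundary-LRT p-values rank a strong and a null
          component identically", {
  ped <- simulatePedigree(400, 2, seed = 10)
  env <- buildEnvMatrices(ped)
  ph <- simulatePhenotypes(ped, varC = 0.35, seed = 11)
  fit <- remlFit(ph$pheno, matrices = list(env$C, env$S), lrt = TRUE)
  expect_lt(fit@waldP[["C"]], fit@waldP[["S"]])
  expect_lt(fit@lrtP[["C"]], fit@lrtP[["S"]])
})
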