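# shared-group effect: one N(0,1) draw per group, one group per
# individual outside any sharing set, rescaled to the target variance
groupEffect <- function(group, target) {
  u <- rnorm(length(unique(group)))
  names(u) <- unique(group)
  scaleTo(u[group], target)
}

# centre and rescale so the sample variance is exactly `target`
scaleTo <- function(x, target) {
  x <- x - mean(x)
  v <- var(x)
  if (v <= 0) stop("degenerate component: zero variance before scaling")
  x * sqrt(target / v)
}

# assemble y = g_snp + g_ped + f + c + s + e on the (sorted) pedigree
# rows; optional preset causal set/effects for correlated trait pairs
buildTraitComponents <- function(ped, geno, varG, varK, varF, varC,
                                 varS, nCausal, causal = NULL, b = NULL) {
  fr <- c(G = varG, K = varK, F = varF, C = varC, S = varS)
  if (any(fr < 0)) stop("variance fractions must be non-negative")
  if (sum(fr) > 1) stop("variance fractions sum to more than 1")
  p <- ped@ped
  n <- nrow(p)
  y <- numeric(n)
  eff <- NULL

  if (varG > 0) {
    if (is.null(geno)) stop("varG > 0 requires genotypes")
    X <- geno@genotypes
    m <- ncol(X)
    if (is.null(causal)) {
      nCausal <- min(nCausal, m)
      causal <- sort(sample.int(m, nCausal))
    }
    if (is.null(b)) b <- rnorm(length(causal))
    # subset causal columns first, then align rows (avoids copying the
    # full panel)
    Z <- X[, causal, drop = FALSE]
    if (!identical(rownames(Z), p$iid))
      Z <- Z[match(p$iid, rownames(Z)), , drop = FALSE]
    Z <- scale(Z)
    g <- drop(Z %*% b)
    sc <- sqrt(varG / var(g - mean(g)))
    y <- y + scaleTo(g, varG)
    eff <- data.frame(snp = colnames(X)[causal], beta = b * sc,
                      stringsAsFactors = FALSE)
  }
  if (varK > 0) {
    A <- relValues(buildPedigreeMatrix(ped))
    L <- chol(A + diag(1e-8, n))
    y <- y + scaleTo(drop(crossprod(L, rnorm(n))), varK)
  }
  if (varF > 0) y <- y + groupEffect(p$fid, varF)
  if (varC > 0) {
    grp <- ifelse(p$couple == "0", paste0("solo", seq_len(n)), p$couple)
    y <- y + groupEffect(grp, varC)
  }
  if (varS > 0) {
    grp <- ifelse(p$pat == "0", paste0("fnd", seq_len(n)),
                  paste(p$fid, p$pat, p$mat))
    y <- y + groupEffect(grp, varS)
  }
  resid <- 1 - sum(fr)
  if (resid > 0) y <- y + scaleTo(rnorm(n), resid)
  list(y = y, effects = eff)
}

#' Simulate a multi-component phenotype on a family cohort
#'
#' Generates \eqn{y = g_{SNP} + g_{ped} + f + c + s + e} with the five
#' named variance fractions as ground truth: a SNP-genetic component
#' from \code{nCausal} causal SNPs with standardised effects, a residual
#' pedigree-genetic component drawn with covariance proportional to the
#' numerator relationship matrix, shared-environment components drawn
#' once per nuclear family / couple / full sibship, and an iid residual.
#' Each realised component is rescaled to carry exactly its target
#' fraction of unit phenotypic variance, so the generating values are
#' exact conditions rather than expectations.  Binary traits are
#' generated on this liability scale and thresholded at the
#' \code{1 - prevalence} quantile.
#'
#' @param ped a [Pedigree-class].
#' @param geno a [GenotypeMatrix-class]; required when \code{varG > 0}.
#' @param varG,varK,varF,varC,varS variance fractions (each >= 0,
#'   summing to <= 1); the residual fraction is 1 minus their sum.
#' @param nCausal number of causal SNPs for the SNP component.
#' @param binary if \code{TRUE}, threshold the liability.
#' @param prevalence population prevalence used for the threshold.
#' @param seed integer seed.
#' @return \code{data.frame} with \code{fid}, \code{iid}, \code{pheno}
#'   and (for binary traits) \code{liability}; attribute
#'   \code{"effects"} holds the causal SNP IDs and their standardised
#'   effect sizes.
#' @examples
#' ped <- simulatePedigree(50, 2, seed = 1)
#' gm <- simulateGenotypes(ped, 100, seed = 2)
#' ph <- simulatePhenotypes(ped, gm, varG = 0.3, varC = 0.2,
#'                          nCausal = 50, seed = 3)
#' var(ph$pheno)
#' @export
simulatePhenotypes <- function(ped, geno = NULL, varG = 0, varK = 0,
                               varF = 0, varC = 0, varS = 0,
                               nCausal = 100, binary = FALSE,
                               prevalence = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (binary && (prevalence <= 0 || prevalence >= 1))
    stop("prevalence must lie in (0, 1)")
  cmp <- buildTraitComponents(ped, geno, varG, varK, varF, varC, varS,
                              nCausal)
  p <- ped@ped
  out <- data.frame(fid = p$fid, iid = p$iid, pheno = cmp$y,
                    stringsAsFactors = FALSE)
  if (binary) {
    out$liability <- cmp$y
    out$pheno <- as.numeric(cmp$y > qnorm(1 - prevalence))
  }
  attr(out, "effects") <- cmp$effects
  out
}

#' Simulate a pair of genetically correlated traits
#'
#' Draws two phenotypes on the same cohort whose SNP-genetic components
#' have correlation \code{rG}: causal effects for trait 2 are
#' \eqn{b_2 = r_G b_1 + \sqrt{1 - r_G^2}\,\eta} on the shared causal
#' set, with \code{causalOverlap} controlling how many causal SNPs the
#' traits share.  Non-genetic components are drawn independently per
#' trait.
#'
#' @param ped,geno cohort and genotypes.
#' @param rG genetic correlation in [-1, 1].
#' @param causalOverlap fraction of causal SNPs shared between traits.
#' @param spec1,spec2 named lists of arguments understood by
#'   [simulatePhenotypes()] (variance fractions, \code{binary},
#'   \code{prevalence}).
#' @param nCausal causal SNP count per trait.
#' @param seed integer seed.
#' @return list with elements \code{pheno1} and \code{pheno2}, each as
#'   returned by [simulatePhenotypes()].
#' @export
simulateTraitPair <- function(ped, geno, rG, causalOverlap = 1,
                              spec1 = list(varG = 0.2),
                              spec2 = list(varG = 0.2),
                              nCausal = 100, seed = NULL) {
  if (abs(rG) > 1) stop("|rG| must be <= 1")
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(geno@genotypes)
  nCausal <- min(nCausal, m)
  nShared <- round(causalOverlap * nCausal)
  pool <- sample.int(m, 2 * nCausal - nShared)
  shared <- pool[seq_len(nShared)]
  c1 <- sort(c(shared, pool[nShared + seq_len(nCausal - nShared)]))
  c2 <- sort(c(shared, pool[nCausal + seq_len(nCausal - nShared)]))
  b1 <- setNames(rnorm(nCausal), as.character(c1))
  b2 <- setNames(rnorm(nCausal), as.character(c2))
  sh <- as.character(shared)
  b2[sh] <- rG * b1[sh] + sqrt(1 - rG^2) * b2[sh]

  mk <- function(causal, b, spec) {
    getv <- function(nm, d = 0) if (is.null(spec[[nm]])) d else spec[[nm]]
    cmp <- buildTraitComponents(ped, geno,
                                varG = getv("varG", 0.2),
                                varK = getv("varK"), varF = getv("varF"),
                                varC = getv("varC"), varS = getv("varS"),
                                nCausal = length(causal),
                                causal = causal, b = unname(b))
    p <- ped@ped
    out <- data.frame(fid = p$fid, iid = p$iid, pheno = cmp$y,
                      stringsAsFactors = FALSE)
    if (isTRUE(spec$binary)) {
      prev <- getv("prevalence", 0.5)
      out$liability <- cmp$y
      out$pheno <- as.numeric(cmp$y > qnorm(1 - prev))
    }
    attr(out, "effects") <- cmp$effects
    out
  }
  list(pheno1 = mk(c1, b1, spec1), pheno2 = mk(c2, b2, spec2))
}

#' Simulate discovery-GWAS summary statistics for known causal effects
#'
#' Emulates an external discovery GWAS of size \code{nDiscovery} on a
#' trait whose true standardised per-SNP effects are those attached by
#' the phenotype simulator: the estimated effect is the true effect plus
#' \eqn{N(0, 1/n)} sampling noise, the standard error is
#' \eqn{1/\sqrt{n}} (standardised genotypes and trait), and p-values are
#' two-sided normal tails.  Per-allele effects are recovered by dividing
#' by each SNP's dosage standard deviation in the reference panel.
#'
#' @param geno reference [GenotypeMatrix-class] supplying the SNP map
#'   and dosage scales.
#' @param effects \code{data.frame(snp, beta)} of true standardised
#'   effects (other SNPs have true effect 0), as returned in the
#'   \code{"effects"} attribute of [simulatePhenotypes()].
#' @param nDiscovery discovery sample size.
#' @param seed integer seed.
#' @return summary-statistics \code{data.frame} (columns \code{snp},
#'   \code{chr}, \code{bp}, \code{a1}, \code{a2}, \code{beta},
#'   \code{se}, \code{p}, \code{n}).
#' @export
simulateDiscoveryStats <- function(geno, effects, nDiscovery,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- geno@map
  m <- nrow(map)
  b <- setNames(numeric(m), map$snp)
  if (!is.null(effects)) b[effects$snp] <- effects$beta
  bhat <- b + rnorm(m, 0, 1 / sqrt(nDiscovery))
  se <- rep(1 / sqrt(nDiscovery), m)
  z <- bhat / se
  sds <- apply(geno@genotypes, 2, sd)
  sds[sds == 0] <- 1
  data.frame(snp = map$snp, chr = map$chr, bp = map$bp,
             a1 = map$a1, a2 = map$a2,
             beta = unname(bhat / sds), se = se / sds,
             p = 2 * pnorm(-abs(z)), n = nDiscovery,
             stringsAsFactors = FALSE)
}

#' Simulate paired GWAS summary statistics with known heritability and
#' genetic correlation
#'
#' Draws per-SNP z-scores for two traits directly from the polygenic
#' expectation used by LD score regression:
#' \eqn{E[z_{1j}^2] = 1 + n_1 h^2_1 \ell_j / m} and
#' \eqn{E[z_{1j} z_{2j}] = r_G \sqrt{h^2_1 h^2_2}\sqrt{n_1 n_2}\,
#' \ell_j / m} for non-overlapping samples, giving calibrated inputs for
#' heritability and genetic-correlation estimation.
#'
#' @param n sample size (length 1 or 2 for the two traits).
#' @param m number of SNPs.
#' @param h2 SNP heritability in [0, 1] (length 1 or 2).
#' @param rG genetic correlation in [-1, 1].
#' @param ldScores per-SNP LD scores (default all 1, i.e. linkage
#'   equilibrium).
#' @param seed integer seed.
#' @return list of two summary-statistics \code{data.frame}s (columns
#'   as in [simulateDiscoveryStats()]).
#' @examples
#' ss <- simulateSumstats(2e4, 5000, h2 = 0.3, rG = 0.5, seed = 1)
#' mean((ss[[1]]$beta / ss[[1]]$se)^2)  # ~ 1 + n h2 / m = 2.2
#' @export
simulateSumstats <- function(n, m, h2, rG = 0, ldScores = NULL,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- rep(n, length.out = 2)
  h2 <- rep(h2, length.out = 2)
  if (any(h2 < 0 | h2 > 1)) stop("h2 must lie in [0, 1]")
  if (abs(rG) > 1) stop("|rG| must be <= 1")
  l <- if (is.null(ldScores)) rep(1, m) else rep(ldScores, length.out = m)
  v1 <- 1 + n[1] * h2[1] * l / m
  v2 <- 1 + n[2] * h2[2] * l / m
  cv <- rG * sqrt(h2[1] * h2[2]) * sqrt(n[1] * n[2]) * l / m
  e1 <- rnorm(m); e2 <- rnorm(m)
  z1 <- sqrt(v1) * e1
  z2 <- (cv / sqrt(v1)) * e1 + sqrt(pmax(v2 - cv^2 / v1, 1e-12)) * e2
  mkdf <- function(z, nn) data.frame(
    snp = sprintf("snp%06d", seq_len(m)), chr = 1L,
    bp = 10000L * seq_len(m), a1 = "A", a2 = "G",
    beta = z / sqrt(nn), se = 1 / sqrt(nn),
    p = 2 * pnorm(-abs(z)), n = nn, stringsAsFactors = FALSE)
  list(mkdf(z1, n[1]), mkdf(z2, n[2]))
}
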