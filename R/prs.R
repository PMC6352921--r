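#' LD clumping of summary statistics
#'
#' Greedy clump-based pruning: proceeding through SNPs by ascending
#' p-value, the most significant unclaimed SNP becomes an index SNP and
#' every unclaimed SNP on the same chromosome within \code{windowKb}
#' kilobases whose genotypic \eqn{r^2} with it exceeds \code{r2Max} is
#' removed.  Ties in p are broken by (chromosome, position) order.
#' SNPs absent from the reference panel are dropped with a message.
#'
#' @param stats summary-statistics \code{data.frame} (columns
#'   \code{snp}, \code{chr}, \code{bp}, \code{p}, ...).
#' @param ref reference [GenotypeMatrix-class] supplying LD.
#' @param r2Max \eqn{r^2} threshold (default 0.1).
#' @param windowKb window half-width in kb (default 250; the window is
#'   \code{bp} +/- \code{windowKb * 1000}, inclusive).
#' @return the retained rows of \code{stats}, ordered by (chr, bp).
#' @export
clumpSumstats <- function(stats, ref, r2Max = 0.1, windowKb = 250) {
  inref <- stats$snp %in% colnames(ref@genotypes)
  if (any(!inref))
    message("dropping ", sum(!inref), " SNPs absent from the reference")
  st <- stats[inref, , drop = FALSE]
  if (nrow(st) == 0) return(st)
  ord <- order(st$p, st$chr, st$bp)
  g <- ref@genotypes[, st$snp, drop = FALSE]
  window <- windowKb * 1000
  claimed <- logical(nrow(st))
  index <- logical(nrow(st))
  for (i in ord) {
    if (claimed[i]) next
    index[i] <- TRUE
    claimed[i] <- TRUE
    nb <- which(!claimed & st$chr == st$chr[i] &
                  abs(st$bp - st$bp[i]) <= window)
    if (length(nb)) {
      r2 <- suppressWarnings(cor(g[, i], g[, nb]))^2
      r2[is.na(r2)] <- 0
      claimed[nb[r2 > r2Max]] <- TRUE
    }
  }
  out <- st[index, , drop = FALSE]
  out[order(out$chr, out$bp), , drop = FALSE]
}

# align summary statistics to the target panel's A1 dosage coding:
# flip the sign when effect/other alleles are swapped, drop
# strand-ambiguous (A/T, C/G) and mismatching SNPs
alignAlleles <- function(stats, map) {
  m <- merge(stats, map[, c("snp", "a1", "a2")], by = "snp",
             suffixes = c("", ".target"))
  ambiguous <- paste0(m$a1, m$a2) %in% c("AT", "TA", "CG", "GC")
  same <- m$a1 == m$a1.target & m$a2 == m$a2.target
  flip <- m$a1 == m$a2.target & m$a2 == m$a1.target
  keep <- !ambiguous & (same | flip)
  dropped <- nrow(stats) - sum(keep)
  if (dropped > 0)
    message("dropping ", dropped,
            " SNPs at allele alignment (ambiguous/mismatched/missing)")
  m <- m[keep, , drop = FALSE]
  m$beta[flip[keep]] <- -m$beta[flip[keep]]
  m$a1 <- m$a1.target; m$a2 <- m$a2.target
  m[, setdiff(names(m), c("a1.target", "a2.target")), drop = FALSE]
}

#' Polygenic risk scores over a p-value threshold grid
#'
#' For each threshold t the score of individual i is
#' \eqn{\sum_{j: p_j \le t} \beta_j x_{ij}} over the (already clumped)
#' summary statistics, with alleles aligned to the target coding (sign
#' flipped when the effect allele is the target's other allele,
#' strand-ambiguous SNPs dropped) and missing dosages mean-imputed per
#' SNP.
#'
#' @param geno target [GenotypeMatrix-class].
#' @param stats clumped summary statistics.
#' @param thresholds increasing p-value grid (default 0.01 to 1 in 0.01
#'   steps, endpoints inclusive).
#' @return a [PRSProfile-class].
#' @export
scorePRS <- function(geno, stats, thresholds = seq(0.01, 1, by = 0.01)) {
  st <- alignAlleles(stats, geno@map)
  if (nrow(st) == 0)
    stop("no SNPs overlap between summary statistics and target panel")
  g <- geno@genotypes[, st$snp, drop = FALSE]
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    ix <- which(is.na(g), arr.ind = TRUE)
    g[ix] <- mu[ix[, 2]]
  }
  ord <- order(st$p)
  g <- g[, ord, drop = FALSE]
  st <- st[ord, , drop = FALSE]
  scores <- matrix(0, nrow(g), length(thresholds),
                   dimnames = list(rownames(g), thresholds))
  nSnps <- integer(length(thresholds))
  prev <- 0L
  acc <- numeric(nrow(g))
  for (t in seq_along(thresholds)) {
    upto <- findInterval(thresholds[t], st$p)
    if (upto > prev) {
      jj <- (prev + 1L):upto
      acc <- acc + drop(g[, jj, drop = FALSE] %*% st$beta[jj])
      prev <- upto
    }
    scores[, t] <- acc
    nSnps[t] <- prev
  }
  new("PRSProfile", scores = scores, thresholds = thresholds,
      nSnps = nSnps, bestThreshold = NA_real_, bestR2 = NA_real_)
}

# generalised-least-squares association of one predictor given fixed
# covariances: returns beta, se, Wald conditional F p, incremental r2
glsAssoc <- function(y, x, X, Vi) {
  W <- cbind(X, x)
  WtVi <- crossprod(W, Vi)
  covB <- solve(WtVi %*% W)
  b <- drop(covB %*% (WtVi %*% y))
  k <- ncol(W)
  n <- length(y)
  # conditional residual scale: ~1 when Vi comes from a full REML fit,
  # and exactly the OLS variance when Vi is the identity
  r <- drop(y - W %*% b)
  s2 <- drop(crossprod(r, Vi %*% r)) / (n - k)
  beta <- unname(b[k])
  se <- sqrt(s2 * covB[k, k])
  Fstat <- (beta / se)^2
  p <- pf(Fstat, 1, n - k, lower.tail = FALSE)
  covOnly <- solve(crossprod(X, Vi) %*% X, crossprod(X, Vi) %*% y)
  r2 <- (var(drop(W %*% b)) - var(drop(X %*% covOnly))) / var(y)
  list(beta = beta, se = unname(se), p = unname(p), r2 = unname(r2))
}

# V^{-1} for the pedigree-random-effect model after REML on y ~ X
nullModelVi <- function(y, X, K, bend = 1e-6) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  fit <- remlFit(y, X, list(K))
  s <- fit@varcomps
  V <- s[[1]] * relValues(K) + diag(s[["E"]], n)
  ch <- tryCatch(chol(V), error = function(e)
    chol(V + diag(bend * var(y), n)))
  chol2inv(ch)
}

#' Select the best-fitting PRS threshold
#'
#' For every threshold in the profile, measures the incremental
#' variance explained by the (standardised) score over the
#' covariate-only mixed model with a pedigree random effect, and
#' returns the threshold maximising it (ties broken towards the
#' smallest threshold).  Variance components are estimated once on the
#' covariate-only model and held fixed across the grid.
#'
#' @param profile a [PRSProfile-class].
#' @param y phenotype vector.
#' @param X covariate matrix (intercept added when NULL).
#' @param K pedigree [RelationshipMatrix-class] (NULL for unrelated
#'   samples, reducing to ordinary least squares).
#' @return the profile with \code{bestThreshold}/\code{bestR2} filled;
#'   the per-threshold r2 values are in attribute \code{"r2"}.
#' @export
bestThreshold <- function(profile, y, X = NULL, K = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  Vi <- if (is.null(K)) diag(1, n) else nullModelVi(y, X, K)
  r2 <- vapply(seq_along(profile@thresholds), function(t) {
    s <- profile@scores[, t]
    if (sd(s) == 0) return(0)
    glsAssoc(y, drop(scale(s)), X, Vi)$r2
  }, numeric(1))
  best <- which.max(r2)  # which.max returns the first (smallest) tie
  profile@bestThreshold <- profile@thresholds[best]
  profile@bestR2 <- r2[best]
  attr(profile, "r2") <- r2
  profile
}

#' Mixed-model association of a polygenic score with a trait
#'
#' Fits \eqn{y = Xb + \beta\,\mathrm{PRS} + u + e} with
#' \eqn{u \sim N(0, \sigma^2 K)} a pedigree random effect controlling
#' for family structure, and tests the score by Wald's conditional
#' F-test.  The score (and a continuous trait) should be standardised
#' so the coefficient is in standard-deviation units; for binary traits
#' the estimate can be moved to the liability scale with
#' [liabilityBeta()].
#'
#' @param y trait vector.
#' @param prs score vector (standardised to mean 0, sd 1 internally if
#'   not already).
#' @param X covariate matrix.
#' @param K pedigree [RelationshipMatrix-class]; NULL reduces to OLS.
#' @return list with \code{beta}, \code{se}, \code{r2}, \code{p}.
#' @export
prsAssoc <- function(y, prs, X = NULL, K = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  prs <- drop(scale(prs))
  W <- cbind(X, prs)
  Vi <- if (is.null(K)) diag(1, n) else nullModelVi(y, W, K)
  glsAssoc(y, prs, X, Vi)
}
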