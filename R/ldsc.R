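#' LD scores from a reference panel
#'
#' The LD score of SNP j is \eqn{\ell_j = 1 + \sum_{k \ne j} r^2_{jk,adj}}
#' over SNPs on the same chromosome within \code{windowKb} kilobases,
#' with the small-sample adjustment
#' \eqn{r^2_{adj} = r^2 - (1 - r^2)/(n - 2)} that unbiases the squared
#' sample correlation.
#'
#' @param geno reference [GenotypeMatrix-class].
#' @param windowKb window half-width in kb (default 1000).
#' @return \code{data.frame} with \code{snp}, \code{chr}, \code{bp},
#'   \code{ldScore}.
#' @export
ldScores <- function(geno, windowKb = 1000) {
  map <- geno@map
  g <- geno@genotypes
  n <- nrow(g)
  if (n < 3) stop("need at least 3 individuals for adjusted r^2")
  window <- windowKb * 1000
  l <- numeric(nrow(map))
  for (cc in unique(map$chr)) {
    ix <- which(map$chr == cc)
    Z <- scale(g[, ix, drop = FALSE])
    Z[is.na(Z)] <- 0
    bp <- map$bp[ix]
    lo <- 1L
    hi <- 1L
    mC <- length(ix)
    for (j in seq_len(mC)) {
      while (bp[j] - bp[lo] > window) lo <- lo + 1L
      while (hi < mC && bp[hi + 1L] - bp[j] <= window) hi <- hi + 1L
      nb <- setdiff(lo:hi, j)
      if (length(nb)) {
        r <- drop(crossprod(Z[, j], Z[, nb, drop = FALSE])) / (n - 1)
        r2 <- r^2
        l[ix[j]] <- sum(r2 - (1 - r2) / (n - 2))
      }
    }
  }
  data.frame(snp = map$snp, chr = map$chr, bp = map$bp,
             ldScore = 1 + l, stringsAsFactors = FALSE)
}

# weighted regression of `yv` on `xv` with intercept; returns
# c(intercept, slope)
wreg <- function(yv, xv, w) {
  sw <- sum(w); sx <- sum(w * xv); sy <- sum(w * yv)
  sxx <- sum(w * xv^2); sxy <- sum(w * xv * yv)
  den <- sw * sxx - sx^2
  c((sxx * sy - sx * sxy) / den, (sw * sxy - sx * sy) / den)
}

# delete-one-block jackknife of a statistic computed from per-SNP data
blockJackknife <- function(m, nBlocks, fun) {
  nBlocks <- max(20L, min(nBlocks, m %/% 10L))
  blk <- cut(seq_len(m), nBlocks, labels = FALSE)
  est <- fun(rep(TRUE, m))
  reps <- vapply(seq_len(nBlocks), function(b) fun(blk != b), numeric(1))
  list(est = est,
       se = sqrt((nBlocks - 1) / nBlocks * sum((reps - mean(reps))^2)),
       nBlocks = nBlocks)
}

# two-step heteroskedasticity weights for the chi2 ~ N l / m regression
ldscWeights <- function(chi2, x, l) {
  h0 <- max(0, min(1, wreg(chi2, x, 1 / pmax(l, 1))[2]))
  1 / (pmax(l, 1) * 2 * (1 + h0 * x)^2)
}

#' SNP heritability by LD score regression
#'
#' Regresses per-SNP association \eqn{\chi^2} statistics on
#' \eqn{N \ell_j / m}: under a polygenic model
#' \eqn{E[\chi^2_j] = 1 + N h^2 \ell_j / m}, so the slope estimates
#' \eqn{h^2} while a free intercept absorbs confounding.  Weights are
#' the canonical heteroskedasticity weights with a two-step update;
#' the standard error is a delete-one-block jackknife over contiguous
#' SNP blocks.
#'
#' @param stats summary statistics (\code{snp}, \code{beta}, \code{se},
#'   \code{n}).
#' @param ld LD scores as from [ldScores()].
#' @param nBlocks jackknife blocks (default 200, floored at 20 and
#'   capped so blocks hold >= 10 SNPs).
#' @return list with \code{h2}, \code{se}, \code{intercept},
#'   \code{interceptSE}, \code{nSnps}.
#' @export
ldscH2 <- function(stats, ld, nBlocks = 200) {
  d <- merge(stats, ld[, c("snp", "ldScore")], by = "snp")
  m <- nrow(d)
  if (m < 200) stop("fewer than 200 overlapping SNPs: LD score ",
                    "regression is unidentifiable at this size")
  d <- d[order(match(d$snp, ld$snp)), ]  # contiguous genome order
  chi2 <- (d$beta / d$se)^2
  x <- d$n * d$ldScore / m
  if (var(x) < 1e-12)
    stop("constant regressor (uniform LD scores and sample size): ",
         "the regression slope is unidentifiable")
  w <- ldscWeights(chi2, x, d$ldScore)
  jk <- blockJackknife(m, nBlocks,
                       function(k) wreg(chi2[k], x[k], w[k])[2])
  jkInt <- blockJackknife(m, nBlocks,
                          function(k) wreg(chi2[k], x[k], w[k])[1])
  list(h2 = jk$est, se = jk$se, intercept = jkInt$est,
       interceptSE = jkInt$se, nSnps = m)
}

#' Cross-trait genetic correlation by LD score regression
#'
#' Regresses per-SNP z-score products on
#' \eqn{\sqrt{N_1 N_2}\,\ell_j / m} to estimate the genetic covariance
#' slope, estimates each trait's \eqn{h^2} by [ldscH2()], and reports
#' \eqn{r_G = \mathrm{gencov}/\sqrt{h^2_1 h^2_2}} with a
#' delete-one-block jackknife standard error of the full ratio.  The
#' cross-trait intercept absorbs sample overlap; the expected overlap
#' term defaults to 0 (independent cohorts).
#'
#' @param stats1,stats2 summary statistics for the two traits.
#' @param ld LD scores.
#' @param nBlocks jackknife blocks.
#' @return list with \code{rG}, \code{se}, \code{gencov}, \code{h2_1},
#'   \code{h2_2}, \code{intercept} (cross-trait), \code{nSnps}.  rG is
#'   clamped to [-1.25, 1.25] with a warning outside [-1, 1].
#' @export
ldscRg <- function(stats1, stats2, ld, nBlocks = 200) {
  d <- merge(merge(stats1, stats2, by = "snp",
                   suffixes = c("1", "2")),
             ld[, c("snp", "ldScore")], by = "snp")
  m <- nrow(d)
  if (m < 200) stop("fewer than 200 overlapping SNPs: genetic ",
                    "correlation is unidentifiable at this size")
  d <- d[order(match(d$snp, ld$snp)), ]
  z1 <- d$beta1 / d$se1
  z2 <- d$beta2 / d$se2
  x1 <- d$n1 * d$ldScore / m
  x2 <- d$n2 * d$ldScore / m
  xc <- sqrt(d$n1 * d$n2) * d$ldScore / m
  if (var(xc) < 1e-12)
    stop("constant regressor (uniform LD scores and sample size): ",
         "the regression slope is unidentifiable")
  w1 <- ldscWeights(z1^2, x1, d$ldScore)
  w2 <- ldscWeights(z2^2, x2, d$ldScore)
  wc <- sqrt(w1 * w2)
  rgOf <- function(k) {
    h1 <- wreg(z1[k]^2, x1[k], w1[k])[2]
    h2 <- wreg(z2[k]^2, x2[k], w2[k])[2]
    gc <- wreg((z1 * z2)[k], xc[k], wc[k])[2]
    gc / sqrt(max(h1, 1e-8) * max(h2, 1e-8))
  }
  jk <- blockJackknife(m, nBlocks, rgOf)
  rg <- jk$est
  if (abs(rg) > 1)
    warning("genetic correlation outside [-1, 1]: ", signif(rg, 3))
  rg <- max(-1.25, min(1.25, rg))
  list(rG = rg, se = jk$se,
       gencov = wreg(z1 * z2, xc, wc)[2],
       h2_1 = wreg(z1^2, x1, w1)[2],
       h2_2 = wreg(z2^2, x2, w2)[2],
       intercept = wreg(z1 * z2, xc, wc)[1],
       nSnps = m)
}

#' Z-test comparing two genetic correlations
#'
#' \eqn{Z = (r_1 - r_2)/\sqrt{SE_1^2 + SE_2^2}}; both the one- and
#' two-sided p-values are reported since reporting conventions differ.
#'
#' @param r1,se1,r2,se2 the two estimates and standard errors.
#' @return list with \code{Z}, \code{pOneSided}, \code{pTwoSided}.
#' @examples
#' zDiff(0.25, 0.10, 0.06, 0.07)$Z  # 1.56
#' @export
zDiff <- function(r1, se1, r2, se2) {
  Z <- (r1 - r2) / sqrt(se1^2 + se2^2)
  list(Z = Z, pOneSided = pnorm(abs(Z), lower.tail = FALSE),
       pTwoSided = 2 * pnorm(abs(Z), lower.tail = FALSE))
}
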