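#' Leave-one-chromosome-out mixed-model association
#'
#' For each chromosome c, variance components of
#' \eqn{y = Xb + g + e}, \eqn{g \sim N(0, \sigma^2_g G_{-c})}, are
#' estimated once with a genomic relationship matrix built from all
#' chromosomes except c (avoiding proximal contamination), and every
#' SNP on c is then tested as a fixed effect given those components.
#' The per-chromosome model is solved in the eigenbasis of
#' \eqn{G_{-c}}, where the covariance is diagonal, making each SNP test
#' a weighted regression.
#'
#' @param y phenotype vector, aligned to the rows of \code{geno}.
#' @param X covariate matrix (intercept added when NULL).
#' @param geno [GenotypeMatrix-class] with at least two chromosomes
#'   (with a single chromosome, build the GRM once with [buildGRM()]
#'   and test SNPs against it via [prsAssoc()]-style fits instead).
#' @return summary-statistics \code{data.frame} (\code{snp}, \code{chr},
#'   \code{bp}, \code{a1}, \code{a2}, \code{beta}, \code{se}, \code{p},
#'   \code{n}).
#' @export
mlmaLoco <- function(y, X = NULL, geno) {
  map <- geno@map
  chroms <- unique(map$chr)
  if (length(chroms) < 2)
    stop("leave-one-chromosome-out needs >= 2 chromosomes; ",
         "for a single chromosome use a plain-GRM mixed model ",
         "(buildGRM + a fixed-SNP GLS fit)")
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  g <- geno@genotypes
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    onC <- map$chr == chroms[ci]
    grm <- buildGRM(geno, snps = which(!onC))
    ed <- eigen(relValues(grm), symmetric = TRUE)
    U <- ed$vectors
    d <- pmax(ed$values, 0)
    yt <- drop(crossprod(U, y))
    Xt <- crossprod(U, X)
    # profile REML over the heritability ratio on the diagonal model
    negll <- function(h) {
      w <- h * d + (1 - h)
      Xw <- Xt / w
      XtWX <- crossprod(Xt, Xw)
      b <- solve(XtWX, crossprod(Xw, yt))
      r <- yt - Xt %*% b
      rss <- sum(r^2 / w)
      s2 <- rss / (n - ncol(X))
      0.5 * (sum(log(w)) + determinant(XtWX)$modulus[1] +
               (n - ncol(X)) * log(s2))
    }
    opt <- optimize(negll, c(1e-6, 1 - 1e-6))
    h <- opt$minimum
    w <- h * d + (1 - h)
    Xw <- Xt / w
    XtWX <- crossprod(Xt, Xw)
    bc <- solve(XtWX, crossprod(Xw, yt))
    r <- drop(yt - Xt %*% bc)
    s2 <- sum(r^2 / w) / (n - ncol(X))
    # test each SNP on c as a fixed effect given (h, s2):
    # residualise SNPs against covariates under the weight metric
    gc <- g[, onC, drop = FALSE]
    if (anyNA(gc)) {
      mu <- colMeans(gc, na.rm = TRUE)
      ix <- which(is.na(gc), arr.ind = TRUE)
      gc[ix] <- mu[ix[, 2]]
    }
    St <- crossprod(U, gc)
    Sproj <- St - Xt %*% solve(XtWX, crossprod(Xw, St))
    xwx <- colSums(Sproj^2 / w)
    xwx[xwx <= 0] <- NA  # monomorphic after projection
    xwy <- colSums(Sproj * (r / w))
    beta <- xwy / xwx
    se <- sqrt(s2 / xwx)
    z <- beta / se
    out[[ci]] <- data.frame(
      snp = map$snp[onC], chr = map$chr[onC], bp = map$bp[onC],
      a1 = map$a1[onC], a2 = map$a2[onC],
      beta = beta, se = se, p = 2 * pnorm(-abs(z)), n = n,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chr, res$bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Genomic inflation factor
#'
#' Median-based lambda: the median association \eqn{\chi^2} divided by
#' the null median \eqn{\chi^2_1} quantile (0.455).
#'
#' @param p vector of p-values (or chi-square statistics via
#'   \code{chisq = TRUE}).
#' @param chisq interpret \code{p} as chi-square statistics.
#' @return lambda.
#' @export
genomicInflation <- function(p, chisq = FALSE) {
  x <- if (chisq) p else qchisq(p, 1, lower.tail = FALSE)
  median(x) / qchisq(0.5, 1)
}
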